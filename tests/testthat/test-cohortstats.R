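test_that("agreement statistic follows its definition", {
  expect_equal(bangdiwala_b(diag(c(3, 5, 2, 4))), 1)
  expect_equal(bangdiwala_b(matrix(c(0, 3, 2, 0), 2, 2)), 0)
  expect_equal(bangdiwala_b(matrix(c(2, 1, 1, 2), 2, 2,
                                   byrow = TRUE)), 8 / 18)
  expect_error(bangdiwala_b(matrix(1, 2, 3)), "square")
  expect_error(bangdiwala_b(matrix(0, 3, 3)), "positive")
})

test_that("rating-based exclusion partitions the cohort", {
  rec <- tibble::tibble(id = sprintf("S%d", 1:6),
                        rating_a = c(1L, 1L, 3L, 4L, 4L, NA),
                        rating_b = c(1L, 4L, 3L, 2L, 4L, 2L))
  qc <- qc_exclude(rec)
  expect_identical(qc$kept$id, c("S1", "S3"))
  expect_identical(qc$excluded$id, c("S2", "S4", "S5", "S6"))
  expect_identical(qc$excluded$reason,
                   c(rep("unusable_rating", 3), "unrated"))
  expect_equal(nrow(qc$kept) + nrow(qc$excluded), nrow(rec))

  # property: partition holds under random rating tables
  set.seed(20)
  for (i in 1:20) {
    r <- tibble::tibble(rating_a = sample(c(1:4, NA), 30, replace = TRUE),
                        rating_b = sample(c(1:4, NA), 30, replace = TRUE))
    q <- qc_exclude(r)
    expect_equal(nrow(q$kept) + nrow(q$excluded), 30)
    expect_true(all(q$kept$rating_a != 4 & q$kept$rating_b != 4))
  }
})

test_that("group summary reproduces the Welch formula", {
  d <- tibble::tibble(group = rep(c("ASD", "TD"), each = 3),
                      metric = c(9, 10, 11, 10, 11, 12))
  gs <- group_summary(d, metric)
  # brute-force Welch t
  x <- c(9, 10, 11); y <- c(10, 11, 12)
  t_manual <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(gs$t_statistic, t_manual)
  expect_equal(gs$f_statistic, 1)              # equal spread

  same <- tibble::tibble(group = rep(c("ASD", "TD"), each = 3),
                         metric = rep(c(9, 10, 11), 2))
  gs2 <- group_summary(same, metric)
  expect_equal(gs2$t_statistic, 0)
  expect_equal(gs2$t_p, 1)
  expect_error(group_summary(d[c(1, 4, 5, 6), ], metric), "at least 2")
})

# brute-force Type-II ANOVA oracle built directly on normal equations
anova_oracle <- function(d) {
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    sum((d$y - X %*% beta)^2)
  }
  one <- rep(1, nrow(d))
  X_full <- cbind(one, d$age, d$status, d$age * d$status)
  rss_full <- rss(X_full)
  df_full <- nrow(d) - 4
  mse <- rss_full / df_full
  X_no_int <- X_full[, 1:3]
  rss_no_int <- rss(X_no_int)
  f_int <- (rss_no_int - rss_full) / mse
  # main effects: compare within the no-interaction model set
  f_age <- (rss(cbind(one, d$status)) - rss_no_int) / mse
  f_status <- (rss(cbind(one, d$age)) - rss_no_int) / mse
  rss_null <- rss(matrix(one))
  f_model <- ((rss_null - rss_full) / 3) / mse
  list(model = f_model, age = f_age, status = f_status,
       interaction = f_int, r2 = 1 - rss_full / rss_null)
}

test_that("age/status ANOVA agrees with the normal-equations oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    d <- tibble::tibble(
      group = sample(c("TD", "ASD"), n, replace = TRUE, prob = c(0.6, 0.4)),
      age = runif(n, 60, 192))
    if (length(unique(d$age[d$group == "TD"])) < 2 ||
        length(unique(d$age[d$group == "ASD"])) < 2) next
    d$metric <- 9 + 0.005 * d$age + 0.3 * (d$group == "ASD") + rnorm(n, 0, 1)
    res <- anova_age_status(d, metric, age = age)
    orc <- anova_oracle(tibble::tibble(
      y = d$metric, age = d$age, status = as.numeric(d$group == "ASD")))
    expect_equal(res$statistic[res$term == "model"], orc$model,
                 tolerance = 1e-8)
    expect_equal(res$r.squared[res$term == "model"], orc$r2,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$term == "age"], orc$age,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$term == "status"], orc$status,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$term == "age:status"], orc$interaction,
                 tolerance = 1e-8)
  }
})

test_that("degenerate ANOVA inputs are handled explicitly", {
  d <- tibble::tibble(group = rep(c("TD", "ASD"), each = 10),
                      age = rep(seq(60, 150, by = 10), 2),
                      metric = 5)
  res <- anova_age_status(d, metric, age = age)
  expect_equal(res$r.squared[res$term == "model"], 0)
  expect_true(all(res$p.value == 1))

  exact <- dplyr::mutate(d, metric = 2 + 0.01 * age)
  res2 <- anova_age_status(exact, metric, age = age)
  expect_equal(res2$r.squared[res2$term == "model"], 1, tolerance = 1e-9)

  one_age <- tibble::tibble(group = rep(c("TD", "ASD"), each = 3),
                            age = c(100, 100, 100, 60, 80, 100),
                            metric = rnorm(6))
  expect_error(anova_age_status(one_age, metric, age = age),
               "distinct age")
})

test_that("volume regressions equal squared Pearson correlation", {
  toy <- tibble::tibble(id = sprintf("S%d", 1:5),
                        metric = c(9.1, 10.2, 9.8, 11.0, 10.4))
  vols <- tibble::tibble(id = toy$id,
                         left_putamen = c(4800, 5100, 4950, 5600, 5200),
                         right_putamen = c(5000, 5000, 5000, 5000, 5000))
  res <- volume_regressions(toy, vols, metric)
  r_manual <- cor(toy$metric, vols$left_putamen)
  expect_equal(res$r.squared[res$structure == "left_putamen"], r_manual^2,
               tolerance = 1e-12)
  expect_identical(res$status[res$structure == "right_putamen"],
                   "degenerate")
  expect_identical(res$status[res$structure == "left_putamen"], "ok")
})

test_that("BH adjustment is monotone and null structures stay null", {
  set.seed(22)
  tr <- simulate_subject_truth(60, 40, seed = 30)
  vols <- simulate_volume_table(tr, seed = 31)
  d <- cbind(tr, metric = tr$true_alpha_freq)
  res <- volume_regressions(d, vols, metric)
  ok <- res[res$status == "ok", ]
  ord <- order(ok$p.value)
  expect_true(all(diff(ok$q.value[ord]) >= -1e-12))
  expect_equal(ok$q.value, p.adjust(ok$p.value, "BH"))
})
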