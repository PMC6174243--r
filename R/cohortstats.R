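# Cohort-level statistics: QC gating with inter-rater agreement,
# case-control summaries, age/status ANOVA, and alpha-vs-brain-volume
# regressions with multiplicity control.

#' Bangdiwala's agreement statistic
#'
#' For a square rater-by-rater contingency table of counts,
#' `B = sum(n_ii^2) / sum(n_i+ * n_+i)`: the ratio of the squared
#' diagonal to the area of the marginal rectangles. B is 1 under perfect
#' agreement and 0 when the diagonal is empty.
#'
#' @param table Square non-negative integer matrix (or table) of
#'   cross-classified ratings with a positive total.
#'
#' @return The agreement statistic, a number in `[0, 1]`.
#' @export
bangdiwala_b <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) abort("agreement table must be square")
  if (any(m < 0) || sum(m) <= 0) {
    abort("agreement table must be non-negative with a positive total")
  }
  denom <- sum(rowSums(m) * colSums(m))
  if (denom == 0) abort("all marginal products are zero")
  sum(diag(m)^2) / denom
}

#' Cross-tabulate two raters' quality ratings
#'
#' @param records Data frame with integer columns `rating_a` and
#'   `rating_b` on the 1-4 quality scale.
#' @param levels Rating levels (default 1:4).
#'
#' @return A 4x4 contingency table (rater A in rows).
#' @export
rating_table <- function(records, levels = 1:4) {
  table(factor(records$rating_a, levels = levels),
        factor(records$rating_b, levels = levels))
}

#' Exclude subjects on quality ratings
#'
#' A subject is excluded when either rater scored the spectrum 4
#' (unusable), or when a rating is missing.
#'
#' @param records Data frame with columns `rating_a`, `rating_b`.
#'
#' @return List with tibbles `kept` and `excluded`; `excluded` gains a
#'   `reason` column ("unusable_rating" or "unrated"). The two parts
#'   partition the input.
#' @export
qc_exclude <- function(records) {
  records <- as_tibble(records)
  unrated <- is.na(records$rating_a) | is.na(records$rating_b)
  unusable <- !unrated & (records$rating_a == 4 | records$rating_b == 4)
  excluded <- records[unrated | unusable, ]
  excluded$reason <- ifelse(unrated[unrated | unusable],
                            "unrated", "unusable_rating")
  list(kept = records[!(unrated | unusable), ], excluded = excluded)
}

#' Case-control summary of one alpha characteristic
#'
#' Per-group mean and SD, Welch's two-sample t-test, and the two-sided
#' variance-ratio test applied to the raw metric.
#'
#' @param data Data frame with a `group` column (levels TD and ASD).
#' @param metric Column name (tidy-eval) of the metric.
#' @param case,reference Group labels (defaults "ASD" and "TD").
#'
#' @return One-row tibble with group means/SDs/sizes, `t_statistic`,
#'   `t_p`, `f_statistic`, `f_p`.
#' @export
group_summary <- function(data, metric, case = "ASD", reference = "TD") {
  v <- eval_tidy(enquo(metric), data)
  g <- as.character(data$group)
  x <- v[g == case & is.finite(v)]
  y <- v[g == reference & is.finite(v)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 finite values")
  }
  tt <- stats::t.test(x, y)
  vt <- variance_ratio_test(x, y)
  tibble(
    n_case = length(x), mean_case = mean(x), sd_case = sd(x),
    n_ref = length(y), mean_ref = mean(y), sd_ref = sd(y),
    t_statistic = unname(tt$statistic), t_p = tt$p.value,
    f_statistic = vt$statistic, f_p = vt$p.value)
}

#' ANOVA of a metric on age, status and their interaction
#'
#' Ordinary least squares of `metric ~ age + status + age:status` with
#' status coded 0 for the reference group and 1 for cases, reporting the
#' overall model F and R-squared plus per-term F tests from Type-II sums
#' of squares.
#'
#' @param data Data frame with a `group` column; both groups must span
#'   more than one distinct age.
#' @param metric Column name (tidy-eval) of the metric.
#' @param age Column name (tidy-eval) of age in months (default `age`).
#' @param case Group label coded 1 (default "ASD").
#'
#' @return Tibble with rows `model`, `age`, `status`, `age:status`:
#'   columns `term`, `statistic` (F), `df1`, `df2`, `p.value`, and
#'   `r.squared` (model row only).
#' @export
anova_age_status <- function(data, metric, age = age, case = "ASD") {
  d <- tibble(
    y = eval_tidy(enquo(metric), data),
    age = eval_tidy(enquo(age), data),
    status = as.numeric(as.character(data$group) == case))
  d <- d[complete.cases(d), ]
  if (length(unique(d$age[d$status == 0])) < 2 ||
      length(unique(d$age[d$status == 1])) < 2) {
    abort("both groups must span more than one distinct age")
  }
  if (var(d$y) == 0) {
    # a constant metric carries no effect of any term
    return(bind_rows(
      tibble(term = "model", statistic = 0, df1 = 3,
             df2 = nrow(d) - 4, p.value = 1, r.squared = 0),
      tibble(term = c("age", "status", "age:status"), statistic = 0,
             df1 = 1, df2 = nrow(d) - 4, p.value = 1,
             r.squared = NA_real_)))
  }
  fit <- lm(y ~ age * status, data = d)
  if (any(is.na(coef(fit)))) abort("rank-deficient design")
  rss_full <- sum(fit$residuals^2)
  if (rss_full < 1e-12 * var(d$y) * nrow(d)) {
    # perfect fit: the overall model explains everything; a term's F is
    # unbounded when it carries signal and zero when it does not
    ss2 <- type2_ss(d)
    term_f <- ifelse(ss2 > 1e-10 * var(d$y) * nrow(d), Inf, 0)
    return(bind_rows(
      tibble(term = "model", statistic = Inf, df1 = 3, df2 = nrow(d) - 4,
             p.value = 0, r.squared = 1),
      tibble(term = names(ss2), statistic = unname(term_f), df1 = 1,
             df2 = nrow(d) - 4, p.value = ifelse(term_f > 0, 0, 1),
             r.squared = NA_real_)))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  a2 <- car::Anova(fit, type = 2)
  terms_ <- c("age", "status", "age:status")
  df2 <- a2["Residuals", "Df"]
  rows <- lapply(terms_, function(tm) {
    tibble(term = tm, statistic = a2[tm, "F value"], df1 = a2[tm, "Df"],
           df2 = df2, p.value = a2[tm, "Pr(>F)"], r.squared = NA_real_)
  })
  bind_rows(
    tibble(term = "model", statistic = unname(fstat[1]),
           df1 = unname(fstat[2]), df2 = unname(fstat[3]),
           p.value = unname(overall_p), r.squared = sm$r.squared),
    bind_rows(rows))
}

# Type-II extra sums of squares of the age/status/interaction design
type2_ss <- function(d) {
  rss <- function(X) sum(qr.resid(qr(X), d$y)^2)
  one <- rep(1, nrow(d))
  X_no_int <- cbind(one, d$age, d$status)
  rss_no_int <- rss(X_no_int)
  c(age = rss(cbind(one, d$status)) - rss_no_int,
    status = rss(cbind(one, d$age)) - rss_no_int,
    `age:status` = rss_no_int - rss(cbind(X_no_int, d$age * d$status)))
}

#' Bivariate regressions of an alpha characteristic on brain volumes
#'
#' Regresses the metric on each structure's volume by simple OLS and
#' reports per-structure R-squared and p, together with
#' Benjamini-Hochberg adjusted q-values across structures. A structure
#' with (near-)constant volume across subjects is reported with status
#' "degenerate" and NA statistics; the remaining structures are
#' unaffected.
#'
#' @param data Data frame with an `id` column and the metric.
#' @param volumes Volume table: `id` plus one numeric column per
#'   structure (mm^3).
#' @param metric Column name (tidy-eval) of the metric.
#' @param structures Structure columns to use (default: every non-id
#'   column of `volumes`).
#'
#' @return Tibble, one row per structure: `structure`, `n`, `estimate`
#'   (slope), `r.squared`, `statistic` (overall F), `p.value`,
#'   `q.value` (BH across structures), `status`.
#' @export
volume_regressions <- function(data, volumes, metric,
                               structures = setdiff(names(volumes), "id")) {
  mv <- eval_tidy(enquo(metric), data)
  d <- tibble(id = data$id, .metric = mv) %>%
    left_join(as_tibble(volumes), by = "id")
  rows <- lapply(structures, function(s) {
    dd <- d[is.finite(d$.metric) & is.finite(d[[s]]), c(".metric", s)]
    names(dd) <- c("y", "x")
    if (nrow(dd) < 3) {
      return(tibble(structure = s, n = nrow(dd), estimate = NA_real_,
                    r.squared = NA_real_, statistic = NA_real_,
                    p.value = NA_real_, status = "too_few"))
    }
    if (sd(dd$x) < .Machine$double.eps^0.5 * max(1, abs(mean(dd$x)))) {
      return(tibble(structure = s, n = nrow(dd), estimate = NA_real_,
                    r.squared = NA_real_, statistic = NA_real_,
                    p.value = NA_real_, status = "degenerate"))
    }
    fit <- lm(y ~ x, data = dd)
    sm <- suppressWarnings(summary(fit))   # exact fits are legitimate here
    fstat <- sm$fstatistic
    tibble(structure = s, n = nrow(dd),
           estimate = unname(coef(fit)[2]),
           r.squared = sm$r.squared,
           statistic = unname(fstat[1]),
           p.value = unname(pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
           status = "ok")
  })
  out <- bind_rows(rows)
  out$q.value <- NA_real_
  ok <- out$status == "ok"
  out$q.value[ok] <- p.adjust(out$p.value[ok], method = "BH")
  dplyr::relocate(out, "q.value", .after = "p.value")
}
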