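# Age-normative model of an alpha characteristic: a local-regression
# mean curve fitted on typically developing subjects, a local scale
# curve fitted on their absolute residuals, and deviation scores for
# every subject.

#' Fit an age-normative model on a reference group
#'
#' Fits the normative mean curve of a metric against age by local linear
#' regression with a tricube kernel (2-year bandwidth by default), then a
#' local scale curve through the absolute residuals, multiplied by
#' `sqrt(pi/2)` so that it estimates the residual SD under approximately
#' Gaussian scatter (half-normal consistency) and floored at a fraction
#' of the global residual SD so the scale never collapses.
#'
#' @param train Data frame of reference (typically developing) subjects.
#' @param age,value Column names (tidy-eval) holding age in months and
#'   the metric.
#' @param metric Label stored on the model (e.g. "frequency" or
#'   "power").
#' @param bandwidth Kernel half-width of the mean curve in months
#'   (default 24).
#' @param scale_bandwidth Kernel half-width of the scale curve (default
#'   `4 * bandwidth`). A variance function needs far more data per
#'   window than a mean: with roughly half-normal residuals the local
#'   scale estimate has a sampling CV of about `0.76 / sqrt(n_local)`,
#'   and dividing by an unstable scale makes deviation scores
#'   heavy-tailed at cohort-scale sample sizes.
#' @param degree Local polynomial degree of the mean curve (default 1).
#' @param scale_floor_frac Lower bound on the scale curve, as a fraction
#'   of the global residual SD (default 0.25). Deviation scores divide
#'   by the scale, so an unbounded lower tail of the scale estimate
#'   gives the scores divergent second moments; a quarter of the global
#'   SD binds only where the local estimate collapses, far below any
#'   real heteroskedasticity of interest.
#'
#' @return A `normative_model` object.
#' @export
fit_normative <- function(train, age, value, metric = "metric",
                          bandwidth = 24, scale_bandwidth = 4 * bandwidth,
                          degree = 1, scale_floor_frac = 0.25) {
  ages <- eval_tidy(enquo(age), train)
  values <- eval_tidy(enquo(value), train)
  keep <- is.finite(ages) & is.finite(values)
  ages <- ages[keep]; values <- values[keep]
  mean_curve <- loess_curve(ages, values, bandwidth, degree)
  # leave-one-out residuals: out-of-sample distances of the training
  # subjects from the curve, free of the in-sample shrinkage that would
  # otherwise make the reference group look tighter than new subjects
  resid_loo <- if (length(ages) >= 6) {
    vapply(seq_along(ages), function(i) {
      cv <- loess_curve(ages[-i], values[-i], bandwidth, degree)
      values[i] - loess_point(cv, min(max(ages[i], min(cv$ages)),
                                      max(cv$ages)))
    }, numeric(1))
  } else {
    values - predict(mean_curve, ages)
  }
  scale_curve <- loess_curve(ages, abs(resid_loo), scale_bandwidth,
                             degree = 1, clip = TRUE)
  floor_ <- scale_floor_frac * sd(resid_loo)
  if (!is.finite(floor_) || floor_ == 0) floor_ <- 1e-8
  model <- structure(
    list(metric = metric, bandwidth = bandwidth, degree = degree,
         scale_floor_frac = scale_floor_frac,
         train_ages = ages, train_values = values,
         mean_curve = mean_curve, scale_curve = scale_curve,
         scale_factor = sqrt(pi / 2), scale_floor = floor_),
    class = "normative_model")
  # fully out-of-sample training scores: the scale at subject i is also
  # estimated without subject i
  scale_loo <- if (length(ages) >= 7) {
    vapply(seq_along(ages), function(i) {
      cv <- loess_curve(ages[-i], abs(resid_loo[-i]), scale_bandwidth,
                        degree = 1, clip = TRUE)
      loess_point(cv, min(max(ages[i], min(cv$ages)), max(cv$ages)))
    }, numeric(1))
  } else {
    predict(scale_curve, ages)
  }
  model$train_z_loo <- resid_loo /
    pmax(model$scale_factor * scale_loo, floor_)
  model
}

# Curves are evaluated on the training-age hull: queries beyond the
# observed age span are held at the boundary value rather than
# extrapolated with the local polynomial (scoring still refuses ages
# more than one bandwidth outside the span).
clamp_age <- function(model, age) {
  pmin(pmax(age, min(model$train_ages)), max(model$train_ages))
}

norm_mean <- function(model, age) {
  predict(model$mean_curve, clamp_age(model, age))
}

norm_scale <- function(model, age) {
  pmax(model$scale_factor * predict(model$scale_curve, clamp_age(model, age)),
       model$scale_floor)
}

#' @param object A `normative_model`.
#' @param newages Ages (months) at which to evaluate the curves.
#' @param level Coverage of the reported normative band (default 0.95).
#' @param ... Unused.
#' @rdname fit_normative
#' @export
predict.normative_model <- function(object, newages, level = 0.95, ...) {
  m <- norm_mean(object, newages)
  s <- norm_scale(object, newages)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tibble(age = newages, mean = m, scale = s,
         lower = m - zq * s, upper = m + zq * s)
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model> %s ~ age: %d training subjects, bandwidth %g months\n",
    x$metric, length(x$train_ages), x$bandwidth))
  invisible(x)
}

#' Score subjects against a normative model
#'
#' Computes, for every subject, the deviation score
#' `z = (value - mean(age)) / scale(age)` and flags outliers at
#' `|z| > outlier_z`. Ages more than one bandwidth outside the training
#' age range are not extrapolated: those subjects come back with
#' `supported = FALSE` and `z = NA`.
#'
#' @param model A `normative_model`.
#' @param data Data frame of subjects to score.
#' @param age,value Column names (tidy-eval) for age (months) and the
#'   metric.
#' @param outlier_z Outlier threshold on |z| (default 1.96).
#'
#' @return `data` with columns `z`, `is_outlier`, `supported` appended.
#' @export
score_normative <- function(model, data, age, value, outlier_z = 1.96) {
  ages <- eval_tidy(enquo(age), data)
  values <- eval_tidy(enquo(value), data)
  lo <- min(model$train_ages) - model$bandwidth
  hi <- max(model$train_ages) + model$bandwidth
  supported <- is.finite(ages) & ages >= lo & ages <= hi & is.finite(values)
  z <- rep(NA_real_, length(ages))
  if (any(supported)) {
    z[supported] <- (values[supported] - norm_mean(model, ages[supported])) /
      norm_scale(model, ages[supported])
  }
  out <- as_tibble(data)
  out$z <- z
  out$is_outlier <- !is.na(z) & abs(z) > outlier_z
  out$supported <- supported
  out
}

#' @rdname fit_normative
#' @param x A `normative_model`.
#' @param n_grid Number of ages in the evaluation grid.
#' @exportS3Method generics::tidy
tidy.normative_model <- function(x, n_grid = 101, ...) {
  grid <- seq(min(x$train_ages), max(x$train_ages), length.out = n_grid)
  predict(x, grid)
}

#' @rdname fit_normative
#' @exportS3Method generics::glance
glance.normative_model <- function(x, ...) {
  resid <- x$train_values - norm_mean(x, x$train_ages)
  tibble(metric = x$metric, n = length(x$train_ages),
         bandwidth = x$bandwidth, degree = x$degree,
         sigma = sd(resid), scale_floor = x$scale_floor)
}

#' @rdname fit_normative
#' @exportS3Method generics::augment
augment.normative_model <- function(x, ...) {
  tibble(age = x$train_ages, value = x$train_values,
         .fitted = norm_mean(x, x$train_ages),
         .scale = norm_scale(x, x$train_ages)) %>%
    mutate(.resid = .data$value - .data$.fitted,
           .z = .data$.resid / .data$.scale,
           .z_loo = x$train_z_loo)
}

#' Two-sided variance-ratio heterogeneity test
#'
#' Compares the dispersion of deviation scores (or raw metrics) between
#' the case and reference groups with the variance ratio
#' `F = var(case) / var(reference)` referred to the F distribution with
#' `(n_case - 1, n_ref - 1)` degrees of freedom; the two-sided p-value
#' doubles the smaller tail.
#'
#' @param case,reference Numeric vectors of scores (each of length
#'   >= 3; non-finite values dropped).
#' @param name Label for the result row.
#'
#' @return One-row tibble: `name`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
variance_ratio_test <- function(case, reference, name = "variance_ratio") {
  case <- case[is.finite(case)]
  reference <- reference[is.finite(reference)]
  if (length(case) < 3 || length(reference) < 3) {
    abort("each group needs at least 3 finite scores")
  }
  v2 <- var(reference)
  if (v2 == 0) abort("reference group has zero variance")
  f <- var(case) / v2
  df1 <- length(case) - 1
  df2 <- length(reference) - 1
  p <- 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE))
  p <- min(p, 1)
  tibble(name = name, statistic = f, df1 = df1, df2 = df2, p.value = p)
}

#' Fisher exact test on outlier proportions
#'
#' Tests whether outliers (subjects beyond the normative threshold) are
#' over- or under-represented in the case group, using the two-sided
#' Fisher exact test on the 2x2 table of outlier counts.
#'
#' @param outliers_case,n_case Outlier count and group size, cases.
#' @param outliers_ref,n_ref Same for the reference group.
#' @param name Label for the result row.
#'
#' @return One-row tibble: `name`, `statistic` (odds ratio estimate),
#'   `p.value`, plus the four table counts.
#' @export
outlier_proportion_test <- function(outliers_case, n_case,
                                    outliers_ref, n_ref,
                                    name = "outlier_proportion") {
  counts <- c(outliers_case, n_case, outliers_ref, n_ref)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (outliers_case > n_case || outliers_ref > n_ref) {
    abort("outlier counts cannot exceed group sizes")
  }
  tab <- matrix(c(outliers_case, n_case - outliers_case,
                  outliers_ref, n_ref - outliers_ref),
                nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab)
  tibble(name = name, statistic = unname(ft$estimate), p.value = ft$p.value,
         outliers_case = outliers_case, n_case = n_case,
         outliers_ref = outliers_ref, n_ref = n_ref)
}

#' Serialize a normative model to JSON
#'
#' The file stores the training data and hyperparameters; the curves are
#' re-derived on load, so the serialized form is small, diffable and
#' independent of R's binary formats.
#'
#' @param model A `normative_model`.
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_normative_json <- function(model, path) {
  jsonlite::write_json(
    list(metric = model$metric,
         bandwidth = model$bandwidth,
         scale_bandwidth = model$scale_curve$bandwidth,
         degree = model$degree,
         scale_floor_frac = model$scale_floor_frac,
         train_ages = model$train_ages,
         train_values = model$train_values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative_json
#' @export
read_normative_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_normative(
    tibble(age = spec$train_ages, value = spec$train_values),
    age, value, metric = spec$metric, bandwidth = spec$bandwidth,
    scale_bandwidth = spec$scale_bandwidth, degree = spec$degree,
    scale_floor_frac = spec$scale_floor_frac)
}
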