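#' Detect bad channels by signal-power outlierness
#'
#' Scores every channel by the log of its total power and flags channels
#' whose score deviates from the cross-channel median by more than
#' `threshold_se` standard errors, where the standard error is the robust
#' (MAD-based) cross-channel spread divided by the square root of the
#' number of channels. When the channels are essentially identical
#' (robust spread zero) nothing is flagged.
#'
#' @param rec An [eeg_recording()] with at least 4 channels.
#' @param threshold_se Flagging threshold in standard errors (> 0,
#'   default 3).
#'
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, threshold_se = 3) {
  if (n_channels(rec) < 4) abort("need at least 4 channels")
  if (threshold_se <= 0) abort("`threshold_se` must be positive")
  score <- log(colMeans(rec$samples^2) + .Machine$double.xmin)
  med <- median(score)
  rsd <- mad(score)
  if (rsd == 0) {
    # degenerate dispersion: a majority of identical channels; anything
    # strictly off the median is bad, nothing else is
    off <- abs(score - med) > 1e-9 * max(1, abs(med))
    return(names(score)[off])
  }
  se <- rsd / sqrt(length(score))
  flagged <- names(score)[abs(score - med) > threshold_se * se]
  if (length(flagged) == length(score)) {
    abort("all channels flagged; threshold too permissive")
  }
  flagged
}

# Smoothing kernel of the spherical-spline interpolator:
# g(x) = (1/4pi) * sum_{n=1}^{N} (2n+1) / (n (n+1))^m * P_n(x)
spline_g <- function(x, m = 4, n_terms = 7) {
  # Legendre polynomials by the Bonnet recurrence, evaluated at cos(angle)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the samples of the listed channels with spherical-spline
#' estimates computed, at every time point, from the remaining good
#' channels (the classic scalp-potential interpolator built from a
#' truncated Legendre series on the unit sphere, with a small ridge for
#' numerical stability). Good channels are returned unchanged; an empty
#' `bad` list returns the input untouched.
#'
#' @param rec An [eeg_recording()].
#' @param bad Character vector of channel labels to reconstruct.
#' @param m Spline stiffness order (default 4).
#' @param n_terms Number of Legendre terms (default 7, adequate for a
#'   10-electrode montage).
#' @param reg Ridge regularization added to the kernel matrix diagonal
#'   (default 1e-5).
#'
#' @return The recording with bad channels reconstructed.
#' @export
spline_interpolate <- function(rec, bad, m = 4, n_terms = 7, reg = 1e-5) {
  bad <- toupper(bad)
  if (length(bad) == 0) return(rec)
  labels <- channel_labels(rec)
  if (!all(bad %in% labels)) abort("`bad` contains labels not in the recording")
  good <- setdiff(labels, bad)
  if (length(good) < 4) abort("need at least 4 good channels to interpolate")

  pos <- as.matrix(rec$montage[match(labels, rec$montage$label),
                               c("x", "y", "z")])
  rownames(pos) <- labels
  cosang <- tcrossprod(pos)                       # unit vectors: dot = cos
  cosang <- pmin(pmax(cosang, -1), 1)

  ng <- length(good)
  G <- spline_g(cosang[good, good, drop = FALSE], m, n_terms)
  M <- rbind(cbind(G + diag(reg, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  Gbg <- spline_g(cosang[bad, good, drop = FALSE], m, n_terms)
  # interpolation operator A: estimates = A %*% good-channel samples
  A <- cbind(Gbg, rep(1, length(bad))) %*%
    solve(M, rbind(diag(ng), rep(0, ng)))

  est <- t(A %*% t(rec$samples[, good, drop = FALSE]))
  out <- rec$samples
  out[, bad] <- est
  set_samples(rec, out)
}
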