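# Linear developmental-time scaling between species, percent-of-max
# normalization and profile resampling.

#' Construct a TimeScaling
#'
#' The linear map between two species' developmental clocks,
#' `T_target = shift + rate * T_reference`. The intercept (`shift`, hours)
#' reflects the offset of the maternal-to-zygotic transition; the slope
#' (`rate`, dimensionless) is the relative developmental rate. For the sea
#' urchins *P. lividus* (reference) and *S. purpuratus* (target) this map
#' is about `T_Sp = 2.42 + 1.037 * T_Pl`.
#'
#' @param shift intercept in hours.
#' @param rate slope; must be positive.
#' @param r_squared goodness of fit of the generating regression (`NA` for
#'   maps stated directly).
#' @param n_genes number of orthologue pairs used (`NA` if not fitted).
#' @return Object of class `TimeScaling`.
#' @export
time_scaling <- function(shift, rate, r_squared = NA_real_, n_genes = NA_integer_) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive (anti-scaling?)")
  structure(list(shift = shift, rate = rate, r_squared = r_squared,
                 n_genes = n_genes), class = "TimeScaling")
}

#' @export
print.TimeScaling <- function(x, ...) {
  cat(sprintf("TimeScaling: T_target = %.4g + %.4g * T_reference (r2=%.4g, n=%s)\n",
              x$shift, x$rate, x$r_squared,
              ifelse(is.na(x$n_genes), "?", x$n_genes)))
  invisible(x)
}

#' Fit the developmental-time scaling from orthologue initiation times
#'
#' Ordinary least squares of target-species initiation times on
#' reference-species initiation times (the target-on-reference orientation;
#' the inverse map is obtained algebraically with [invert_scaling()], not
#' by re-fitting). A Theil-Sen option (median of pairwise slopes) is
#' available for initiation-time sets with heterochronic outliers.
#'
#' @param reference initiation times in the reference species, hpf.
#' @param target matching initiation times in the target species, hpf.
#' @param method `"ols"` (default) or `"theilsen"`.
#' @return A [time_scaling()] with `shift`, `rate`, `r_squared`, `n_genes`.
#' @export
#' @examples
#' t_pl <- 5:26
#' fit_time_scaling(t_pl, 2.42 + 1.037 * t_pl)
fit_time_scaling <- function(reference, target, method = c("ols", "theilsen")) {
  method <- match.arg(method)
  ok <- is.finite(reference) & is.finite(target)
  x <- reference[ok]; y <- target[ok]
  if (length(unique(x)) < 2) stop("need at least 2 distinct reference times")
  if (method == "ols") {
    fit <- lm(y ~ x)
    shift <- unname(coef(fit)[1]); rate <- unname(coef(fit)[2])
    rss <- sum(fit$residuals^2)
  } else {
    cmb <- which(upper.tri(diag(length(x))), arr.ind = TRUE)
    dx <- x[cmb[, 2]] - x[cmb[, 1]]
    slopes <- (y[cmb[, 2]] - y[cmb[, 1]])[dx != 0] / dx[dx != 0]
    rate <- median(slopes)
    shift <- median(y - rate * x)
    rss <- sum((y - shift - rate * x)^2)
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  if (!is.finite(rate) || rate <= 0) {
    stop("fitted rate is not positive (anti-scaling); check pairing")
  }
  time_scaling(shift, rate, r2, length(x))
}

#' Map reference-species time to target-species time
#'
#' @param scaling a `TimeScaling`.
#' @param t reference-species time(s), hpf.
#' @return `shift + rate * t`; strictly increasing in `t`.
#' @export
map_time <- function(scaling, t) {
  stopifnot(inherits(scaling, "TimeScaling"))
  scaling$shift + scaling$rate * t
}

#' Invert a developmental-time scaling
#'
#' @param scaling a `TimeScaling` with positive rate.
#' @return The algebraic inverse `TimeScaling(-shift/rate, 1/rate)`;
#'   composing it with the original is the identity to machine precision.
#' @export
invert_scaling <- function(scaling) {
  stopifnot(inherits(scaling, "TimeScaling"))
  if (scaling$rate <= 0) stop("rate must be positive")
  time_scaling(-scaling$shift / scaling$rate, 1 / scaling$rate,
               scaling$r_squared, scaling$n_genes)
}

#' Percent-of-maximum normalization of a temporal profile
#'
#' Divides each (linear-scale) value by the profile maximum and scales to
#' percent, so 100 is the maximal expression in the measured interval.
#' This removes technical level differences (primer efficiency,
#' measurement platform) before cross-species profile comparison.
#'
#' @param profile numeric vector of linear expression values over time
#'   (`NA` allowed), with at least one positive value.
#' @return The profile in percent of its maximum; the maximum of the output
#'   is exactly 100. Idempotent and invariant to positive rescaling.
#' @export
normalize_to_max <- function(profile) {
  m <- suppressWarnings(max(profile, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) stop("profile has no positive value")
  # divide first: m/m is exactly 1 in IEEE arithmetic, so max(output) == 100
  (profile / m) * 100
}

#' Row-wise percent-of-maximum normalization
#'
#' @param m numeric matrix (genes x time points) of linear values.
#' @return Matrix of the same shape with every row passed through
#'   [normalize_to_max()].
#' @export
percent_of_max <- function(m) {
  t(apply(m, 1, normalize_to_max))
}

#' Resample a temporal profile onto a new time grid
#'
#' Linear interpolation between measured points; values at time stamps
#' shared with the source grid are returned unchanged. Extrapolation
#' outside the measured window is refused.
#'
#' @param profile values at `source_times`.
#' @param source_times measured time points, strictly increasing.
#' @param target_times requested time points, all within
#'   `[min(source_times), max(source_times)]` (up to a 1e-9 h tolerance).
#' @return Profile values at `target_times`.
#' @export
resample_profile <- function(profile, source_times, target_times) {
  stopifnot(length(profile) == length(source_times))
  if (any(target_times < min(source_times) - 1e-9) ||
      any(target_times > max(source_times) + 1e-9)) {
    stop("target times outside the measured window (extrapolation refused)")
  }
  approx(source_times, profile, xout = pmin(pmax(target_times, min(source_times)),
                                            max(source_times)))$y
}

#' Equivalent-stage pairing between two measured grids
#'
#' Applies a `TimeScaling` to the reference grid and snaps each mapped time
#' to the nearest measured target stage, logging the largest snap distance.
#'
#' @param scaling a `TimeScaling` (reference -> target).
#' @param ref_times measured reference-species stages, hpf.
#' @param target_times measured target-species stages, hpf.
#' @return data.frame with columns `ref_index`, `target_index`,
#'   `snap_distance_h`.
#' @export
equivalent_stages <- function(scaling, ref_times, target_times) {
  mapped <- map_time(scaling, ref_times)
  idx <- vapply(mapped, function(m) which.min(abs(target_times - m)), 1L)
  snap <- abs(target_times[idx] - mapped)
  message(sprintf("equivalent stages snapped (max distance %.3g h)", max(snap)))
  data.frame(ref_index = seq_along(ref_times), target_index = idx,
             snap_distance_h = snap)
}
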