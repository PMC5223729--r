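#' Fit a beta distribution by the method of moments
#'
#' Inverts the first two moments of a beta distribution: given a mean in
#' (0, 1) and a standard error, returns the `(alpha, beta)` pair whose
#' analytic mean and standard deviation equal the inputs. Used to turn the
#' printed `mean (SE)` of a probability or utility parameter into a sampling
#' distribution for probabilistic sensitivity analysis.
#'
#' @param mean Mean of the quantity, strictly between 0 and 1.
#' @param se Standard error, strictly between 0 and
#'   `sqrt(mean * (1 - mean))` (the variance of a beta distribution cannot
#'   exceed `mean * (1 - mean)`).
#'
#' @return Named numeric vector `c(alpha = , beta = )`, both strictly
#'   positive.
#'
#' @examples
#' beta_from_mean_se(0.5, sqrt(0.25 / 5)) # alpha = beta = 2
#' beta_from_mean_se(0.77, 0.00413)       # close to beta(7978, 2383)
#' @export
beta_from_mean_se <- function(mean, se) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(se), length(se) == 1L)
  if (mean <= 0 || mean >= 1) {
    stop("beta_from_mean_se(): `mean` must lie strictly in (0, 1), got ",
         format(mean), call. = FALSE)
  }
  bound <- sqrt(mean * (1 - mean))
  if (se <= 0 || se >= bound) {
    stop("beta_from_mean_se(): `se` must lie in (0, ", format(bound),
         ") = (0, sqrt(mean * (1 - mean))) for mean = ", format(mean),
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' Returns the `(shape, scale)` pair with `shape * scale == mean` and
#' `sqrt(shape) * scale == se`, i.e. `shape = (mean/se)^2` and
#' `scale = se^2/mean`. Cost and resource-use parameters, which are
#' non-negative and often right-skewed, are sampled from these fits.
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#'
#' @return Named numeric vector `c(shape = , scale = )`.
#'
#' @examples
#' gamma_from_mean_se(9104, 349.61) # approx. (678.06, 13.43)
#' @export
gamma_from_mean_se <- function(mean, se) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(se), length(se) == 1L)
  if (mean <= 0 || se <= 0) {
    stop("gamma_from_mean_se(): `mean` and `se` must both be positive",
         call. = FALSE)
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Fit a log-normal distribution from a ratio and its confidence interval
#'
#' Hazard ratios and relative risks reported as `ratio (lo to hi)` are
#' represented on the log scale: `mu = log(ratio)` and
#' `sigma = (log(hi) - log(lo)) / (2 * z)` where `z` is the two-sided
#' normal quantile for `level` (1.959964 at the default 95%).
#'
#' @param ratio Point estimate of the hazard ratio / relative risk.
#' @param lo,hi Confidence limits, `0 < lo <= ratio <= hi`.
#' @param level Confidence level of `(lo, hi)`; default 0.95.
#'
#' @return Named numeric vector `c(mu = , sigma = )` with attribute
#'   `degenerate = TRUE` when `lo == hi == ratio` (sigma 0, a fixed ratio).
#'
#' @examples
#' lognormal_from_ratio_ci(0.68, 0.48, 0.96) # approx. (-0.386, 0.177)
#' @export
lognormal_from_ratio_ci <- function(ratio, lo, hi, level = 0.95) {
  stopifnot(is.numeric(ratio), is.numeric(lo), is.numeric(hi),
            length(ratio) == 1L, length(lo) == 1L, length(hi) == 1L,
            level > 0, level < 1)
  if (!(lo > 0 && lo <= ratio && ratio <= hi)) {
    stop("lognormal_from_ratio_ci(): need 0 < lo <= ratio <= hi, got (",
         format(ratio), ", ", format(lo), ", ", format(hi), ")",
         call. = FALSE)
  }
  if (lo == hi && lo != ratio) {
    stop("lognormal_from_ratio_ci(): degenerate interval lo == hi != ratio",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(mu = log(ratio), sigma = (log(hi) - log(lo)) / (2 * z))
  if (lo == hi) attr(out, "degenerate") <- TRUE
  out
}
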