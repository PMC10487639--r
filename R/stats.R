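#' Gaussian peak height for a count histogram
#'
#' Height (in counts per bin) of a normal density holding `n`
#' observations in a histogram of bin width `w`:
#' `n / (w * sd * sqrt(2*pi))`. Used to initialize the background
#' component of the bimodal fit.
#'
#' @param n number of observations.
#' @param bin_width histogram bin width in score units.
#' @param sd standard deviation in score units.
#' @return peak height in count units.
#' @examples
#' gaussian_peak_height(1000, 0.015, 0.05)  # ~5.32e5
#' @export
gaussian_peak_height <- function(n, bin_width, sd) {
  n / (bin_width * sd * sqrt(2 * pi))
}

new_bimodal_fit <- function(bg_mean, bg_sd, bg_amplitude, tp_mean, tp_sd,
                            tp_amplitude, bin_width, score_range,
                            histogram = NULL, residual_norm = NA_real_,
                            n_scores = NA_integer_) {
  stopifnot(bg_sd > 0, tp_sd > 0, bg_amplitude >= 0, tp_amplitude >= 0)
  k <- sqrt(2 * pi) / bin_width
  structure(list(
    bg_mean = bg_mean, bg_sd = bg_sd, bg_amplitude = bg_amplitude,
    tp_mean = tp_mean, tp_sd = tp_sd, tp_amplitude = tp_amplitude,
    bg_count = bg_amplitude * bg_sd * k,
    tp_count = tp_amplitude * tp_sd * k,
    estimated_tp_count = tp_amplitude * tp_sd * k,
    bin_width = bin_width, score_range = score_range,
    histogram = histogram, residual_norm = residual_norm,
    n_scores = n_scores), class = "bimodal_fit")
}

#' Two-Gaussian model of a score histogram (fit-free constructor)
#'
#' Builds a `bimodal_fit` object directly from component parameters,
#' bypassing the least-squares fit. Useful for calibration (e.g. a
#' perfectly separable classifier) and for constructing reference
#' classifiers.
#'
#' @param bg_mean,bg_sd,bg_count background (noise) component.
#' @param tp_mean,tp_sd,tp_count true-positive component.
#' @param bin_width histogram bin width in score units.
#' @param score_range length-2 range for cutoff grids (default: 4 sd
#'   beyond the component means).
#' @return object of class `bimodal_fit`.
#' @export
bimodal_model <- function(bg_mean, bg_sd, bg_count, tp_mean, tp_sd, tp_count,
                          bin_width = 0.015, score_range = NULL) {
  if (is.null(score_range))
    score_range <- c(min(bg_mean - 4 * bg_sd, tp_mean - 4 * tp_sd),
                     max(bg_mean + 4 * bg_sd, tp_mean + 4 * tp_sd))
  k <- bin_width / sqrt(2 * pi)
  new_bimodal_fit(bg_mean, bg_sd, bg_count / bg_sd * k,
                  tp_mean, tp_sd, tp_count / tp_sd * k,
                  bin_width, score_range)
}

#' Fit a bimodal Gaussian model to LCCmax scores
#'
#' Histograms the candidate scores (default bin width 0.015) and fits the
#' sum of two Gaussians by bounded least squares: one component for the
#' background noise, one for the true-positive particle population. The
#' background is initialized at the mean and standard deviation of the
#' score volume and constrained near them (mean within two volume
#' standard deviations, sd within a factor of two); its peak height is
#' initialized as `N / (w * sd * sqrt(2*pi))`. Components are reordered
#' after the fit so that `tp_mean > bg_mean`.
#'
#' @param scores numeric LCCmax values of the extracted candidates
#'   (>= 50).
#' @param volume_mean,volume_sd mean and standard deviation of the full
#'   score volume (background statistics).
#' @param bin_width histogram bin width in score units.
#' @return object of class `bimodal_fit`, including the binned histogram
#'   and the residual norm of the fit.
#' @export
fit_bimodal <- function(scores, volume_mean, volume_sd, bin_width = 0.015) {
  if (length(scores) < 50) stop("need at least 50 scores", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  w <- bin_width
  breaks <- seq(floor(min(scores) / w) * w, max(scores) + w, by = w)
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: scores fall into a single bin", call. = FALSE)
  n <- length(scores)

  # particle component initialized away from the background component so
  # the two Gaussians start linearly independent
  m2_init <- max(as.numeric(quantile(scores, 0.9)),
                 volume_mean + 2.5 * volume_sd)
  start <- list(
    a1 = gaussian_peak_height(n, w, volume_sd), m1 = volume_mean, s1 = volume_sd,
    a2 = max(1, counts[which.min(abs(centers - m2_init))]),
    m2 = m2_init, s2 = 1.5 * volume_sd)
  lower <- c(a1 = 0, m1 = volume_mean - 2 * volume_sd, s1 = 0.5 * volume_sd,
             a2 = 0, m2 = volume_mean, s2 = w / 4)
  upper <- c(a1 = Inf, m1 = volume_mean + 2 * volume_sd, s1 = 2 * volume_sd,
             a2 = Inf, m2 = max(scores), s2 = diff(range(scores)) + w)
  start$m2 <- min(max(start$m2, lower[["m2"]]), upper[["m2"]])
  start$s2 <- min(max(start$s2, lower[["s2"]]), upper[["s2"]])

  model <- function(p, x) {
    p[["a1"]] * exp(-(x - p[["m1"]])^2 / (2 * p[["s1"]]^2)) +
      p[["a2"]] * exp(-(x - p[["m2"]])^2 / (2 * p[["s2"]]^2))
  }
  fit <- minpack.lm::nls.lm(
    par = unlist(start), lower = lower, upper = upper,
    fn = function(p) counts - model(p, centers),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0L, 5L))
    stop("bimodal fit did not converge: ", fit$message, call. = FALSE)
  p <- as.list(fit$par)
  if (p$m2 < p$m1) p <- list(a1 = p$a2, m1 = p$m2, s1 = p$s2,
                             a2 = p$a1, m2 = p$m1, s2 = p$s1)
  new_bimodal_fit(p$m1, p$s1, p$a1, p$m2, p$s2, p$a2, w,
                  score_range = range(scores),
                  histogram = tibble::tibble(center = centers, count = counts),
                  residual_norm = sqrt(fit$deviance),
                  n_scores = n)
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("<bimodal_fit>\n")
  cat(sprintf("  background: mean %.4f, sd %.4f, count %.1f\n",
              x$bg_mean, x$bg_sd, x$bg_count))
  cat(sprintf("  particles:  mean %.4f, sd %.4f, count %.1f\n",
              x$tp_mean, x$tp_sd, x$estimated_tp_count))
  invisible(x)
}

#' @export
tidy.bimodal_fit <- function(x, ...) {
  tibble::tibble(
    component = c("background", "true_positive"),
    mean = c(x$bg_mean, x$tp_mean),
    sd = c(x$bg_sd, x$tp_sd),
    amplitude = c(x$bg_amplitude, x$tp_amplitude),
    count = c(x$bg_count, x$tp_count))
}

#' @export
glance.bimodal_fit <- function(x, ...) {
  tibble::tibble(estimated_tp_count = x$estimated_tp_count,
                 bg_count = x$bg_count,
                 bin_width = x$bin_width,
                 residual_norm = x$residual_norm,
                 n_scores = x$n_scores)
}

#' Sensitivity and false-discovery rate at a score cutoff
#'
#' True and false positives above the cutoff are the upper-tail masses
#' of the fitted particle and background Gaussians (count-scaled).
#' Sensitivity = TP / (TP + FN) and FDR = FP / (FP + TP); the FDR of an
#' empty retrieval set is defined as 0.
#'
#' @param fit a `bimodal_fit`.
#' @param cutoff score cutoff(s); vectorized.
#' @return tibble with `cutoff`, `sensitivity`, `fdr`.
#' @export
sensitivity_fdr <- function(fit, cutoff) {
  stopifnot(inherits(fit, "bimodal_fit"))
  tp_tail <- pnorm(cutoff, fit$tp_mean, fit$tp_sd, lower.tail = FALSE)
  fp_tail <- pnorm(cutoff, fit$bg_mean, fit$bg_sd, lower.tail = FALSE)
  tp <- fit$tp_count * tp_tail
  fp <- fit$bg_count * fp_tail
  fdr <- ifelse(tp + fp > 0, fp / (fp + tp), 0)
  tibble::tibble(cutoff = cutoff, sensitivity = tp_tail, fdr = fdr)
}

#' Sensitivity/FDR curve over a cutoff grid
#'
#' Slides the classifier over evenly spaced score cutoffs spanning the
#' fitted score range (500 by default) and records sensitivity and FDR
#' at each.
#'
#' @param fit a `bimodal_fit`.
#' @param n_cutoffs number of evenly spaced cutoffs.
#' @param cutoffs explicit cutoff grid (overrides `n_cutoffs`).
#' @return tibble of class `tm_roc_curve` with `cutoff`, `sensitivity`,
#'   `fdr`.
#' @export
roc_curve <- function(fit, n_cutoffs = 500, cutoffs = NULL) {
  if (is.null(cutoffs))
    cutoffs <- seq(fit$score_range[1], fit$score_range[2],
                   length.out = n_cutoffs)
  out <- sensitivity_fdr(fit, cutoffs)
  class(out) <- c("tm_roc_curve", class(out))
  out
}

#' Best operating point: the largest rectangle under the curve (RUC)
#'
#' Evaluates `sensitivity * (1 - FDR)` at every curve sample and returns
#' the maximizing point; ties break toward the higher cutoff. A perfect
#' classifier attains 1, and the diagonal reference curve with
#' sensitivity equal to FDR attains 0.25 (a random classifier).
#'
#' @param curve data frame with `cutoff`, `sensitivity` and `fdr`
#'   columns (e.g. from [roc_curve()]).
#' @return one-row tibble with `cutoff`, `sensitivity`, `fdr`,
#'   `ruc_value`.
#' @export
ruc_point <- function(curve) {
  if (!nrow(curve)) stop("empty curve", call. = FALSE)
  ruc <- curve$sensitivity * (1 - curve$fdr)
  best <- max(ruc)
  idx <- which(ruc == best)
  idx <- idx[which.max(curve$cutoff[idx])]
  tibble::tibble(cutoff = curve$cutoff[idx],
                 sensitivity = curve$sensitivity[idx],
                 fdr = curve$fdr[idx],
                 ruc_value = best)
}
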