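# Nonparametric gain statistics across light x contrast conditions:
# response ranges, offset changes, relative contrast gain control,
# photo-tagging classification, stability checks and count arithmetic.

#' Response range of a trace
#'
#' Baseline activity is the 5th percentile of the response (`R_min`), the
#' maximum response the 95th percentile (`R_max`), and the operating range
#' `S = R_max - R_min`. Percentiles use linear interpolation between order
#' statistics.
#'
#' @param trace a [response_trace()] or numeric vector.
#' @param probs percentile pair (default `c(0.05, 0.95)`).
#' @return list with `R_min`, `R_max`, `S`.
#' @export
response_range <- function(trace, probs = c(0.05, 0.95)) {
  x <- if (inherits(trace, "response_trace")) trace$values else as.numeric(trace)
  if (!length(x)) stop("empty response trace", call. = FALSE)
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  list(R_min = q[1], R_max = q[2], S = q[2] - q[1])
}

#' Additive/subtractive offset change between light conditions
#'
#' The change in baseline between light-on and light-off, normalized by the
#' full (reference) range of responses:
#' `R_offset = (Rmin_on - Rmin_off) / (Rmax_ref - Rmin_ref)`. The reference
#' range defaults to the light-off condition's range, normalizing the light
#' effect by the control dynamic range.
#'
#' @param Rmin_on,Rmin_off 5th percentiles under light-on/off.
#' @param Rmax_ref,Rmin_ref reference range endpoints (light-off by
#'   convention).
#' @return signed dimensionless offset; `NA` with a flag when the reference
#'   range is zero.
#' @export
offset_change <- function(Rmin_on, Rmin_off, Rmax_ref, Rmin_ref) {
  rng <- Rmax_ref - Rmin_ref
  if (rng <= 0) {
    return(structure(NA_real_, flag = "zero_range"))
  }
  (Rmin_on - Rmin_off) / rng
}

#' Relative strength of contrast gain control between light conditions
#'
#' `G_relative = (S_low_on / S_high_on) / (S_low_off / S_high_off)`: the
#' ratio of contrast-gain ratios under light-on versus light-off. A value of
#' 1 indicates that the optogenetic manipulation leaves contrast gain
#' control unaffected; it is invariant to common rescaling of all four
#' ranges.
#'
#' @param S_low_on,S_high_on,S_low_off,S_high_off operating ranges `S` per
#'   light x contrast condition (all > 0).
#' @return dimensionless ratio; `NA` with a flag when any range is zero.
#' @export
relative_gain_control <- function(S_low_on, S_high_on, S_low_off, S_high_off) {
  s <- c(S_low_on, S_high_on, S_low_off, S_high_off)
  if (any(s <= 0)) {
    return(structure(NA_real_, flag = "zero_range"))
  }
  (S_low_on / S_high_on) / (S_low_off / S_high_off)
}

#' Gain ledger for one unit across light x contrast conditions
#'
#' Computes `R_min`, `R_max` and `S` for each of the four light x contrast
#' conditions, then the derived statistics: `Rmin_ratio`/`Rmax_ratio`
#' (on/off, per contrast), `R_offset` (per contrast, normalized by the
#' light-off range), `gain_ratio` (`S_on / S_off`, per contrast), and
#' `G_relative`.
#'
#' @param low_off,low_on,high_off,high_on response traces (or numeric
#'   vectors) for the four conditions.
#' @return object of class `gain_summary`: `ranges` (data frame, one row per
#'   condition) and `derived` (named list).
#' @export
gain_summary <- function(low_off, low_on, high_off, high_on) {
  conds <- list(low_off = low_off, low_on = low_on,
                high_off = high_off, high_on = high_on)
  rr <- lapply(conds, response_range)
  ranges <- data.frame(
    contrast = c("low", "low", "high", "high"),
    light = c(FALSE, TRUE, FALSE, TRUE),
    R_min = vapply(rr, `[[`, numeric(1), "R_min"),
    R_max = vapply(rr, `[[`, numeric(1), "R_max"),
    S = vapply(rr, `[[`, numeric(1), "S"),
    row.names = names(conds)
  )
  derived <- list(
    Rmin_ratio_low = rr$low_on$R_min / rr$low_off$R_min,
    Rmax_ratio_low = rr$low_on$R_max / rr$low_off$R_max,
    Rmin_ratio_high = rr$high_on$R_min / rr$high_off$R_min,
    Rmax_ratio_high = rr$high_on$R_max / rr$high_off$R_max,
    R_offset_low = offset_change(rr$low_on$R_min, rr$low_off$R_min,
                                 rr$low_off$R_max, rr$low_off$R_min),
    R_offset_high = offset_change(rr$high_on$R_min, rr$high_off$R_min,
                                  rr$high_off$R_max, rr$high_off$R_min),
    gain_ratio_low = rr$low_on$S / rr$low_off$S,
    gain_ratio_high = rr$high_on$S / rr$high_off$S,
    G_relative = relative_gain_control(rr$low_on$S, rr$high_on$S,
                                       rr$low_off$S, rr$high_off$S)
  )
  structure(list(ranges = ranges, derived = derived), class = "gain_summary")
}

#' @export
print.gain_summary <- function(x, ...) {
  cat("<gain_summary>\n")
  print(x$ranges)
  cat(sprintf("  gain ratio low %.3f, high %.3f; G_relative %.3f\n",
              x$derived$gain_ratio_low, x$derived$gain_ratio_high,
              x$derived$G_relative))
  invisible(x)
}

#' Contrast-response ratio
#'
#' Ratio of firing rates during high-contrast over low-contrast stimulation.
#'
#' @param rate_high,rate_low mean firing rates.
#' @return the ratio; when `rate_low` is zero the unit responds only during
#'   high-contrast stimulation and `Inf` is returned with a flag.
#' @export
contrast_response_ratio <- function(rate_high, rate_low) {
  if (rate_low == 0) {
    return(structure(Inf, flag = "high_contrast_only"))
  }
  rate_high / rate_low
}

#' Photo-tagging classification of putative PV-positive interneurons
#'
#' A unit is classified as a putative PVI if (a) its firing rate shows a
#' significant increase under light-on conditions, assessed by a one-sided
#' paired t test at `alpha`, and (b) its spike width is strictly less than
#' 0.25 ms (the narrow-spiking criterion, which excludes pyramidal cells
#' recruited by disinhibition).
#'
#' @param spike_width trough-to-peak spike width in ms.
#' @param rates_on,rates_off paired per-trial firing rates.
#' @param alpha significance level (default 0.05).
#' @param width_max spike-width criterion in ms (default 0.25, strict).
#' @return logical; carries the t-test p value as `attr(, "p_value")`.
#' @export
classify_putative_pvi <- function(spike_width, rates_on, rates_off,
                                  alpha = 0.05, width_max = 0.25) {
  if (length(rates_on) != length(rates_off)) {
    stop("rates_on and rates_off must be paired", call. = FALSE)
  }
  if (length(rates_on) < 3) {
    stop("classification refused: need at least 3 trial pairs", call. = FALSE)
  }
  d <- rates_on - rates_off
  if (stats::sd(d) == 0) {
    # constant paired difference: the direction is unambiguous
    p <- if (mean(d) > 0) 0 else 1
  } else {
    p <- stats::t.test(rates_on, rates_off, paired = TRUE,
                       alternative = "greater")$p.value
  }
  structure(p < alpha && spike_width < width_max, p_value = p)
}

#' Firing-rate stability across stimulus halves
#'
#' For each unit, compares the light-on/light-off firing-rate ratio in the
#' first half of the stimulus against the same ratio in the second half, and
#' tests the paired population difference with a Wilcoxon signed-rank test.
#'
#' @param rates_on,rates_off matrices (units x time bins) or lists of
#'   per-unit rate vectors, aligned in time across light conditions.
#' @param split_frac fraction of the duration defining the first half
#'   (default 0.5, i.e. 0-20 s vs 20-40 s for a 40-s stimulus).
#' @return list with `ratios` (data frame: unit, first, second), dropped
#'   unit count (`n_dropped`, zero-denominator units), and `p_value`.
#' @export
firing_stability <- function(rates_on, rates_off, split_frac = 0.5) {
  as_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else x
  }
  on <- as_list(rates_on); off <- as_list(rates_off)
  stopifnot(length(on) == length(off))
  first <- second <- rep(NA_real_, length(on))
  for (i in seq_along(on)) {
    n <- length(on[[i]])
    split <- floor(split_frac * n)
    if (split < 1 || split >= n) stop("both halves must be non-empty",
                                      call. = FALSE)
    m_off1 <- mean(off[[i]][seq_len(split)])
    m_off2 <- mean(off[[i]][seq(split + 1, n)])
    if (m_off1 == 0 || m_off2 == 0) next  # dropped: zero denominator
    first[i] <- mean(on[[i]][seq_len(split)]) / m_off1
    second[i] <- mean(on[[i]][seq(split + 1, n)]) / m_off2
  }
  ok <- !is.na(first)
  d <- first[ok] - second[ok]
  p <- if (!length(d) || all(d == 0)) 1 else
    stats::wilcox.test(first[ok], second[ok], paired = TRUE,
                       exact = FALSE)$p.value
  list(ratios = data.frame(unit = seq_along(on), first = first,
                           second = second),
       n_dropped = sum(!ok), p_value = p)
}

#' Coexpression rate from histology counts
#'
#' @param n_positive,n_total counts with `0 <= n_positive <= n_total`,
#'   `n_total > 0`.
#' @return list with `percent` (raw) and `percent_rounded` (integer percent,
#'   as printed in histology summaries).
#' @export
#' @examples
#' coexpression_rate(602, 661)$percent_rounded  # 91
coexpression_rate <- function(n_positive, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_positive < 0 || n_positive > n_total) {
    stop("need 0 <= n_positive <= n_total", call. = FALSE)
  }
  pct <- 100 * n_positive / n_total
  list(percent = pct, percent_rounded = round(pct))
}
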