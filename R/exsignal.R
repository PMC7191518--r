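# Extracellular signal processing: analog MUA and LFP extraction, PSTHs,
# noise-burst response quantification and optogenetic effect measures.

#' Continuous response trace
#'
#' Container for a continuous response signal: an analog multiunit-activity
#' (MUA) amplitude, a firing rate, or any regularly sampled response.
#'
#' @param values numeric signal.
#' @param fs sample rate in Hz (canonical analog MUA: 12,000 Hz; LN-unit
#'   rates: one sample per 25-ms chord, i.e. 40 Hz).
#' @param t0 time of the first sample in seconds.
#' @param labels named list of metadata (unit, penetration, light, contrast,
#'   layer, ...).
#' @return object of class `response_trace`.
#' @export
response_trace <- function(values, fs, t0 = 0, labels = list()) {
  stopifnot(is.numeric(values), length(values) > 0)
  assert_scalar_num(fs, lower = 1e-12)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 labels = labels),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  lab <- if (length(x$labels)) {
    paste0(" [", paste(names(x$labels), unlist(lapply(x$labels, format)),
                       sep = "=", collapse = ", "), "]")
  } else ""
  cat(sprintf("<response_trace: %d samples at %g Hz%s>\n",
              length(x$values), x$fs, lab))
  invisible(x)
}

#' Peristimulus time histogram (PSTH)
#'
#' @param bin_edges bin edges in seconds (uniform 25-ms bins by convention).
#' @param values rate (spikes/s) or MUA amplitude per bin.
#' @param n_trials number of contributing trials.
#' @param light logical light condition.
#' @param masked logical per bin; masked bins (e.g. light-artifact bins) are
#'   skipped by downstream peak/baseline measures.
#' @return object of class `psth`.
#' @export
psth <- function(bin_edges, values, n_trials, light = FALSE,
                 masked = rep(FALSE, length(values))) {
  stopifnot(length(bin_edges) == length(values) + 1,
            length(masked) == length(values))
  structure(list(bin_edges = bin_edges, values = as.numeric(values),
                 n_trials = n_trials, light = light, masked = masked),
            class = "psth")
}

bin_centers <- function(p) p$bin_edges[-length(p$bin_edges)] +
  diff(p$bin_edges) / 2

# rational resampling factors for integer sample rates
resample_factors <- function(fs_in, fs_out) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(fs_out), round(fs_in))
  list(p = round(fs_out) / d, q = round(fs_in) / d)
}

#' Extract analog multiunit activity (MUA) from a raw voltage trace
#'
#' Measures the signal power in the spike band: band-pass filter 300-6,000 Hz
#' (4th-order Butterworth by default), full-wave rectify, low-pass filter
#' below 6,000 Hz, and resample to 12,000 Hz. All filtering is zero-phase
#' (forward-backward), so response peaks are not delayed; resampling uses
#' polyphase anti-aliased decimation.
#'
#' @param raw numeric voltage trace.
#' @param fs input sample rate in Hz (>= 24 kHz so the 6-kHz band edge is
#'   below Nyquist).
#' @param band band-pass corners in Hz (default `c(300, 6000)`).
#' @param order band-pass filter order (default 4).
#' @param fs_out output sample rate (default 12,000 Hz).
#' @param labels metadata passed to the output trace.
#' @return a [response_trace()] at `fs_out`; values are non-negative.
#' @export
analog_mua <- function(raw, fs, band = c(300, 6000), order = 4,
                       fs_out = 12000, labels = list()) {
  assert_scalar_num(fs, lower = 1e-12)
  if (fs < 4 * band[2]) {
    stop(sprintf("input rate %g Hz is too low for a %g-Hz band edge (need >= %g Hz)",
                 fs, band[2], 4 * band[2]), call. = FALSE)
  }
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, raw)
  x <- abs(x)
  lp <- signal::butter(order, band[2] / (fs / 2) * 0.999, type = "low")
  x <- signal::filtfilt(lp, x)
  rf <- resample_factors(fs, fs_out)
  if (rf$p != rf$q) x <- signal::resample(x, rf$p, rf$q)
  response_trace(pmax(x, 0), fs = fs_out, labels = labels)
}

#' Extract the local field potential (LFP)
#'
#' Low-pass filters the raw trace below 300 Hz with an 8th-order Chebyshev
#' Type I filter (configurable passband ripple), applied zero-phase.
#'
#' @param raw numeric voltage trace.
#' @param fs input sample rate in Hz (> 600).
#' @param corner low-pass corner in Hz (default 300).
#' @param ripple passband ripple in dB (default 0.05).
#' @param labels metadata passed to the output trace.
#' @return a [response_trace()] at the input rate.
#' @export
extract_lfp <- function(raw, fs, corner = 300, ripple = 0.05,
                        labels = list()) {
  assert_scalar_num(fs, lower = 1e-12)
  if (fs <= 2 * corner) {
    stop(sprintf("input rate %g Hz must exceed twice the %g-Hz corner",
                 fs, corner), call. = FALSE)
  }
  ch <- signal::cheby1(8, ripple, corner / (fs / 2), type = "low")
  response_trace(signal::filtfilt(ch, raw), fs = fs, labels = labels)
}

#' Build a PSTH from spike times or a continuous trace
#'
#' Bins spike times (or bin-averages a continuous trace) into 25-ms bins
#' over `window`. If `light_onset` is given, the two bins at and after light
#' onset are masked to exclude photoelectric artifacts.
#'
#' @param x either a list of per-trial spike-time vectors (seconds), or a
#'   [response_trace()].
#' @param window `c(start, end)` in seconds, relative to stimulus onset.
#' @param bin bin width in seconds (default 0.025).
#' @param light_onset optional light-onset time in seconds; the two bins
#'   starting at or after it are masked.
#' @param light logical light condition recorded in the output.
#' @return a [psth()]; rates are `count / (n_trials * bin)` for spike input,
#'   or mean amplitude per bin for trace input.
#' @export
build_psth <- function(x, window, bin = 0.025, light_onset = NULL,
                       light = !is.null(light_onset)) {
  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1L
  if (inherits(x, "response_trace")) {
    t <- x$t0 + (seq_along(x$values) - 1) / x$fs
    idx <- findInterval(t, edges, rightmost.closed = TRUE)
    vals <- vapply(seq_len(n_bins), function(b) {
      v <- x$values[idx == b]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    n_trials <- 1L
  } else {
    stopifnot(is.list(x))
    n_trials <- length(x)
    all_t <- unlist(x, use.names = FALSE)
    all_t <- all_t[all_t >= window[1] & all_t < window[2]]
    counts <- if (length(all_t)) {
      tabulate(findInterval(all_t, edges), nbins = n_bins)
    } else numeric(n_bins)
    vals <- counts / (max(n_trials, 1L) * bin)
  }
  masked <- rep(FALSE, n_bins)
  if (!is.null(light_onset)) {
    first <- which(edges[-length(edges)] >= light_onset - 1e-9)[1]
    if (!is.na(first)) masked[first + 0:1] <- first + 0:1 <= n_bins
  }
  psth(edges, vals, n_trials = n_trials, light = light, masked = masked)
}

#' Peak response to a noise burst
#'
#' The peak response is the largest-amplitude unmasked bin within 150 ms of
#' noise onset (six 25-ms bins).
#'
#' @param p a [psth()].
#' @param noise_onset noise onset in seconds.
#' @param search_window search window after onset in seconds (default 0.15).
#' @return list with `peak` (amplitude), `latency_bin` (index into the PSTH)
#'   and `latency_s` (bin start relative to onset).
#' @export
peak_noise_response <- function(p, noise_onset, search_window = 0.15) {
  stopifnot(inherits(p, "psth"))
  ctr <- bin_centers(p)
  cand <- which(ctr >= noise_onset & ctr < noise_onset + search_window &
                  !p$masked)
  if (!length(cand)) {
    stop("no unmasked bins within the peak search window", call. = FALSE)
  }
  b <- cand[which.max(p$values[cand])]
  list(peak = p$values[b], latency_bin = b,
       latency_s = p$bin_edges[b] - noise_onset)
}

#' Baseline activity of a PSTH
#'
#' Mean over all unmasked bins before sound onset (t < 0).
#'
#' @param p a [psth()].
#' @param sound_onset sound onset in seconds (default 0).
#' @return mean baseline amplitude.
#' @export
psth_baseline <- function(p, sound_onset = 0) {
  ctr <- bin_centers(p)
  pre <- which(ctr < sound_onset & !p$masked)
  if (!length(pre)) stop("no unmasked pre-onset baseline bins", call. = FALSE)
  mean(p$values[pre])
}

#' Quantify the optogenetic effect on a noise response
#'
#' Percent change of the peak noise response between light-on and light-off
#' PSTHs, plus the same measure for pre-sound baseline activity.
#'
#' @param psth_on,psth_off light-on and light-off [psth()]s over matched
#'   windows.
#' @param noise_onset noise onset in seconds.
#' @return list with `peak_change_pct`, `baseline_change_pct`, and the
#'   underlying peaks/baselines. If the light-off peak is zero the change is
#'   `NA` with `flag = "zero_reference"`.
#' @export
opto_effect <- function(psth_on, psth_off, noise_onset = 0) {
  pk_on <- peak_noise_response(psth_on, noise_onset)
  pk_off <- peak_noise_response(psth_off, noise_onset)
  base_on <- psth_baseline(psth_on)
  base_off <- psth_baseline(psth_off)
  flag <- NULL
  peak_change <- if (pk_off$peak == 0) {
    flag <- "zero_reference"
    NA_real_
  } else 100 * (pk_on$peak - pk_off$peak) / pk_off$peak
  baseline_change <- if (base_off == 0) NA_real_ else
    100 * (base_on - base_off) / base_off
  list(peak_change_pct = peak_change, baseline_change_pct = baseline_change,
       peak_on = pk_on$peak, peak_off = pk_off$peak,
       baseline_on = base_on, baseline_off = base_off, flag = flag)
}

#' Noise responsiveness criterion
#'
#' A unit counts as noise responsive if its peak response is at least a
#' doubling of baseline firing (inclusive).
#'
#' @param p a [psth()].
#' @param noise_onset noise onset in seconds.
#' @return logical; if the baseline is zero the criterion degenerates to
#'   `peak > 0` and the result carries `attr(, "degenerate") = TRUE`.
#' @export
is_noise_responsive <- function(p, noise_onset = 0) {
  pk <- peak_noise_response(p, noise_onset)$peak
  base <- psth_baseline(p)
  if (base == 0) {
    return(structure(pk > 0, degenerate = TRUE))
  }
  pk >= 2 * base
}
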