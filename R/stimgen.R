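#' Contrast condition for dynamic random chord stimuli
#'
#' A contrast condition fixes the uniform distribution from which per-tone
#' sound levels are drawn: its mean and its width (range). The canonical
#' conditions keep the mean at 40 dB SPL and use a 20-dB range ("low"
#' contrast) or a 40-dB range ("high" contrast), so that the high-contrast
#' level SD is twice the low-contrast one.
#'
#' @param name `"low"` or `"high"`, or any label when `mean_level` and
#'   `level_range` are given explicitly.
#' @param mean_level mean tone level in dB SPL (default 40).
#' @param level_range width of the uniform level distribution in dB
#'   (default 20 for `"low"`, 40 for `"high"`).
#' @return object of class `contrast_condition` with fields `name`,
#'   `mean_level`, `level_range`, plus the implied level SD
#'   (`sigma_L_nominal = level_range / sqrt(12)`).
#' @export
#' @examples
#' contrast_condition("high")
contrast_condition <- function(name = c("low", "high"),
                               mean_level = 40,
                               level_range = NULL) {
  if (is.null(level_range)) {
    name <- match.arg(name)
    level_range <- switch(name, low = 20, high = 40)
  }
  assert_scalar_num(mean_level, lower = 0)
  assert_scalar_num(level_range, lower = 0)
  if (mean_level - level_range / 2 < 0) {
    stop("level distribution extends below 0 dB SPL: ",
         "require mean_level - level_range/2 >= 0", call. = FALSE)
  }
  structure(
    list(name = name, mean_level = mean_level, level_range = level_range,
         sigma_L_nominal = level_range / sqrt(12)),
    class = "contrast_condition"
  )
}

#' @export
print.contrast_condition <- function(x, ...) {
  cat(sprintf("<contrast_condition '%s': mean %g dB SPL, range %g dB, sigma_L %0.2f dB>\n",
              x$name, x$mean_level, x$level_range, x$sigma_L_nominal))
  invisible(x)
}

#' Quarter-octave frequency axis
#'
#' Geometric frequency sequence with ratio 2^(1/4), endpoints inclusive. The
#' span must be a whole number of octaves. The canonical axis, 1-64 kHz,
#' yields 25 tone frequencies.
#'
#' @param f_lo,f_hi endpoint frequencies in Hz; `f_hi` must equal
#'   `f_lo * 2^k` for an integer `k >= 1`.
#' @return ascending numeric vector of frequencies in Hz.
#' @export
#' @examples
#' length(quarter_octave_axis(1000, 64000))  # 25
quarter_octave_axis <- function(f_lo, f_hi) {
  assert_scalar_num(f_lo, lower = 1e-12)
  assert_scalar_num(f_hi, lower = 1e-12)
  k <- log2(f_hi / f_lo)
  if (k < 1 - 1e-9 || abs(k - round(k)) > 1e-9) {
    stop(sprintf(
      "span f_hi/f_lo = %g is not a power of two >= 2; a quarter-octave axis needs a whole number of octaves",
      f_hi / f_lo), call. = FALSE)
  }
  f_lo * 2^(seq(0, round(k), by = 0.25))
}

#' Generate a dynamic random chord (DRC) stimulus
#'
#' A DRC is a sequence of chords, each the superposition of pure tones at
#' fixed frequencies; the level (dB SPL) of each tone is redrawn for every
#' chord from the condition's uniform distribution, independently across
#' tones and chords. Chords last 25 ms with 5-ms linear onset/offset ramps.
#' Tone phases are randomized once per tone from the stimulus seed.
#'
#' @param condition a [contrast_condition()].
#' @param duration total duration in seconds; must be a positive multiple of
#'   `chord_dur`. The canonical sequence is 40 s = 1,600 chords.
#' @param seed integer seed; levels and phases are reproducible under it.
#' @param f_lo,f_hi frequency axis endpoints (default 1-64 kHz, giving 25
#'   quarter-octave-spaced tones).
#' @param chord_dur chord duration in seconds (default 0.025).
#' @param ramp_dur linear ramp duration in seconds (default 0.005).
#' @param level_step optional dB step for a discretized level distribution;
#'   `NULL` (default) draws from the continuous uniform.
#' @return object of class `drc_stimulus`: fields `freqs_hz`, `levels`
#'   (n_freqs x n_chords matrix, dB SPL), `chord_dur`, `ramp_dur`, `seed`,
#'   `condition`, `phases` (radians, one per tone), and `noise_burst`
#'   (`NULL` until [embed_noise_burst()] is applied).
#' @export
#' @examples
#' drc <- generate_drc(contrast_condition("low"), duration = 1, seed = 1)
#' dim(drc$levels)  # 25 x 40
generate_drc <- function(condition, duration, seed,
                         f_lo = 1000, f_hi = 64000,
                         chord_dur = 0.025, ramp_dur = 0.005,
                         level_step = NULL) {
  stopifnot(inherits(condition, "contrast_condition"))
  assert_scalar_num(duration, lower = 1e-12)
  n_chords <- duration / chord_dur
  if (abs(n_chords - round(n_chords)) > 1e-9) {
    stop(sprintf("duration %g s is not a multiple of chord_dur %g s",
                 duration, chord_dur), call. = FALSE)
  }
  n_chords <- as.integer(round(n_chords))
  freqs <- quarter_octave_axis(f_lo, f_hi)
  n_freqs <- length(freqs)
  lo <- condition$mean_level - condition$level_range / 2
  hi <- condition$mean_level + condition$level_range / 2
  out <- with_seed(seed, {
    phases <- stats::runif(n_freqs, 0, 2 * pi)
    levels <- if (condition$level_range == 0) {
      matrix(condition$mean_level, n_freqs, n_chords)
    } else if (is.null(level_step)) {
      matrix(stats::runif(n_freqs * n_chords, lo, hi), n_freqs, n_chords)
    } else {
      grid <- seq(lo, hi, by = level_step)
      matrix(sample(grid, n_freqs * n_chords, replace = TRUE),
             n_freqs, n_chords)
    }
    list(phases = phases, levels = levels)
  })
  structure(
    list(freqs_hz = freqs, levels = out$levels,
         chord_dur = chord_dur, ramp_dur = ramp_dur,
         seed = seed, condition = condition, phases = out$phases,
         noise_burst = NULL),
    class = "drc_stimulus"
  )
}

#' @export
print.drc_stimulus <- function(x, ...) {
  cat(sprintf("<drc_stimulus: %d tones x %d chords (%g s), condition '%s', seed %s>\n",
              nrow(x$levels), ncol(x$levels), ncol(x$levels) * x$chord_dur,
              x$condition$name, format(x$seed)))
  if (!is.null(x$noise_burst)) {
    cat(sprintf("  noise burst: chords %s replaced (%g dB SPL, seed %d)\n",
                paste(range(x$noise_burst$chords), collapse = "-"),
                x$noise_burst$level, x$noise_burst$seed))
  }
  invisible(x)
}

#' Duration of a DRC stimulus in seconds
#' @param drc a `drc_stimulus`.
#' @return duration in seconds.
#' @export
drc_duration <- function(drc) ncol(drc$levels) * drc$chord_dur

# per-chord amplitude envelope with overlap-added linear cross-fade ramps:
# chord k ramps up over its first ramp_dur while chord k-1 ramps down over the
# same interval, so each chord occupies one 25-ms period of the output.
chord_envelope <- function(i, n_chords, chord_dur, ramp_dur, fs, n_total) {
  t0 <- (i - 1) * chord_dur
  i0 <- floor(t0 * fs)                        # first sample index (0-based)
  i1 <- min(ceiling((t0 + chord_dur + ramp_dur) * fs), n_total) - 1L
  idx <- i0:i1
  t <- idx / fs - t0
  env <- pmin(1, t / ramp_dur)
  env <- pmin(env, pmax(0, 1 - (t - chord_dur) / ramp_dur))
  list(idx = idx + 1L, env = pmax(0, env), t = idx / fs)
}

#' Synthesize the audio waveform of a DRC
#'
#' Each tone is rendered as a phase-continuous sinusoid whose amplitude is set
#' chord-by-chord from the level matrix (dB SPL mapped to linear amplitude
#' against a calibration reference), with 5-ms linear ramps per chord.
#' Consecutive chords cross-fade (a chord's onset ramp overlaps the previous
#' chord's offset ramp) so the chord period stays exactly `chord_dur`. Chords
#' claimed by an embedded noise burst are rendered as frozen broadband noise
#' instead.
#'
#' @param drc a `drc_stimulus`.
#' @param sample_rate output sample rate in Hz; must be at least twice the
#'   highest tone frequency. The hardware rate used with ultrasonic stimuli
#'   is 200 kHz.
#' @param ref_db,ref_amp calibration: a tone at `ref_db` dB SPL has peak
#'   amplitude `ref_amp` (defaults 94 dB SPL -> 1.0). Only relative levels
#'   matter downstream.
#' @return numeric waveform of length `duration * sample_rate`, with
#'   attributes `sample_rate`, `ref_db`, `ref_amp`.
#' @export
synthesize_waveform <- function(drc, sample_rate, ref_db = 94, ref_amp = 1) {
  stopifnot(inherits(drc, "drc_stimulus"))
  assert_scalar_num(sample_rate, lower = 1)
  if (sample_rate < 2 * max(drc$freqs_hz)) {
    stop(sprintf(
      "sample_rate %g Hz aliases the %g-Hz tone; need >= %g Hz",
      sample_rate, max(drc$freqs_hz), 2 * max(drc$freqs_hz)), call. = FALSE)
  }
  n_chords <- ncol(drc$levels)
  n_total <- as.integer(round(n_chords * drc$chord_dur * sample_rate))
  wave <- numeric(n_total)
  burst_chords <- if (is.null(drc$noise_burst)) integer() else drc$noise_burst$chords

  amp <- ref_amp * 10^((drc$levels - ref_db) / 20)   # dB SPL -> linear
  two_pi_f <- 2 * pi * drc$freqs_hz
  for (i in seq_len(n_chords)) {
    ce <- chord_envelope(i, n_chords, drc$chord_dur, drc$ramp_dur,
                         sample_rate, n_total)
    if (i %in% burst_chords) next
    # tones x samples: sin(2 pi f t + phi) weighted by this chord's amplitudes
    seg <- amp[, i] * sin(outer(two_pi_f, ce$t) + drc$phases)
    wave[ce$idx] <- wave[ce$idx] + colSums(seg) * ce$env
  }

  if (length(burst_chords)) {
    nb <- drc$noise_burst
    burst_amp <- ref_amp * 10^((nb$level - ref_db) / 20)
    for (i in burst_chords) {
      ce <- chord_envelope(i, n_chords, drc$chord_dur, drc$ramp_dur,
                           sample_rate, n_total)
      noise <- with_seed(nb$seed + i, stats::rnorm(length(ce$idx)))
      # frozen Gaussian noise scaled so RMS matches a tone at the burst level
      wave[ce$idx] <- wave[ce$idx] + burst_amp / sqrt(2) * noise * ce$env
    }
  }
  attr(wave, "sample_rate") <- sample_rate
  attr(wave, "ref_db") <- ref_db
  attr(wave, "ref_amp") <- ref_amp
  wave
}

#' Embed a frozen broadband noise burst in a DRC
#'
#' Replaces the chords overlapping `[onset, onset + burst_dur)` with frozen
#' broadband noise (identical waveform across repeats for a given seed). The
#' standard probe is a 50-ms burst 500 ms into a 1-s DRC, replacing two 25-ms
#' chords. The level matrix is left intact; the substitution is recorded in
#' the stimulus metadata and honoured by [synthesize_waveform()].
#'
#' @param drc a `drc_stimulus`.
#' @param onset burst onset in seconds; must align to a chord boundary.
#' @param burst_dur burst duration in seconds; must be a multiple of the
#'   chord duration. Zero leaves the stimulus unchanged.
#' @param seed integer seed freezing the noise waveform.
#' @param level noise level in dB SPL (default 80, the standard probe level).
#' @return the modified `drc_stimulus`.
#' @export
embed_noise_burst <- function(drc, onset, burst_dur, seed, level = 80) {
  stopifnot(inherits(drc, "drc_stimulus"))
  assert_scalar_num(onset, lower = 0)
  assert_scalar_num(burst_dur, lower = 0)
  if (burst_dur == 0) return(drc)
  cd <- drc$chord_dur
  k0 <- onset / cd
  nk <- burst_dur / cd
  if (abs(k0 - round(k0)) > 1e-9 || abs(nk - round(nk)) > 1e-9) {
    stop("noise burst onset and duration must align to chord boundaries",
         call. = FALSE)
  }
  chords <- round(k0) + seq_len(round(nk))
  if (max(chords) > ncol(drc$levels)) {
    stop("noise burst extends past the end of the stimulus", call. = FALSE)
  }
  drc$noise_burst <- list(chords = chords, onset = onset,
                          dur = burst_dur, seed = as.integer(seed),
                          level = level)
  drc
}

#' Alternating-contrast DRC sequence
#'
#' Builds `n_reps` one-second DRC segments that alternate between low and
#' high contrast (starting with low) while keeping the same spectrotemporal
#' pattern: a single standard-uniform pattern is drawn once and mapped
#' affinely onto each condition's level distribution, so per-chord rank order
#' is identical across segments and a mid-range level (the 40-dB mean) maps
#' to itself in both conditions. The first low-contrast segment is flagged
#' for exclusion from analysis to avoid silence-to-sound onset responses.
#'
#' @param n_reps number of segments (>= 2); the standard protocol uses 11.
#' @param seed integer seed for the shared pattern and tone phases.
#' @param segment_dur duration of each segment in seconds (default 1).
#' @param low,high the two [contrast_condition()]s.
#' @param f_lo,f_hi,chord_dur,ramp_dur as in [generate_drc()].
#' @return object of class `drc_sequence`: a list of `drc_stimulus` segments,
#'   each with an `exclude` flag (TRUE only for the first segment) and the
#'   shared `pattern` stored as an attribute.
#' @export
alternating_contrast_sequence <- function(n_reps, seed, segment_dur = 1,
                                          low = contrast_condition("low"),
                                          high = contrast_condition("high"),
                                          f_lo = 1000, f_hi = 64000,
                                          chord_dur = 0.025, ramp_dur = 0.005) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  n_chords <- round(segment_dur / chord_dur)
  freqs <- quarter_octave_axis(f_lo, f_hi)
  n_freqs <- length(freqs)
  pat <- with_seed(seed, {
    list(u = matrix(stats::runif(n_freqs * n_chords), n_freqs, n_chords),
         phases = stats::runif(n_freqs, 0, 2 * pi))
  })
  segments <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cond <- if (r %% 2 == 1) low else high
    levels <- cond$mean_level + (pat$u - 0.5) * cond$level_range
    seg <- structure(
      list(freqs_hz = freqs, levels = levels,
           chord_dur = chord_dur, ramp_dur = ramp_dur,
           seed = seed, condition = cond, phases = pat$phases,
           noise_burst = NULL),
      class = "drc_stimulus"
    )
    seg$exclude <- (r == 1L)
    segments[[r]] <- seg
  }
  structure(segments, class = "drc_sequence", pattern = pat)
}

#' Measure the level SD and waveform contrast of a DRC
#'
#' `sigma_L` is the SD of the level-matrix entries in dB. The waveform
#' contrast `c` is the SD over mean of the amplitude envelope of the
#' synthesized waveform, with the envelope computed from the analytic signal
#' (Hilbert transform); this definition is recorded in the output.
#'
#' @param drc a `drc_stimulus`.
#' @param audio optional waveform from [synthesize_waveform()]; if `NULL`,
#'   only `sigma_L` is computed and requesting `c` is an error.
#' @param want_c compute the envelope contrast (requires `audio`).
#' @return list with `sigma_L` (dB), `c` (dimensionless or `NA`), and
#'   `c_definition`.
#' @export
measure_contrast <- function(drc, audio = NULL, want_c = !is.null(audio)) {
  stopifnot(inherits(drc, "drc_stimulus"))
  sigma_L <- stats::sd(as.vector(drc$levels))
  cval <- NA_real_
  if (want_c) {
    if (is.null(audio)) {
      stop("waveform contrast `c` requested but no synthesized audio supplied",
           call. = FALSE)
    }
    env <- envelope_analytic(as.numeric(audio))
    cval <- stats::sd(env) / mean(env)
  }
  list(sigma_L = sigma_L, c = cval,
       c_definition = "sd/mean of analytic-signal envelope of full waveform")
}
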