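# Synthetic extracellular and intracellular data generators. These provide
# ground truth for every downstream analysis stage, so that STRF fitting,
# gain statistics, access-resistance compensation and conductance estimation
# can all be validated by parameter recovery.

#' Ground-truth parameters for a simulated linear-nonlinear (LN) unit
#'
#' Defines a rank-1 spectrotemporal kernel (frequency kernel x history
#' kernel) feeding an output nonlinearity whose gain depends on stimulus
#' contrast and on a simulated optogenetic light condition. Contrast gain
#' control is encoded by `gain_low / gain_high`: a ratio of 2 exactly
#' compensates the doubling of the level SD between the canonical low- and
#' high-contrast conditions. The light condition multiplies gain by
#' `light_gain_factor` (identically at both contrasts) and adds
#' `light_offset`.
#'
#' @param true_kf frequency kernel weights (one per tone; 25 for the
#'   canonical axis).
#' @param true_kh history kernel weights (one per 25-ms lag); rescaled to
#'   unit L2 norm.
#' @param bias baseline response level (response units).
#' @param gain_low,gain_high multiplicative output gain per contrast
#'   condition (> 0).
#' @param light_gain_factor multiplicative effect of light on gain (> 0).
#' @param light_offset additive effect of light (response units).
#' @param noise_sd SD of additive Gaussian response noise (>= 0).
#' @param nonlinearity `"halfwave"` (half-wave-rectified linear, the
#'   default), `"logistic"`, or `"linear"` (identity; the degenerate case
#'   used for exact-recovery validation).
#' @param seed integer seed for response noise.
#' @return object of class `ln_unit_params`.
#' @export
ln_unit_params <- function(true_kf, true_kh, bias = 0,
                           gain_low = 2, gain_high = 1,
                           light_gain_factor = 1, light_offset = 0,
                           noise_sd = 0,
                           nonlinearity = c("halfwave", "logistic", "linear"),
                           seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(length(true_kf) >= 1, length(true_kh) >= 1)
  if (gain_low <= 0 || gain_high <= 0 || light_gain_factor <= 0) {
    stop("gains must be positive", call. = FALSE)
  }
  assert_scalar_num(noise_sd, lower = 0)
  nrm <- sqrt(sum(true_kh^2))
  if (nrm == 0) stop("true_kh must be non-zero", call. = FALSE)
  structure(
    list(true_kf = as.numeric(true_kf), true_kh = as.numeric(true_kh) / nrm,
         bias = bias, gain_low = gain_low, gain_high = gain_high,
         light_gain_factor = light_gain_factor, light_offset = light_offset,
         noise_sd = noise_sd, nonlinearity = nonlinearity,
         seed = as.integer(seed)),
    class = "ln_unit_params"
  )
}

# rank-1 linear drive of an LN unit: per-chord convolution of the level
# matrix with outer(kf, kh). Chords before stimulus onset are treated as the
# condition mean level, so the drive is defined for every chord.
ln_drive <- function(levels, kf, kh, pad_level) {
  n_h <- length(kh)
  n_chords <- ncol(levels)
  if (n_h > n_chords) {
    stop("history kernel is longer than the stimulus", call. = FALSE)
  }
  padded <- cbind(matrix(pad_level, nrow(levels), n_h - 1), levels)
  proj <- as.numeric(crossprod(kf, padded))   # kf . levels per (padded) chord
  drive <- numeric(n_chords)
  for (l in seq_len(n_h)) {
    drive <- drive + kh[l] * proj[(n_h - l) + seq_len(n_chords)]
  }
  drive
}

apply_nonlinearity <- function(x, type) {
  switch(type,
         halfwave = pmax(x, 0),
         logistic = 1 / (1 + exp(-x)),
         linear = x)
}

#' Simulate an LN unit's response to a DRC
#'
#' The per-chord drive is the convolution of the stimulus level matrix with
#' the rank-1 kernel `outer(true_kf, true_kh)`. The response rate is
#' `bias + light_offset * light + gain * f(drive)` with additive Gaussian
#' noise, floored at zero; `gain` is the contrast-appropriate gain times the
#' light gain factor when the light is on.
#'
#' @param params an [ln_unit_params()].
#' @param drc a `drc_stimulus` (its `condition$name` selects
#'   `gain_low`/`gain_high`).
#' @param light_on logical: is the optogenetic light on?
#' @return a [response_trace()] at the chord rate (one sample per 25-ms
#'   chord) with labels `light` and `contrast`.
#' @export
simulate_ln_unit <- function(params, drc, light_on = FALSE) {
  stopifnot(inherits(params, "ln_unit_params"), inherits(drc, "drc_stimulus"))
  drive <- ln_drive(drc$levels, params$true_kf, params$true_kh,
                    pad_level = drc$condition$mean_level)
  gain <- if (identical(drc$condition$name, "high")) params$gain_high else params$gain_low
  if (light_on) gain <- gain * params$light_gain_factor
  rate <- params$bias + params$light_offset * light_on +
    gain * apply_nonlinearity(drive, params$nonlinearity)
  if (params$noise_sd > 0) {
    rate <- rate + with_seed(params$seed + 7L * light_on +
                               13L * identical(drc$condition$name, "high"),
                             stats::rnorm(length(rate), 0, params$noise_sd))
  }
  response_trace(pmax(rate, 0), fs = 1 / drc$chord_dur,
                 labels = list(light = light_on,
                               contrast = drc$condition$name))
}

#' Simulate a light-on/light-off PSTH pair for a noise-burst probe
#'
#' Generates Poisson-count peristimulus time histograms around a noise-burst
#' onset at t = 0. The firing-rate profile is `baseline` before onset and an
#' exponentially decaying evoked transient peaking at `peak` after onset.
#' The light condition scales the post-onset rate by
#' `1 + light_effect_pct / 100`, so the constructed peak change equals
#' `light_effect_pct` exactly in expectation; baseline (t < 0) is untouched.
#'
#' @param baseline,peak firing rates in spikes/s (`peak >= baseline >= 0`).
#' @param light_effect_pct percent change of the evoked response under light.
#' @param n_trials trials per condition.
#' @param seed integer seed.
#' @param window time window in seconds around onset (default -0.25 to 0.5).
#' @param bin bin width in seconds (default 0.025).
#' @param decay_tau decay time constant of the evoked transient in seconds.
#' @return list with `on` and `off` [psth()] objects and the construction
#'   truth (`truth$peak_change_pct`).
#' @export
simulate_noise_psth <- function(baseline, peak, light_effect_pct = 0,
                                n_trials = 50, seed = 1L,
                                window = c(-0.25, 0.5), bin = 0.025,
                                decay_tau = 0.05) {
  assert_scalar_num(baseline, lower = 0)
  assert_scalar_num(peak, lower = baseline)
  edges <- seq(window[1], window[2], by = bin)
  centers <- edges[-length(edges)] + bin / 2
  rate_off <- ifelse(centers < 0, baseline,
                     baseline + (peak - baseline) *
                       exp(-pmax(centers - bin / 2, 0) / decay_tau))
  scale_on <- 1 + light_effect_pct / 100
  rate_on <- ifelse(centers < 0, rate_off, rate_off * scale_on)
  counts <- with_seed(seed, {
    list(off = stats::rpois(length(centers), rate_off * bin * n_trials),
         on = stats::rpois(length(centers), rate_on * bin * n_trials))
  })
  list(
    off = psth(edges, counts$off / (n_trials * bin), n_trials, light = FALSE),
    on = psth(edges, counts$on / (n_trials * bin), n_trials, light = TRUE),
    truth = list(peak_change_pct = light_effect_pct,
                 baseline = baseline, peak = peak)
  )
}

#' Simulation parameters for in vivo whole-cell recordings
#'
#' Describes a passive membrane (input resistance and time constant) recorded
#' through an electrode with access resistance `R_access` whose voltage drop
#' is low-passed with time constant `tau_access`, plus spontaneous up states
#' (rectangular depolarizing plateaus arriving as a Poisson process), inserted
#' stereotyped spikes when the membrane crosses threshold, and Gaussian trial
#' noise.
#'
#' @param R_input input resistance in megaohms.
#' @param tau_input membrane time constant in ms.
#' @param R_access electrode access resistance in megaohms (>= 0).
#' @param tau_access electrode time constant in ms (< `tau_input`).
#' @param E_rest resting potential in mV.
#' @param E_syn synaptic reversal potential in mV.
#' @param g_syn_peak peak synaptic conductance in nS used when the drive is
#'   derived from a DRC stimulus.
#' @param up_state_rate Poisson rate of spontaneous up states in Hz.
#' @param up_amp,up_amp_jitter,up_dur up-state amplitude (mV), amplitude SD
#'   across events (mV), and duration (ms).
#' @param spike_threshold membrane potential at which a stereotyped spike is
#'   inserted, in mV; `Inf` disables spiking.
#' @param trial_noise_sd SD of white recording noise in mV.
#' @param seed integer seed.
#' @return object of class `patch_sim_params`.
#' @export
patch_sim_params <- function(R_input = 100, tau_input = 20,
                             R_access = 20, tau_access = 0.5,
                             E_rest = -70, E_syn = 0, g_syn_peak = 3,
                             up_state_rate = 0, up_amp = 15,
                             up_amp_jitter = 2, up_dur = 300,
                             spike_threshold = Inf,
                             trial_noise_sd = 0.3, seed = 1L) {
  assert_scalar_num(R_input, lower = 1e-9)
  assert_scalar_num(R_access, lower = 0)
  if (tau_access >= tau_input) {
    stop("tau_access must be smaller than tau_input", call. = FALSE)
  }
  assert_scalar_num(trial_noise_sd, lower = 0)
  structure(
    list(R_input = R_input, tau_input = tau_input,
         R_access = R_access, tau_access = tau_access,
         E_rest = E_rest, E_syn = E_syn, g_syn_peak = g_syn_peak,
         up_state_rate = up_state_rate, up_amp = up_amp,
         up_amp_jitter = up_amp_jitter, up_dur = up_dur,
         spike_threshold = spike_threshold,
         trial_noise_sd = trial_noise_sd, seed = as.integer(seed)),
    class = "patch_sim_params"
  )
}

#' Synaptic conductance drive derived from a DRC level matrix
#'
#' Maps the summed per-chord tone level (relative to its minimum) linearly to
#' `[0, g_peak]` nS, sample-held within each chord and smoothed with a 2-ms
#' exponential filter so conductance transients have realistic rise times.
#'
#' @param drc a `drc_stimulus`.
#' @param fs sample rate in Hz.
#' @param g_peak peak conductance in nS.
#' @param smooth_tau smoothing time constant in ms.
#' @param burst_factor drive assigned to embedded noise-burst chords, as a
#'   multiple of `g_peak` (a loud broadband burst drives the cell harder
#'   than any chord; default 1.5).
#' @return numeric conductance vector (nS) of length `duration * fs`.
#' @export
drc_conductance_drive <- function(drc, fs, g_peak = 3, smooth_tau = 2,
                                  burst_factor = 1.5) {
  per_chord <- colSums(drc$levels)
  rng <- range(per_chord)
  g_chord <- if (diff(rng) == 0) rep(0.5 * g_peak, length(per_chord)) else
    g_peak * (per_chord - rng[1]) / diff(rng)
  if (!is.null(drc$noise_burst)) {
    g_chord[drc$noise_burst$chords] <- burst_factor * g_peak
  }
  spc <- round(drc$chord_dur * fs)
  g <- rep(g_chord, each = spc)
  a <- exp(-1000 / fs / smooth_tau)
  as.numeric(stats::filter(g * (1 - a), a, method = "recursive"))
}

# stereotyped action-potential waveform inserted at threshold crossings:
# sharp-onset rise (exponential, giving a d2V/dt2 kink at onset), fast fall,
# brief afterhyperpolarization. Returns mV relative to the onset voltage.
spike_waveform <- function(fs, height = 60, rise_ms = 0.3, fall_ms = 0.5,
                           ahp_mV = 4, ahp_ms = 2) {
  dt <- 1000 / fs
  t_rise <- seq(0, rise_ms, by = dt)
  rise <- height * (exp(t_rise / rise_ms * 3) - 1) / (exp(3) - 1)
  t_fall <- seq(dt, fall_ms, by = dt)
  fall <- height * exp(-3 * t_fall / fall_ms) * (1 + ahp_mV / height) - ahp_mV
  t_ahp <- seq(dt, ahp_ms, by = dt)
  ahp <- -ahp_mV * (1 - t_ahp / ahp_ms)
  c(rise, fall, ahp)
}

#' Simulate a set of whole-cell voltage sweeps
#'
#' Each sweep consists of a pre-stimulus pulse epoch (a square current
#' waveform: `pulse_cycles` cycles at `pulse_hz`, amplitude `pulse_amp` pA,
#' 50% duty cycle) followed by a stimulus epoch during which the sweep's
#' holding current `I_inj` is applied and the synaptic conductance drive
#' plays. The passive membrane is integrated by exponential Euler; the
#' recorded voltage adds the electrode component (`I * R_access` low-passed
#' at `tau_access`), inserted up states and spikes, and white trial noise.
#'
#' @param params a [patch_sim_params()].
#' @param I_levels injected-current levels in pA (one sweep subset per
#'   level); at least 2 levels are needed for conductance recovery.
#' @param n_trials sweeps per current level.
#' @param stimulus a `drc_stimulus` providing the conductance drive, or
#'   `NULL` to use `g_syn` directly.
#' @param g_syn optional explicit conductance drive (nS) at `fs` over the
#'   stimulus epoch; overrides `stimulus`.
#' @param fs sample rate in Hz (>= 10 kHz; default 20 kHz).
#' @param pulse_amp,pulse_hz,pulse_cycles pre-stimulus square-pulse train
#'   parameters (defaults: 40 pA, 20 Hz, 20 cycles).
#' @return object of class `voltage_sweep_set`: `sweeps` (trial x time
#'   matrix of recorded mV), `V_true` (electrode-free, noise-free membrane
#'   voltage; simulator ground truth), `I_inj` (pA per sweep), `fs`,
#'   `epochs` (sample ranges of the pulse and stimulus epochs), `pulse`
#'   metadata, `g_syn` (the drive actually used), truth lists `up_sweeps`
#'   and `spike_times`, and `params`.
#' @export
simulate_whole_cell <- function(params, I_levels = c(-80, -40, 0, 40),
                                n_trials = 25, stimulus = NULL, g_syn = NULL,
                                fs = 20000, pulse_amp = 40, pulse_hz = 20,
                                pulse_cycles = 20) {
  stopifnot(inherits(params, "patch_sim_params"))
  if (length(I_levels) < 2) {
    stop("at least 2 current levels are required for conductance recovery",
         call. = FALSE)
  }
  if (fs < 10000) stop("sample rate must be >= 10 kHz", call. = FALSE)
  dt <- 1000 / fs  # ms

  # current template: pulse epoch then stimulus epoch
  cycle_samps <- round(fs / pulse_hz)
  pulse_epoch <- rep(c(rep(pulse_amp, cycle_samps %/% 2),
                       rep(0, cycle_samps - cycle_samps %/% 2)), pulse_cycles)
  n_pulse <- length(pulse_epoch)
  if (is.null(g_syn)) {
    g_syn <- if (is.null(stimulus)) numeric(fs) else
      drc_conductance_drive(stimulus, fs, params$g_syn_peak)
  }
  n_stim <- length(g_syn)
  n_total <- n_pulse + n_stim
  g_syn_full <- c(numeric(n_pulse), g_syn)

  n_sweeps <- length(I_levels) * n_trials
  I_sweep <- rep(I_levels, each = n_trials)

  g_L <- 1000 / params$R_input   # nS
  Cm <- params$tau_input * g_L   # pF (tau in ms, g in nS), so dt*g/Cm is unitless

  # integrate membrane: V common dynamics except for I (per sweep), so
  # vectorize across sweeps at each time step
  V <- matrix(params$E_rest, n_sweeps, n_total)
  v <- rep(params$E_rest, n_sweeps)
  for (t in seq_len(n_total)) {
    I_t <- if (t <= n_pulse) rep(pulse_epoch[t], n_sweeps) else I_sweep
    g_tot <- g_L + g_syn_full[t]
    v_inf <- (g_L * params$E_rest + g_syn_full[t] * params$E_syn + I_t) / g_tot
    v <- v_inf + (v - v_inf) * exp(-dt * g_tot / Cm)
    V[, t] <- v
  }

  # electrode component: first-order low-pass of I * R_access
  a <- exp(-dt / params$tau_access)
  I_full <- cbind(matrix(pulse_epoch, n_sweeps, n_pulse, byrow = TRUE),
                  matrix(rep(I_sweep, n_stim), n_sweeps, n_stim))
  # pA x MOhm = microvolts; /1000 gives mV
  V_el <- t(apply(I_full * params$R_access / 1000, 1, function(row) {
    as.numeric(stats::filter(row * (1 - a), a, method = "recursive"))
  }))
  if (params$R_access == 0) V_el <- matrix(0, n_sweeps, n_total)

  # up states: Poisson plateaus added to the membrane voltage
  up_truth <- vector("list", n_sweeps)
  sim_dur_s <- n_total / fs
  V <- with_seed(params$seed, {
    if (params$up_state_rate > 0) {
      for (s in seq_len(n_sweeps)) {
        n_ev <- stats::rpois(1, params$up_state_rate * sim_dur_s)
        if (n_ev > 0) {
          t0 <- sort(stats::runif(n_ev, 0, sim_dur_s))
          up_truth[[s]] <- t0
          for (tt in t0) {
            i0 <- max(1, round(tt * fs))
            i1 <- min(n_total, i0 + round(params$up_dur / 1000 * fs))
            amp <- stats::rnorm(1, params$up_amp, params$up_amp_jitter)
            V[s, i0:i1] <- V[s, i0:i1] + amp
          }
        }
      }
    }
    V
  })

  # spikes: insert a stereotyped waveform at upward threshold crossings
  spk <- spike_waveform(fs)
  refract <- round(0.003 * fs)
  spike_truth <- vector("list", n_sweeps)
  if (is.finite(params$spike_threshold)) {
    for (s in seq_len(n_sweeps)) {
      above <- V[s, ] >= params$spike_threshold
      cross <- which(above & !c(FALSE, above[-n_total]))
      keep <- integer()
      last <- -Inf
      for (ci in cross) {
        if (ci - last > refract) { keep <- c(keep, ci); last <- ci }
      }
      spike_truth[[s]] <- keep / fs
      for (ci in keep) {
        i1 <- min(n_total, ci + length(spk) - 1L)
        V[s, ci:i1] <- V[s, ci:i1] + spk[seq_len(i1 - ci + 1L)]
      }
    }
  }

  noise <- with_seed(params$seed + 1L, {
    if (params$trial_noise_sd > 0) {
      matrix(stats::rnorm(n_sweeps * n_total, 0, params$trial_noise_sd),
             n_sweeps, n_total)
    } else matrix(0, n_sweeps, n_total)
  })

  structure(
    list(sweeps = V + V_el + noise,
         V_true = V,
         I_inj = I_sweep, fs = fs,
         epochs = list(pulse = c(1L, n_pulse),
                       stim = c(n_pulse + 1L, n_total)),
         pulse = list(amp = pulse_amp, hz = pulse_hz, cycles = pulse_cycles),
         g_syn = g_syn,
         up_sweeps = up_truth, spike_times = spike_truth,
         params = params),
    class = "voltage_sweep_set"
  )
}

#' @export
print.voltage_sweep_set <- function(x, ...) {
  cat(sprintf("<voltage_sweep_set: %d sweeps x %d samples at %g kHz, I_inj {%s} pA>\n",
              nrow(x$sweeps), ncol(x$sweeps), x$fs / 1000,
              paste(unique(x$I_inj), collapse = ", ")))
  invisible(x)
}
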