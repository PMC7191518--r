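# Intracellular whole-cell analysis: up-state exclusion, access-resistance
# fitting and compensation, spike detection and threshold validation,
# per-timepoint Ohmic conductance estimation, PSP metrics and the power-law
# membrane-potential-to-rate fit.
#
# Units throughout: voltages mV, currents pA, resistances MOhm,
# conductances nS, time constants ms. V(mV) = I(pA) * R(MOhm) / 1000;
# G(nS) = 1000 / R(MOhm).

# bimodality coefficient of a sample; > 5/9 suggests a bimodal distribution
bimodality_coefficient <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- mean(z^2)
  if (s2 == 0) return(0)
  g1 <- mean(z^3) / s2^1.5
  g2 <- mean(z^4) / s2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Detect an up state in a voltage sweep
#'
#' Spontaneous up states produce a bimodal membrane-potential distribution,
#' so they can be detected by threshold crossing where the threshold is the
#' mean V_m recorded during both up and down states (the cross-sweep mean).
#' A sweep is flagged when it stays above the threshold for longer than a
#' minimum dwell time.
#'
#' @param sweep numeric voltage trace in mV.
#' @param threshold detection threshold in mV (the cross-sweep mean V_m).
#' @param fs sample rate in Hz.
#' @param min_dwell minimum supra-threshold dwell in seconds (default 0.05).
#' @return logical: does the sweep contain an up state?
#' @export
detect_up_states <- function(sweep, threshold, fs, min_dwell = 0.05) {
  above <- sweep > threshold
  if (!any(above)) return(FALSE)
  r <- rle(above)
  any(r$values & r$lengths >= min_dwell * fs)
}

#' Flag up-state sweeps in a sweep set
#'
#' Applies the mean-threshold rule to every sweep, guarded by a bimodality
#' precondition: the rule is meaningless for a unimodal V_m distribution, so
#' when the pooled sample's bimodality coefficient is below 5/9 no sweep is
#' flagged.
#'
#' @param vss a `voltage_sweep_set` or a trials x time matrix.
#' @param fs sample rate (taken from the sweep set when available).
#' @param epoch `"pulse"`, `"stim"`, or `"all"`: portion used for detection.
#' @param min_dwell minimum dwell in seconds.
#' @param check_bimodal apply the bimodality precondition (default TRUE).
#' @return logical vector, one flag per sweep.
#' @export
flag_up_state_sweeps <- function(vss, fs = NULL, epoch = "all",
                                 min_dwell = 0.05, check_bimodal = TRUE) {
  if (inherits(vss, "voltage_sweep_set")) {
    rng <- switch(epoch, all = c(1L, ncol(vss$sweeps)), vss$epochs[[epoch]])
    M <- vss$sweeps[, rng[1]:rng[2], drop = FALSE]
    fs <- vss$fs
  } else {
    M <- vss
    if (is.null(fs)) stop("fs required for a bare sweep matrix", call. = FALSE)
  }
  if (check_bimodal && bimodality_coefficient(as.vector(M)) <= 5 / 9) {
    return(rep(FALSE, nrow(M)))
  }
  thr <- mean(M)
  apply(M, 1, detect_up_states, threshold = thr, fs = fs,
        min_dwell = min_dwell)
}

#' Mean pulse response of a sweep set
#'
#' Averages the voltage change evoked by the pre-stimulus square-pulse train
#' over pulse cycles and over up-state-free sweeps. Each cycle's response is
#' measured relative to the voltage just before pulse onset. The first two
#' cycles are dropped so the membrane has settled into its periodic steady
#' state.
#'
#' @param vss a `voltage_sweep_set`.
#' @param exclude_up_states exclude sweeps flagged by
#'   [flag_up_state_sweeps()] on the pulse epoch (default TRUE).
#' @param drop_cycles initial cycles discarded (default 2).
#' @param baseline_ms pre-onset window for the per-cycle baseline (ms).
#' @return list with `delta_v` (mV, mean voltage change over one pulse
#'   on-phase), `t_ms`, `I_inj` (pulse amplitude, pA), `fs`, and duty-cycle
#'   metadata (`T_on_ms`, `T_off_ms`) used by [fit_access_model()].
#' @export
mean_pulse_response <- function(vss, exclude_up_states = TRUE,
                                drop_cycles = 2, baseline_ms = 0.5) {
  stopifnot(inherits(vss, "voltage_sweep_set"))
  fs <- vss$fs
  keep <- rep(TRUE, nrow(vss$sweeps))
  if (exclude_up_states) {
    keep <- !flag_up_state_sweeps(vss, epoch = "pulse")
  }
  if (!any(keep)) stop("all sweeps contain up states", call. = FALSE)
  cyc <- round(fs / vss$pulse$hz)
  on_samps <- cyc %/% 2
  base_n <- max(1L, round(baseline_ms / 1000 * fs))
  p0 <- vss$epochs$pulse[1]
  acc <- numeric(on_samps)
  n_acc <- 0L
  for (c_i in seq(drop_cycles + 1L, vss$pulse$cycles)) {
    onset <- p0 + (c_i - 1L) * cyc        # first sample of the on-phase
    base_idx <- (onset - base_n):(onset - 1L)
    if (base_idx[1] < 1) next
    seg <- vss$sweeps[keep, onset:(onset + on_samps - 1L), drop = FALSE]
    base <- rowMeans(vss$sweeps[keep, base_idx, drop = FALSE])
    acc <- acc + colSums(seg - base)
    n_acc <- n_acc + sum(keep)
  }
  list(delta_v = acc / n_acc, t_ms = seq_len(on_samps) / fs * 1000,
       I_inj = vss$pulse$amp, fs = fs,
       T_on_ms = on_samps / fs * 1000,
       T_off_ms = (cyc - on_samps) / fs * 1000)
}

# amplitude correction for a periodic square-pulse steady state: the rise
# observed from the pre-pulse baseline is attenuated by (1 - b) / (1 - a b)
# with a = exp(-T_on/tau), b = exp(-T_off/tau)
duty_cycle_correction <- function(tau, T_on, T_off) {
  a <- exp(-T_on / tau); b <- exp(-T_off / tau)
  (1 - a * b) / (1 - b)
}

#' Fit the double-exponential access model to a mean pulse response
#'
#' Models the mean voltage change as
#' `dV(t)/I = R_access (1 - exp(-t/tau_access)) + R_input (1 - exp(-t/tau_input))`:
#' a fast component from the electrode plus a slow exponential from the
#' membrane. The fit is separable nonlinear least squares: a coarse grid
#' over the two time constants with an exact linear solve for the two
#' amplitudes at each grid point (the retained `mse_surface` shows a clear
#' minimum), followed by local refinement. When the response comes from a
#' periodic pulse train, the amplitudes are corrected for the duty cycle so
#' they estimate the true resistances.
#'
#' @param pulse a list from [mean_pulse_response()], or a numeric `delta_v`
#'   trace (then `I_inj` and `fs` are required).
#' @param I_inj pulse amplitude in pA.
#' @param fs sample rate in Hz.
#' @param tau_access_grid,tau_input_grid time-constant grids in ms.
#' @param refine run local refinement after the grid search (default TRUE).
#' @return object of class `access_fit`: `R_access`, `tau_access` (ms),
#'   `R_input`, `tau_input` (ms), `mse_surface` (data frame over the grid),
#'   `mse`, and `flag` (non-NULL when the grid minimum lies on the boundary
#'   and a widened grid was used).
#' @export
fit_access_model <- function(pulse, I_inj = NULL, fs = NULL,
                             tau_access_grid = exp(seq(log(0.05), log(5),
                                                       length.out = 25)),
                             tau_input_grid = exp(seq(log(2), log(150),
                                                      length.out = 30)),
                             refine = TRUE) {
  if (is.list(pulse)) {
    delta_v <- pulse$delta_v
    I_inj <- pulse$I_inj
    fs <- pulse$fs
    T_on <- pulse$T_on_ms %||% Inf
    T_off <- pulse$T_off_ms %||% Inf
  } else {
    delta_v <- as.numeric(pulse)
    T_on <- Inf; T_off <- Inf
    if (is.null(I_inj) || is.null(fs)) {
      stop("I_inj and fs required with a bare delta_v trace", call. = FALSE)
    }
  }
  # sample k after onset sits at t = k/fs: the first on-sample already
  # reflects one full integration step
  t_ms <- (if (is.list(pulse)) pulse$t_ms else NULL) %||%
    (seq_along(delta_v) / fs * 1000)
  y <- delta_v / I_inj * 1000  # mV/pA * 1000 = MOhm scale

  sse_at <- function(ta, ti) {
    B <- cbind(1 - exp(-t_ms / ta), 1 - exp(-t_ms / ti))
    fit <- stats::lm.fit(B, y)
    list(sse = sum(fit$residuals^2), amps = fit$coefficients)
  }

  run_grid <- function(tag, tig) {
    grid <- expand.grid(tau_access = tag, tau_input = tig)
    grid <- grid[grid$tau_access < grid$tau_input, ]
    res <- vapply(seq_len(nrow(grid)), function(i) {
      sse_at(grid$tau_access[i], grid$tau_input[i])$sse
    }, numeric(1))
    grid$mse <- res / length(y)
    grid
  }

  grid <- run_grid(tau_access_grid, tau_input_grid)
  best <- which.min(grid$mse)
  flag <- NULL
  on_edge <- grid$tau_access[best] %in% range(tau_access_grid) ||
    grid$tau_input[best] %in% range(tau_input_grid)
  if (on_edge) {
    flag <- "grid_boundary"
    wide_a <- exp(seq(log(min(tau_access_grid) / 10),
                      log(max(tau_access_grid) * 10), length.out = 35))
    wide_i <- exp(seq(log(min(tau_input_grid) / 10),
                      log(max(tau_input_grid) * 10), length.out = 40))
    grid <- run_grid(wide_a, wide_i)
    best <- which.min(grid$mse)
  }
  ta <- grid$tau_access[best]; ti <- grid$tau_input[best]

  if (refine) {
    obj <- function(par) {
      ta <- exp(par[1]); ti <- exp(par[2])
      if (ta >= ti) return(1e12)
      sse_at(ta, ti)$sse
    }
    opt <- stats::optim(log(c(ta, ti)), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    ta <- exp(opt$par[1]); ti <- exp(opt$par[2])
  }
  final <- sse_at(ta, ti)
  amps <- final$amps
  # undo periodic-steady-state attenuation of each component's amplitude
  R_access <- amps[1] * duty_cycle_correction(ta, T_on, T_off)
  R_input <- amps[2] * duty_cycle_correction(ti, T_on, T_off)

  structure(
    list(R_access = unname(R_access), tau_access = ta,
         R_input = unname(R_input), tau_input = ti,
         mse = final$sse / length(y), mse_surface = grid, flag = flag),
    class = "access_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.access_fit <- function(x, ...) {
  cat(sprintf("<access_fit: R_access %.1f MOhm (tau %.2f ms), R_input %.1f MOhm (tau %.1f ms), mse %.3g>\n",
              x$R_access, x$tau_access, x$R_input, x$tau_input, x$mse))
  invisible(x)
}

# electrode voltage component for an arbitrary current waveform: I*R_access
# low-passed with a first-order filter of time constant tau_access
electrode_component <- function(I_pA, R_access, tau_access, fs) {
  a <- exp(-1000 / fs / tau_access)
  as.numeric(stats::filter(I_pA * R_access / 1000 * (1 - a), a,
                           method = "recursive"))
}

# reconstruct the per-sweep current waveform of a voltage_sweep_set
sweep_current_waveform <- function(vss, sweep_idx) {
  cyc <- round(vss$fs / vss$pulse$hz)
  pulse_epoch <- rep(c(rep(vss$pulse$amp, cyc %/% 2),
                       rep(0, cyc - cyc %/% 2)), vss$pulse$cycles)
  n_stim <- vss$epochs$stim[2] - vss$epochs$stim[1] + 1L
  c(pulse_epoch, rep(vss$I_inj[sweep_idx], n_stim))
}

#' Subtract the access-resistance component from recorded sweeps
#'
#' For each sweep, the electrode voltage — the injected-current waveform
#' times `R_access`, low-passed with the electrode kernel
#' `1 - exp(-t/tau_access)` at the current transitions — is subtracted from
#' the recorded voltage, leaving an estimate of the true membrane potential.
#' Sweeps with zero injected current are unchanged.
#'
#' @param vss a `voltage_sweep_set`.
#' @param fit an [fit_access_model()] result (an `access_fit`).
#' @return the sweep set with `sweeps` replaced by compensated voltages and
#'   a `compensated` flag set.
#' @export
compensate_access <- function(vss, fit) {
  stopifnot(inherits(vss, "voltage_sweep_set"), inherits(fit, "access_fit"))
  out <- vss
  for (s in seq_len(nrow(vss$sweeps))) {
    I_wave <- sweep_current_waveform(vss, s)
    out$sweeps[s, ] <- vss$sweeps[s, ] -
      electrode_component(I_wave, fit$R_access, fit$tau_access, vss$fs)
  }
  out$compensated <- TRUE
  out
}

#' Detect spikes in a voltage sweep
#'
#' Upward crossings of a threshold positioned seven standard deviations
#' above the mean V_m. The mean is computed after median-filter despiking
#' (3-ms window) and the SD robustly (scaled MAD of the raw trace), so that
#' sparse large spikes do not inflate the threshold; crossings within a
#' 2-ms refractory window are merged.
#'
#' @param sweep numeric voltage trace in mV.
#' @param fs sample rate in Hz.
#' @param n_sd threshold in SDs above the mean (default 7).
#' @param refractory merge window in seconds (default 0.002).
#' @return list with `times` (s), `indices`, and `threshold` (mV).
#' @export
detect_spikes <- function(sweep, fs, n_sd = 7, refractory = 0.002) {
  k <- round(0.003 * fs)
  if (k %% 2 == 0) k <- k + 1
  despiked <- stats::runmed(sweep, k)
  sd_robust <- stats::mad(sweep)
  if (sd_robust == 0) {
    return(list(times = numeric(0), indices = integer(0), threshold = Inf))
  }
  thr <- mean(despiked) + n_sd * sd_robust
  above <- sweep >= thr
  cross <- which(above & !c(FALSE, above[-length(above)]))
  keep <- integer()
  last <- -Inf
  for (ci in cross) {
    if (ci - last > refractory * fs) { keep <- c(keep, ci); last <- ci }
  }
  list(times = keep / fs, indices = keep, threshold = thr)
}

#' Spike threshold from the pre-crossing inflection point
#'
#' The spike threshold is the voltage at the inflection point of the spike
#' waveform within 1 ms before the detection-threshold crossing,
#' operationalized as the maximum of the second time-derivative of a
#' lightly smoothed (0.2-ms Gaussian) copy of the trace.
#'
#' @param sweep numeric voltage trace in mV.
#' @param spike_index sample index of the detection crossing (from
#'   [detect_spikes()]).
#' @param fs sample rate in Hz.
#' @param window pre-crossing search window in seconds (default 0.001).
#' @return threshold voltage in mV; flagged (`attr(, "flag")`) when the
#'   window is truncated by the sweep start, or degenerate when the
#'   curvature peaks at the window edge (no interior inflection, e.g. a
#'   pure exponential rise).
#' @export
spike_threshold <- function(sweep, spike_index, fs, window = 0.001) {
  n_win <- round(window * fs)
  i0 <- spike_index - n_win
  flag <- NULL
  if (i0 < 1) {
    i0 <- 1
    flag <- "window_truncated"
  }
  idx <- i0:spike_index
  # 0.2-ms Gaussian smoothing
  sigma <- 0.0002 * fs
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  lo <- max(1L, i0 - half); hi <- min(length(sweep), spike_index + half)
  v_sm <- if (hi - lo + 1L > length(kern)) {
    sm <- stats::filter(sweep[lo:hi], kern, sides = 2)
    as.numeric(sm)[idx - lo + 1L]
  } else sweep[idx]  # segment too short to smooth
  v_sm[!is.finite(v_sm)] <- sweep[idx][!is.finite(v_sm)]
  d2 <- diff(diff(v_sm))
  if (!length(d2) || all(!is.finite(d2))) {
    return(structure(NA_real_, flag = "degenerate"))
  }
  j <- which.max(d2)
  if (j >= length(d2)) flag <- c(flag, "degenerate_no_inflection")
  structure(unname(sweep[idx[j + 1L]]), flag = flag)
}

#' Validate access-resistance compensation via spike thresholds
#'
#' If compensation is complete, spike threshold should not depend on the
#' injected current; any residual linear dependence of threshold on I_inj
#' has a slope equal to the uncompensated access resistance.
#'
#' @param thresholds spike thresholds in mV, one per spike.
#' @param I_inj injected current (pA) active when each spike occurred.
#' @return list with `residual_R_access` (MOhm, the slope converted from
#'   mV/pA), `slope_se` and `n_levels`.
#' @export
validate_compensation <- function(thresholds, I_inj) {
  lv <- unique(I_inj)
  if (length(lv) < 2) {
    stop("spikes at >= 2 current levels are required", call. = FALSE)
  }
  if (stats::sd(thresholds) == 0) {
    return(list(residual_R_access = 0, slope_se = 0, n_levels = length(lv)))
  }
  fit <- stats::lm(thresholds ~ I_inj)
  co <- summary(fit)$coefficients
  list(residual_R_access = unname(co[2, 1]) * 1000,  # mV/pA -> MOhm
       slope_se = unname(co[2, 2]) * 1000,
       n_levels = length(lv))
}

#' Per-timepoint Ohmic input-conductance estimation
#'
#' At each timepoint of the stimulus epoch, fits an ordinary least-squares
#' line to the recorded membrane potential across all sweeps as a function
#' of injected current. The inverse of the slope is the conductance estimate
#' at that timepoint (`G(nS) = 1 / slope(mV/pA)`); the intercept is the
#' zero-current voltage. Reconstruction r-squared is computed by predicting
#' every sweep's voltage from `(G, offset, I)` over all timepoints.
#'
#' @param vss a (typically compensated) `voltage_sweep_set`.
#' @param sweep_subset optional logical/integer subset of sweeps (e.g. to
#'   drop up-state sweeps).
#' @param epoch `"stim"` (default) or `"all"`.
#' @return object of class `conductance_trace`: `G` (nS per timepoint),
#'   `R_input_t` (MOhm), `offset` (mV), `r2_reconstruction`, `fs`.
#' @export
estimate_conductance <- function(vss, sweep_subset = NULL, epoch = "stim") {
  stopifnot(inherits(vss, "voltage_sweep_set"))
  rng <- switch(epoch, all = c(1L, ncol(vss$sweeps)), vss$epochs[[epoch]])
  V <- vss$sweeps[, rng[1]:rng[2], drop = FALSE]
  I <- vss$I_inj
  if (!is.null(sweep_subset)) {
    V <- V[sweep_subset, , drop = FALSE]
    I <- I[sweep_subset]
  }
  if (length(unique(I)) < 2) {
    stop("need >= 2 distinct current levels", call. = FALSE)
  }
  if (nrow(V) < 4) stop("need >= 2 trials per current level", call. = FALSE)
  Ic <- I - mean(I)
  denom <- sum(Ic^2)
  slope <- as.numeric(crossprod(V, Ic)) / denom   # mV/pA per timepoint
  offset <- colMeans(V) - slope * mean(I)
  pred <- outer(I, slope) + matrix(offset, nrow(V), ncol(V), byrow = TRUE)
  ss_res <- sum((V - pred)^2)
  ss_tot <- sum((V - mean(V))^2)
  structure(
    list(G = 1 / slope, R_input_t = slope * 1000, offset = offset,
         r2_reconstruction = 1 - ss_res / ss_tot, fs = vss$fs,
         n_sweeps = nrow(V)),
    class = "conductance_trace"
  )
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("<conductance_trace: %d timepoints, median G %.2f nS, reconstruction r2 %.3f>\n",
              length(x$G), stats::median(x$G), x$r2_reconstruction))
  invisible(x)
}

#' Noise-evoked PSP amplitude and membrane-potential variability
#'
#' The PSP amplitude is the peak of the trial-mean voltage in a post-onset
#' window minus the pre-onset baseline (the mean over the 50 ms before
#' onset). `amplitude_sd` is the SD of per-trial peak amplitudes, `sigma_Vm`
#' the SD of V_m across trials averaged over timepoints, and `mean_Vm` the
#' overall mean during the analyzed epoch.
#'
#' @param sweeps trials x time matrix of membrane voltage (mV) at zero
#'   holding current.
#' @param fs sample rate in Hz.
#' @param noise_onset burst onset in seconds from the start of the matrix.
#' @param peak_window post-onset search window in seconds (default
#'   `c(0.005, 0.1)`).
#' @param baseline_window pre-onset baseline length in seconds (default
#'   0.05).
#' @param despike remove action potentials with a 3-ms median filter before
#'   measuring, so the metrics describe the subthreshold potential
#'   (default TRUE).
#' @return list with `amplitude`, `amplitude_sd`, `mean_Vm`, `sigma_Vm`
#'   (all mV).
#' @export
psp_metrics <- function(sweeps, fs, noise_onset,
                        peak_window = c(0.005, 0.1),
                        baseline_window = 0.05, despike = TRUE) {
  stopifnot(is.matrix(sweeps))
  if (despike) {
    k <- round(0.003 * fs)
    if (k %% 2 == 0) k <- k + 1
    sweeps <- t(apply(sweeps, 1, stats::runmed, k = k))
  }
  on_i <- round(noise_onset * fs)
  b0 <- on_i - round(baseline_window * fs)
  if (b0 < 1) stop("no pre-onset samples for the baseline", call. = FALSE)
  base_idx <- b0:(on_i - 1L)
  pk_idx <- (on_i + round(peak_window[1] * fs)):
    min(ncol(sweeps), on_i + round(peak_window[2] * fs))
  mean_trace <- colMeans(sweeps)
  amplitude <- max(mean_trace[pk_idx]) - mean(mean_trace[base_idx])
  per_trial <- apply(sweeps[, pk_idx, drop = FALSE], 1, max) -
    rowMeans(sweeps[, base_idx, drop = FALSE])
  list(amplitude = amplitude,
       amplitude_sd = stats::sd(per_trial),
       mean_Vm = mean(sweeps),
       sigma_Vm = mean(apply(sweeps, 2, stats::sd)))
}

#' Fit the power-law mapping from membrane potential to firing rate
#'
#' Fits `rate = k * (Vm - V_rest)_+^p` (the subscript + denoting half-wave
#' rectification) jointly across contrast conditions: the exponent `p` is
#' shared while the gain factor `k` varies by condition. For a fixed `p` the
#' gains have a closed-form least-squares solution, so the fit is a 1-D
#' optimization over `p`.
#'
#' @param mean_Vm per-bin mean membrane potential (mV).
#' @param mean_rate per-bin mean spiking response (paired with `mean_Vm`).
#' @param condition per-bin condition labels (e.g. `"low"`/`"high"`).
#' @param V_rest resting potential in mV.
#' @param p_range search interval for the exponent (default `c(0.2, 8)`).
#' @return object of class `power_law_fit`: `k` (named per condition), `p`,
#'   `V_rest`, `gain_change` (`k_high / k_low` when both conditions are
#'   present), `sse`.
#' @export
fit_power_law <- function(mean_Vm, mean_rate, condition, V_rest,
                          p_range = c(0.2, 8)) {
  stopifnot(length(mean_Vm) == length(mean_rate),
            length(condition) == length(mean_Vm))
  x <- pmax(mean_Vm - V_rest, 0)
  if (all(x == 0)) {
    stop("all mean_Vm at or below V_rest: power-law fit undefined",
         call. = FALSE)
  }
  condition <- as.character(condition)
  conds <- unique(condition)
  sse_for <- function(p) {
    sse <- 0
    for (cn in conds) {
      sel <- condition == cn
      xp <- x[sel]^p
      k <- if (sum(xp^2) > 0) sum(xp * mean_rate[sel]) / sum(xp^2) else 0
      k <- max(k, 0)
      sse <- sse + sum((mean_rate[sel] - k * xp)^2)
    }
    sse
  }
  opt <- stats::optimize(sse_for, p_range, tol = 1e-10)
  p <- opt$minimum
  k <- vapply(conds, function(cn) {
    sel <- condition == cn
    xp <- x[sel]^p
    if (sum(xp^2) > 0) max(sum(xp * mean_rate[sel]) / sum(xp^2), 0) else 0
  }, numeric(1))
  gain_change <- if (all(c("low", "high") %in% conds)) {
    k[["high"]] / k[["low"]]
  } else NA_real_
  structure(list(k = k, p = p, V_rest = V_rest, gain_change = gain_change,
                 sse = opt$objective),
            class = "power_law_fit")
}

#' Predict firing rate from a power-law fit
#'
#' @param object a `power_law_fit`.
#' @param mean_Vm membrane potentials in mV.
#' @param condition condition label(s) selecting the gain factor.
#' @param ... unused.
#' @return predicted rates (zero wherever `mean_Vm <= V_rest`).
#' @export
predict.power_law_fit <- function(object, mean_Vm, condition, ...) {
  k <- object$k[as.character(condition)]
  unname(k * pmax(mean_Vm - object$V_rest, 0)^object$p)
}
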