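test_that("up-state detection flags plateaus but not unimodal noise", {
  fs <- 10000
  # flat trace at rest: never flagged
  expect_false(detect_up_states(rep(-70, fs), threshold = -60, fs = fs))
  # simulator sweep with inserted plateaus is flagged
  up <- fixture_quiet_cell(up_state_rate = 1.5, trial_noise_sd = 0.3,
                           seed = 12, n_trials = 4, stim_samples = 40000)
  flags <- flag_up_state_sweeps(up, epoch = "all")
  has_up <- lengths(up$up_sweeps) > 0
  expect_true(any(flags))
  expect_true(all(has_up[flags]))  # no false positives against truth
  expect_gt(mean(flags[has_up]), 0.8)
  # unimodal noisy traces: false-positive rate < 5% over 100 sweeps
  set.seed(13)
  noise_only <- matrix(rnorm(100 * fs, -70, 2), 100)
  expect_lt(mean(flag_up_state_sweeps(noise_only, fs = fs)), 0.05)
})

test_that("access model recovers all four parameters within 5% noiselessly", {
  vss <- fixture_quiet_cell(R_access = 20, tau_access = 0.5,
                            R_input = 100, tau_input = 20,
                            trial_noise_sd = 0, seed = 3)
  fit <- fit_access_model(mean_pulse_response(vss))
  expect_lt(abs(fit$R_access - 20) / 20, 0.05)
  expect_lt(abs(fit$tau_access - 0.5) / 0.5, 0.05)
  expect_lt(abs(fit$R_input - 100) / 100, 0.05)
  expect_lt(abs(fit$tau_input - 20) / 20, 0.05)
  # steady-state consistency: dV -> I (R_access + R_input) / 1000 within 1%
  t_inf <- seq(0.001, 200, by = 0.05)
  dv_inf <- fit$R_access * (1 - exp(-max(t_inf) / fit$tau_access)) +
    fit$R_input * (1 - exp(-max(t_inf) / fit$tau_input))
  expect_lt(abs(dv_inf - 120) / 120, 0.01)
  # absent electrode component is recovered as ~0
  v0 <- fixture_quiet_cell(R_access = 0, tau_access = 0.5,
                           trial_noise_sd = 0, seed = 4)
  fit0 <- fit_access_model(mean_pulse_response(v0))
  expect_lt(abs(fit0$R_access), 1)
  # the error surface has an interior minimum
  expect_true(is.data.frame(fit$mse_surface))
  expect_null(fit$flag)
})

test_that("access compensation restores the electrode-free voltage", {
  vss <- fixture_quiet_cell(R_access = 20, trial_noise_sd = 0, seed = 5,
                            I_levels = c(-40, 0, 40), n_trials = 1)
  fit <- fit_access_model(mean_pulse_response(vss))
  comp <- compensate_access(vss, fit)
  expect_lt(sqrt(mean((comp$sweeps - vss$V_true)^2)), 0.2)
  # zero-current sweeps only carry the pulse-epoch correction; their
  # stimulus epoch is unchanged
  zi <- which(vss$I_inj == 0)
  st <- vss$epochs$stim
  expect_equal(comp$sweeps[zi, (st[1] + 2000):st[2]],
               vss$sweeps[zi, (st[1] + 2000):st[2]], tolerance = 1e-8)
  # doubling R_access in the fit doubles the subtracted component
  fit2 <- fit
  fit2$R_access <- 2 * fit$R_access
  comp2 <- compensate_access(vss, fit2)
  expect_equal(vss$sweeps - comp2$sweeps, 2 * (vss$sweeps - comp$sweeps),
               tolerance = 1e-10)
})

test_that("spike detection finds inserted spikes at the 7-SD threshold", {
  fs <- 20000
  set.seed(14)
  sweep <- rnorm(2 * fs, -70, 0.5)
  expect_length(detect_spikes(rep(-70, fs), fs)$times, 0)
  # three inserted stereotyped spikes
  spk <- contrastgain:::spike_waveform(fs)
  for (at in c(0.3, 0.9, 1.5) * fs) {
    idx <- at + seq_along(spk)
    sweep[idx] <- sweep[idx] + spk
  }
  det <- detect_spikes(sweep, fs)
  expect_length(det$times, 3)
  expect_equal(det$times, c(0.3, 0.9, 1.5), tolerance = 0.002)
  # threshold equals the despiked mean + 7 robust SDs
  quiet <- rnorm(fs, -70, 0.5)
  dq <- detect_spikes(quiet, fs)
  k <- round(0.003 * fs) + 1
  expect_equal(dq$threshold,
               mean(stats::runmed(quiet, k)) + 7 * stats::mad(quiet),
               tolerance = 1e-9)
})

test_that("spike threshold sits at the waveform's onset kink", {
  fs <- 20000
  # piecewise trace: flat baseline, then a sharp-onset rise (the kink)
  base <- rep(-65, 0.01 * fs)
  rise <- -65 + 80 * (seq_len(0.002 * fs) / (0.002 * fs))^3
  sweep <- c(base, rise)
  cross <- which(sweep >= -20)[1]
  th <- spike_threshold(sweep, cross, fs)
  # the max-curvature point lies within the rise, close to the crossing
  expect_gt(th, -65)
  expect_lt(th, sweep[cross])
  # identical spikes at different baselines: thresholds differ by the shift
  th2 <- spike_threshold(sweep + 10, cross, fs)
  expect_equal(th2 - th, 10, tolerance = 1e-9)
  # truncated window flagged
  tr <- spike_threshold(sweep[(cross - 3):length(sweep)], 4, fs)
  expect_true("window_truncated" %in% attr(tr, "flag"))
})

test_that("spike-threshold slope quantifies residual access resistance", {
  p <- patch_sim_params(R_input = 100, tau_input = 20, R_access = 20,
                        tau_access = 0.5, trial_noise_sd = 0.2,
                        spike_threshold = -50, g_syn_peak = 8, seed = 11)
  drc <- generate_drc(contrast_condition("high"), 2, seed = 4)
  vss <- simulate_whole_cell(p, I_levels = c(-40, 0, 40, 80), n_trials = 3,
                             stimulus = drc, fs = 20000)
  st <- vss$epochs$stim
  collect <- function(vset) {
    out_th <- out_I <- numeric(0)
    for (s in seq_len(nrow(vset$sweeps))) {
      sw <- vset$sweeps[s, st[1]:st[2]]
      det <- detect_spikes(sw, vset$fs)
      for (i in det$indices) {
        out_th <- c(out_th, spike_threshold(sw, i, vset$fs))
        out_I <- c(out_I, vset$I_inj[s])
      }
    }
    list(th = out_th, I = out_I)
  }
  raw <- collect(vss)
  vr <- validate_compensation(raw$th, raw$I)
  expect_lt(abs(vr$residual_R_access - 20) / 20, 0.1)
  fit <- fit_access_model(mean_pulse_response(vss))
  cc <- collect(compensate_access(vss, fit))
  vc <- validate_compensation(cc$th, cc$I)
  expect_lt(abs(vc$residual_R_access), 2)
  # compensation removes >= 90% of the current dependence
  expect_lt(abs(vc$residual_R_access),
            0.1 * abs(vr$residual_R_access))
  # degenerate cases
  expect_equal(validate_compensation(rep(-50, 6),
                                     rep(c(0, 40), 3))$residual_R_access, 0)
  expect_error(validate_compensation(c(-50, -49), c(40, 40)), "2 current")
})

test_that("Ohmic conductance estimation is exact for a static membrane", {
  vss <- fixture_quiet_cell(R_access = 0, trial_noise_sd = 0,
                            I_levels = c(-80, -40, 0, 40), n_trials = 2,
                            stim_samples = 5000)
  ct <- estimate_conductance(vss)
  # after ~10 membrane time constants the step response to I_inj has settled
  settled <- ct$G[4000:5000]
  expect_true(all(abs(settled - 10) < 0.01))  # 1000 / 100 MOhm = 10 nS
  expect_equal(ct$r2_reconstruction, 1, tolerance = 1e-9)
})

test_that("conductance estimation tracks a 5-nS synaptic step within 10%", {
  g <- c(numeric(10000), rep(5, 10000))
  p <- patch_sim_params(R_input = 100, tau_input = 20, R_access = 20,
                        tau_access = 0.5, trial_noise_sd = 0.3, seed = 15)
  vss <- simulate_whole_cell(p, I_levels = c(-80, -40, 0, 40),
                             n_trials = 10, g_syn = g, fs = 20000)
  fit <- fit_access_model(mean_pulse_response(vss))
  comp <- compensate_access(vss, fit)
  ct <- estimate_conductance(comp)
  g_base <- median(ct$G[4000:9500])
  g_step <- median(ct$G[12000:19500])
  expect_lt(abs(g_base - 10) / 10, 0.1)
  expect_lt(abs((g_step - g_base) - 5) / 5, 0.1)
  # end-to-end: recovered conductance trace matches ground truth
  truth <- 10 + g
  nrmse <- sqrt(mean((ct$G[2000:19500] - truth[2000:19500])^2)) /
    mean(truth)
  expect_lt(nrmse, 0.1)
})

test_that("reconstruction captures >= 97% of variance at 10% trial noise", {
  # passive linear membrane, R_input 100 MOhm, tau 20 ms, R_access 0,
  # DRC-like drive, 4 current levels x 25 trials
  drc <- generate_drc(contrast_condition("high"), 1, seed = 16)
  p0 <- patch_sim_params(R_input = 100, tau_input = 20, R_access = 0,
                         tau_access = 0.5, trial_noise_sd = 0, seed = 16)
  quiet <- simulate_whole_cell(p0, I_levels = c(-80, -40, 0, 40),
                               n_trials = 1, stimulus = drc, fs = 10000)
  st <- quiet$epochs$stim
  mean_resp <- colMeans(quiet$sweeps[, st[1]:st[2]])
  noise_sd <- 0.1 * sd(mean_resp)
  p <- patch_sim_params(R_input = 100, tau_input = 20, R_access = 0,
                        tau_access = 0.5, trial_noise_sd = noise_sd,
                        seed = 17)
  vss <- simulate_whole_cell(p, I_levels = c(-80, -40, 0, 40),
                             n_trials = 25, stimulus = drc, fs = 10000)
  ct <- estimate_conductance(vss)
  expect_gte(ct$r2_reconstruction, 0.97)
})

test_that("PSP metrics are baseline-invariant with sensible variability", {
  fs <- 10000
  t <- seq_len(fs) / fs
  psp_shape <- 5 * exp(-(t - 0.52)^2 / 0.0005) * (t > 0.5)
  base <- -65 + outer(rep(1, 20), psp_shape)
  m <- psp_metrics(base, fs, noise_onset = 0.5, despike = FALSE)
  expect_equal(m$amplitude, max(psp_shape), tolerance = 0.05)
  expect_equal(m$amplitude_sd, 0, tolerance = 1e-9)  # identical trials
  # baseline-shifted copies leave the amplitude unchanged
  m2 <- psp_metrics(base + 12, fs, noise_onset = 0.5, despike = FALSE)
  expect_equal(m2$amplitude, m$amplitude, tolerance = 1e-9)
  expect_equal(m2$mean_Vm, m$mean_Vm + 12, tolerance = 1e-9)
  # PSP scaled x0.8: amplitude ratio recovered
  set.seed(18)
  lo <- base + rnorm(length(base), 0, 0.2)
  hi <- -65 + outer(rep(1, 20), 0.8 * psp_shape) +
    rnorm(length(base), 0, 0.2)
  mlo <- psp_metrics(lo, fs, noise_onset = 0.5, despike = FALSE)
  mhi <- psp_metrics(hi, fs, noise_onset = 0.5, despike = FALSE)
  expect_lt(abs(mhi$amplitude / mlo$amplitude - 0.8), 0.05)
  expect_error(psp_metrics(base, fs, noise_onset = 0.001), "pre-onset")
})

test_that("power-law fit recovers gains and a shared exponent", {
  # linear case: p = 1, k = 1 recovered within 1%
  set.seed(19)
  Vm <- runif(200, -70, -50)
  cond <- rep(c("low", "high"), 100)
  rate1 <- pmax(Vm + 65, 0)
  f1 <- fit_power_law(Vm, rate1, cond, V_rest = -65)
  expect_lt(abs(f1$p - 1), 0.01)
  expect_lt(abs(f1$k[["low"]] - 1), 0.01)
  expect_lt(abs(f1$k[["high"]] - 1), 0.01)
  # k_low 2, k_high 1, p 2 at 5% noise recovered within 10%
  k_true <- ifelse(cond == "low", 2, 1)
  rate2 <- k_true * pmax(Vm + 65, 0)^2
  rate2 <- rate2 + rnorm(200, 0, 0.05 * sd(rate2))
  f2 <- fit_power_law(Vm, rate2, cond, V_rest = -65)
  expect_lt(abs(f2$p - 2) / 2, 0.1)
  expect_lt(abs(f2$k[["low"]] - 2) / 2, 0.1)
  expect_lt(abs(f2$k[["high"]] - 1), 0.1)
  expect_lt(abs(f2$gain_change - 0.5) / 0.5, 0.1)
  # half-wave rectification: below rest predicts zero
  expect_equal(predict(f2, c(-80, -70), c("low", "low")), c(0, 0))
  expect_error(fit_power_law(c(-80, -75), c(0, 0), c("low", "low"),
                             V_rest = -65), "undefined")
})
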