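# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# canonical smooth rank-1 ground-truth kernels (25 freqs x 8 lags)
fixture_kernels <- function(center = 12, width = 2.5, n_freqs = 25,
                            n_h = 8) {
  kf <- exp(-((seq_len(n_freqs) - center)^2) / (2 * width^2)) * 0.05
  kh <- c(0.2, 1, 0.6, 0.3, 0.1, rep(0, n_h - 5))[seq_len(n_h)]
  list(kf = kf, kh = kh / sqrt(sum(kh^2)))
}

# noiseless LN unit + DRC + design, the workhorse for exact STRF checks
fixture_ln_design <- function(seed = 1, duration = 20, noise_sd = 0,
                              condition = contrast_condition("high"),
                              light_on = FALSE, n_lags = 8, ...) {
  k <- fixture_kernels(n_h = n_lags)
  par <- ln_unit_params(k$kf, k$kh, bias = 5, gain_low = 2, gain_high = 1,
                        noise_sd = noise_sd, seed = seed * 101L, ...)
  drc <- generate_drc(condition, duration, seed = seed)
  tr <- simulate_ln_unit(par, drc, light_on = light_on)
  list(params = par, drc = drc, trace = tr,
       design = build_design(drc, tr$values, n_lags = n_lags),
       kf = k$kf, kh = k$kh)
}

# quiescent whole-cell recording (no synaptic drive) for access-model tests
fixture_quiet_cell <- function(R_access = 20, tau_access = 0.5,
                               R_input = 100, tau_input = 20,
                               trial_noise_sd = 0, seed = 3,
                               I_levels = c(-40, 40), n_trials = 2,
                               fs = 20000, stim_samples = 20000, ...) {
  p <- patch_sim_params(R_input = R_input, tau_input = tau_input,
                        R_access = R_access, tau_access = tau_access,
                        trial_noise_sd = trial_noise_sd, seed = seed, ...)
  simulate_whole_cell(p, I_levels = I_levels, n_trials = n_trials,
                      g_syn = numeric(stim_samples), fs = fs)
}
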