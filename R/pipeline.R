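# End-to-end orchestration: configuration, seeded simulated experiments
# (extracellular and intracellular), population summaries and text-format
# report/serialization helpers.

ex_defaults <- function() list(
  kind = "extracellular",
  n_units = 12,            # simulated MUs
  n_drcs = 4,              # DRC stimuli per condition
  n_reps = 3,              # repeats per DRC
  drc_duration = 40,       # s per DRC
  n_lags = 8,
  gain_low = 2, gain_high = 1,
  light_gain_factor = 1.1, light_offset = 0,
  noise_sd = 2,
  nonlinearity = "halfwave",
  bias = 5,
  cc_threshold = 0.04,
  seed = 1L
)

in_defaults <- function() list(
  kind = "intracellular",
  n_cells = 4,
  n_reps_sequence = 11,    # alternating 1-s segments per sweep
  I_levels = c(-80, -40, 0, 40),
  n_trials = 3,            # sweeps per current level
  fs = 10000,
  R_input = 100, tau_input = 20, R_access = 20, tau_access = 0.5,
  E_rest = -70, g_syn_peak = 6,
  spike_threshold = -50,
  trial_noise_sd = 0.3,
  noise_burst_onset = 0.5, noise_burst_dur = 0.05,
  seed = 1L
)

#' Run configuration for a simulated experiment
#'
#' Flat key-value configuration with schema validation: unknown keys are
#' rejected, and a run is reproducible from its configuration and seed.
#'
#' @param kind `"extracellular"` or `"intracellular"`.
#' @param ... overrides of the defaults for that kind (see
#'   [run_extracellular_experiment()] / [run_intracellular_experiment()]).
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(kind = c("extracellular", "intracellular"), ...) {
  kind <- match.arg(kind)
  cfg <- if (kind == "extracellular") ex_defaults() else in_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

# md5 of the JSON-serialized config, so reports can embed a config hash
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

# smooth random frequency kernel (Gaussian bump at a random best frequency)
# and a damped history kernel; the ground truth for one simulated unit
random_unit_kernels <- function(n_freqs = 25, n_h = 8, seed = 1L) {
  with_seed(seed, {
    ctr <- sample(4:(n_freqs - 3), 1)
    width <- stats::runif(1, 1.2, 2.5)
    kf <- exp(-((seq_len(n_freqs) - ctr)^2) / (2 * width^2))
    kh <- exp(-(seq_len(n_h) - 2)^2 / 3)
    kh[1] <- 0.3 * kh[1]
    list(kf = kf * 0.05, kh = kh / sqrt(sum(kh^2)), bf_bin = ctr)
  })
}

#' Simulate a population gain ledger under an optogenetic manipulation
#'
#' For each simulated LN unit, generates one DRC response trace per
#' light x contrast condition and computes the nonparametric gain ledger
#' ([gain_summary()]). The light effect is a gain multiplier applied
#' identically at both contrasts (plus an optional additive offset), so the
#' expected `G_relative` is 1: the manipulation changes overall gain but
#' not contrast gain control.
#'
#' @param n_units number of simulated units.
#' @param light_gain_factor,light_offset light effect on gain/offset.
#' @param gain_low,gain_high contrast gains (ratio 2 encodes full contrast
#'   gain control).
#' @param noise_sd response noise SD (per repeat; repeats are averaged).
#' @param duration DRC duration in seconds (default 40).
#' @param n_drcs,n_reps DRC stimuli per condition and repeats per DRC
#'   (defaults 4 and 3, the standard protocol: 480 s of data per
#'   condition).
#' @param seed population seed; unit `u` uses `seed + u`.
#' @return data frame with one row per unit: gain ratios, `G_relative`,
#'   `R_offset` and `Rmin`/`Rmax` ratios per contrast.
#' @export
simulate_gain_population <- function(n_units = 50, light_gain_factor = 1.1,
                                     light_offset = 0, gain_low = 2,
                                     gain_high = 1, noise_sd = 2,
                                     duration = 40, n_drcs = 4, n_reps = 3,
                                     seed = 1L) {
  low <- contrast_condition("low")
  high <- contrast_condition("high")
  n_chords <- round(duration / 0.025)
  rows <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    us <- seed + u
    kern <- random_unit_kernels(seed = us)
    par <- ln_unit_params(kern$kf, kern$kh, bias = 5,
                          gain_low = gain_low, gain_high = gain_high,
                          light_gain_factor = light_gain_factor,
                          light_offset = light_offset,
                          noise_sd = noise_sd, seed = us * 101L)
    # n_drcs stimuli per condition, each presented n_reps times; repeats
    # averaged, stimuli concatenated
    cond_trace <- function(cond, seed_base, light) {
      unlist(lapply(seq_len(n_drcs), function(d) {
        drc <- generate_drc(cond, duration, seed = seed_base + d)
        reps <- vapply(seq_len(n_reps), function(r) {
          p <- par
          p$seed <- par$seed + 1000L * d + r + 500L * light
          simulate_ln_unit(p, drc, light_on = light)$values
        }, numeric(n_chords))
        rowMeans(reps)
      }))
    }
    gs <- gain_summary(
      low_off = cond_trace(low, us * 17L, FALSE),
      low_on = cond_trace(low, us * 17L, TRUE),
      high_off = cond_trace(high, us * 23L, FALSE),
      high_on = cond_trace(high, us * 23L, TRUE)
    )
    d <- gs$derived
    rows[[u]] <- data.frame(
      unit = u,
      gain_ratio_low = d$gain_ratio_low, gain_ratio_high = d$gain_ratio_high,
      G_relative = as.numeric(d$G_relative),
      R_offset_low = as.numeric(d$R_offset_low),
      R_offset_high = as.numeric(d$R_offset_high),
      Rmin_ratio_low = d$Rmin_ratio_low, Rmax_ratio_low = d$Rmax_ratio_low,
      Rmin_ratio_high = d$Rmin_ratio_high, Rmax_ratio_high = d$Rmax_ratio_high
    )
  }
  do.call(rbind, rows)
}

signed_rank_p <- function(x, mu = 1) {
  if (all(x == mu)) return(1)
  stats::wilcox.test(x, mu = mu, exact = FALSE)$p.value
}

#' Run a simulated extracellular experiment end to end
#'
#' Composes the full extracellular analysis chain on simulated LN units:
#' for each unit, DRC stimuli are generated for both contrasts (the
#' standard protocol: `n_drcs` stimuli, each presented `n_reps` times,
#' giving `n_drcs * n_reps * drc_duration` seconds of data per condition),
#' responses are simulated under light-off/light-on, an STRF is fitted to
#' 90% of the light-off responses and evaluated on the held-out 10% (units
#' with CC below the selection threshold are excluded), the light-off STRF
#' is transferred to light-on data with a single scale factor, and the
#' nonparametric gain ledger is computed.
#'
#' @param config a [run_config()] of kind `"extracellular"`.
#' @param out_dir optional directory; when given, writes `units.csv` and
#'   `summary.json`.
#' @return list of class `cgc_report`: `units` (per-unit data frame),
#'   `population` (medians and signed-rank p-values), `config`,
#'   `config_hash`, `fit_seconds_per_condition`.
#' @export
run_extracellular_experiment <- function(config = run_config("extracellular"),
                                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$kind == "extracellular")
  low <- contrast_condition("low")
  high <- contrast_condition("high")
  rows <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    us <- config$seed + u
    kern <- random_unit_kernels(n_h = config$n_lags, seed = us)
    par <- ln_unit_params(kern$kf, kern$kh, bias = config$bias,
                          gain_low = config$gain_low,
                          gain_high = config$gain_high,
                          light_gain_factor = config$light_gain_factor,
                          light_offset = config$light_offset,
                          noise_sd = config$noise_sd,
                          nonlinearity = config$nonlinearity,
                          seed = us * 101L)
    # stimuli: n_drcs per contrast; responses averaged over n_reps repeats
    resp_of <- function(cond, cond_seed_base, light) {
      traces <- lapply(seq_len(config$n_drcs), function(d) {
        drc <- generate_drc(cond, config$drc_duration,
                            seed = cond_seed_base + d)
        reps <- vapply(seq_len(config$n_reps), function(r) {
          p <- par; p$seed <- par$seed + 1000L * d + r + 500L * light
          simulate_ln_unit(p, drc, light_on = light)$values
        }, numeric(config$drc_duration / 0.025))
        list(drc = drc, mean = rowMeans(reps))
      })
      traces
    }
    lo_off <- resp_of(low, us * 17L, FALSE)
    lo_on <- resp_of(low, us * 17L, TRUE)
    hi_off <- resp_of(high, us * 23L, FALSE)
    hi_on <- resp_of(high, us * 23L, TRUE)

    # STRF selection on light-off high-contrast data, 90/10 split
    design <- build_design(hi_off[[1]]$drc, hi_off[[1]]$mean,
                           n_lags = config$n_lags)
    for (d in seq_len(config$n_drcs)[-1]) {
      dd <- build_design(hi_off[[d]]$drc, hi_off[[d]]$mean,
                         n_lags = config$n_lags)
      design$X <- rbind(design$X, dd$X)
      design$y <- c(design$y, dd$y)
    }
    sp <- split_design(design, 0.1)
    strf <- fit_separable_strf(sp$train)
    ev <- evaluate_cc(strf, sp$test, threshold = config$cc_threshold)
    met <- strf_metrics(strf)

    # cross-condition transfer: light-off STRF, scale factor, light-on data
    design_on <- build_design(hi_on[[1]]$drc, hi_on[[1]]$mean,
                              n_lags = config$n_lags)
    xc <- cross_condition_scale(strf, design_on)

    cat_vals <- function(tr) unlist(lapply(tr, `[[`, "mean"))
    gs <- gain_summary(cat_vals(lo_off), cat_vals(lo_on),
                       cat_vals(hi_off), cat_vals(hi_on))
    d <- gs$derived
    rows[[u]] <- data.frame(
      unit = u, seed = us, cc = ev$cc, include = ev$include,
      bf_hz = met$bf, bandwidth_oct = met$bandwidth,
      temporal_window_ms = met$temporal_window,
      cross_scale = xc$scale, cc_on = xc$cc_on,
      gain_ratio_low = d$gain_ratio_low,
      gain_ratio_high = d$gain_ratio_high,
      G_relative = as.numeric(d$G_relative),
      R_offset_low = as.numeric(d$R_offset_low),
      R_offset_high = as.numeric(d$R_offset_high)
    )
  }
  units <- do.call(rbind, rows)
  inc <- units[units$include, , drop = FALSE]
  population <- list(
    n_units = nrow(units), n_included = nrow(inc),
    median_cc = stats::median(units$cc),
    median_G_relative = stats::median(inc$G_relative),
    median_gain_ratio_low = stats::median(inc$gain_ratio_low),
    median_gain_ratio_high = stats::median(inc$gain_ratio_high),
    p_G_relative_vs_1 = signed_rank_p(inc$G_relative, 1),
    p_gain_ratio_low_vs_1 = signed_rank_p(inc$gain_ratio_low, 1)
  )
  report <- structure(
    list(units = units, population = population, config = config,
         config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("contrastgain")),
         fit_seconds_per_condition =
           config$n_drcs * config$n_reps * config$drc_duration),
    class = "cgc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run a simulated intracellular experiment end to end
#'
#' For each simulated cell: builds the alternating-contrast sequence
#' (`n_reps_sequence` one-second DRC segments alternating low/high contrast
#' with a 50-ms frozen noise burst 500 ms into each), simulates whole-cell
#' sweeps at several holding currents, fits and compensates access
#' resistance from the pre-stimulus pulse train, estimates the input
#' conductance per timepoint, compares conductance between contrasts
#' (excluding the first low-contrast segment), and measures PSP amplitude
#' per contrast from the zero-current sweeps.
#'
#' @param config a [run_config()] of kind `"intracellular"`.
#' @param out_dir optional output directory (`cells.csv`, `summary.json`).
#' @return list of class `cgc_report` with `cells`, `population`, `config`,
#'   `config_hash`.
#' @export
run_intracellular_experiment <- function(config = run_config("intracellular"),
                                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), config$kind == "intracellular")
  rows <- vector("list", config$n_cells)
  fs <- config$fs
  for (ci in seq_len(config$n_cells)) {
    cs <- config$seed + 1000L * ci
    seq_drc <- alternating_contrast_sequence(config$n_reps_sequence,
                                             seed = cs)
    seq_drc <- lapply(seq_drc, embed_noise_burst,
                      onset = config$noise_burst_onset,
                      burst_dur = config$noise_burst_dur, seed = cs + 7L)
    # conductance drive: per-segment, normalized per segment so the drive
    # statistics are contrast invariant (the null the analysis must recover)
    g_syn <- unlist(lapply(seq_drc, drc_conductance_drive, fs = fs,
                           g_peak = config$g_syn_peak))
    par <- patch_sim_params(R_input = config$R_input,
                            tau_input = config$tau_input,
                            R_access = config$R_access,
                            tau_access = config$tau_access,
                            E_rest = config$E_rest,
                            g_syn_peak = config$g_syn_peak,
                            spike_threshold = config$spike_threshold,
                            trial_noise_sd = config$trial_noise_sd,
                            seed = cs)
    vss <- simulate_whole_cell(par, I_levels = config$I_levels,
                               n_trials = config$n_trials,
                               g_syn = g_syn, fs = fs)
    fit <- fit_access_model(mean_pulse_response(vss))
    comp <- compensate_access(vss, fit)

    # per-contrast conductance: 1-s segments, first (low) excluded
    seg_len <- round(fs * 1)
    stim0 <- vss$epochs$stim[1]
    seg_G <- function(seg_idx) {
      rngs <- lapply(seg_idx, function(s) {
        stim0 + (s - 1L) * seg_len + seq_len(seg_len) - 1L
      })
      sub <- comp
      sub$epochs$stim <- c(1L, length(unlist(rngs)))
      sub$sweeps <- comp$sweeps[, unlist(rngs), drop = FALSE]
      sub$epochs$stim <- c(1L, ncol(sub$sweeps))
      stats::median(estimate_conductance(sub, epoch = "stim")$G)
    }
    segs <- seq_len(config$n_reps_sequence)
    low_segs <- setdiff(segs[segs %% 2 == 1], 1L)  # first low excluded
    high_segs <- segs[segs %% 2 == 0]
    G_low <- seg_G(low_segs)
    G_high <- seg_G(high_segs)

    # PSP metrics from zero-holding-current sweeps, per contrast
    zero_sweeps <- which(vss$I_inj == 0)
    psp_of <- function(seg_idx) {
      mats <- lapply(seg_idx, function(s) {
        rng <- stim0 + (s - 1L) * seg_len + seq_len(seg_len) - 1L
        comp$sweeps[zero_sweeps, rng, drop = FALSE]
      })
      psp_metrics(do.call(rbind, mats), fs,
                  noise_onset = config$noise_burst_onset)
    }
    psp_low <- psp_of(low_segs)
    psp_high <- psp_of(high_segs)

    r2 <- estimate_conductance(comp, epoch = "stim")$r2_reconstruction
    rows[[ci]] <- data.frame(
      cell = ci, seed = cs,
      R_access_fit = fit$R_access, tau_access_fit = fit$tau_access,
      R_input_fit = fit$R_input, tau_input_fit = fit$tau_input,
      G_low_nS = G_low, G_high_nS = G_high,
      dG_pct = 100 * (G_high - G_low) / G_low,
      psp_amp_low = psp_low$amplitude, psp_amp_high = psp_high$amplitude,
      sigma_Vm_low = psp_low$sigma_Vm, sigma_Vm_high = psp_high$sigma_Vm,
      r2_reconstruction = r2
    )
  }
  cells <- do.call(rbind, rows)
  population <- list(
    n_cells = nrow(cells),
    median_dG_pct = stats::median(cells$dG_pct),
    median_psp_amp_low = stats::median(cells$psp_amp_low),
    median_psp_amp_high = stats::median(cells$psp_amp_high),
    median_r2 = stats::median(cells$r2_reconstruction),
    n_segments_per_contrast = length(setdiff(
      which(seq_len(config$n_reps_sequence) %% 2 == 1), 1L))
  )
  report <- structure(
    list(cells = cells, population = population, config = config,
         config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("contrastgain"))),
    class = "cgc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cgc_report <- function(x, ...) {
  cat(sprintf("<cgc_report (%s), config %s>\n", x$config$kind, x$config_hash))
  utils::str(x$population)
  invisible(x)
}

#' Write a report to CSV + JSON
#'
#' Writes the per-unit (or per-cell) table to `units.csv`/`cells.csv` and
#' the population summary — including the config, its hash, and the package
#' version — to `summary.json`.
#'
#' @param report a `cgc_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$units %||% report$cells
  tab_name <- if (is.null(report$units)) "cells.csv" else "units.csv"
  csv <- file.path(dir, tab_name)
  utils::write.csv(tab, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(population = report$population,
         config = unclass(report$config),
         config_hash = report$config_hash,
         package_version = report$package_version),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Write / read a DRC stimulus as CSV + JSON sidecar
#'
#' The level matrix goes to `<stem>_levels.csv` (one row per frequency) and
#' the metadata (frequency axis, chord/ramp durations, seed, condition,
#' phases, any noise-burst substitution) to `<stem>_meta.json`, so a
#' stimulus round-trips exactly through text files.
#'
#' @param drc a `drc_stimulus`.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_drc <- function(drc, stem) {
  lv <- file.path(paste0(stem, "_levels.csv"))
  utils::write.table(drc$levels, lv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(freqs_hz = drc$freqs_hz, chord_dur = drc$chord_dur,
               ramp_dur = drc$ramp_dur, seed = drc$seed,
               condition = unclass(drc$condition), phases = drc$phases,
               noise_burst = drc$noise_burst)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(lv, paste0(stem, "_meta.json")))
}

#' @rdname write_drc
#' @param stem path stem used by [write_drc()].
#' @export
read_drc <- function(stem) {
  levels <- as.matrix(utils::read.table(paste0(stem, "_levels.csv"),
                                        sep = ","))
  dimnames(levels) <- NULL
  m <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  cond <- contrast_condition(m$condition$name, m$condition$mean_level,
                             m$condition$level_range)
  drc <- structure(
    list(freqs_hz = m$freqs_hz, levels = levels, chord_dur = m$chord_dur,
         ramp_dur = m$ramp_dur, seed = m$seed, condition = cond,
         phases = m$phases, noise_burst = NULL),
    class = "drc_stimulus"
  )
  if (!is.null(m$noise_burst) && length(m$noise_burst)) {
    drc$noise_burst <- list(chords = m$noise_burst$chords,
                            onset = m$noise_burst$onset,
                            dur = m$noise_burst$dur,
                            seed = m$noise_burst$seed,
                            level = m$noise_burst$level)
  }
  drc
}
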