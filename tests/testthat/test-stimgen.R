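test_that("quarter-octave axis spans whole octaves with 2^(1/4) spacing", {
  f <- quarter_octave_axis(1000, 64000)
  expect_length(f, 25)
  expect_equal(f[1], 1000)
  expect_equal(f[25], 64000)
  expect_equal(f[5], 2000)  # exact octave landmark
  expect_equal(unique(round(diff(log2(f)), 10)), 0.25)
  expect_length(quarter_octave_axis(1000, 2000), 5)
  expect_error(quarter_octave_axis(1000, 48000), "power of two")
})

test_that("DRC levels are uniform with the stated mean and range", {
  drc <- generate_drc(contrast_condition("low"), 40, seed = 11)
  expect_equal(dim(drc$levels), c(25, 1600))
  expect_lt(abs(mean(drc$levels) - 40), 0.2)
  expect_lte(diff(range(drc$levels)), 20)
  # Kolmogorov-Smirnov uniformity at n = 40,000
  ks <- suppressWarnings(
    stats::ks.test(as.vector(drc$levels), "punif", 30, 50))
  expect_gt(ks$p.value, 0.01)
})

test_that("level SD converges to range/sqrt(12) and doubles with range", {
  # one million draws: a 1000-s high-contrast sequence has 40,000 chords
  big <- generate_drc(contrast_condition("high"), 1000, seed = 2)
  expect_lt(abs(sd(big$levels) - 40 / sqrt(12)), 0.02)
  lo <- generate_drc(contrast_condition("low"), 200, seed = 3)
  hi <- generate_drc(contrast_condition("high"), 200, seed = 4)
  expect_lt(abs(sd(hi$levels) / sd(lo$levels) - 2), 0.05)
})

test_that("degenerate and invalid stimulus requests are handled", {
  flat <- generate_drc(contrast_condition("flat", 40, 0), 1, seed = 1)
  expect_true(all(flat$levels == 40))
  expect_error(generate_drc(contrast_condition("low"), 0.99, seed = 1),
               "multiple of chord_dur")
  expect_error(contrast_condition("bad", 5, 20), "below 0 dB")
})

test_that("stimulus generation is reproducible under the seed", {
  a <- generate_drc(contrast_condition("high"), 2, seed = 9)
  b <- generate_drc(contrast_condition("high"), 2, seed = 9)
  expect_identical(a$levels, b$levels)
  expect_identical(a$phases, b$phases)
  wa <- synthesize_waveform(a, 200000)
  wb <- synthesize_waveform(b, 200000)
  expect_identical(wa, wb)
})

test_that("waveform synthesis has the right length, calibration and ramps", {
  drc <- generate_drc(contrast_condition("low"), 1, seed = 5)
  w <- synthesize_waveform(drc, 200000)
  expect_length(w, 200000)  # duration x sample rate
  expect_error(synthesize_waveform(drc, 100000), "aliases")

  # single-tone train at constant level: sustained RMS matches the analytic
  # sinusoid RMS amp/sqrt(2) for the calibration amplitude
  one <- generate_drc(contrast_condition("flat", 40, 0), 0.5, seed = 1,
                      f_lo = 1000, f_hi = 2000)
  one$levels <- one$levels[1, , drop = FALSE]
  one$freqs_hz <- one$freqs_hz[1]
  one$phases <- one$phases[1]
  w1 <- synthesize_waveform(one, 50000)
  amp <- 10^((40 - 94) / 20)
  mid <- w1[(0.25 * 50000):(0.26 * 50000)]  # sustain of chord 11
  expect_lt(abs(sd(mid) - amp / sqrt(2)) / (amp / sqrt(2)), 0.02)
  # ramped onset: first sample near zero, envelope grows over 5 ms
  expect_lt(max(abs(w1[1:10])), amp / 10)
})

test_that("noise bursts replace aligned chords with frozen noise", {
  drc <- generate_drc(contrast_condition("low"), 1, seed = 6,
                      f_lo = 1000, f_hi = 8000)
  nb <- embed_noise_burst(drc, onset = 0.5, burst_dur = 0.05, seed = 77)
  expect_equal(nb$noise_burst$chords, c(21, 22))  # [0.5, 0.55) s
  expect_identical(embed_noise_burst(drc, 0.5, 0, seed = 1)$noise_burst,
                   NULL)
  expect_error(embed_noise_burst(drc, 0.51, 0.05, seed = 1), "align")
  w1 <- synthesize_waveform(nb, 50000)
  w2 <- synthesize_waveform(nb, 50000)
  expect_identical(w1, w2)  # frozen noise bit-identical
  # different burst seed changes only the burst epoch
  nb2 <- embed_noise_burst(drc, onset = 0.5, burst_dur = 0.05, seed = 78)
  w3 <- synthesize_waveform(nb2, 50000)
  pre <- 1:(0.49 * 50000)
  expect_identical(w1[pre], w3[pre])
  burst <- (0.505 * 50000):(0.545 * 50000)
  expect_false(identical(w1[burst], w3[burst]))
})

test_that("alternating sequence preserves the pattern across contrasts", {
  seqs <- alternating_contrast_sequence(11, seed = 21)
  expect_length(seqs, 11)
  labs <- vapply(seqs, function(s) s$condition$name, character(1))
  expect_equal(labs, rep(c("low", "high"), length.out = 11))
  expect_true(seqs[[1]]$exclude)
  expect_false(any(vapply(seqs[-1], `[[`, logical(1), "exclude")))
  # rank order identical and the 40-dB midpoint is a fixed point
  r1 <- rank(as.vector(seqs[[1]]$levels))
  r2 <- rank(as.vector(seqs[[2]]$levels))
  expect_identical(r1, r2)
  mapped <- (seqs[[1]]$levels - 40) * 2 + 40
  expect_equal(mapped, seqs[[2]]$levels, tolerance = 1e-12)
  expect_error(alternating_contrast_sequence(1, seed = 1), ">= 2")
})

test_that("contrast measures report level SD and envelope contrast", {
  flat <- generate_drc(contrast_condition("flat", 40, 0), 1, seed = 1)
  expect_equal(measure_contrast(flat)$sigma_L, 0)
  lo <- generate_drc(contrast_condition("low"), 500, seed = 2)
  expect_lt(abs(measure_contrast(lo)$sigma_L - 20 / sqrt(12)), 0.05)
  expect_error(measure_contrast(lo, want_c = TRUE), "audio")
  short <- generate_drc(contrast_condition("high"), 0.5, seed = 3)
  w <- synthesize_waveform(short, 200000)
  mc <- measure_contrast(short, audio = w)
  expect_true(is.finite(mc$c) && mc$c > 0)
})
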