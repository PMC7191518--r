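test_that("lagged design has the documented shape and layout", {
  drc <- generate_drc(contrast_condition("high"), 40, seed = 1)
  y <- rnorm(1600)
  d <- build_design(drc, y, n_lags = 8)
  expect_equal(dim(d$X), c(1593, 200))  # (1600 - 8 + 1) x (25 x 8)
  expect_equal(d$y, y[8:1600])
  # column (l-1)*25 + f holds levels[f, t - l + 1]
  expect_equal(d$X[1, 25 + 3], drc$levels[3, 7])   # lag 1, freq 3, chord 8
  expect_equal(d$X[10, 3], drc$levels[3, 17])      # lag 0, freq 3, chord 17
  dc <- build_design(drc, y, n_lags = 8, center = TRUE)
  expect_lt(max(abs(colMeans(dc$X))), 1e-10)
  expect_error(build_design(drc, y[-1], n_lags = 8), "match")
  expect_error(build_design(drc, y, n_lags = 3), ">= 4")
})

test_that("ALS recovers a noiseless rank-1 kernel exactly", {
  fx <- fixture_ln_design(seed = 2, duration = 20)
  fit <- fit_separable_strf(fx$design)
  K_true <- outer(fx$kf, fx$kh)  # gain_high = 1 folded into the kernel scale
  K_fit <- outer(fit$k_f, fit$k_h)
  expect_lt(norm(K_fit - K_true, "F") / norm(K_true, "F"), 1e-6)
  expect_equal(fit$bias, 5, tolerance = 1e-6)
  ev <- evaluate_cc(fit, fx$design)
  expect_equal(ev$cc, 1, tolerance = 1e-9)
  expect_true(ev$include)
  # scale convention
  expect_equal(sum(fit$k_h^2), 1, tolerance = 1e-12)
  expect_gt(fit$k_f[which.max(abs(fit$k_f))], 0)
})

test_that("ALS loss is non-increasing and the optimum is start-independent", {
  fx <- fixture_ln_design(seed = 3, duration = 10)
  fit <- fit_separable_strf(fx$design)
  expect_true(all(diff(fit$fit_meta$loss_trace) <= 1e-12))
  K_ref <- outer(fit$k_f, fit$k_h)
  set.seed(42)
  for (i in 1:10) {
    alt <- fit_separable_strf(fx$design, kh_init = rnorm(8))
    expect_lt(norm(outer(alt$k_f, alt$k_h) - K_ref, "F"), 1e-6)
    expect_true(all(diff(alt$fit_meta$loss_trace) <= 1e-12))
  }
})

test_that("ALS matches the rank-1 SVD truncation of the full kernel", {
  # independent oracle: unconstrained least-squares kernel, truncated to
  # rank 1 by SVD, intercept refitted
  svd_rank1_loss <- function(X, y, nf, nl) {
    b <- lm.fit(cbind(1, X), y)$coefficients
    K <- matrix(b[-1], nf, nl)
    sv <- svd(K)
    K1 <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
    pred <- X %*% as.vector(K1)
    mean((y - pred - (mean(y) - mean(pred)))^2)
  }
  # noiseless: both losses are numerically zero
  fx <- fixture_ln_design(seed = 4, duration = 10)
  fit0 <- fit_separable_strf(fx$design)
  l0 <- svd_rank1_loss(fx$design$X, fx$design$y, 25, 8)
  expect_lt(fit0$fit_meta$final_loss, 1e-3 * var(fx$design$y))
  expect_lt(abs(fit0$fit_meta$final_loss - l0), 1e-3 * var(fx$design$y))
  # noisy small design: ALS is within 0.1% of (in fact no worse than) the
  # SVD-truncation loss
  set.seed(5)
  nf <- 6; nl <- 4; n <- 400
  X <- matrix(rnorm(n * nf * nl), n)
  y <- as.numeric(X %*% as.vector(outer(rnorm(nf), rnorm(nl))) + 1.5 +
                    rnorm(n, 0, 0.5))
  fit <- fit_separable_strf(X, y = y, n_freqs = nf, n_lags = nl)
  expect_lt(fit$fit_meta$final_loss, svd_rank1_loss(X, y, nf, nl) * 1.001)
})

test_that("prediction is linear in the kernels with an additive bias", {
  fx <- fixture_ln_design(seed = 6, duration = 5)
  fit <- fit_separable_strf(fx$design)
  zero <- fit
  zero$k_f <- numeric(25)
  expect_equal(predict(zero, fx$design),
               rep(fit$bias, nrow(fx$design$X)))
  dbl <- fit
  dbl$k_f <- 2 * fit$k_f
  expect_equal(predict(dbl, fx$design) - fit$bias,
               2 * (predict(fit, fx$design) - fit$bias), tolerance = 1e-10)
  expect_error(predict(fit, fx$design$X[, 1:100]), "columns")
})

test_that("inclusion criterion excludes unpredictive and degenerate units", {
  fx <- fixture_ln_design(seed = 7, duration = 10)
  fit <- fit_separable_strf(fx$design)
  # independent noise: CC near 0, excluded
  set.seed(8)
  ev <- evaluate_cc(fit, fx$design, y = rnorm(nrow(fx$design$X)))
  expect_lt(abs(ev$cc), 0.1)
  expect_false(ev$include)
  # threshold is inclusive at 0.04 and strict below it
  expect_false(evaluate_cc(fit, fx$design,
                           y = rnorm(nrow(fx$design$X)))$include)
  # zero-variance prediction flagged and excluded
  flat <- fit
  flat$k_f <- numeric(25)
  evf <- evaluate_cc(flat, fx$design)
  expect_true(is.na(evf$cc))
  expect_false(evf$include)
  expect_equal(evf$flag, "zero_variance_prediction")
})

test_that("tuning metrics match geometric constructions", {
  freq_axis <- quarter_octave_axis(1000, 64000)
  base <- structure(
    list(k_f = numeric(25), k_h = numeric(8), bias = 0,
         freq_axis = freq_axis, lag_axis = (0:7) * 0.025,
         fit_meta = list()),
    class = "separable_strf")

  # Gaussian bump centered on bin 12
  g <- base
  g$k_f <- exp(-((1:25) - 12)^2 / 8)
  g$k_h <- c(0, 1, 0.5, rep(0, 5))
  expect_equal(strf_metrics(g)$bf, freq_axis[12])

  # triangular frequency kernel: peak 1 at bin 13, linear decay 0.2/bin;
  # half height 0.5 crossed 2.5 bins either side = 5 bins = 1.25 octaves
  tr <- base
  tr$k_f <- pmax(1 - abs((1:25) - 13) * 0.2, 0)
  tr$k_h <- c(0, 1, rep(0, 6))
  expect_equal(strf_metrics(tr)$bandwidth, 5 * 0.25, tolerance = 1e-9)

  # history kernel peaking at 50 ms (lag bin 3), linear decay 0.25/bin:
  # half-height crossings 2 bins either side = 100 ms width
  th <- base
  th$k_f <- exp(-((1:25) - 12)^2 / 8)
  th$k_h <- pmax(1 - abs((1:8) - 3) * 0.25, 0)
  expect_equal(strf_metrics(th)$temporal_window, 100, tolerance = 1e-9)

  # peak of the outer product and degenerate flag
  expect_equal(strf_metrics(th)$peak_coeff, max(outer(th$k_f, th$k_h)))
  expect_equal(strf_metrics(base)$flag, "degenerate_kernel")
})

test_that("a single scale factor captures pure gain changes", {
  fx <- fixture_ln_design(seed = 9, duration = 10)
  fit <- fit_separable_strf(fx$design)
  # closed-form: y_on = 0.5 (yhat - bias) + 2 -> scale exactly 0.5
  y_on <- 0.5 * (predict(fit, fx$design) - fit$bias) + 2
  xc <- cross_condition_scale(fit, fx$design, y_on = y_on)
  expect_equal(xc$scale, 0.5, tolerance = 1e-9)
  expect_equal(xc$offset, 2, tolerance = 1e-9)
  # identical responses -> scale 1
  xc1 <- cross_condition_scale(fit, fx$design, y_on = fx$design$y)
  expect_equal(xc1$scale, 1, tolerance = 1e-6)
  # LN fixture with a 1.1 light gain factor
  fx_on <- fixture_ln_design(seed = 9, duration = 10, light_on = TRUE,
                             light_gain_factor = 1.1)
  xc2 <- cross_condition_scale(fit, fx_on$design)
  expect_lt(abs(xc2$scale - 1.1), 0.05)
})

test_that("gain-only changes preserve cross-condition predictive power", {
  # when the simulator applies only a multiplicative gain change, the
  # cross-condition CC (with a scale factor) matches the within-condition
  # CC to within 2%
  # a pure multiplicative gain change scales the whole response, noise
  # included, so the on-condition noise SD is scaled by the same factor
  fx_off <- fixture_ln_design(seed = 10, duration = 40, noise_sd = 0.5)
  fx_on <- fixture_ln_design(seed = 10, duration = 40, noise_sd = 0.6,
                             light_on = TRUE, light_gain_factor = 1.2)
  fit <- fit_separable_strf(split_design(fx_off$design)$train)
  cc_within <- evaluate_cc(fit, fx_off$design)$cc
  cc_cross <- cross_condition_scale(fit, fx_on$design)$cc_on
  expect_lt(abs(cc_cross - cc_within) / cc_within, 0.02)
})

test_that("best frequency is recovered in >= 95% of seeded moderate-SNR runs", {
  hits <- 0; n_runs <- 100
  for (s in seq_len(n_runs)) {
    kern <- contrastgain:::random_unit_kernels(seed = s)
    par <- ln_unit_params(kern$kf, kern$kh, bias = 5, gain_low = 2,
                          gain_high = 1, noise_sd = 1, seed = s * 101L)
    drc <- generate_drc(contrast_condition("high"), 40, seed = s * 7L)
    tr <- simulate_ln_unit(par, drc)
    sp <- split_design(build_design(drc, tr$values, n_lags = 8))
    fit <- fit_separable_strf(sp$train)
    if (which.max(fit$k_f) == kern$bf_bin) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})
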