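# Space-time separable spectrotemporal receptive field (STRF) estimation by
# alternating least squares, prediction, tuning metrics, and cross-condition
# transfer with a single scale factor.

#' Build a lagged design matrix from a DRC level matrix and a response
#'
#' The response is averaged within each 25-ms chord frame; row `t` of the
#' design contains the stimulus levels at lags `0 .. n_lags - 1` chords, and
#' the first `n_lags - 1` chords are dropped from the response so every row
#' has a full history. Columns are ordered frequency-fastest, i.e. column
#' `(l - 1) * n_freqs + f` holds `levels[f, t - l + 1]`, matching
#' `as.vector(outer(k_f, k_h))`.
#'
#' @param levels dB level matrix (n_freqs x n_chords) or a `drc_stimulus`.
#' @param response a [response_trace()] covering the stimulus, or a numeric
#'   per-chord response.
#' @param n_lags number of 25-ms lags (>= 4, i.e. >= 100 ms; default 8).
#' @param chord_dur chord duration in seconds (default 0.025).
#' @param center mean-center the design columns (default FALSE; the fit
#'   handles the intercept either way).
#' @param freq_axis optional frequency axis in Hz (taken from a
#'   `drc_stimulus` automatically).
#' @return object of class `strf_design`: `X` (rows x (n_freqs * n_lags)),
#'   `y`, `n_freqs`, `n_lags`, `freq_axis`, `lag_axis` (seconds).
#' @export
build_design <- function(levels, response, n_lags = 8, chord_dur = 0.025,
                         center = FALSE, freq_axis = NULL) {
  if (inherits(levels, "drc_stimulus")) {
    freq_axis <- levels$freqs_hz
    chord_dur <- levels$chord_dur
    levels <- levels$levels
  }
  stopifnot(is.matrix(levels))
  if (n_lags < 4) stop("n_lags must be >= 4 (>= 100 ms)", call. = FALSE)
  n_freqs <- nrow(levels)
  n_chords <- ncol(levels)

  if (inherits(response, "response_trace")) {
    spc <- response$fs * chord_dur
    n_resp_chords <- length(response$values) / spc
    if (abs(n_resp_chords - n_chords) > 1e-6) {
      stop(sprintf("response covers %.2f chords but stimulus has %d",
                   n_resp_chords, n_chords), call. = FALSE)
    }
    y_chord <- if (abs(spc - 1) < 1e-9) response$values else {
      frame <- rep(seq_len(n_chords), each = round(spc))
      as.numeric(tapply(response$values, frame, mean))
    }
  } else {
    y_chord <- as.numeric(response)
    if (length(y_chord) != n_chords) {
      stop("per-chord response length does not match the stimulus",
           call. = FALSE)
    }
  }
  if (n_lags > n_chords) stop("n_lags exceeds stimulus length", call. = FALSE)

  rows <- n_lags:n_chords
  X <- matrix(0, length(rows), n_freqs * n_lags)
  for (l in seq_len(n_lags)) {
    X[, (l - 1) * n_freqs + seq_len(n_freqs)] <- t(levels[, rows - l + 1,
                                                          drop = FALSE])
  }
  col_means <- colMeans(X)
  if (center) X <- sweep(X, 2, col_means)
  structure(
    list(X = X, y = y_chord[rows], n_freqs = n_freqs, n_lags = n_lags,
         freq_axis = freq_axis, lag_axis = (seq_len(n_lags) - 1) * chord_dur,
         centered = center, col_means = col_means, chord_dur = chord_dur),
    class = "strf_design"
  )
}

#' Split a design into contiguous train and test portions
#'
#' The held-out portion is the final contiguous fraction of the sequence,
#' which avoids temporal leakage between train and test.
#'
#' @param design an `strf_design`.
#' @param test_frac held-out fraction (default 0.1).
#' @return list with `train` and `test` `strf_design` objects.
#' @export
split_design <- function(design, test_frac = 0.1) {
  stopifnot(inherits(design, "strf_design"))
  n <- nrow(design$X)
  n_train <- floor((1 - test_frac) * n)
  take <- function(idx) {
    d <- design
    d$X <- design$X[idx, , drop = FALSE]
    d$y <- design$y[idx]
    d
  }
  list(train = take(seq_len(n_train)),
       test = take(seq(n_train + 1, n)))
}

# ridge-stabilized least squares of y on A with intercept; returns coef,
# intercept, and whether the ridge floor had to be engaged
solve_ls <- function(A, y, lambda) {
  Ac <- sweep(A, 2, colMeans(A))
  yc <- y - mean(y)
  G <- crossprod(Ac)
  scale <- mean(diag(G))
  if (scale == 0) scale <- 1
  rhs <- crossprod(Ac, yc)
  ridge_flagged <- FALSE
  lam <- lambda * scale
  coef <- tryCatch(
    solve(G + diag(lam, ncol(G)), rhs),
    error = function(e) {
      ridge_flagged <<- TRUE
      solve(G + diag(max(lam, 1e-10 * scale), ncol(G)), rhs)
    }
  )
  list(coef = as.numeric(coef),
       intercept = mean(y) - sum(colMeans(A) * coef),
       ridge_flagged = ridge_flagged)
}

#' Fit a separable STRF by alternating least squares
#'
#' Fits the rank-1 model `y = X %*% as.vector(outer(k_f, k_h)) + bias` by
#' block coordinate descent: solve for `k_f` by linear regression holding
#' `k_h` fixed, then for `k_h` holding `k_f` fixed, iterating to
#' convergence. Each subproblem is an ordinary (optionally ridge-penalized)
#' regression with an intercept, so the loss is non-increasing across
#' iterations. At exit the scale convention `||k_h|| = 1` is applied and the
#' sign is fixed so the largest-magnitude element of `k_f` is positive.
#'
#' `k_h` is initialized as a unit impulse at the second lag bin, a
#' deterministic start that reaches the same optimum as random starts on
#' well-posed problems.
#'
#' @param design an `strf_design` from [build_design()], or a design matrix
#'   `X` (then `y`, `n_freqs`, `n_lags` must be supplied).
#' @param y,n_freqs,n_lags only needed when `design` is a bare matrix.
#' @param lambda relative ridge penalty applied to both subproblems, as a
#'   fraction of the mean diagonal of the subproblem Gram matrix (default 0;
#'   a ridge floor engages automatically on singular subproblems and is
#'   flagged in `fit_meta`).
#' @param tol convergence tolerance on the relative loss change
#'   (default 1e-8).
#' @param max_iter maximum ALS iterations (default 200).
#' @param kh_init optional initial history kernel.
#' @return object of class `separable_strf` with fields `k_f`, `k_h`,
#'   `bias`, `freq_axis`, `lag_axis`, and `fit_meta` (`n_iters`,
#'   `final_loss`, `loss_trace`, `converged`, `ridge_flagged`).
#' @export
fit_separable_strf <- function(design, y = NULL, n_freqs = NULL,
                               n_lags = NULL, lambda = 0, tol = 1e-8,
                               max_iter = 200, kh_init = NULL) {
  if (inherits(design, "strf_design")) {
    X <- design$X; y <- design$y
    n_freqs <- design$n_freqs; n_lags <- design$n_lags
    freq_axis <- design$freq_axis; lag_axis <- design$lag_axis
  } else {
    X <- design
    stopifnot(!is.null(y), !is.null(n_freqs), !is.null(n_lags))
    freq_axis <- NULL; lag_axis <- (seq_len(n_lags) - 1) * 0.025
  }
  if (nrow(X) <= n_freqs + n_lags) {
    stop("not enough rows in the design to fit both kernels", call. = FALSE)
  }
  Xarr <- array(X, c(nrow(X), n_freqs, n_lags))

  kh <- if (is.null(kh_init)) {
    k <- numeric(n_lags); k[min(2L, n_lags)] <- 1; k
  } else as.numeric(kh_init)
  kf <- numeric(n_freqs)
  bias <- mean(y)
  loss_trace <- numeric(0)
  ridge_flagged <- FALSE
  converged <- FALSE

  freq_features <- function(kh) {
    A <- matrix(0, nrow(X), n_freqs)
    for (l in seq_len(n_lags)) if (kh[l] != 0) A <- A + Xarr[, , l] * kh[l]
    A
  }
  lag_features <- function(kf) {
    B <- matrix(0, nrow(X), n_lags)
    for (l in seq_len(n_lags)) B[, l] <- Xarr[, , l] %*% kf
    B
  }

  for (it in seq_len(max_iter)) {
    sf <- solve_ls(freq_features(kh), y, lambda)
    kf <- sf$coef
    sh <- solve_ls(lag_features(kf), y, lambda)
    kh <- sh$coef
    bias <- sh$intercept
    ridge_flagged <- ridge_flagged || sf$ridge_flagged || sh$ridge_flagged
    resid <- y - lag_features(kf) %*% kh - bias
    loss <- mean(resid^2)
    loss_trace <- c(loss_trace, loss)
    if (it > 1) {
      prev <- loss_trace[it - 1]
      if (prev == 0 || abs(prev - loss) / max(prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    }
  }

  # scale/sign convention
  nrm <- sqrt(sum(kh^2))
  if (nrm > 0) {
    kh <- kh / nrm
    kf <- kf * nrm
  }
  if (length(kf) && kf[which.max(abs(kf))] < 0) {
    kf <- -kf; kh <- -kh
  }

  structure(
    list(k_f = kf, k_h = kh, bias = bias,
         freq_axis = freq_axis, lag_axis = lag_axis,
         fit_meta = list(n_iters = length(loss_trace),
                         final_loss = loss_trace[length(loss_trace)],
                         loss_trace = loss_trace,
                         converged = converged,
                         ridge_flagged = ridge_flagged)),
    class = "separable_strf"
  )
}

#' @export
print.separable_strf <- function(x, ...) {
  cat(sprintf("<separable_strf: %d freqs x %d lags, bias %.3g, loss %.4g (%d iters%s)>\n",
              length(x$k_f), length(x$k_h), x$bias, x$fit_meta$final_loss,
              x$fit_meta$n_iters,
              if (isTRUE(x$fit_meta$converged)) ", converged" else ""))
  invisible(x)
}

#' Predict responses from a separable STRF
#'
#' @param object a `separable_strf`.
#' @param design an `strf_design` or bare design matrix with matching lag
#'   and frequency counts.
#' @param ... unused.
#' @return numeric predicted response, `X %*% vec(outer(k_f, k_h)) + bias`.
#' @export
predict.separable_strf <- function(object, design, ...) {
  X <- if (inherits(design, "strf_design")) design$X else design
  k <- as.vector(outer(object$k_f, object$k_h))
  if (ncol(X) != length(k)) {
    stop(sprintf("design has %d columns but the STRF implies %d",
                 ncol(X), length(k)), call. = FALSE)
  }
  as.numeric(X %*% k + object$bias)
}

#' Held-out prediction quality and inclusion decision
#'
#' Pearson correlation between predicted and actual held-out responses. A
#' unit is included in further analysis when CC >= 0.04; units below that
#' are considered unpredictive.
#'
#' @param strf a `separable_strf`.
#' @param design held-out `strf_design` (or design matrix).
#' @param y held-out response (taken from the design when omitted).
#' @param threshold inclusion threshold (default 0.04).
#' @return list with `cc`, `include`, and `flag`
#'   (`"zero_variance_prediction"` when CC is undefined; such units are
#'   excluded).
#' @export
evaluate_cc <- function(strf, design, y = NULL, threshold = 0.04) {
  if (inherits(design, "strf_design") && is.null(y)) y <- design$y
  pred <- predict(strf, design)
  cc <- safe_cc(pred, y)
  if (is.na(cc)) {
    return(list(cc = NA_real_, include = FALSE,
                flag = "zero_variance_prediction"))
  }
  list(cc = cc, include = cc >= threshold, flag = NULL)
}

# half-amplitude width of a kernel around its peak, by linear interpolation
# on the supplied axis; returns the contiguous width in axis units
half_width <- function(values, axis, peak_idx) {
  half <- values[peak_idx] / 2
  # left crossing
  left <- axis[1]
  i <- peak_idx
  while (i > 1 && values[i - 1] >= half) i <- i - 1
  if (i > 1) {
    f <- (values[i] - half) / (values[i] - values[i - 1])
    left <- axis[i] - f * (axis[i] - axis[i - 1])
  }
  # right crossing
  right <- axis[length(axis)]
  j <- peak_idx
  while (j < length(values) && values[j + 1] >= half) j <- j + 1
  if (j < length(values)) {
    f <- (values[j] - half) / (values[j] - values[j + 1])
    right <- axis[j] + f * (axis[j + 1] - axis[j])
  }
  right - left
}

#' Tuning metrics of a separable STRF
#'
#' Best frequency (BF) is the frequency bin with the largest frequency-kernel
#' coefficient. Spectral bandwidth is the contiguous width (in octaves, on
#' the log-spaced axis) around the BF where the frequency kernel stays at or
#' above half its peak, with linear interpolation at the half-height
#' crossings. The temporal integration window is measured the same way on
#' the history kernel around its peak coefficient within the first 100 ms,
#' at 50% of that peak's amplitude.
#'
#' @param strf a `separable_strf` with a frequency axis.
#' @param max_lag_s cap for the history peak search in seconds (default 0.1).
#' @return list of class `tuning_metrics`: `bf` (Hz), `bandwidth` (octaves),
#'   `temporal_window` (ms), `peak_coeff` (max of the outer product). An
#'   all-zero kernel yields `NA` metrics with `flag = "degenerate_kernel"`.
#' @export
strf_metrics <- function(strf, max_lag_s = 0.1) {
  stopifnot(inherits(strf, "separable_strf"))
  kf <- strf$k_f; kh <- strf$k_h
  if (all(kf == 0) || all(kh == 0)) {
    return(structure(list(bf = NA_real_, bandwidth = NA_real_,
                          temporal_window = NA_real_, peak_coeff = NA_real_,
                          flag = "degenerate_kernel"),
                     class = "tuning_metrics"))
  }
  if (is.null(strf$freq_axis)) {
    stop("STRF has no frequency axis; build the design from a drc_stimulus",
         call. = FALSE)
  }
  pf <- which.max(kf)
  bf <- strf$freq_axis[pf]
  bandwidth <- half_width(kf, log2(strf$freq_axis), pf)

  in_window <- which(strf$lag_axis <= max_lag_s + 1e-12)
  ph <- in_window[which.max(kh[in_window])]
  temporal_window <- half_width(kh, strf$lag_axis * 1000, ph)

  structure(list(bf = bf, bandwidth = bandwidth,
                 temporal_window = temporal_window,
                 peak_coeff = max(outer(kf, kh)), flag = NULL),
            class = "tuning_metrics")
}

#' Cross-condition transfer of an STRF with a single scale factor
#'
#' Takes an STRF fitted in one condition (e.g. light off) and describes
#' another condition's responses with the only modification being a scale
#' factor on the stimulus-driven component (a change in gain) plus an
#' offset: minimizes `|| y_on - (a * (yhat_off - bias_off) + b) ||^2` in
#' closed form.
#'
#' @param strf_off STRF fitted on the reference condition.
#' @param design_on design built from the other condition's stimulus/response.
#' @param y_on response (taken from the design when omitted).
#' @return list with `scale` (a), `offset` (b), and `cc_on` (correlation of
#'   the scaled prediction with the response); degenerate predictions are
#'   flagged.
#' @export
cross_condition_scale <- function(strf_off, design_on, y_on = NULL) {
  if (inherits(design_on, "strf_design") && is.null(y_on)) y_on <- design_on$y
  z <- predict(strf_off, design_on) - strf_off$bias
  if (stats::sd(z) == 0) {
    return(list(scale = NA_real_, offset = NA_real_, cc_on = NA_real_,
                flag = "degenerate_prediction"))
  }
  a <- stats::cov(z, y_on) / stats::var(z)
  b <- mean(y_on) - a * mean(z)
  list(scale = a, offset = b, cc_on = safe_cc(a * z + b, y_on), flag = NULL)
}
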