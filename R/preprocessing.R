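#' Epoched multichannel EEG container
#'
#' Trials x channels x samples array with sampling rate, optional class
#' labels and the epoch window relative to the cue.
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels optional integer class label per trial.
#' @param tmin epoch start relative to the cue, seconds (default 0).
#' @return object of class `epoched_eeg` with fields `data`, `fs`,
#'   `labels`, `tmin`, `tmax`.
#' @export
epoched_eeg <- function(data, fs, labels = NULL, tmin = 0) {
  if (!is.array(data) || length(dim(data)) != 3)
    ra_stop("data must be a trials x channels x samples array",
            "riemalign_error_invalid_input")
  if (!all(is.finite(data)))
    ra_stop("data contains non-finite values", "riemalign_error_invalid_input")
  if (fs <= 0)
    ra_stop("fs must be positive", "riemalign_error_invalid_input")
  if (!is.null(labels) && length(labels) != dim(data)[1])
    ra_stop("labels must match the number of trials",
            "riemalign_error_invalid_input")
  structure(list(data = data, fs = fs,
                 labels = if (!is.null(labels)) as.integer(labels) else NULL,
                 tmin = tmin, tmax = tmin + dim(data)[3] / fs),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d trials, %d channels, %d samples @ %g Hz (%.3f..%.3f s)\n",
              d[1], d[2], d[3], x$fs, x$tmin, x$tmax))
  invisible(x)
}

# polynomial with given (complex) roots, leading coefficient 1
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Butterworth bandpass filter design
#'
#' Digital bandpass design by the classical analog-prototype route: the
#' order-`order` Butterworth lowpass poles are frequency-transformed to a
#' bandpass (doubling the order) and discretized with the bilinear
#' transform after prewarping the band edges. No DSP package ships with the
#' supported environment, so the design is implemented here; it reproduces
#' the reference implementation (SciPy `butter`) to near machine precision
#' (see the test suite).
#'
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order analog prototype order per pass (default 5).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 5) {
  if (low <= 0 || high <= low || high >= fs / 2)
    ra_stop("need 0 < low < high < fs/2", "riemalign_error_invalid_input")
  # analog lowpass prototype (cutoff 1 rad/s): poles only, unit gain
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- 1
  # prewarped band edges; bilinear uses internal rate 2*fs
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass on zeros/poles/gain
  pb <- bw * p / 2
  p_bp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  gain <- gain * bw^order
  # bilinear transform
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  gain_d <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  list(b = Re(poly_from_roots(z_d)) * gain_d,
       a = Re(poly_from_roots(p_d)))
}

# direct-form II transposed IIR filter with initial state zi
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  z <- if (is.null(zi)) numeric(nfilt - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nfilt > 2)
      for (j in seq_len(nfilt - 2))
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nfilt - 1] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial conditions for a unit step (lfilter_zi)
filter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  n <- nfilt - 1
  A <- rbind(-a[2:nfilt], cbind(diag(1, n - 1), numeric(n - 1)))
  B <- b[2:nfilt] - a[2:nfilt] * b[1]
  solve(diag(n) - t(A), B)
}

# zero-phase filtering with odd-reflection padding (filtfilt)
filtfilt_ra <- function(b, a, x) {
  npad <- 3 * (max(length(a), length(b)) - 1)
  if (length(x) <= npad)
    ra_stop("signal too short for zero-phase filtering",
            "riemalign_error_invalid_input")
  ext <- c(2 * x[1] - x[(npad + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)])
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + length(x))]
}

#' Bandpass-filter epoched EEG
#'
#' Per-channel Butterworth filtering. The default is zero-phase
#' forward-backward application (order `order` per pass) with
#' odd-reflection padding and steady-state initial conditions, which keeps
#' epochs time-aligned; `causal = TRUE` applies a single forward pass.
#' After filtering, signals are approximately zero-mean, which is what
#' justifies the uncentered covariance estimator of [trial_covariance()].
#'
#' @param epochs `epoched_eeg`.
#' @param low,high passband edges in Hz (defaults 10 and 30, the
#'   sensorimotor mu/beta band).
#' @param order Butterworth order per pass (default 5).
#' @param causal single forward pass instead of zero-phase (default FALSE).
#' @return filtered `epoched_eeg`.
#' @export
bandpass_filter <- function(epochs, low = 10, high = 30, order = 5,
                            causal = FALSE) {
  if (!inherits(epochs, "epoched_eeg"))
    ra_stop("epoched_eeg required", "riemalign_error_invalid_input")
  ba <- butter_bandpass(low, high, epochs$fs, order)
  d <- epochs$data
  dims <- dim(d)
  for (tr in seq_len(dims[1])) for (ch in seq_len(dims[2])) {
    d[tr, ch, ] <- if (causal) iir_filter(ba$b, ba$a, d[tr, ch, ])
                   else filtfilt_ra(ba$b, ba$a, d[tr, ch, ])
  }
  epoched_eeg(d, epochs$fs, epochs$labels, epochs$tmin)
}

#' Extract a time window from epoched EEG
#'
#' Cuts `round((end - start) * fs)` samples starting at `start` seconds
#' (relative to the cue, same convention as `tmin`). The canonical
#' motor-imagery window 0.5--2.5 s at 250 Hz yields 500 samples.
#'
#' @param epochs `epoched_eeg`.
#' @param start,end window in seconds, must lie within the recorded epoch.
#' @return windowed `epoched_eeg`.
#' @export
extract_window <- function(epochs, start, end) {
  if (!inherits(epochs, "epoched_eeg"))
    ra_stop("epoched_eeg required", "riemalign_error_invalid_input")
  if (start < epochs$tmin - 1e-9 || end > epochs$tmax + 1e-9 || end <= start)
    ra_stop("window outside recorded epoch", "riemalign_error_invalid_input")
  fs <- epochs$fs
  i0 <- round((start - epochs$tmin) * fs)
  l <- round((end - start) * fs)
  if (i0 + l > dim(epochs$data)[3])
    ra_stop("window outside recorded epoch", "riemalign_error_invalid_input")
  epoched_eeg(epochs$data[, , (i0 + 1):(i0 + l), drop = FALSE],
              fs, epochs$labels, start)
}

#' Trial covariance matrices from epoched EEG
#'
#' `X_i = E_i E_i' / (l - 1)` per trial, without mean subtraction: signals
#' are assumed zero-mean after bandpass filtering (set `center = TRUE` for
#' unfiltered inputs). Every matrix is validated against the SPD
#' invariants; a rank-deficient trial raises a singular-covariance error
#' naming the trial unless `regularize` adds a small ridge `epsilon * I`
#' (default `1e-10 * trace/n` per trial).
#'
#' @param epochs `epoched_eeg` with at least 2 samples per trial.
#' @param regularize add `epsilon * I` to each covariance.
#' @param epsilon ridge size; default `1e-10 * mean(diag(X))` per trial.
#' @param center subtract the per-channel mean before the outer product.
#' @return `spd_dataset` with the epochs' labels and a `domain_id` of
#'   `"epochs"`.
#' @export
trial_covariance <- function(epochs, regularize = FALSE, epsilon = NULL,
                             center = FALSE) {
  if (!inherits(epochs, "epoched_eeg"))
    ra_stop("epoched_eeg required", "riemalign_error_invalid_input")
  dims <- dim(epochs$data)
  l <- dims[3]
  if (l < 2)
    ra_stop("need at least 2 samples per trial", "riemalign_error_invalid_input")
  mats <- vector("list", dims[1])
  for (tr in seq_len(dims[1])) {
    E <- matrix(epochs$data[tr, , ], nrow = dims[2])
    if (center) E <- E - rowMeans(E)
    X <- tcrossprod(E) / (l - 1)
    if (regularize) {
      eps <- if (is.null(epsilon)) 1e-10 * mean(diag(X)) else epsilon
      X <- X + diag(eps, dims[2])
    }
    ok <- tryCatch({ spd_eigen(X); TRUE },
                   riemalign_error_singular = function(e) FALSE)
    if (!ok)
      ra_stop(sprintf("covariance of trial %d is singular (rank-deficient trial); consider regularize = TRUE",
                      tr), "riemalign_error_singular")
    mats[[tr]] <- sym_part(X)
  }
  spd_dataset(mats, labels = epochs$labels, domain_id = "epochs",
              validate = FALSE)
}
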