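# Zero-phase IIR filtering and FFT resampling primitives.
#
# Filtering is vectorized over signals: X is a (signals x time) matrix and
# the IIR recursion runs once over time with vector arithmetic across all
# signals (trials x channels collapse into rows), which keeps the per-band
# filter-bank pass cheap even for a thousand epochs.

# Butterworth band-pass: `order` is the final filter order (must be even
# for a band-pass; signal::butter doubles the prototype order).
.design_bandpass <- function(low_hz, high_hz, sr, order = 4) {
  nyq <- sr / 2
  if (high_hz > nyq) {
    stop("configuration error: band edge ", high_hz,
         " Hz is above the Nyquist frequency (", nyq, " Hz)")
  }
  # an edge at (or grazing) Nyquist is designed marginally below it
  high_hz <- min(high_hz, 0.99 * nyq)
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("configuration error: band edges must satisfy 0 < low < high")
  }
  if (order %% 2 != 0) stop("band-pass order must be even")
  bt <- signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
  list(b = bt$b, a = bt$a)
}

# One forward IIR pass along the columns (time) of X, zero initial state.
.iir_forward <- function(b, a, X) {
  m <- max(length(a), length(b)) - 1
  bb <- c(b, numeric(m + 1 - length(b)))
  aa <- c(a, numeric(m + 1 - length(a)))
  bb <- bb / aa[1]
  aa <- aa / aa[1]
  ns <- nrow(X)
  nt <- ncol(X)
  Y <- matrix(0, ns, nt)
  z <- matrix(0, ns, m)  # direct form II transposed state
  for (t in seq_len(nt)) {
    xt <- X[, t]
    yt <- bb[1] * xt + z[, 1]
    if (m > 1) {
      for (k in seq_len(m - 1)) {
        z[, k] <- z[, k + 1] + bb[k + 1] * xt - aa[k + 1] * yt
      }
    }
    z[, m] <- bb[m + 1] * xt - aa[m + 1] * yt
    Y[, t] <- yt
  }
  Y
}

# Zero-phase (forward-backward) filtering along time (columns) with odd
# reflection padding at both ends, as is standard for filtfilt. The
# recursion is compiled (src/filtfilt.cpp); .iir_forward above is its
# reference implementation, kept for testing.
.filtfilt_mat <- function(b, a, X) {
  single <- is.null(dim(X))
  if (single) X <- matrix(X, nrow = 1)
  Y <- .cpp_filtfilt_cols(as.numeric(b), as.numeric(a), X)
  if (single) Y <- drop(Y)
  Y
}

# FFT-based resampling along the columns (time) of X to n_new samples.
# Exact for signals band-limited below the new Nyquist rate; callers
# low-pass filter first (anti-aliasing).
.resample_fft <- function(X, n_new) {
  single <- is.null(dim(X))
  if (single) X <- matrix(X, nrow = 1)
  n_old <- ncol(X)
  if (n_new == n_old) return(if (single) drop(X) else X)
  F <- mvfft(t(X))  # n_old x signals, FFT over time
  G <- matrix(0 + 0i, n_new, ncol(F))
  n_keep <- min(n_old, n_new)
  half <- n_keep %/% 2
  pos <- seq_len(half + 1)                 # DC .. +half
  G[pos, ] <- F[pos, , drop = FALSE]
  if (half > 1) {
    neg <- seq_len(half - if (n_keep %% 2 == 0) 1 else 0)
    G[n_new - neg + 1, ] <- F[n_old - neg + 1, , drop = FALSE]
  }
  if (n_keep %% 2 == 0 && n_new > n_old) {
    # split the old Nyquist bin symmetrically when upsampling
    G[half + 1, ] <- G[half + 1, ] / 2
    G[n_new - half + 1, ] <- G[half + 1, ]
  }
  Y <- t(Re(mvfft(G, inverse = TRUE))) / n_old
  if (single) drop(Y) else Y
}
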