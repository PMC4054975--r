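# ERP branch: 0.5-16 Hz filtering, 36 Hz downsampling, first-second
# window, regularized Fisher spatial filters, 216 sample features
# (6 filters x 36 samples per trial).

#' Preprocess epochs for the ERP branch
#'
#' Band-pass filters each trial 0.5-16 Hz (zero-phase), resamples to 36 Hz
#' (FFT-based; the 16 Hz low-pass doubles as the anti-alias filter), and
#' truncates to the first second after letter onset, yielding exactly 36
#' samples per channel per trial.
#'
#' @param epochs An `epoch_set` at the acquisition sampling rate with 2-s
#'   trials.
#' @return An `epoch_set` at 36 Hz with 36 samples per trial.
#' @export
preprocess_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  sr <- epochs$sampling_rate
  if (sr < 72) {
    stop("sampling rate ", sr, " Hz is too low to honor 16 Hz content ",
         "before resampling to 36 Hz (need >= 72 Hz)")
  }
  d <- dim(epochs$data)
  dur_s <- d[3] / sr
  filt <- .design_bandpass(0.5, 16, sr)
  flat <- matrix(epochs$data, d[1] * d[2], d[3])
  # remove the per-trial channel mean first: the 0.5 Hz high-pass removes
  # DC only asymptotically, which a 2-s epoch never reaches
  flat <- flat - rowMeans(flat)
  flat <- .filtfilt_mat(filt$b, filt$a, flat)
  n_new <- round(36 * dur_s)
  # chunked FFT resampling to bound the complex working memory
  res <- matrix(0, nrow(flat), n_new)
  chunk <- max(1L, floor(2e6 / d[3]))
  starts <- seq(1L, nrow(flat), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(flat))
    res[idx, ] <- .resample_fft(flat[idx, , drop = FALSE], n_new)
  }
  keep <- seq_len(min(36L, n_new))  # first second after onset
  epochs$data <- array(res[, keep], dim = c(d[1], d[2], length(keep)))
  epochs$sampling_rate <- 36
  epochs
}

#' Fit regularized Fisher spatial filters
#'
#' Treats every time sample of every trial as a channel-space observation
#' labeled by the trial's workload class. The between-class scatter is
#' built from the per-sample class-mean differences and the within-class
#' scatter from the residuals around the per-sample class means; both are
#' pooled over the 36 samples into a single scatter pair. The within-class
#' scatter is regularized as `(1 - lambda) * Sw + lambda *
#' (trace(Sw) / channels) * I` and the top `n_filters` generalized
#' eigenvectors by Fisher criterion are returned.
#'
#' @param erp_epochs A 36-sample `epoch_set` from [preprocess_erp()].
#' @param lambda Regularization weight in `[0, 1]` (default 0.4).
#' @param n_filters Number of spatial filters (default 6).
#' @return An object of class `fsf_model`: `filters` (n_filters x
#'   channels, unit-norm sign-canonicalized rows), `fisher_values`
#'   (descending), `lambda`.
#' @export
fit_fsf <- function(erp_epochs, lambda = 0.4, n_filters = 6) {
  stopifnot(inherits(erp_epochs, "epoch_set"))
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("configuration error: lambda must lie in [0, 1]")
  }
  d <- dim(erp_epochs$data)
  cls <- erp_epochs$labels$workload
  if (sum(cls == "high") < 2 || sum(cls == "low") < 2) {
    stop("need at least 2 trials per workload class to fit FSF")
  }
  n_ch <- d[2]
  idx_hi <- which(cls == "high")
  idx_lo <- which(cls == "low")
  # scatters pooled over the time samples, computed from class-mean
  # time courses M (channels x samples) and unfolded raw sums:
  #   Sb = sum_t (mh_t - ml_t)(mh_t - ml_t)' = Dm Dm'
  #   Sw = sum_{class} [ sum_{i,t} x x' - n_class * M M' ]
  scatter_class <- function(idx) {
    n_c <- length(idx)
    m <- colMeans(erp_epochs$data[idx, , , drop = FALSE])  # ch x samples
    x <- matrix(aperm(erp_epochs$data[idx, , , drop = FALSE],
                      c(2, 1, 3)), n_ch, n_c * d[3])
    list(m = m, sw = tcrossprod(x) - n_c * tcrossprod(m))
  }
  hi <- scatter_class(idx_hi)
  lo <- scatter_class(idx_lo)
  sb <- tcrossprod(hi$m - lo$m)
  sw <- hi$sw + lo$sw
  sw_reg <- (1 - lambda) * sw + lambda * (sum(diag(sw)) / n_ch) * diag(n_ch)
  ev <- eigen(sw_reg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12) {
    stop("regularized within-class scatter is singular; use lambda > 0")
  }
  n_filters <- min(n_filters, n_ch)
  es <- eigen(solve(sw_reg, sb))
  ord <- order(Re(es$values), decreasing = TRUE)[seq_len(n_filters)]
  structure(list(
    filters = .canon_rows(t(Re(es$vectors[, ord, drop = FALSE]))),
    fisher_values = Re(es$values[ord]),
    lambda = lambda
  ), class = "fsf_model")
}

#' @export
print.fsf_model <- function(x, ...) {
  cat("<fsf_model>", nrow(x$filters), "filters x", ncol(x$filters),
      "channels (lambda =", x$lambda, ")\n")
  cat("  Fisher values:", paste(sprintf("%.3g", x$fisher_values),
                                collapse = " "), "\n")
  invisible(x)
}

#' Extract ERP sample features
#'
#' Projects each 36-sample trial through the Fisher spatial filters and
#' concatenates the filtered time courses (filter-major, sample-minor):
#' 6 filters x 36 samples = 216 features per trial.
#'
#' @param erp_epochs A 36-sample `epoch_set`.
#' @param model An `fsf_model` with matching channel count.
#' @return A `feature_matrix` with `branch = "erp"` provenance.
#' @export
extract_erp_features <- function(erp_epochs, model) {
  stopifnot(inherits(erp_epochs, "epoch_set"), inherits(model, "fsf_model"))
  d <- dim(erp_epochs$data)
  if (ncol(model$filters) != d[2]) {
    stop("channel count mismatch: model has ", ncol(model$filters),
         ", epochs have ", d[2])
  }
  n_f <- nrow(model$filters)
  # project all trials in one multiply; reorder to filter-major,
  # sample-minor per trial
  ch_by_rest <- matrix(aperm(erp_epochs$data, c(2, 3, 1)), d[2],
                       d[3] * d[1])
  proj <- array(model$filters %*% ch_by_rest, dim = c(n_f, d[3], d[1]))
  vals <- t(matrix(aperm(proj, c(2, 1, 3)), d[3] * n_f, d[1]))
  prov <- data.frame(
    branch = "erp", band = NA_character_,
    filter = rep(seq_len(n_f), each = d[3]),
    sample = rep(seq_len(d[3]), n_f),
    stringsAsFactors = FALSE
  )
  structure(list(values = vals, provenance = prov,
                 labels = erp_epochs$labels),
            class = "feature_matrix")
}
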