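# Oscillatory branch: filter bank, common spatial patterns, log-power
# features (72 = 6 bands x 12 filters per trial with the default bank).

#' Band-pass filter an epoch set through a filter bank
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per band to every trial. Filtering is per-epoch; the short edge
#' transients of 2-s epochs are accepted.
#'
#' @param epochs An `epoch_set`.
#' @param bands A band table as returned by [default_bands()].
#' @return A named list (one `epoch_set` per band), same shapes as input.
#' @export
apply_filter_bank <- function(epochs, bands = default_bands()) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, d[1] * d[2], d[3])  # (trial,channel) x time
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (k in seq_len(nrow(bands))) {
    filt <- .design_bandpass(bands$low_hz[k], bands$high_hz[k],
                             epochs$sampling_rate)
    res <- epochs
    res$data <- array(.filtfilt_mat(filt$b, filt$a, flat), dim = d)
    out[[k]] <- res
  }
  out
}

# Per-band, per-trial channel covariances computed without keeping all
# band-filtered copies alive (one band at a time); the memory-lean
# workhorse behind prepare_branches().
.band_covariances <- function(epochs, bands) {
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, d[1] * d[2], d[3])
  rows0 <- (seq_len(d[2]) - 1L) * d[1]
  denom <- d[3] - 1
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (k in seq_len(nrow(bands))) {
    filt <- .design_bandpass(bands$low_hz[k], bands$high_hz[k],
                             epochs$sampling_rate)
    fb <- .filtfilt_mat(filt$b, filt$a, flat)
    covs <- array(0, dim = c(d[2], d[2], d[1]))
    for (tr in seq_len(d[1])) {
      x <- fb[tr + rows0, , drop = FALSE]
      x <- x - rowMeans(x)
      covs[, , tr] <- tcrossprod(x) / denom
    }
    out[[k]] <- covs
  }
  out
}

# Per-trial channel covariances of an epoch set: channels x channels x
# trials array. Unnormalized (raw variance scale) -- trace normalization
# happens inside fit_csp; log-power features use the raw scale.
.trial_covariances <- function(epochs) {
  d <- dim(epochs$data)
  covs <- array(0, dim = c(d[2], d[2], d[1]))
  denom <- d[3] - 1
  for (i in seq_len(d[1])) {
    x <- matrix(epochs$data[i, , ], d[2], d[3])
    x <- x - rowMeans(x)
    covs[, , i] <- tcrossprod(x) / denom
  }
  covs
}

# Mean of (optionally trace-normalized) covariances over a trial subset.
.class_mean_cov <- function(covs, idx, trace_norm = TRUE) {
  d <- dim(covs)[1]
  m <- matrix(covs[, , idx, drop = FALSE], d * d, length(idx))
  if (trace_norm) {
    tr <- colSums(m[seq(1, d * d, by = d + 1), , drop = FALSE])
    m <- m * rep(1 / tr, each = d * d)
  }
  matrix(rowMeans(m), d, d)
}

# Canonicalize spatial filter rows: unit norm, largest-|coefficient|
# entry positive.
.canon_rows <- function(W) {
  for (r in seq_len(nrow(W))) {
    w <- W[r, ]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    W[r, ] <- w
  }
  W
}

# CSP core on two class-mean covariances: generalized symmetric
# eigenproblem C_high w = lambda (C_high + C_low) w via whitening.
.csp_eig <- function(c_high, c_low) {
  cc <- c_high + c_low
  ec <- eigen(cc, symmetric = TRUE)
  if (min(ec$values) < max(ec$values) * 1e-10) {
    stop("singular pooled covariance; consider regularizing the ",
         "covariance estimates or reducing the channel count")
  }
  whit <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  es <- eigen(whit %*% c_high %*% whit, symmetric = TRUE)
  list(eigenvalues = es$values,               # descending, in [0, 1]
       filters = t(whit %*% es$vectors))      # rows: filters, same order
}

#' Fit common spatial patterns for one frequency band
#'
#' Solves the generalized symmetric eigenproblem of the two class-average
#' trial covariances (each trial covariance trace-normalized before
#' averaging, so high-variance trials cannot dominate). The eigenvalue of
#' a filter is the fraction of (normalized) variance attributable to the
#' high-workload class, in `[0, 1]`; the returned model keeps the
#' `n_pairs` largest-eigenvalue filters followed by the `n_pairs`
#' smallest.
#'
#' @param band_epochs A band-filtered `epoch_set` with two workload
#'   classes.
#' @param n_pairs Number of filter pairs to keep (default 6, i.e. 12
#'   filters).
#' @param band Optional band descriptor (single row of a band table)
#'   stored in the model.
#' @param trace_norm Trace-normalize each trial covariance before class
#'   averaging (default TRUE). Normalization keeps high-variance trials
#'   from dominating but gives up exact invariance of the eigenvalues
#'   under channel mixing; set FALSE for the textbook unnormalized CSP.
#' @return An object of class `csp_model`: `filters` (2*n_pairs x
#'   channels, unit-norm sign-canonicalized rows), `eigenvalues`,
#'   `n_pairs`, `band`.
#' @export
fit_csp <- function(band_epochs, n_pairs = 6, band = NULL,
                    trace_norm = TRUE) {
  stopifnot(inherits(band_epochs, "epoch_set"))
  covs <- .trial_covariances(band_epochs)
  .fit_csp_cov(covs, band_epochs$labels$workload, n_pairs, band,
               trace_norm)
}

.fit_csp_cov <- function(covs, workload, n_pairs = 6, band = NULL,
                         trace_norm = TRUE) {
  idx_hi <- which(workload == "high")
  idx_lo <- which(workload == "low")
  if (length(idx_hi) < 2 || length(idx_lo) < 2) {
    stop("need at least 2 trials per workload class to fit CSP")
  }
  n_ch <- dim(covs)[1]
  if (n_ch < 2 * n_pairs) {
    stop("need at least ", 2 * n_pairs, " channels for ", n_pairs,
         " CSP filter pairs")
  }
  sol <- .csp_eig(.class_mean_cov(covs, idx_hi, trace_norm),
                  .class_mean_cov(covs, idx_lo, trace_norm))
  keep <- c(seq_len(n_pairs), n_ch - n_pairs + seq_len(n_pairs))
  structure(list(
    filters = .canon_rows(sol$filters[keep, , drop = FALSE]),
    eigenvalues = sol$eigenvalues[keep],
    n_pairs = n_pairs,
    band = band
  ), class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model>", nrow(x$filters), "filters x", ncol(x$filters),
      "channels")
  if (!is.null(x$band)) cat(" [", x$band$name, "]")
  cat("\n  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                                collapse = " "), "\n")
  invisible(x)
}

#' Extract filter-bank CSP log-power features
#'
#' For every trial, band and spatial filter: the log of the variance of
#' the spatially filtered band-passed signal. With the default six-band
#' bank and six filter pairs this yields 72 features per trial, ordered
#' band-major then filter-minor, with per-feature provenance.
#'
#' @param band_epochs Named list of band-filtered `epoch_set`s (as from
#'   [apply_filter_bank()]).
#' @param models Named list of `csp_model`s fitted on the same bands.
#' @param log Take the log of the projected variance (default TRUE, the
#'   standard CSP feature; set FALSE for raw band power).
#' @return A `feature_matrix`: list with `values` (trials x features),
#'   `provenance` (data.frame `branch`, `band`, `filter`, `sample`), and
#'   the trial `labels`.
#' @export
extract_fbcsp_features <- function(band_epochs, models, log = TRUE) {
  if (!identical(names(band_epochs), names(models))) {
    stop("band/model mismatch: bands ",
         paste(names(band_epochs), collapse = ","), " vs models ",
         paste(names(models), collapse = ","))
  }
  covs <- lapply(band_epochs, .trial_covariances)
  .extract_fbcsp_cov(covs, models, band_epochs[[1]]$labels, log = log)
}

.extract_fbcsp_cov <- function(cov_list, models, labels, log = TRUE) {
  blocks <- vector("list", length(models))
  prov <- vector("list", length(models))
  for (k in seq_along(models)) {
    W <- models[[k]]$filters
    covs <- cov_list[[k]]
    d <- dim(covs)[1]
    # diag(W C W') for all trials at once: row f of WW is vec(w_f w_f'),
    # so WW %*% vec(C) stacks the projected variances
    WW <- t(apply(W, 1, function(w) as.vector(tcrossprod(w))))
    v <- t(WW %*% matrix(covs, d * d, dim(covs)[3]))
    blocks[[k]] <- if (log) base::log(pmax(v, .Machine$double.xmin)) else v
    prov[[k]] <- data.frame(branch = "fb", band = names(models)[k],
                            filter = seq_len(nrow(W)), sample = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  structure(list(
    values = do.call(cbind, blocks),
    provenance = do.call(rbind, prov),
    labels = labels
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "trials x", ncol(x$values),
      "features (", paste(unique(x$provenance$branch), collapse = "+"),
      ")\n")
  invisible(x)
}
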