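# EOG cleaning, epoch segmentation and target-trial exclusion.

#' Remove ocular (EOG) contamination by linear regression
#'
#' Replaces every EEG channel by itself minus the least-squares linear
#' combination of all EOG channels, with regression coefficients estimated
#' from the channel cross-covariances over the full recording. EOG channels
#' are retained unmodified. Cleaning is applied once to the continuous
#' recording, before any training/testing split (only artifact statistics
#' cross that boundary).
#'
#' @param recording An `eeg_recording` with at least one EEG and one EOG
#'   channel.
#' @return The recording with cleaned EEG channels; shape unchanged. The
#'   fitted coefficients (EOG x EEG) are attached as attribute
#'   `"eog_coefficients"`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_blocks_per_context_per_level = 1,
#'                     letters_per_block = 6)
#' rec <- remove_eog(generate_session(cfg))
remove_eog <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  is_eog <- recording$channel_roles == "EOG"
  is_eeg <- recording$channel_roles == "EEG"
  if (!any(is_eog)) stop("recording has no EOG channels to regress out")
  if (!any(is_eeg)) stop("recording has no EEG channels")
  eog <- recording$signal[is_eog, , drop = FALSE]
  eeg <- recording$signal[is_eeg, , drop = FALSE]
  eog_c <- eog - rowMeans(eog)
  eeg_c <- eeg - rowMeans(eeg)
  cov_oo <- tcrossprod(eog_c) / (ncol(eog_c) - 1)
  if (all(cov_oo == 0)) {
    coef <- matrix(0, nrow(eog), nrow(eeg))
  } else {
    ev <- eigen(cov_oo, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < max(ev) * 1e-12) {
      qrd <- qr(t(eog_c))
      bad <- recording$channel_labels[is_eog][qrd$pivot[-seq_len(qrd$rank)]]
      stop("EOG covariance is rank deficient; degenerate channel(s): ",
           paste(bad, collapse = ", "))
    }
    cov_oe <- tcrossprod(eog_c, eeg_c) / (ncol(eog_c) - 1)
    coef <- solve(cov_oo, cov_oe)  # (EOG x EEG)
    eeg <- eeg - t(coef) %*% eog
  }
  recording$signal[is_eeg, ] <- eeg
  attr(recording, "eog_coefficients") <- coef
  recording
}

#' Segment a recording into letter-locked trials
#'
#' Cuts one fixed-duration trial per scheduled letter, starting at the
#' letter onset (0-based, half-open sample window `[onset, onset + n)`, so
#' consecutive trials at the 2-s event pitch do not overlap). Only EEG
#' channels are kept. Each trial carries the workload level, affective
#' context, block index, target flag, and a `half` label marking whether
#' its block falls in the first or second six-block half of its context.
#'
#' @param recording An `eeg_recording` with an event table.
#' @param duration_s Trial duration in seconds (default 2).
#' @return An object of class `epoch_set`: list with `data` (trials x
#'   channels x samples array), `sampling_rate`, `channel_labels` (EEG
#'   only), and `labels` (data.frame with `workload`, `context`, `block`,
#'   `half`, `is_target`).
#' @export
segment_epochs <- function(recording, duration_s = 2.0) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_samp <- round(duration_s * recording$sampling_rate)
  events <- recording$events
  n_total <- ncol(recording$signal)
  over <- events$onset_sample + n_samp > n_total
  if (any(over)) {
    stop("event(s) truncated by the end of the recording: onset sample(s) ",
         paste(head(events$onset_sample[over], 3), collapse = ", "))
  }
  is_eeg <- recording$channel_roles == "EEG"
  eeg <- recording$signal[is_eeg, , drop = FALSE]
  n_trials <- nrow(events)
  n_ch <- nrow(eeg)
  data <- array(0, dim = c(n_trials, n_ch, n_samp))
  for (i in seq_len(n_trials)) {
    idx <- events$onset_sample[i] + seq_len(n_samp)  # 0-based onset
    data[i, , ] <- eeg[, idx]
  }
  labels <- data.frame(
    workload = events$workload,
    context = events$context,
    block = events$block,
    half = NA_integer_,
    is_target = events$is_target,
    stringsAsFactors = FALSE
  )
  # half = 1 for a context's first half of blocks (first six in the full
  # protocol), 2 for the rest
  for (ctx in unique(labels$context)) {
    blocks <- sort(unique(labels$block[labels$context == ctx]))
    first <- blocks[seq_len(ceiling(length(blocks) / 2))]
    labels$half[labels$context == ctx] <-
      ifelse(labels$block[labels$context == ctx] %in% first, 1L, 2L)
  }
  structure(list(
    data = data,
    sampling_rate = recording$sampling_rate,
    channel_labels = recording$channel_labels[is_eeg],
    labels = labels
  ), class = "epoch_set")
}

#' Discard target-letter trials
#'
#' Target letters evoke identification-related potentials (notably a P300)
#' that would confound workload decoding, so their trials are excluded
#' before feature extraction. Ordering of the remaining trials is
#' preserved.
#'
#' @param epochs An `epoch_set` whose labels carry `is_target` flags.
#' @return The `epoch_set` restricted to non-target trials.
#' @export
discard_targets <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$labels$is_target)) {
    stop("epochs carry no is_target flags")
  }
  keep <- !epochs$labels$is_target
  subset_epochs(epochs, keep)
}

#' Subset an epoch set by trial index
#'
#' @param epochs An `epoch_set`.
#' @param idx Logical or integer trial index.
#' @return The subsetted `epoch_set` (trial order as indexed).
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx, , drop = FALSE]
  rownames(epochs$labels) <- NULL
  epochs
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", x$sampling_rate, "Hz\n")
  if (nrow(x$labels)) {
    cat("  workload:", paste(names(table(x$labels$workload)),
                             table(x$labels$workload), collapse = ", "), "\n")
    cat("  contexts:", paste(unique(x$labels$context), collapse = ", "),
        "; blocks:", length(unique(x$labels$block)), "\n")
  }
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]
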