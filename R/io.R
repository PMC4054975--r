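# File interchange: 16-bit EDF signal container with a TSV event sidecar,
# a binary-plus-JSON epoch container, JSON model bundles, and feature CSV.
#
# No EDF package ships with R, so a minimal reader/writer for the
# continuous 16-bit EDF layout is implemented here (ASCII header, one
# second per data record, per-channel physical scaling). Events live in
# the TSV sidecar rather than an annotations channel.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file plus TSV event sidecar
#'
#' Signals are stored as 16-bit integers with per-channel physical
#' scaling (uV); channel roles are encoded in the EDF labels
#' (`"EEG Fz"`, `"EOG VEOGu"`). Events go to a tab-separated sidecar with
#' columns `onset_s`, `letter`, `is_target`, `block`, `workload`,
#' `context` (onset in seconds, 0-based sample-aligned). The trailing
#' partial second, if any, is zero-padded in the EDF and trimmed on read
#' using the sample count stored in the header reserved field.
#'
#' @param recording An `eeg_recording`.
#' @param edf_path Output EDF file path.
#' @param events_path Output TSV path (default: `edf_path` with
#'   `.events.tsv`).
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(recording, edf_path,
                            events_path = sub("\\.edf$", ".events.tsv",
                                              edf_path)) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig <- recording$signal
  ns <- nrow(sig)
  sr <- recording$sampling_rate
  if (sr != round(sr)) stop("EDF writer needs an integer sampling rate")
  n_rec <- ceiling(ncol(sig) / sr)
  phys_min <- apply(sig, 1, min)
  phys_max <- apply(sig, 1, max)
  flat <- phys_min == phys_max
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(edf_path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("synthetic subject", 80),
    .edf_pad("workloadbci synthetic n-back session", 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8),
    .edf_pad(paste0("nsamples=", ncol(sig)), 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4)
  )
  labels <- paste(recording$channel_roles, recording$channel_labels)
  hdr <- paste0(
    hdr,
    paste(vapply(labels, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("synthetic", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_min), .edf_pad, "", width = 8),
          collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), .edf_pad, "", width = 8),
          collapse = ""),
    paste(rep(.edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_pad(32767, 8), ns), collapse = ""),
    paste(rep(.edf_pad("none", 80), ns), collapse = ""),
    paste(rep(.edf_pad(sr, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeBin(charToRaw(hdr), con)
  gain <- (32767 - (-32768)) / (phys_max - phys_min)
  padded <- matrix(0, ns, n_rec * sr)
  padded[, seq_len(ncol(sig))] <- sig
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * sr + seq_len(sr)
    dig <- round((padded[, cols] - phys_min) * gain - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  ev <- recording$events
  out <- data.frame(
    onset_s = ev$onset_sample / sr,
    letter = ev$letter,
    is_target = as.integer(ev$is_target),
    block = ev$block,
    workload = ev$workload,
    context = ev$context
  )
  write.table(out, events_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(edf = edf_path, events = events_path))
}

#' Read a recording from an EDF file plus TSV event sidecar
#'
#' Counterpart of [write_recording()]. Channel roles are recovered from
#' the EDF label prefixes; event onsets are converted back to 0-based
#' samples.
#'
#' @param edf_path EDF file path.
#' @param events_path TSV sidecar path (default as written).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(edf_path,
                           events_path = sub("\\.edf$", ".events.tsv",
                                             edf_path)) {
  con <- file(edf_path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)        # transducer
  for (i in seq_len(ns)) rd(8)         # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)        # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("mixed per-channel sampling rates are not supported")
  }
  sr <- spr[1] / dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    sig[, (r - 1) * spr[1] + seq_len(spr[1])] <-
      matrix(raw, spr[1], ns)[, seq_len(ns)] |> t()
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sig * gain + (phys_min - dig_min * gain)
  n_samp <- if (grepl("^nsamples=", reserved)) {
    as.integer(sub("^nsamples=", "", reserved))
  } else {
    ncol(sig)
  }
  sig <- sig[, seq_len(n_samp), drop = FALSE]
  roles <- sub(" .*$", "", labels)
  chan <- sub("^[A-Z]+ ", "", labels)
  rownames(sig) <- chan
  ev <- read.table(events_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("numeric", "character", "integer",
                                  "integer", "character", "character"))
  events <- data.frame(
    onset_sample = as.integer(round(ev$onset_s * sr)),
    letter = as.character(ev$letter),
    is_target = as.logical(ev$is_target),
    block = ev$block,
    workload = ev$workload,
    context = ev$context,
    stringsAsFactors = FALSE
  )
  structure(list(signal = sig, channel_labels = chan,
                 channel_roles = roles, sampling_rate = sr,
                 events = events),
            class = "eeg_recording")
}

#' Write an epoch set to a binary container with a JSON header
#'
#' Stores the trial tensor as little-endian doubles in `<path>.bin` and
#' everything else (dimensions, sampling rate, channel labels, trial
#' labels) in `<path>.json`.
#'
#' @param epochs An `epoch_set`.
#' @param path Path prefix (without extension).
#' @return Invisibly, the two paths.
#' @export
write_epoch_set <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  hdr <- list(dim = dim(epochs$data),
              sampling_rate = epochs$sampling_rate,
              channel_labels = epochs$channel_labels,
              labels = epochs$labels)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(paste0(path, c(".json", ".bin")))
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path Path prefix (without extension).
#' @return An `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- prod(hdr$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  data <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  structure(list(data = array(data, dim = hdr$dim),
                 sampling_rate = hdr$sampling_rate,
                 channel_labels = hdr$channel_labels,
                 labels = as.data.frame(hdr$labels)),
            class = "epoch_set")
}

#' Save a fitted model bundle to JSON
#'
#' Serializes any combination of `csp_model`s, an `fsf_model`, per-branch
#' `selection_model`s and an `lda_model` (matrices as nested numeric
#' arrays).
#'
#' @param bundle A named list of fitted model objects.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
save_model_bundle <- function(bundle, path) {
  strip <- function(x) {
    if (is.object(x)) {
      out <- lapply(unclass(x), strip)
      out[[".class"]] <- class(x)[1]
      out
    } else if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  jsonlite::write_json(strip(bundle), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model bundle written by [save_model_bundle()]
#'
#' @param path JSON path.
#' @return The named list of model objects with their classes restored.
#' @export
load_model_bundle <- function(path) {
  restore <- function(x) {
    if (is.list(x)) {
      cls <- x[[".class"]]
      x[[".class"]] <- NULL
      x <- lapply(x, restore)
      if (!is.null(cls)) class(x) <- cls
    }
    x
  }
  restore(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Write a feature matrix to CSV with provenance columns
#'
#' One row per trial: the trial labels, then one column per feature named
#' from its provenance (`branch_band_filter` or `branch_filter_sample`).
#'
#' @param features A `feature_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  p <- features$provenance
  nm <- ifelse(p$branch == "fb",
               paste(p$branch, p$band, p$filter, sep = "_"),
               paste(p$branch, p$filter, p$sample, sep = "_"))
  vals <- as.data.frame(features$values)
  names(vals) <- make.unique(nm)
  out <- cbind(features$labels, vals)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
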