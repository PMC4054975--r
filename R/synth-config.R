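#' Classical EEG frequency bands used by the filter bank
#'
#' The six-band bank covering the classical EEG rhythms: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-12 Hz), beta (12-30 Hz), gamma (30-47 Hz) and
#' high-gamma (53-90 Hz). The 47-53 Hz gap excludes power-line noise.
#'
#' @param names Optional character vector restricting the bank to a subset
#'   (e.g. `c("delta", "theta", "alpha")` for a low-band-only analysis).
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
#' @examples
#' default_bands()
#' default_bands(c("delta", "theta", "alpha"))
default_bands <- function(names = NULL) {
  bands <- data.frame(
    name    = c("delta", "theta", "alpha", "beta", "gamma", "gamma2"),
    low_hz  = c(1, 4, 8, 12, 30, 53),
    high_hz = c(4, 8, 12, 30, 47, 90),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    missing <- setdiff(names, bands$name)
    if (length(missing)) {
      stop("unknown band name(s): ", paste(missing, collapse = ", "))
    }
    bands <- bands[match(names, bands$name), , drop = FALSE]
    rownames(bands) <- NULL
  }
  bands
}

.band_names <- c("delta", "theta", "alpha", "beta", "gamma", "gamma2")

# Baseline source amplitudes (standard deviation, uV) per rhythm in the
# synthetic generator. Roughly follows the amplitude ordering of resting
# scalp EEG: strong slow rhythms, weak gamma.
.base_source_sd <- c(
  delta = 10, theta = 8, alpha = 12, beta = 5, gamma = 2.5, gamma2 = 1.5
)

.named_ratio <- function(x, what) {
  if (is.null(names(x)) || !all(names(x) %in% .band_names)) {
    stop(what, " must be a named vector with names among: ",
         paste(.band_names, collapse = ", "))
  }
  out <- setNames(rep(1, length(.band_names)), .band_names)
  out[names(x)] <- x
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("all ", what, " power ratios must be finite and > 0")
  }
  out
}

#' Configuration for the synthetic n-back EEG study generator
#'
#' Defines one simulated subject's recording: montage size, sampling rate,
#' the n-back block schedule (two affective contexts, alternating 0-back /
#' 2-back blocks, letters at a 2-s pitch of 500 ms presentation + 1500 ms
#' ISI, 25% targets), and the planted effects that carry class and context
#' information:
#'
#' * `band_power_effects` — multiplicative power ratio (high/low workload)
#'   applied to each rhythm's source variance. The defaults plant the
#'   canonical workload signature: more frontal slow-wave power (delta,
#'   theta up), alpha suppression under load, and mild beta involvement,
#'   so most of the discriminative signal lives in the low bands.
#' * `erp_amplitude_effect` — additive difference (uV) of the event-locked
#'   response peak between high and low workload.
#' * `context_shift` — stress/relax power ratio of a dedicated stationary
#'   "arousal" source per named band, independent of workload; the
#'   source of cross-context nonstationarity. In the relaxed context
#'   these sources sit at the noise floor, so the large default ratios
#'   describe slow-wave arousal activity that is effectively absent in
#'   relaxation and prominent under stress — which is exactly why a
#'   relax-calibrated classifier never learns to cancel it.
#'
#' @param seed Integer; fully determines the generated recording.
#' @param n_eeg_channels,n_eog_channels Montage sizes (28 EEG + 4 EOG).
#' @param sampling_rate Sampling rate in Hz; must be at least 180 so the
#'   53-90 Hz band is representable.
#' @param n_blocks_per_context_per_level Number of blocks of each workload
#'   level in each affective context (6 gives the full 24-block session).
#' @param letters_per_block Letters shown per 2-min block.
#' @param letter_duration,isi Letter presentation time and inter-stimulus
#'   interval, in ms (together the 2-s trial pitch).
#' @param target_fraction Fraction of letters that are targets, in (0, 1).
#' @param band_power_effects Named vector of high/low workload power ratios.
#' @param erp_amplitude_effect ERP peak difference high - low workload (uV).
#' @param context_shift Named vector of stress/relax power ratios,
#'   carried by a dedicated stationary arousal source per shifted band.
#' @param context_source_overlap Spatial correlation in `[0, 1]` between
#'   each band's arousal source pattern and its workload source pattern
#'   (default 0.6): load and arousal arise from distinct but
#'   neighbouring generators, so context power leaks into
#'   workload-tuned spatial filters without destroying the load signal
#'   itself.
#' @param eog_artifact_rate Ocular artifact (blink/saccade) rate, events/min.
#' @param noise_sd White sensor-noise standard deviation (uV).
#' @param context_order `"relax-first"` or `"stress-first"`.
#' @param workload_order `"low-first"` or `"high-first"`: the workload level
#'   of each context's first block (levels alternate within a context).
#' @return An object of class `synth_config`.
#' @seealso [generate_session()], [generate_study()]
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_blocks_per_context_per_level = 1,
#'                     letters_per_block = 10)
#' cfg$sampling_rate
synth_config <- function(seed,
                         n_eeg_channels = 28,
                         n_eog_channels = 4,
                         sampling_rate = 256,
                         n_blocks_per_context_per_level = 6,
                         letters_per_block = 60,
                         letter_duration = 500,
                         isi = 1500,
                         target_fraction = 0.25,
                         band_power_effects = c(delta = 1.3, theta = 1.45,
                                                alpha = 0.65, beta = 1.1),
                         erp_amplitude_effect = 0.8,
                         context_shift = c(delta = 25, theta = 25),
                         eog_artifact_rate = 15,
                         noise_sd = 4,
                         context_source_overlap = 0.35,
                         context_order = c("relax-first", "stress-first"),
                         workload_order = c("low-first", "high-first")) {
  context_order <- match.arg(context_order)
  workload_order <- match.arg(workload_order)
  if (!is.finite(context_source_overlap) || context_source_overlap < 0 ||
      context_source_overlap > 1) {
    stop("configuration error: context_source_overlap must lie in [0, 1]")
  }
  counts <- c(n_eeg_channels = n_eeg_channels,
              n_eog_channels = n_eog_channels,
              n_blocks_per_context_per_level = n_blocks_per_context_per_level,
              letters_per_block = letters_per_block)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("configuration error: counts must be positive integers (",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "), ")")
  }
  if (sampling_rate < 2 * 90) {
    stop("configuration error: sampling_rate must be at least 180 Hz ",
         "so the 53-90 Hz band is representable")
  }
  if (!is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1) {
    stop("configuration error: target_fraction must lie in (0, 1)")
  }
  if (letter_duration <= 0 || isi <= 0) {
    stop("configuration error: letter_duration and isi must be positive")
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_eeg_channels = as.integer(n_eeg_channels),
    n_eog_channels = as.integer(n_eog_channels),
    sampling_rate = sampling_rate,
    n_blocks_per_context_per_level = as.integer(n_blocks_per_context_per_level),
    letters_per_block = as.integer(letters_per_block),
    letter_duration = letter_duration,
    isi = isi,
    target_fraction = target_fraction,
    band_power_effects = .named_ratio(band_power_effects, "band_power_effects"),
    erp_amplitude_effect = erp_amplitude_effect,
    context_shift = .named_ratio(context_shift, "context_shift"),
    eog_artifact_rate = eog_artifact_rate,
    noise_sd = noise_sd,
    context_source_overlap = context_source_overlap,
    context_order = context_order,
    workload_order = workload_order
  ), class = "synth_config")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "\n")
  cat(" ", x$n_eeg_channels, "EEG +", x$n_eog_channels, "EOG channels @",
      x$sampling_rate, "Hz\n")
  cat("  blocks:", 2 * x$n_blocks_per_context_per_level,
      "per context x 2 contexts (", x$context_order, ",",
      x$workload_order, ")\n")
  cat("  letters/block:", x$letters_per_block,
      sprintf("(%.0f%% targets)", 100 * x$target_fraction), "\n")
  eff <- x$band_power_effects[x$band_power_effects != 1]
  if (length(eff)) {
    cat("  workload power ratios:",
        paste(sprintf("%s=%.2f", names(eff), eff), collapse = " "), "\n")
  }
  shift <- x$context_shift[x$context_shift != 1]
  if (length(shift)) {
    cat("  context shift ratios:",
        paste(sprintf("%s=%.2f", names(shift), shift), collapse = " "), "\n")
  }
  cat("  ERP effect:", x$erp_amplitude_effect, "uV; noise sd:",
      x$noise_sd, "uV\n")
  invisible(x)
}
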