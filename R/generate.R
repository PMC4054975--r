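# Synthetic n-back EEG session generator.
#
# Signal model: one stationary band-limited Gaussian source per classical
# rhythm (brick-wall band-limited white noise, standardized), scaled per
# block by workload/context power ratios, spatially mixed through a seeded
# random orthonormal forward matrix; plus an event-locked biphasic ERP on a
# fixed centro-parietal channel subset, ocular artifacts on the EOG
# channels leaking into frontal EEG with fixed known coefficients, and
# white sensor noise.

.eeg_labels_28 <- c(
  "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FCz", "FC2", "FC6",
  "C3", "Cz", "C4",
  "CP5", "CP1", "CPz", "CP2", "CP6",
  "P7", "P3", "Pz", "P4", "P8",
  "O1", "Oz", "O2"
)
.eog_labels_4 <- c("VEOGu", "VEOGd", "HEOGl", "HEOGr")

# ERP topography: centro-parietal positive deflection (relative weights on
# the labelled channels when present in the montage).
.erp_topography <- c(
  FC1 = 0.4, FCz = 0.5, FC2 = 0.4, Cz = 0.8, C3 = 0.4, C4 = 0.4,
  CP1 = 0.7, CPz = 0.9, CP2 = 0.7, Pz = 1.0, P3 = 0.5, P4 = 0.5
)
.erp_base_amplitude <- 4  # uV peak at low workload

# Arousal sources sit at the noise floor in the relaxed context
# (amplitude = this fraction of the band's base source SD); the
# stress/relax power ratio in context_shift is applied on top. A
# classifier calibrated in relaxation therefore never learns to cancel
# them, while stress- or combined-calibrated ones do.
.arousal_relax_frac <- 0.15

# Fixed EOG -> frontal EEG leakage coefficients (rows: frontal labels;
# cols: VEOGu, VEOGd, HEOGl, HEOGr). Known exactly so that regression-based
# cleaning can be verified against ground truth.
.eog_leak <- rbind(
  AF3 = c(0.20, 0.10, 0.06, -0.06),
  AF4 = c(0.20, 0.10, -0.06, 0.06),
  F7  = c(0.08, 0.04, 0.12, -0.04),
  F3  = c(0.12, 0.06, 0.05, -0.03),
  Fz  = c(0.15, 0.08, 0.00, 0.00),
  F4  = c(0.12, 0.06, -0.03, 0.05),
  F8  = c(0.08, 0.04, -0.04, 0.12)
)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Band-limited unit-variance Gaussian noise via spectral masking.
.band_noise <- function(n, sr, lo, hi) {
  w <- rnorm(n)
  f <- fft(w)
  freq <- (seq_len(n) - 1) * sr / n
  fold <- pmin(freq, sr - freq)  # two-sided spectrum folded to [0, sr/2]
  mask <- fold >= lo & fold <= hi
  s <- Re(fft(f * mask, inverse = TRUE)) / n
  s / sd(s)
}

# Biphasic event-locked template on a 1-s grid: small early negativity
# (~150 ms), dominant positive deflection centred ~300 ms, ~400 ms wide,
# unit peak amplitude, confined to the first second after onset.
.erp_template <- function(sr) {
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  shape <- exp(-(t - 0.3)^2 / (2 * 0.085^2)) -
    0.4 * exp(-(t - 0.15)^2 / (2 * 0.05^2))
  shape / max(shape)
}

.block_schedule <- function(config) {
  nb <- config$n_blocks_per_context_per_level
  contexts <- if (config$context_order == "relax-first") {
    c("relax", "stress")
  } else {
    c("stress", "relax")
  }
  levels0 <- if (config$workload_order == "low-first") {
    c("low", "high")
  } else {
    c("high", "low")
  }
  data.frame(
    block = seq_len(4 * nb),
    context = rep(contexts, each = 2 * nb),
    workload = rep(rep(levels0, nb), 2),
    stringsAsFactors = FALSE
  )
}

#' Generate one subject's synthetic n-back EEG session
#'
#' Produces a continuous multichannel recording covering two affective
#' contexts of `2 * n_blocks_per_context_per_level` two-minute n-back
#' blocks each (0-back/2-back alternating), with letters scheduled at the
#' trial pitch `letter_duration + isi` (2 s by default) and the configured
#' fraction of targets. The planted effects (band-power ratios, ERP
#' amplitude difference, context shift) are described in [synth_config()].
#' The output is bitwise reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return An object of class `eeg_recording`: a list with `signal`
#'   (channels x samples matrix, uV), `channel_labels`, `channel_roles`
#'   (`"EEG"`/`"EOG"`), `sampling_rate`, and `events` (data.frame with
#'   `onset_sample` (0-based), `letter`, `is_target`, `block`, `workload`,
#'   `context`).
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_blocks_per_context_per_level = 1,
#'                     letters_per_block = 6)
#' rec <- generate_session(cfg)
#' dim(rec$signal)
#' table(rec$events$workload)
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    sr <- config$sampling_rate
    pitch_s <- (config$letter_duration + config$isi) / 1000
    pitch <- round(pitch_s * sr)
    spb <- config$letters_per_block * pitch
    sched <- .block_schedule(config)
    n_blocks <- nrow(sched)
    n <- n_blocks * spb
    n_eeg <- config$n_eeg_channels
    n_eog <- config$n_eog_channels

    eeg_labels <- if (n_eeg <= length(.eeg_labels_28)) {
      .eeg_labels_28[seq_len(n_eeg)]
    } else {
      c(.eeg_labels_28, paste0("EEG", seq_len(n_eeg - length(.eeg_labels_28))))
    }
    eog_labels <- if (n_eog <= length(.eog_labels_4)) {
      .eog_labels_4[seq_len(n_eog)]
    } else {
      c(.eog_labels_4, paste0("EOG", seq_len(n_eog - length(.eog_labels_4))))
    }

    # --- event schedule -----------------------------------------------
    n_tgt <- round(config$target_fraction * config$letters_per_block)
    ev <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      letters_b <- sample(LETTERS, config$letters_per_block, replace = TRUE)
      tgt <- rep(FALSE, config$letters_per_block)
      tgt[sample.int(config$letters_per_block, n_tgt)] <- TRUE
      if (sched$workload[b] == "low") {
        # 0-back: the target letter is "X"
        letters_b[tgt] <- "X"
        clash <- !tgt & letters_b == "X"
        if (any(clash)) {
          letters_b[clash] <- sample(setdiff(LETTERS, "X"), sum(clash),
                                     replace = TRUE)
        }
      }
      ev[[b]] <- data.frame(
        onset_sample = as.integer((b - 1L) * spb +
          (seq_len(config$letters_per_block) - 1L) * pitch),
        letter = letters_b,
        is_target = tgt,
        block = sched$block[b],
        workload = sched$workload[b],
        context = sched$context[b],
        stringsAsFactors = FALSE
      )
    }
    events <- do.call(rbind, ev)
    rownames(events) <- NULL

    # --- oscillatory sources ------------------------------------------
    bands <- default_bands()
    n_src <- nrow(bands)
    forward <- matrix(rnorm(n_eeg * n_src), n_eeg, n_src)
    forward <- if (n_eeg >= n_src) {
      qr.Q(qr(forward))  # orthonormal spatial patterns
    } else {
      sweep(forward, 2, sqrt(colSums(forward^2)), "/")
    }
    sources <- matrix(0, n_src, n)
    for (k in seq_len(n_src)) {
      sources[k, ] <- .band_noise(n, sr, bands$low_hz[k], bands$high_hz[k])
    }
    # workload sources: per-block amplitude gain from the power ratios
    gain_block <- matrix(0, n_src, n_blocks)
    for (k in seq_len(n_src)) {
      bn <- bands$name[k]
      gain_block[k, ] <- .base_source_sd[bn] *
        sqrt(config$band_power_effects[bn])^(sched$workload == "high")
    }
    gains <- gain_block[, rep(seq_len(n_blocks), each = spb), drop = FALSE]
    eeg <- forward %*% (sources * gains)
    rm(sources, gains)

    # arousal sources: one extra stationary source per context-shifted
    # band, carrying the stress/relax power ratio, with a spatial
    # pattern partially overlapping that band's workload source (load
    # and arousal arise from distinct but neighbouring generators)
    shifted <- which(config$context_shift != 1)
    rho <- config$context_source_overlap
    for (k in shifted) {
      bn <- .band_names[k]
      kb <- match(bn, bands$name)
      src <- .band_noise(n, sr, bands$low_hz[kb], bands$high_hz[kb])
      fresh <- rnorm(n_eeg)
      fresh <- fresh / sqrt(sum(fresh^2))
      pat <- rho * forward[, kb] + sqrt(1 - rho^2) * fresh
      pat <- pat / sqrt(sum(pat^2))
      g <- .base_source_sd[bn] * .arousal_relax_frac *
        sqrt(config$context_shift[bn])^(sched$context == "stress")
      eeg <- eeg + pat %*% t(src * g[rep(seq_len(n_blocks), each = spb)])
    }

    # --- event-locked ERP ---------------------------------------------
    tpl <- .erp_template(sr)
    topo <- rep(0, n_eeg)
    hit <- match(names(.erp_topography), eeg_labels)
    topo[hit[!is.na(hit)]] <- .erp_topography[!is.na(hit)]
    if (all(topo == 0)) topo[seq_len(min(3, n_eeg))] <- c(1, 0.8, 0.8)[
      seq_len(min(3, n_eeg))]
    erp_series <- numeric(n)
    amp <- .erp_base_amplitude +
      config$erp_amplitude_effect * (events$workload == "high")
    for (i in seq_len(nrow(events))) {
      idx <- events$onset_sample[i] + seq_along(tpl)  # 1-based slice
      erp_series[idx] <- erp_series[idx] + amp[i] * tpl
    }
    eeg <- eeg + topo %*% t(erp_series)
    rm(erp_series)

    # --- ocular artifacts ---------------------------------------------
    blink <- .artifact_series(n, sr, rate_per_min = config$eog_artifact_rate,
                              width_s = 0.30, amp_mean = 120, amp_sd = 20)
    sacc <- .artifact_series(n, sr, rate_per_min = config$eog_artifact_rate / 2,
                             width_s = 0.20, amp_mean = 50, amp_sd = 10)
    eog_mix <- rbind(
      VEOGu = c(1.00, 0.10),
      VEOGd = c(-0.70, 0.05),
      HEOGl = c(0.10, 1.00),
      HEOGr = c(0.08, -0.85)
    )
    eog <- matrix(0, n_eog, n)
    take <- min(n_eog, nrow(eog_mix))
    eog[seq_len(take), ] <- eog_mix[seq_len(take), , drop = FALSE] %*%
      rbind(blink, sacc)
    eog <- eog + matrix(rnorm(n_eog * n, sd = 1), n_eog, n)

    leak <- matrix(0, n_eeg, n_eog)
    lhit <- match(rownames(.eog_leak), eeg_labels)
    keep <- !is.na(lhit)
    leak[lhit[keep], seq_len(min(n_eog, ncol(.eog_leak)))] <-
      .eog_leak[keep, seq_len(min(n_eog, ncol(.eog_leak))), drop = FALSE]
    eeg <- eeg + leak %*% eog

    # --- sensor noise and assembly ------------------------------------
    eeg <- eeg + matrix(rnorm(n_eeg * n, sd = config$noise_sd), n_eeg, n)
    signal <- rbind(eeg, eog)
    rownames(signal) <- c(eeg_labels, eog_labels)

    structure(list(
      signal = signal,
      channel_labels = c(eeg_labels, eog_labels),
      channel_roles = c(rep("EEG", n_eeg), rep("EOG", n_eog)),
      sampling_rate = sr,
      events = events
    ), class = "eeg_recording")
  })
}

# Sum of smooth transient bumps (half-cosine^2 windows) at Poisson onsets.
.artifact_series <- function(n, sr, rate_per_min, width_s, amp_mean, amp_sd) {
  out <- numeric(n)
  n_ev <- rpois(1, rate_per_min * n / sr / 60)
  if (n_ev == 0) return(out)
  w <- round(width_s * sr)
  bump <- sin(seq(0, pi, length.out = w))^2
  onsets <- sort(sample.int(max(n - w, 1), n_ev, replace = TRUE))
  amps <- rnorm(n_ev, amp_mean, amp_sd)
  for (i in seq_len(n_ev)) {
    idx <- onsets[i]:(onsets[i] + w - 1)
    out[idx] <- out[idx] + amps[i] * bump
  }
  out
}

#' Generate a counterbalanced multi-subject synthetic study
#'
#' Derives an independent seed per subject from `config$seed` and cycles
#' the four counterbalancing scenarios (context order x starting workload
#' level) across subjects, so that with `n_subjects = 4` each scenario
#' appears exactly once.
#'
#' @param config A [synth_config()]; its `context_order`/`workload_order`
#'   are overridden by the per-subject scenario.
#' @param n_subjects Number of subjects (>= 1).
#' @return A list of `eeg_recording` objects of length `n_subjects`, with
#'   names `subject01`, `subject02`, ...
#' @export
#' @examples
#' cfg <- synth_config(seed = 3, n_blocks_per_context_per_level = 1,
#'                     letters_per_block = 4)
#' study <- generate_study(cfg, n_subjects = 2)
#' names(study)
generate_study <- function(config, n_subjects) {
  stopifnot(inherits(config, "synth_config"))
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    out[[i]] <- generate_session(.subject_config(config, i))
  }
  names(out) <- sprintf("subject%02d", seq_len(n_subjects))
  out
}

# Subject i's configuration: derived seed plus the cycled
# counterbalancing scenario (context order x starting workload level).
.subject_config <- function(config, i) {
  scenarios <- expand.grid(
    workload_order = c("low-first", "high-first"),
    context_order = c("relax-first", "stress-first"),
    stringsAsFactors = FALSE
  )
  sc <- scenarios[(i - 1) %% 4 + 1, ]
  cfg_i <- config
  cfg_i$seed <- subject_seed(config$seed, i)
  cfg_i$context_order <- sc$context_order
  cfg_i$workload_order <- sc$workload_order
  cfg_i
}

#' Deterministic per-subject seed derivation
#'
#' @param seed Study-level seed.
#' @param i Subject index (1-based).
#' @return An integer seed below 2^31.
#' @export
subject_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 1000003 + i * 7919) %%
               .Machine$integer.max)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$signal), "channels x", ncol(x$signal),
      "samples @", x$sampling_rate, "Hz (",
      sum(x$channel_roles == "EEG"), "EEG,",
      sum(x$channel_roles == "EOG"), "EOG )\n")
  cat("  events:", nrow(x$events), "in", length(unique(x$events$block)),
      "blocks;", sum(x$events$is_target), "targets\n")
  invisible(x)
}
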