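# Shared fixtures: reduced-size generator configurations and hand-built
# epoch sets. All fixtures are built in code at test time.

# A fast session: 12 EEG channels, 180 Hz, 2 blocks per context per
# level, 10 letters per block (still the full two-context protocol
# structure, at roughly 1/50 the compute of the default study).
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_eeg_channels = 12, sampling_rate = 180,
               n_blocks_per_context_per_level = 2, letters_per_block = 10,
               noise_sd = 2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# An epoch_set built directly from a trials x channels x samples array.
make_epochs <- function(data, workload, context = "relax", block = 1L,
                        sr = 180, half = 1L, is_target = FALSE) {
  n <- dim(data)[1]
  structure(list(
    data = data,
    sampling_rate = sr,
    channel_labels = paste0("ch", seq_len(dim(data)[2])),
    labels = data.frame(
      workload = rep_len(workload, n), context = rep_len(context, n),
      block = rep_len(block, n), half = rep_len(half, n),
      is_target = rep_len(is_target, n), stringsAsFactors = FALSE)
  ), class = "epoch_set")
}

# Label-complete epoch set mirroring the full protocol (24 blocks, 45
# non-target trials per block) with degenerate 1 x 1 signal content; used
# to exercise fold construction at full structural scale cheaply.
protocol_epochs <- function(n_per_level = 6, trials_per_block = 45) {
  blocks <- 4 * n_per_level
  per_ctx <- 2 * n_per_level
  labels <- do.call(rbind, lapply(seq_len(blocks), function(b) {
    ctx <- if (b <= per_ctx) "relax" else "stress"
    b_in <- (b - 1) %% per_ctx + 1
    data.frame(
      workload = rep(if (b_in %% 2 == 1) "low" else "high",
                     trials_per_block),
      context = ctx, block = b,
      half = if (b_in <= n_per_level) 1L else 2L,
      is_target = FALSE, stringsAsFactors = FALSE)
  }))
  structure(list(
    data = array(0, dim = c(nrow(labels), 1, 1)),
    sampling_rate = 180, channel_labels = "ch1", labels = labels
  ), class = "epoch_set")
}

# Two-class Gaussian feature matrix with controllable mean shift.
make_features <- function(n_per_class, d, delta = 0, seed = 1, sd = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * d, 0, sd), n_per_class, d),
    matrix(rnorm(n_per_class * d, 0, sd), n_per_class, d) + delta
  )
  structure(list(
    values = x,
    provenance = data.frame(branch = "fb", band = "alpha",
                            filter = seq_len(d), sample = NA_integer_),
    labels = data.frame(
      workload = rep(c("low", "high"), each = n_per_class),
      context = "relax", block = 1L, half = 1L, is_target = FALSE,
      stringsAsFactors = FALSE)
  ), class = "feature_matrix")
}

# Welch-style band power of one channel (independent oracle for planted
# band effects): mean squared magnitude of the FFT bins inside the band.
oracle_band_power <- function(x, sr, lo, hi) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2 / n
  freq <- (seq_len(n) - 1) * sr / n
  keep <- freq >= lo & freq <= hi
  mean(sp[keep])
}

# Independent brute-force mRMR: naive re-implementation with plain loops
# over all candidates at every step (no incremental caching).
oracle_mrmr <- function(x, y, k, bins = 8) {
  disc <- apply(x, 2, function(col) {
    br <- unique(quantile(col, probs = seq(0, 1, length.out = bins + 1),
                          names = FALSE))
    if (length(br) < 2) return(rep(1L, length(col)))
    findInterval(col, br, rightmost.closed = TRUE, all.inside = TRUE)
  })
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
    s
  }
  rel <- apply(disc, 2, mi, b = y)
  picked <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf; best_j <- NA
    for (j in setdiff(seq_len(ncol(x)), picked)) {
      red <- if (length(picked)) {
        mean(sapply(picked, function(p) mi(disc[, j], disc[, p])))
      } else 0
      sc <- rel[j] - red
      if (sc > best + 1e-12) { best <- sc; best_j <- j }
    }
    picked <- c(picked, best_j)
  }
  picked
}
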