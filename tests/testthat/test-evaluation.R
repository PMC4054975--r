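# Cross-validation scheme construction, fusion, chance level, and the
# behavioral performance statistic.

test_that("general scheme folds have 900 train and 180 test trials", {
  ep <- protocol_epochs()
  folds <- make_folds(ep, scheme_spec("general", seed = 3))
  expect_length(folds, 6)
  for (f in folds) {
    expect_length(f$train_idx, 900)
    expect_length(f$test_idx, 180)
    expect_length(f$test_blocks, 4)
    lab <- ep$labels[f$test_idx, ]
    expect_true(all(table(lab$workload, lab$context) == 45))
    lab_tr <- ep$labels[f$train_idx, ]
    expect_true(all(table(lab_tr$workload, lab_tr$context) == 225))
  }
})

test_that("within scheme folds have 450 train and 90 test trials", {
  ep <- protocol_epochs()
  folds <- make_folds(ep, scheme_spec("within", train_context = "stress",
                                      seed = 4))
  expect_length(folds, 6)
  for (f in folds) {
    expect_length(f$train_idx, 450)
    expect_length(f$test_idx, 90)
    expect_true(all(ep$labels$context[c(f$train_idx, f$test_idx)] ==
                      "stress"))
    expect_true(all(table(ep$labels$workload[f$test_idx]) == 45))
  }
})

test_that("across folds train on one context and test on the other", {
  ep <- protocol_epochs()
  folds <- make_folds(ep, scheme_spec("across", train_context = "relax",
                                      seed = 5))
  for (f in folds) {
    expect_true(all(ep$labels$context[f$train_idx] == "relax"))
    expect_true(all(ep$labels$context[f$test_idx] == "stress"))
    expect_length(f$train_idx, 450)
    expect_length(f$test_idx, 90)
  }
})

test_that("combined folds match the within training size to within 2", {
  ep <- protocol_epochs()
  folds <- make_folds(ep, scheme_spec("combined", test_context = "relax",
                                      seed = 6))
  expect_length(folds, 6)
  for (f in folds) {
    expect_lte(abs(length(f$train_idx) - 450), 2)
    # 6 training blocks per context, none of them a test block
    expect_equal(length(f$train_blocks), 12)
    expect_length(intersect(f$train_blocks, f$test_blocks), 0)
    expect_true(all(ep$labels$context[f$test_idx] == "relax"))
    # workload balance preserved to within one trial per context
    lab <- ep$labels[f$train_idx, ]
    tab <- table(lab$context, lab$workload)
    expect_true(all(abs(tab[, "low"] - tab[, "high"]) <= 1))
  }
})

test_that("halves schemes stay inside / cross between context halves", {
  ep <- protocol_epochs()
  fw <- make_folds(ep, scheme_spec("halves_within", seed = 7))
  fa <- make_folds(ep, scheme_spec("halves_across", seed = 7))
  expect_length(fw, 12)  # 2 contexts x 2 train halves x 3 folds
  expect_length(fa, 12)
  for (f in fw) {
    expect_length(f$train_blocks, 4)
    expect_length(f$test_blocks, 2)
    h <- unique(ep$labels$half[c(f$train_idx, f$test_idx)])
    expect_length(h, 1)
    expect_length(unique(ep$labels$context[c(f$train_idx, f$test_idx)]), 1)
  }
  for (f in fa) {
    expect_false(unique(ep$labels$half[f$train_idx]) ==
                   unique(ep$labels$half[f$test_idx]))
    expect_length(unique(ep$labels$context[c(f$train_idx, f$test_idx)]), 1)
  }
})

test_that("folds partition blocks with no train/test overlap", {
  ep <- protocol_epochs()
  specs <- list(
    scheme_spec("general", seed = 8),
    scheme_spec("within", train_context = "relax", seed = 8),
    scheme_spec("across", train_context = "stress", seed = 8),
    scheme_spec("combined", test_context = "stress", seed = 8),
    scheme_spec("halves_within", seed = 8),
    scheme_spec("halves_across", seed = 8)
  )
  for (sp in specs) {
    folds <- make_folds(ep, sp)
    for (f in folds) {
      expect_length(intersect(f$train_blocks, f$test_blocks), 0)
      expect_length(intersect(f$train_idx, f$test_idx), 0)
    }
    if (sp$name %in% c("general", "within")) {
      tested <- unlist(lapply(folds, `[[`, "test_blocks"))
      expect_false(any(duplicated(tested)))  # each block tested once
    }
  }
})

test_that("missing blocks trigger the reduced-fold fallback", {
  ep <- protocol_epochs(n_per_level = 3)  # 6 blocks per context
  expect_warning(
    folds <- make_folds(ep, scheme_spec("within", train_context = "relax",
                                        seed = 9)),
    "falling back")
  expect_length(folds, 3)
})

test_that("fold draws are reproducible from the scheme seed", {
  ep <- protocol_epochs()
  sp <- scheme_spec("combined", test_context = "relax", seed = 11)
  expect_identical(make_folds(ep, sp), make_folds(ep, sp))
})

test_that("majority vote counts labels and applies the tie rule", {
  expect_equal(majority_vote(rep("high", 45)), "high")
  expect_equal(majority_vote(c(rep("high", 23), rep("low", 22))), "high")
  expect_equal(majority_vote(c(rep("low", 23), rep("high", 22))), "low")
  # even-count tie: mean signed score decides; positive -> "high"
  labels <- c("high", "low")
  expect_equal(majority_vote(labels, scores = c(2, -1)), "high")
  expect_equal(majority_vote(labels, scores = c(1, -2)), "low")
  expect_equal(majority_vote(labels), "high")  # scoreless tie rule
  expect_error(majority_vote(character(0)), "at least one")
})

test_that("chance level reproduces the printed thresholds", {
  expect_equal(chance_level(1080, 0.05), 53.1)
  expect_equal(round(chance_level(24, 0.05)), 71)
  # monotone toward 50% with growing n
  ns <- c(24, 90, 1080, 1e4, 1e8)
  cl <- sapply(ns, chance_level)
  expect_true(all(diff(cl) <= 0))
  expect_equal(cl[length(cl)], 50, tolerance = 1e-3)
  expect_error(chance_level(100, alpha = 0), "alpha")
  # exact-binomial variant stays close to the normal approximation
  expect_lt(abs(chance_level(1080, method = "binomial") - 53.1), 0.3)
})

test_that("n-back behavioral performance is the correct-response rate", {
  expect_equal(nback_performance(TP = 45, TN = 15, FP = 0, FN = 0), 1)
  expect_equal(nback_performance(TP = 40, TN = 50, FP = 5, FN = 5), 0.9)
  expect_error(nback_performance(0, 0, 0, 0), "all-zero")
  expect_error(nback_performance(-1, 2, 0, 0), "non-negative")
})

test_that("a strongly planted effect is decoded near-perfectly and fused", {
  cfg <- synth_config(seed = 61, sampling_rate = 180, n_eeg_channels = 12,
                      n_blocks_per_context_per_level = 3,
                      letters_per_block = 30,
                      band_power_effects = c(alpha = 0.25, theta = 2.5),
                      context_shift = c(delta = 1),
                      erp_amplitude_effect = 0, noise_sd = 0.3)
  ep <- preprocess_recording(generate_session(cfg))
  res <- suppressWarnings(
    run_scheme(ep, scheme_spec("within", train_context = "relax",
                               variety = "fb", seed = 62),
               n_pairs = 2, k_select = 8))
  expect_gte(res$mean_accuracy, 0.95)
  # block-level fusion cannot do worse than the trial level here
  block_acc <- mean(res$block_votes$fused == res$block_votes$truth)
  expect_gte(block_acc, res$mean_accuracy)
})

test_that("restricting the bank to low bands barely hurts planted-low data", {
  cfg <- synth_config(seed = 63, sampling_rate = 180, n_eeg_channels = 12,
                      n_blocks_per_context_per_level = 3,
                      letters_per_block = 30, noise_sd = 4,
                      erp_amplitude_effect = 0)
  ep <- preprocess_recording(generate_session(cfg))
  sp <- function(seed) scheme_spec("general", variety = "fb", seed = seed)
  full <- suppressWarnings(
    run_scheme(ep, sp(64), bands = default_bands(), n_pairs = 2))
  low <- suppressWarnings(
    run_scheme(ep, sp(64),
               bands = default_bands(c("delta", "theta", "alpha")),
               n_pairs = 2))
  expect_gte(low$mean_accuracy, full$mean_accuracy - 0.05)
})

test_that("null simulations exceed chance at about the nominal rate", {
  # no planted effects at all: the scheme accuracy should beat the 5%
  # binomial chance threshold in at most ~8% of simulations
  n_sims <- 200
  hits <- 0
  for (s in seq_len(n_sims)) {
    cfg <- synth_config(seed = 7000 + s, sampling_rate = 180,
                        n_eeg_channels = 8, n_eog_channels = 2,
                        n_blocks_per_context_per_level = 2,
                        letters_per_block = 10,
                        band_power_effects = c(delta = 1),
                        context_shift = c(delta = 1),
                        erp_amplitude_effect = 0, noise_sd = 2)
    ep <- preprocess_recording(generate_session(cfg))
    res <- suppressWarnings(run_scheme(
      ep, scheme_spec("general", variety = "fb", seed = s),
      bands = default_bands(c("theta", "alpha")), n_pairs = 2,
      k_select = 6))
    n_test <- sum(res$per_fold$n_test)
    if (100 * res$mean_accuracy > chance_level(n_test)) hits <- hits + 1
  }
  expect_lte(hits / n_sims, 0.05 + 0.03)
})
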