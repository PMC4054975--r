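# Block-wise cross-validation schemes, majority-vote fusion, chance
# level, and the behavioral n-back performance statistic.

#' Specify an evaluation scheme
#'
#' The five block-wise stratified cross-validation schemes:
#'
#' * `general` — both contexts pooled; 6 folds, 20 train / 4 test blocks,
#'   workload and context balanced per fold.
#' * `within` — one context's 12 blocks; 6 folds, 10 train / 2 test.
#' * `across` — train folds as `within` on `train_context`, tested on
#'   2-block folds of the other context.
#' * `combined` — per fold, 6 randomly drawn training blocks per context
#'   (all trials of 4 of them, every other trial of the remaining 2, so
#'   the training-set size matches `within`), tested on 2 blocks of
#'   `test_context`; repeated `n_folds` times under the seed.
#' * `halves_within` / `halves_across` — time-control analogues of
#'   within/across over the first/second six-block half of each context
#'   (threefold, 4 train / 2 test), averaged over contexts and halves.
#'
#' Folds never split a block across train and test.
#'
#' @param name Scheme name.
#' @param train_context Context trained on (`within`, `across`).
#' @param test_context Context tested on (`combined`).
#' @param variety Feature variety: `"fb"`, `"erp"` or `"both"`.
#' @param n_folds Number of folds/repetitions (default 6).
#' @param seed Seed for the stratified block shuffle.
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(name = c("general", "within", "across", "combined",
                                 "halves_within", "halves_across"),
                        train_context = NULL, test_context = NULL,
                        variety = c("fb", "erp", "both"),
                        n_folds = 6, seed = 1) {
  name <- match.arg(name)
  variety <- match.arg(variety)
  if (name %in% c("within", "across") && is.null(train_context)) {
    stop("scheme '", name, "' needs a train_context")
  }
  if (name == "combined" && is.null(test_context)) {
    stop("scheme 'combined' needs a test_context")
  }
  structure(list(name = name, train_context = train_context,
                 test_context = test_context, variety = variety,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat("<scheme_spec>", x$name, "/", x$variety)
  if (!is.null(x$train_context)) cat(" train:", x$train_context)
  if (!is.null(x$test_context)) cat(" test:", x$test_context)
  cat(" (", x$n_folds, "folds, seed", x$seed, ")\n")
  invisible(x)
}

# Unique (block, context, workload) table of an epoch set.
.block_table <- function(labels) {
  bt <- unique(labels[, c("block", "context", "workload", "half")])
  bt[order(bt$block), , drop = FALSE]
}

# sample() without the 1:x surprise on length-1 inputs
.resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# Stratified assignment of one context's blocks to folds: returns a list
# of test-block sets (each 1 low + 1 high), length = attainable folds.
.fold_assign <- function(bt, n_folds) {
  lows <- .resample(bt$block[bt$workload == "low"])
  highs <- .resample(bt$block[bt$workload == "high"])
  n_eff <- min(n_folds, length(lows), length(highs))
  lapply(seq_len(n_eff), function(f) c(lows[f], highs[f]))
}

.trials_of_blocks <- function(labels, blocks) {
  which(labels$block %in% blocks)
}

# Every-other-trial subsampling of two halved blocks with alternating
# starting parity (keeps the two-block total at one full block of trials).
.halved_trials <- function(labels, blocks) {
  out <- integer(0)
  for (j in seq_along(blocks)) {
    idx <- which(labels$block == blocks[j])
    start <- if (j %% 2 == 1) 1L else 2L
    out <- c(out, idx[seq(start, length(idx), by = 2)])
  }
  out
}

#' Construct cross-validation folds for a scheme
#'
#' Draws the stratified block-to-fold assignment under the scheme's seed
#' and resolves it to trial indices. If a context holds fewer complete
#' blocks than the scheme expects, the number of folds falls back to what
#' the blocks support, with a warning.
#'
#' @param epochs An `epoch_set` with block/context/half labels (targets
#'   already discarded).
#' @param spec A [scheme_spec()].
#' @return A list of folds; each fold is a list with `train_blocks`,
#'   `test_blocks`, `train_idx`, `test_idx`.
#' @export
make_folds <- function(epochs, spec) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "scheme_spec"))
  labels <- epochs$labels
  bt <- .block_table(labels)
  .with_seed(spec$seed, switch(
    spec$name,
    general = .folds_general(labels, bt, spec),
    within = .folds_within(labels, bt, spec),
    across = .folds_across(labels, bt, spec),
    combined = .folds_combined(labels, bt, spec),
    halves_within = .folds_halves(labels, bt, spec, across = FALSE),
    halves_across = .folds_halves(labels, bt, spec, across = TRUE)
  ))
}

.check_folds <- function(n_eff, n_req, what) {
  if (n_eff < 1) stop("not enough blocks to build any fold for ", what)
  if (n_eff < n_req) {
    warning("only ", n_eff, " of the requested ", n_req,
            " folds are attainable for ", what, "; falling back")
  }
  n_eff
}

.folds_general <- function(labels, bt, spec) {
  ctxs <- sort(unique(bt$context))
  assign <- lapply(ctxs, function(cx) {
    .fold_assign(bt[bt$context == cx, ], spec$n_folds)
  })
  n_eff <- .check_folds(min(lengths(assign)), spec$n_folds, "'general'")
  lapply(seq_len(n_eff), function(f) {
    test_blocks <- unlist(lapply(assign, `[[`, f))
    train_blocks <- setdiff(bt$block, test_blocks)
    list(train_blocks = train_blocks, test_blocks = test_blocks,
         train_idx = .trials_of_blocks(labels, train_blocks),
         test_idx = .trials_of_blocks(labels, test_blocks))
  })
}

.folds_within <- function(labels, bt, spec, test_labels = labels,
                          test_bt = bt) {
  btc <- bt[bt$context == spec$train_context, ]
  if (!nrow(btc)) stop("no blocks in train_context '",
                       spec$train_context, "'")
  assign <- .fold_assign(btc, spec$n_folds)
  n_eff <- .check_folds(length(assign), spec$n_folds,
                        paste0("'within' on ", spec$train_context))
  lapply(seq_len(n_eff), function(f) {
    test_blocks <- assign[[f]]
    train_blocks <- setdiff(btc$block, test_blocks)
    list(train_blocks = train_blocks, test_blocks = test_blocks,
         train_idx = .trials_of_blocks(labels, train_blocks),
         test_idx = .trials_of_blocks(labels, test_blocks))
  })
}

.folds_across <- function(labels, bt, spec) {
  other <- setdiff(unique(bt$context), spec$train_context)
  if (length(other) != 1) {
    stop("'across' needs exactly one other context; found: ",
         paste(other, collapse = ", "))
  }
  btc <- bt[bt$context == spec$train_context, ]
  bto <- bt[bt$context == other, ]
  a_train <- .fold_assign(btc, spec$n_folds)
  a_test <- .fold_assign(bto, spec$n_folds)
  n_eff <- .check_folds(min(length(a_train), length(a_test)), spec$n_folds,
                        paste0("'across' from ", spec$train_context))
  lapply(seq_len(n_eff), function(f) {
    train_blocks <- setdiff(btc$block, a_train[[f]])
    test_blocks <- a_test[[f]]
    list(train_blocks = train_blocks, test_blocks = test_blocks,
         train_idx = .trials_of_blocks(labels, train_blocks),
         test_idx = .trials_of_blocks(labels, test_blocks))
  })
}

.folds_combined <- function(labels, bt, spec) {
  ctxs <- sort(unique(bt$context))
  if (!spec$test_context %in% ctxs) {
    stop("test_context '", spec$test_context, "' not present")
  }
  folds <- vector("list", spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    btt <- bt[bt$context == spec$test_context, ]
    test_blocks <- c(.resample(btt$block[btt$workload == "low"], 1),
                     .resample(btt$block[btt$workload == "high"], 1))
    train_blocks <- integer(0)
    train_idx <- integer(0)
    for (cx in ctxs) {
      avail <- bt[bt$context == cx & !bt$block %in% test_blocks, ]
      n_lo <- min(3, sum(avail$workload == "low"))
      n_hi <- min(3, sum(avail$workload == "high"))
      lows <- .resample(avail$block[avail$workload == "low"], n_lo)
      highs <- .resample(avail$block[avail$workload == "high"], n_hi)
      # the last low/high pair contributes every other trial only
      halved <- c(tail(lows, 1), tail(highs, 1))
      full <- setdiff(c(lows, highs), halved)
      train_blocks <- c(train_blocks, full, halved)
      train_idx <- c(train_idx, .trials_of_blocks(labels, full),
                     .halved_trials(labels, halved))
    }
    folds[[f]] <- list(train_blocks = sort(train_blocks),
                       test_blocks = test_blocks,
                       train_idx = sort(train_idx),
                       test_idx = .trials_of_blocks(labels, test_blocks))
  }
  folds
}

.folds_halves <- function(labels, bt, spec, across) {
  folds <- list()
  for (cx in sort(unique(bt$context))) {
    for (h_train in 1:2) {
      bth <- bt[bt$context == cx & bt$half == h_train, ]
      h_test <- if (across) 3 - h_train else h_train
      btt <- bt[bt$context == cx & bt$half == h_test, ]
      if (!nrow(bth) || !nrow(btt)) next
      n_req <- min(spec$n_folds, 3L)
      a_train <- .fold_assign(bth, n_req)
      a_test <- if (across) .fold_assign(btt, n_req) else a_train
      n_eff <- .check_folds(min(length(a_train), length(a_test)), n_req,
                            paste0("halves on ", cx, " half ", h_train))
      for (f in seq_len(n_eff)) {
        train_blocks <- setdiff(bth$block, a_train[[f]])
        test_blocks <- a_test[[f]]
        folds[[length(folds) + 1]] <- list(
          train_blocks = train_blocks, test_blocks = test_blocks,
          train_idx = .trials_of_blocks(labels, train_blocks),
          test_idx = .trials_of_blocks(labels, test_blocks))
      }
    }
  }
  folds
}

#' Precompute the per-branch representations of an epoch set
#'
#' Caches what the per-fold model fits need: per-trial channel
#' covariances of each band-filtered copy (oscillatory branch) and the
#' 36 Hz ERP-preprocessed epochs (ERP branch). Both are label-free
#' transforms, so computing them once per subject and reusing them across
#' folds and schemes leaks nothing across the train/test boundary.
#'
#' @param epochs An `epoch_set` (targets discarded).
#' @param bands Filter-bank band table (default [default_bands()]).
#' @param varieties Which branches to prepare (`"fb"`, `"erp"` or both).
#' @return An object of class `branch_data`.
#' @export
prepare_branches <- function(epochs, bands = default_bands(),
                             varieties = c("fb", "erp")) {
  out <- list(labels = epochs$labels, bands = bands)
  if ("fb" %in% varieties) {
    out$fb_covs <- .band_covariances(epochs, bands)
  }
  if ("erp" %in% varieties) {
    out$erp <- preprocess_erp(epochs)
  }
  structure(out, class = "branch_data")
}

.subset_branches <- function(prep, idx, variety = "both") {
  out <- prep
  out$labels <- prep$labels[idx, , drop = FALSE]
  if (!is.null(prep$fb_covs) && variety %in% c("fb", "both")) {
    out$fb_covs <- lapply(prep$fb_covs, function(a) a[, , idx, drop = FALSE])
  } else {
    out$fb_covs <- NULL
  }
  if (!is.null(prep$erp) && variety %in% c("erp", "both")) {
    out$erp <- subset_epochs(prep$erp, idx)
  } else {
    out$erp <- NULL
  }
  out
}

# Fit the full model stack (spatial filters, selection, LDA) on training
# branch data and predict on test branch data.
.fit_predict <- function(train, test, variety, n_pairs = 6,
                         k_select = 18, lambda = 0.4, bins = 8) {
  fb_tr <- fb_te <- erp_tr <- erp_te <- NULL
  if (variety %in% c("fb", "both")) {
    models <- lapply(names(train$fb_covs), function(bn) {
      .fit_csp_cov(train$fb_covs[[bn]], train$labels$workload, n_pairs,
                   band = train$bands[train$bands$name == bn, ])
    })
    names(models) <- names(train$fb_covs)
    feat_tr <- .extract_fbcsp_cov(train$fb_covs, models, train$labels)
    feat_te <- .extract_fbcsp_cov(test$fb_covs, models, test$labels)
    sel <- mrmr_select(feat_tr, k = min(k_select, ncol(feat_tr$values)),
                       bins = bins)
    fb_tr <- apply_selection(feat_tr, sel)
    fb_te <- apply_selection(feat_te, sel)
  }
  if (variety %in% c("erp", "both")) {
    model <- fit_fsf(train$erp, lambda = lambda)
    feat_tr <- extract_erp_features(train$erp, model)
    feat_te <- extract_erp_features(test$erp, model)
    sel <- mrmr_select(feat_tr, k = min(k_select, ncol(feat_tr$values)),
                       bins = bins)
    erp_tr <- apply_selection(feat_tr, sel)
    erp_te <- apply_selection(feat_te, sel)
  }
  xtr <- assemble_variety(fb_tr, erp_tr, variety)
  xte <- assemble_variety(fb_te, erp_te, variety)
  lda <- train_lda(xtr)
  predict(lda, xte)
}

#' Run one cross-validation scheme
#'
#' Per fold: fit the spatial filters (CSP per band and/or FSF), the mRMR
#' selection and the shrinkage LDA on the training trials only, then
#' predict the test trials. Reports per-fold accuracies, their mean, and
#' block-level majority-vote fused decisions.
#'
#' @param epochs An `epoch_set` (targets discarded).
#' @param spec A [scheme_spec()].
#' @param bands Filter-bank band table (restrict for band ablations).
#' @param prepared Optional [prepare_branches()] result for `epochs` (must
#'   match `bands`); computed on the fly when absent.
#' @param n_pairs CSP filter pairs per band (default 6).
#' @param k_select Features selected per branch (default 18).
#' @param lambda FSF regularization weight (default 0.4).
#' @return An object of class `scheme_result`: `per_fold` (data.frame
#'   `fold`, `accuracy`, `n_train`, `n_test`), `mean_accuracy`,
#'   `block_votes` (data.frame `block`, `truth`, `fused`), `spec`.
#' @export
run_scheme <- function(epochs, spec, bands = default_bands(),
                       prepared = NULL, n_pairs = 6, k_select = 18,
                       lambda = 0.4) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "scheme_spec"))
  folds <- make_folds(epochs, spec)
  if (is.null(prepared)) {
    prepared <- prepare_branches(epochs, bands, varieties = unique(
      c("fb", "erp")[c(spec$variety %in% c("fb", "both"),
                       spec$variety %in% c("erp", "both"))]))
  }
  per_fold <- data.frame(fold = seq_along(folds), accuracy = NA_real_,
                         n_train = NA_integer_, n_test = NA_integer_)
  pred_block <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    pred <- .fit_predict(
      .subset_branches(prepared, fold$train_idx, spec$variety),
      .subset_branches(prepared, fold$test_idx, spec$variety),
      spec$variety, n_pairs, k_select, lambda)
    truth <- epochs$labels$workload[fold$test_idx]
    per_fold$accuracy[f] <- mean(pred$label == truth)
    per_fold$n_train[f] <- length(fold$train_idx)
    per_fold$n_test[f] <- length(fold$test_idx)
    pred_block[[f]] <- data.frame(
      block = epochs$labels$block[fold$test_idx],
      truth = truth, label = pred$label, score = pred$score,
      stringsAsFactors = FALSE)
  }
  pred_block <- do.call(rbind, pred_block)
  votes <- lapply(split(pred_block, pred_block$block), function(df) {
    data.frame(block = df$block[1], truth = df$truth[1],
               fused = majority_vote(df$label, df$score),
               stringsAsFactors = FALSE)
  })
  votes <- do.call(rbind, votes)
  rownames(votes) <- NULL
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 block_votes = votes, spec = spec),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat("<scheme_result>", x$spec$name, "/", x$spec$variety, ":",
      sprintf("%.1f%%", 100 * x$mean_accuracy), "over",
      nrow(x$per_fold), "folds\n")
  cat("  block-fused accuracy:",
      sprintf("%.1f%%", 100 * mean(x$block_votes$fused ==
                                     x$block_votes$truth)), "\n")
  invisible(x)
}

#' Tidy per-fold accuracies of a scheme result
#'
#' @param result A `scheme_result`.
#' @return A data.frame with one row per fold: `scheme`, `variety`,
#'   `fold`, `accuracy`, `n_train`, `n_test`.
#' @export
tidy_result <- function(result) {
  stopifnot(inherits(result, "scheme_result"))
  cbind(data.frame(scheme = result$spec$name,
                   variety = result$spec$variety),
        result$per_fold)
}

#' Majority vote over trial decisions of a block
#'
#' Returns the most frequent label. With the protocol's 45 relevant trials
#' per block a tie is impossible; for even counts a tie resolves by the
#' mean signed classifier score (positive mean picks the second entry of
#' `class_order`, i.e. `"high"`).
#'
#' @param labels Character vector of per-trial predicted labels.
#' @param scores Optional numeric signed scores used only to break ties.
#' @param class_order Label pair, low first (default `c("low", "high")`).
#' @return A single label.
#' @export
#' @examples
#' majority_vote(c("high", "high", "low"))
majority_vote <- function(labels, scores = NULL,
                          class_order = c("low", "high")) {
  if (length(labels) == 0) stop("majority_vote needs at least one label")
  counts <- table(factor(labels, levels = class_order))
  if (counts[1] == counts[2]) {
    if (!is.null(scores) && mean(scores) < 0) return(class_order[1])
    return(class_order[2])
  }
  names(counts)[which.max(counts)]
}

#' Binomial chance-level accuracy threshold
#'
#' The accuracy below which a two-class classifier is statistically
#' indistinguishable from guessing, for `n_trials` test decisions at
#' significance `alpha`. The default convention uses the two-sided
#' normal-approximation bound with a ceiling to the next achievable
#' correct count: `k = ceil(n/2 + z * sqrt(n/4))` with
#' `z = qnorm(1 - alpha/2)`, reported as `100 * k / n` rounded to one
#' decimal. An exact-binomial variant is available via `method`.
#'
#' @param n_trials Number of test decisions (>= 1).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param method `"normal-ceiling"` (default) or `"binomial"` (exact
#'   binomial quantile).
#' @return Chance-level threshold in percent, rounded to one decimal.
#' @export
#' @examples
#' chance_level(1080)  # 53.1
#' chance_level(24)    # 70.8 -> 71% at integer precision
chance_level <- function(n_trials, alpha = 0.05,
                         method = c("normal-ceiling", "binomial")) {
  method <- match.arg(method)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  k <- switch(method,
    "normal-ceiling" = ceiling(n_trials / 2 +
                                 qnorm(1 - alpha / 2) * sqrt(n_trials / 4)),
    "binomial" = stats::qbinom(1 - alpha / 2, n_trials, 0.5) + 1
  )
  k <- min(k, n_trials)
  round(100 * k / n_trials, 1)
}

#' Behavioral n-back performance
#'
#' The block-level task accuracy from the response counts:
#' `Perf = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param TP,TN,FP,FN Non-negative response counts (true/false
#'   positives/negatives).
#' @return Performance as a proportion in `[0, 1]`.
#' @export
#' @examples
#' nback_performance(TP = 40, TN = 50, FP = 5, FN = 5)  # 0.9
nback_performance <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) stop("performance undefined for all-zero counts")
  (TP + TN) / total
}
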