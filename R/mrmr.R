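# mRMR feature selection (MID scheme: relevance minus mean redundancy),
# with mutual information estimated after equal-frequency discretization.

# Equal-frequency discretization into at most `bins` levels; a constant
# (undiscretizable) feature maps to a single level and thus zero MI.
.discretize_ef <- function(x, bins = 8) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Mutual information (nats) between two integer-coded variables.
.mi_disc <- function(x, y, nx = max(x), ny = max(y)) {
  joint <- tabulate((x - 1L) * ny + y, nbins = nx * ny)
  joint <- joint[joint > 0] / length(x)
  px <- tabulate(x, nbins = nx) / length(x)
  py <- tabulate(y, nbins = ny) / length(y)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(joint * log(joint))
  max(hx + hy - hxy, 0)
}

#' mRMR feature selection
#'
#' Greedy forward selection maximizing `I(feature; class) - mean over
#' already-picked features of I(feature; picked)` (the difference, "MID",
#' scheme). Mutual information is estimated after equal-frequency
#' discretization of each feature. Ties break deterministically toward
#' the lowest column index. Constant features receive zero relevance.
#'
#' @param features A `feature_matrix` with two-class labels.
#' @param k Number of features to select (default 18).
#' @param bins Number of discretization bins (default 8; equal-frequency
#'   binning is robust to the skew of log-power features).
#' @return An object of class `selection_model`: `selected_indices`
#'   (ordered by selection step), `scores` (incremental mRMR score per
#'   pick), `k`, `discretization_bins`.
#' @export
mrmr_select <- function(features, k = 18, bins = 8) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values
  n <- nrow(x)
  p <- ncol(x)
  if (k > p) {
    stop("k = ", k, " exceeds the number of features (", p, ")")
  }
  cls <- features$labels$workload
  if (length(unique(cls)) < 2) stop("need two classes for mRMR selection")
  y <- as.integer(factor(cls))
  ny <- max(y)
  disc <- matrix(0L, n, p)
  for (j in seq_len(p)) disc[, j] <- .discretize_ef(x[, j], bins)

  # one-hot block layout (`bins` slots per feature): every pairwise
  # contingency table then comes out of a single crossprod
  D <- matrix(0, n, p * bins)
  D[cbind(rep(seq_len(n), p),
          (rep(seq_len(p), each = n) - 1L) * bins + as.vector(disc))] <- 1
  grp <- rep(seq_len(p), each = bins)
  xlogx_by_feature <- function(m) {
    # m: (p*bins) x q of probabilities; per-feature sum of x log x
    as.vector(rowsum(rowSums(ifelse(m > 0, m * log(m), 0)), grp))
  }
  px <- colSums(D) / n
  hx <- -as.vector(rowsum(ifelse(px > 0, px * log(px), 0), grp))
  Y <- matrix(0, n, ny)
  Y[cbind(seq_len(n), y)] <- 1
  py <- colSums(Y) / n
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -xlogx_by_feature(crossprod(D, Y) / n)
  relevance <- pmax(hx + hy - hxy, 0)

  selected <- integer(k)
  scores <- numeric(k)
  red_sum <- numeric(p)  # running sum of MI with picked features
  avail <- rep(TRUE, p)
  for (step in seq_len(k)) {
    score <- relevance - if (step == 1) 0 else red_sum / (step - 1)
    score[!avail] <- -Inf
    pick <- which.max(score)  # which.max takes the first (lowest index) tie
    selected[step] <- pick
    scores[step] <- score[pick]
    avail[pick] <- FALSE
    if (step < k) {
      P <- D[, (pick - 1L) * bins + seq_len(bins), drop = FALSE]
      hxp <- -xlogx_by_feature(crossprod(D, P) / n)
      red_sum <- red_sum + pmax(hx + hx[pick] - hxp, 0)
    }
  }
  structure(list(selected_indices = selected, scores = scores, k = k,
                 discretization_bins = bins),
            class = "selection_model")
}

#' Apply a selection model to a feature matrix
#'
#' @param features A `feature_matrix`.
#' @param selection A `selection_model` fitted on features with the same
#'   columns.
#' @return The `feature_matrix` restricted to the selected columns, in
#'   selection order.
#' @export
apply_selection <- function(features, selection) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(selection, "selection_model"))
  idx <- selection$selected_indices
  if (max(idx) > ncol(features$values)) {
    stop("selection refers to columns beyond the feature matrix")
  }
  features$values <- features$values[, idx, drop = FALSE]
  features$provenance <- features$provenance[idx, , drop = FALSE]
  rownames(features$provenance) <- NULL
  features
}

#' @export
print.selection_model <- function(x, ...) {
  cat("<selection_model>", x$k, "features,", x$discretization_bins,
      "bins\n  picks:", paste(x$selected_indices, collapse = " "), "\n")
  invisible(x)
}
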