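# Feature-variety assembly and shrinkage LDA.

#' Assemble a feature variety from the two branches
#'
#' Combines the per-branch (already mRMR-selected) feature matrices into
#' the classifier input: `"fb"` (oscillatory only), `"erp"` (time-domain
#' only) or `"both"` (fb block first, then erp; 18 + 18 = 36 columns with
#' the default selections).
#'
#' @param fb,erp `feature_matrix` objects for the oscillatory and ERP
#'   branches (either may be NULL when not used by the variety).
#' @param variety One of `"fb"`, `"erp"`, `"both"`.
#' @return A `feature_matrix`.
#' @export
assemble_variety <- function(fb = NULL, erp = NULL,
                             variety = c("both", "fb", "erp")) {
  variety <- match.arg(variety)
  if (variety == "fb") return(fb)
  if (variety == "erp") return(erp)
  if (is.null(fb) || is.null(erp)) {
    stop("variety 'both' needs both branch feature matrices")
  }
  if (nrow(fb$values) != nrow(erp$values)) {
    stop("trial-count mismatch between branches: ", nrow(fb$values),
         " vs ", nrow(erp$values))
  }
  structure(list(
    values = cbind(fb$values, erp$values),
    provenance = rbind(fb$provenance, erp$provenance),
    labels = fb$labels
  ), class = "feature_matrix")
}

# Ledoit-Wolf-type analytic shrinkage intensity toward nu * I, computed
# from centered observations Z (n x d), as standard for covariance-
# regularized LDA in small-sample EEG settings.
.shrinkage_gamma <- function(z) {
  n <- nrow(z)
  d <- ncol(z)
  s <- crossprod(z) / (n - 1)
  nu <- sum(diag(s)) / d
  # sum over entries of the empirical variance of z_i z_j across samples:
  # sum_ij mean_k[(z_ki z_kj)^2] - sum_ij mean_k[z_ki z_kj]^2
  zsq_mean <- crossprod(z) / n
  var_sum <- sum(crossprod(z^2)) / n - sum(zsq_mean^2)
  denom <- sum((s - diag(nu, d))^2)
  if (denom <= 0) return(0)
  g <- (n / (n - 1)^2) * var_sum / denom
  min(max(g, 0), 1)
}

#' Train a shrinkage LDA classifier
#'
#' Linear discriminant analysis on a two-class feature matrix whose
#' pooled within-class covariance is shrunk toward `(trace / d) * I` with
#' an analytically computed (Ledoit-Wolf-type) intensity `gamma`, the
#' standard stabilization for small-sample EEG classification. Weights
#' are proportional to the inverse shrunk covariance times the class-mean
#' difference; the bias places the decision boundary at the midpoint of
#' the projected class means.
#'
#' @param features A `feature_matrix` with both workload classes present.
#' @param gamma Optional fixed shrinkage intensity in `[0, 1]`; by default
#'   computed from the training data.
#' @return An object of class `lda_model`: `weights`, `bias`, `gamma`,
#'   `class_order = c("low", "high")` (scores > 0 predict `"high"`).
#' @export
train_lda <- function(features, gamma = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values
  cls <- features$labels$workload
  idx_hi <- which(cls == "high")
  idx_lo <- which(cls == "low")
  if (length(idx_hi) < 2 || length(idx_lo) < 2) {
    stop("need at least 2 trials per workload class to train the LDA")
  }
  mu_hi <- colMeans(x[idx_hi, , drop = FALSE])
  mu_lo <- colMeans(x[idx_lo, , drop = FALSE])
  z <- rbind(sweep(x[idx_hi, , drop = FALSE], 2, mu_hi),
             sweep(x[idx_lo, , drop = FALSE], 2, mu_lo))
  if (is.null(gamma)) gamma <- .shrinkage_gamma(z)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  d <- ncol(x)
  s <- crossprod(z) / (nrow(z) - 2)  # pooled within-class covariance
  nu <- sum(diag(s)) / d
  sigma <- (1 - gamma) * s + gamma * diag(nu, d)
  w <- solve(sigma, mu_hi - mu_lo)
  b <- -sum(w * (mu_hi + mu_lo)) / 2
  structure(list(weights = as.numeric(w), bias = b, gamma = gamma,
                 class_order = c("low", "high")),
            class = "lda_model")
}

#' Predict workload labels and signed scores
#'
#' The signed score is `weights . x + bias`; positive scores map to the
#' second entry of `class_order` (`"high"`). A trial exactly on the
#' decision boundary (score 0) is deterministically assigned `"high"`
#' (documented tie rule).
#'
#' @param object An `lda_model`.
#' @param features A `feature_matrix` (or plain matrix) with matching
#'   feature dimension.
#' @param ... Unused.
#' @return A list with `label` (character vector) and `score` (numeric).
#' @export
predict.lda_model <- function(object, features, ...) {
  x <- if (inherits(features, "feature_matrix")) features$values else features
  if (ncol(x) != length(object$weights)) {
    stop("feature dimension mismatch: model has ", length(object$weights),
         ", input has ", ncol(x))
  }
  score <- as.numeric(x %*% object$weights + object$bias)
  label <- ifelse(score >= 0, object$class_order[2], object$class_order[1])
  list(label = label, score = score)
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", length(x$weights), "features, gamma =",
      signif(x$gamma, 3), "\n")
  invisible(x)
}
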