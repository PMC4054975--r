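# mRMR selection, feature-variety assembly, shrinkage LDA and
# prediction, with brute-force and closed-form oracles (oracle_mrmr
# lives in helper-fixtures.R).

test_that("mRMR agrees with a brute-force oracle on small problems", {
  for (rep in 1:5) {
    set.seed(30 + rep)
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(
      y + rnorm(n, sd = 0.8),            # informative
      matrix(rnorm(n * 5), n, 5)         # noise
    )
    x[, 3] <- x[, 1] + rnorm(n, sd = 0.05)  # near-copy of the informative
    fm <- make_features(n / 2, ncol(x))
    fm$values <- x
    fm$labels$workload <- ifelse(y == 1, "high", "low")
    sel <- mrmr_select(fm, k = 4)
    oracle <- oracle_mrmr(x, y, 4)
    expect_equal(sel$selected_indices, oracle)
  }
})

test_that("redundant copies are penalized after the first pick", {
  set.seed(32)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  informative <- y + rnorm(n, sd = 0.5)
  x <- cbind(informative, informative, rnorm(n), rnorm(n))
  fm <- make_features(n / 2, 4)
  fm$values <- x
  fm$labels$workload <- ifelse(y == 1, "high", "low")
  sel <- mrmr_select(fm, k = 2)
  expect_equal(sel$selected_indices[1], 1)  # ties break to lowest index
  expect_true(sel$selected_indices[2] %in% c(3, 4))
})

test_that("first pick maximizes marginal relevance; k = all enumerates", {
  set.seed(33)
  n <- 150
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 4] <- x[, 4] + y * 1.5
  fm <- make_features(n / 2, 6)
  fm$values <- x
  fm$labels$workload <- ifelse(y == 1, "high", "low")
  sel <- mrmr_select(fm, k = 6)
  expect_equal(sel$selected_indices[1], 4)
  expect_setequal(sel$selected_indices, 1:6)
  expect_equal(sel$selected_indices, oracle_mrmr(x, y, 6))
  # constant feature: zero relevance, no error
  x2 <- cbind(x, 7)
  fm$values <- x2
  fm$provenance <- rbind(fm$provenance, fm$provenance[1, ])
  sel2 <- mrmr_select(fm, k = 7)
  expect_equal(sel2$selected_indices[1], 4)
  expect_error(mrmr_select(fm, k = 8), "exceeds")
})

test_that("variety assembly concatenates fb before erp with provenance", {
  fb <- make_features(10, 3, delta = 1, seed = 41)
  erp <- make_features(10, 2, delta = 1, seed = 42)
  erp$provenance$branch <- "erp"
  both <- assemble_variety(fb, erp, "both")
  expect_equal(ncol(both$values), 5)
  expect_equal(both$provenance$branch, c(rep("fb", 3), rep("erp", 2)))
  expect_identical(both$values[, 1:3], fb$values)
  expect_identical(assemble_variety(fb, NULL, "fb"), fb)
  small <- make_features(4, 2)
  expect_error(assemble_variety(fb, small, "both"), "mismatch")
})

test_that("shrinkage LDA separates and matches its closed-form oracle", {
  # far-separated clouds: perfect training accuracy
  fm <- make_features(30, 4, delta = 10, seed = 51)
  model <- train_lda(fm)
  pred <- predict(model, fm)
  expect_equal(pred$label, fm$labels$workload)
  # gamma = 1: weights proportional to the class-mean difference
  m1 <- train_lda(fm, gamma = 1)
  x <- fm$values
  mu_hi <- colMeans(x[fm$labels$workload == "high", ])
  mu_lo <- colMeans(x[fm$labels$workload == "low", ])
  z <- rbind(sweep(x[fm$labels$workload == "high", ], 2, mu_hi),
             sweep(x[fm$labels$workload == "low", ], 2, mu_lo))
  s <- crossprod(z) / (nrow(z) - 2)
  nu <- sum(diag(s)) / 4
  expect_equal(m1$weights, (mu_hi - mu_lo) / nu, tolerance = 1e-10)
  # generic gamma: direct sample-discriminant oracle at 1e-10
  g <- model$gamma
  sigma <- (1 - g) * s + g * diag(nu, 4)
  w_oracle <- solve(sigma, mu_hi - mu_lo)
  expect_equal(model$weights, as.numeric(w_oracle), tolerance = 1e-10)
  expect_equal(model$bias, -sum(w_oracle * (mu_hi + mu_lo)) / 2,
               tolerance = 1e-10)
})

test_that("the discriminant converges to the analytic direction", {
  # known 2-D Gaussians: w should align with solve(Sigma, mu_h - mu_l)
  set.seed(52)
  n <- 1e5
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2, 2)
  ch <- chol(sigma)
  mu <- c(1, -0.5)
  x <- rbind(matrix(rnorm(2 * n), n, 2) %*% ch,
             sweep(matrix(rnorm(2 * n), n, 2) %*% ch, 2, -mu))
  fm <- make_features(n, 2)
  fm$values <- x
  model <- train_lda(fm)
  w_true <- solve(sigma, mu)
  angle <- acos(sum(model$weights * w_true) /
                  sqrt(sum(model$weights^2) * sum(w_true^2)))
  expect_lt(angle, 0.02)
  expect_lt(model$gamma, 0.01)  # large-sample limit: no shrinkage needed
})

test_that("shrinkage intensity grows as samples shrink toward dimension", {
  # a decidedly non-spherical covariance, so the spherical target is
  # wrong and shrinkage must vanish as data accumulate
  d <- 10
  scales <- seq(0.3, 3, length.out = d)
  gam <- sapply(c(12, 60, 2000), function(n_per) {
    fm <- make_features(n_per, d, delta = 0.5, seed = 53)
    fm$values <- sweep(fm$values, 2, scales, "*")
    train_lda(fm)$gamma
  })
  expect_true(gam[1] > gam[2])
  expect_true(gam[2] > gam[3])
  expect_lt(gam[3], 0.05)
})

test_that("prediction obeys the documented sign and tie rules", {
  fm <- make_features(20, 3, delta = 5, seed = 54)
  model <- train_lda(fm)
  pred <- predict(model, fm)
  # negating the model flips every label
  neg <- model
  neg$weights <- -model$weights
  neg$bias <- -model$bias
  pred_neg <- predict(neg, fm)
  expect_true(all(pred$label != pred_neg$label))
  expect_equal(pred_neg$score, -pred$score)
  # exact boundary goes to "high"
  on_boundary <- matrix(0, 1, 3)
  m0 <- model
  m0$bias <- 0
  expect_equal(predict(m0, on_boundary)$label, "high")
  expect_error(predict(model, matrix(0, 1, 5)), "mismatch")
})

test_that("training is blind to test-fold labels", {
  ep <- discard_targets(segment_epochs(generate_session(tiny_config(42))))
  pb <- prepare_branches(ep, default_bands(c("theta", "alpha")),
                         varieties = "fb")
  tr <- which(ep$labels$block <= 6)
  sub <- workloadbci:::.subset_branches(pb, tr)
  models <- lapply(names(sub$fb_covs), function(bn) {
    workloadbci:::.fit_csp_cov(sub$fb_covs[[bn]], sub$labels$workload, 2)
  })
  fit_once <- function() {
    feat <- workloadbci:::.extract_fbcsp_cov(sub$fb_covs,
                                             setNames(models,
                                                      names(sub$fb_covs)),
                                             sub$labels)
    sel <- mrmr_select(feat, k = 6)
    train_lda(apply_selection(feat, sel))
  }
  m1 <- fit_once()
  ep$labels$workload[-tr] <- sample(ep$labels$workload[-tr])  # scramble test
  m2 <- fit_once()
  expect_identical(m1, m2)
})
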