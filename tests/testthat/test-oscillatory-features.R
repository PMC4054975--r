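# Filter bank, CSP and log-power feature extraction, checked against
# direct dense-eigendecomposition and direct-variance oracles.

sine_epochs <- function(freq, n_trials = 4, n_ch = 3, sr = 180,
                        dur = 8, noise = 0) {
  t <- seq(0, dur - 1 / sr, by = 1 / sr)
  data <- array(0, dim = c(n_trials, n_ch, length(t)))
  set.seed(1)
  for (i in seq_len(n_trials)) {
    for (c in seq_len(n_ch)) {
      data[i, c, ] <- sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) +
        rnorm(length(t), sd = noise)
    }
  }
  make_epochs(data, workload = rep(c("low", "high"), length.out = n_trials),
              sr = sr)
}

test_that("the filter bank isolates a pure 10 Hz tone into alpha", {
  # long trials so the measured response reflects the filter frequency
  # response rather than epoch-edge transients
  ep <- sine_epochs(10)
  out <- apply_filter_bank(ep, default_bands())
  expect_named(out, c("delta", "theta", "alpha", "beta", "gamma", "gamma2"))
  vin <- var(as.numeric(ep$data[1, 1, ]))
  expect_gt(var(as.numeric(out$alpha$data[1, 1, ])), 0.95 * vin)
  expect_lt(var(as.numeric(out$delta$data[1, 1, ])), 0.01 * vin)
  # zero input stays zero in every band
  zero <- make_epochs(array(0, dim = c(2, 2, 64)), c("low", "high"))
  for (b in apply_filter_bank(zero)) expect_true(all(b$data == 0))
  # band above Nyquist rejected
  ep90 <- make_epochs(array(rnorm(2 * 2 * 64), c(2, 2, 64)),
                      c("low", "high"), sr = 100)
  expect_error(apply_filter_bank(ep90, default_bands("gamma2")), "Nyquist")
})

test_that("zero-phase filtering matches signal::filtfilt semantics", {
  # same Butterworth coefficients, single long signal: the matrix
  # implementation must agree with the reference away from the edges
  set.seed(5)
  x <- rnorm(2000)
  bt <- signal::butter(2, c(8, 12) / 90, type = "pass")
  ours <- workloadbci:::.filtfilt_mat(bt$b, bt$a, x)
  ref <- signal::filtfilt(bt, x)
  core <- 200:1800
  expect_lt(max(abs(ours[core] - ref[core])) / sd(ref[core]), 0.02)
  # and introduces no phase lag on a tone
  t <- seq(0, 10, by = 1 / 180)
  tone <- sin(2 * pi * 10 * t)
  filtered <- workloadbci:::.filtfilt_mat(bt$b, bt$a, tone)
  lag <- which.max(ccf(filtered, tone, lag.max = 5, plot = FALSE)$acf) - 6
  expect_equal(lag, 0)
})

test_that("CSP matches a dense generalized-eigenproblem oracle", {
  set.seed(11)
  n_ch <- 5
  n_tr <- 40
  n_s <- 100
  data <- array(rnorm(n_tr * n_ch * n_s), dim = c(n_tr, n_ch, n_s))
  # class high has 10x variance on channel 1
  hi <- seq_len(n_tr) %% 2 == 0
  data[hi, 1, ] <- data[hi, 1, ] * sqrt(10)
  ep <- make_epochs(data, workload = ifelse(hi, "high", "low"))
  model <- fit_csp(ep, n_pairs = 2)
  expect_equal(dim(model$filters), c(4, n_ch))
  expect_true(all(model$eigenvalues >= 0 & model$eigenvalues <= 1))
  # leading filter targets channel 1
  expect_equal(which.max(abs(model$filters[1, ])), 1)
  # oracle: explicit trace-normalized class covariances and a dense
  # solve of eig((Ch + Cl)^-1 Ch), independent of the whitening route
  ncov <- function(idx) {
    m <- 0
    for (i in idx) {
      x <- data[i, , ] - rowMeans(data[i, , ])
      ci <- tcrossprod(x) / (n_s - 1)
      m <- m + ci / sum(diag(ci))
    }
    m / length(idx)
  }
  ch <- ncov(which(hi)); cl <- ncov(which(!hi))
  ev <- sort(Re(eigen(solve(ch + cl) %*% ch)$values), decreasing = TRUE)
  expect_equal(model$eigenvalues, ev[c(1, 2, 4, 5)], tolerance = 1e-8)
  # rows are unit-norm and sign-canonicalized
  expect_equal(rowSums(model$filters^2), rep(1, 4))
  for (r in 1:4) {
    expect_gt(model$filters[r, which.max(abs(model$filters[r, ]))], 0)
  }
})

test_that("identical class covariances give eigenvalues of one half", {
  set.seed(12)
  base <- matrix(rnorm(3 * 200), 3, 200)
  data <- array(0, dim = c(4, 3, 200))
  for (i in 1:4) data[i, , ] <- base
  ep <- make_epochs(data, workload = c("low", "high", "low", "high"))
  model <- fit_csp(ep, n_pairs = 1)
  expect_equal(model$eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("CSP eigenvalues are invariant to invertible channel mixing", {
  set.seed(13)
  data <- array(rnorm(30 * 6 * 80), dim = c(30, 6, 80))
  hi <- seq_len(30) > 15
  data[hi, 2, ] <- data[hi, 2, ] * 2
  ep <- make_epochs(data, workload = ifelse(hi, "high", "low"))
  mix <- matrix(rnorm(36), 6, 6) + diag(6)
  mixed <- ep
  for (i in seq_len(30)) mixed$data[i, , ] <- mix %*% data[i, , ]
  # unnormalized CSP: eigenvalues exactly invariant
  m1 <- fit_csp(ep, n_pairs = 2, trace_norm = FALSE)
  m2 <- fit_csp(mixed, n_pairs = 2, trace_norm = FALSE)
  expect_lt(max(abs(m1$eigenvalues - m2$eigenvalues)), 1e-6)
  # trace-normalized default: invariant up to the per-trial weighting
  n1 <- fit_csp(ep, n_pairs = 2)
  n2 <- fit_csp(mixed, n_pairs = 2)
  expect_lt(max(abs(n1$eigenvalues - n2$eigenvalues)), 0.02)
})

test_that("CSP precondition errors are raised", {
  data <- array(rnorm(4 * 3 * 50), dim = c(4, 3, 50))
  ep <- make_epochs(data, workload = "low")
  expect_error(fit_csp(ep), "2 trials per workload class")
  ep2 <- make_epochs(data, workload = c("low", "low", "high", "high"))
  expect_error(fit_csp(ep2, n_pairs = 6), "channels")
})

test_that("log-power features equal directly computed projected variances", {
  set.seed(14)
  data <- array(rnorm(6 * 4 * 120), dim = c(6, 4, 120))
  ep <- make_epochs(data, workload = rep(c("low", "high"), 3))
  bands <- default_bands(c("theta", "alpha"))
  be <- apply_filter_bank(ep, bands)
  models <- lapply(names(be), function(bn) {
    fit_csp(be[[bn]], n_pairs = 2,
            band = bands[bands$name == bn, ])
  })
  names(models) <- names(be)
  fm <- extract_fbcsp_features(be, models)
  expect_equal(dim(fm$values), c(6, 2 * 4))
  expect_equal(fm$provenance$band, rep(c("theta", "alpha"), each = 4))
  # direct oracle: log variance of the filtered, projected time course
  for (tr in c(1, 5)) {
    for (f in 1:4) {
      proj <- models$alpha$filters[f, ] %*%
        (be$alpha$data[tr, , ] - rowMeans(be$alpha$data[tr, , ]))
      expect_equal(fm$values[tr, 4 + f], log(sum(proj^2) / (120 - 1)),
                   tolerance = 1e-10)
    }
  }
  # unit-variance projection maps to feature 0
  one <- make_epochs(array(rnorm(2 * 12 * 5000), dim = c(2, 12, 5000)),
                     c("low", "high"))
  # log(var) of standard normal projected through a unit-norm filter is
  # near log(1) = 0
  m <- list(alpha = structure(list(filters = diag(12)[1:2, ],
                                   eigenvalues = rep(0.5, 2),
                                   n_pairs = 1, band = NULL),
                              class = "csp_model"))
  f0 <- extract_fbcsp_features(list(alpha = one), m)
  expect_lt(max(abs(f0$values)), 0.1)
  # band/model mismatch rejected
  expect_error(extract_fbcsp_features(be, models[c(2, 1)]), "mismatch")
})

test_that("a 28-channel fit yields the 12 x 28 filter matrix", {
  set.seed(15)
  data <- array(rnorm(26 * 28 * 60), dim = c(26, 28, 60))
  ep <- make_epochs(data, workload = rep(c("low", "high"), 13))
  model <- fit_csp(ep)
  expect_equal(dim(model$filters), c(12, 28))
  expect_equal(length(model$eigenvalues), 12)
})
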