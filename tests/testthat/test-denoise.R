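test_that("whitening yields an orthonormal column space", {
  set.seed(1)
  # a centered matrix with orthonormal columns is already white
  q <- svd(scale(matrix(rnorm(200), 50, 4), scale = FALSE))$u
  w <- whiten(q)
  expect_equal(w$Xw, q, tolerance = 1e-10)
  # duplicated column collapses to rank 1
  cdup <- cbind(rnorm(30), 0)
  cdup[, 2] <- cdup[, 1]
  expect_equal(whiten(cdup)$rank, 1)
  # random full-rank matrix: Gram matrix is the identity
  x <- matrix(rnorm(1000), 100, 10)
  g <- crossprod(whiten(x)$Xw)
  expect_lt(max(abs(g - diag(10))), 1e-8)
  expect_error(whiten(matrix(0, 10, 3)), "whiten")
})

test_that("concatenated-SVD singular values encode canonical correlations", {
  set.seed(2)
  x <- matrix(rnorm(400), 100, 4)
  # identical datasets: leading singular values sqrt(2), correlation 1
  m <- fit_cca(x, x)
  expect_equal(m$d[1:4], rep(sqrt(2), 4), tolerance = 1e-8)
  expect_equal(m$canonical_correlations, rep(1, 4), tolerance = 1e-8)
  # independent long series: largest correlation near zero
  set.seed(3)
  a <- matrix(rnorm(3000 * 3), 3000, 3)
  b <- matrix(rnorm(3000 * 3), 3000, 3)
  expect_lt(fit_cca(a, b)$canonical_correlations[1], 0.1)
  expect_error(fit_cca(a, b[-1, ]), "same number of time samples")
})

test_that("canonical correlations match the principal-angle oracle", {
  # oracle: singular values of t(Xf_white) %*% Xn_white are the cosines of
  # the principal angles between the two whitened column spaces
  for (seed in 1:5) {
    set.seed(seed)
    xf <- matrix(rnorm(50 * 8), 50, 8)
    xn <- 0.5 * xf[, sample(8)] + matrix(rnorm(50 * 8), 50, 8)
    m <- fit_cca(xf, xn)
    oracle <- svd(crossprod(whiten(xf)$Xw, whiten(xn)$Xw))$d
    expect_equal(m$canonical_correlations, oracle[seq_len(8)],
                 tolerance = 1e-8)
    expect_equal(m$d[1]^2 - 1, oracle[1], tolerance = 1e-8)
  }
})

test_that("noise removal is an idempotent orthogonal projection", {
  set.seed(4)
  x <- matrix(rnorm(80 * 6), 80, 6)
  m <- fit_cca(x, matrix(rnorm(80 * 4), 80, 4))
  xc <- scale(x, center = TRUE, scale = FALSE)
  attr(xc, "scaled:center") <- NULL
  # th = 0 returns the centered data unchanged
  expect_equal(remove_noise(x, m, 0), xc)
  d1 <- remove_noise(x, m, 3)
  # residual has no projection on the removed basis
  expect_lt(max(abs(crossprod(m$U[, 1:3], d1))), 1e-8)
  # idempotent
  expect_equal(remove_noise(d1, m, 3), d1, tolerance = 1e-10)
  # never increases column energy
  expect_true(all(colSums(d1^2) <= colSums(xc^2) + 1e-10))
  expect_error(remove_noise(x, m, ncol(m$U) + 1), "between 0 and")
})

test_that("planted signals survive removal of a known noise subspace", {
  set.seed(5)
  n <- 200
  m <- fit_cca(matrix(rnorm(n * 5), n, 5), matrix(rnorm(n * 4), n, 4))
  U3 <- m$U[, 1:3]
  planted <- scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)
  planted_perp <- planted - U3 %*% crossprod(U3, planted)
  xf <- planted_perp + U3 %*% matrix(rnorm(15), 3, 5)
  den <- remove_noise(xf, m, 3)
  rms <- sqrt(mean((den - scale(planted_perp, scale = FALSE))^2))
  expect_lt(rms, 1e-6)
})

test_that("motion correlation follows the textbook Pearson formula", {
  x <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  mo <- c(2, 1, 4, 3, 5)
  r <- motion_correlation(x, mo)
  manual <- sum((x - mean(x)) * (mo - mean(mo))) /
    sqrt(sum((x - mean(x))^2) * sum((mo - mean(mo))^2))
  expect_equal(r, manual)
  expect_equal(motion_correlation(cbind(mo), mo), 1)
  expect_error(motion_correlation(cbind(rep(1, 5)), mo), "zero-variance")
})

test_that("threshold selection sweeps the motion-correlation curve", {
  cfg <- fast_config()
  sim <- simulate_cohort(cfg, c(control = 3), seed = 21)
  # a vacuous cutoff accepts the first threshold
  rep1 <- select_threshold(sim$cohort, th_range = 1:5, cutoff = 1.0)
  expect_equal(rep1$th, 1)
  expect_equal(dim(rep1$curves), c(3L, 5L))
  expect_true(all(is.finite(rep1$curves)))
  # with no motion-correlated component at all, th* = 1 at the 0.1 cutoff
  quiet <- fast_config(burst_amp = 0, shared_amp = 0, drift_amp = 0)
  sim0 <- simulate_cohort(quiet, c(control = 3), seed = 22)
  expect_equal(select_threshold(sim0$cohort, th_range = 1:5)$th, 1)
  # an unreachable cutoff reports the best achieved correlation
  expect_error(select_threshold(sim$cohort, th_range = 1:2, cutoff = 1e-9),
               "best achieved")
})

test_that("strong planted motion components are removed within th <= 4", {
  cfg <- fast_config(burst_amp = 6, burst_rate = 8)
  sim <- simulate_cohort(cfg, c(control = 3), seed = 23)
  rep <- select_threshold(sim$cohort, th_range = 1:10)
  expect_lte(rep$th, 4)
  # the mean curve is below cutoff at the selection and was above before
  expect_lt(rep$mean_curve[rep$th], 0.1)
})

test_that("significance cutoff inverts Fisher's z-transform", {
  # alpha = 0.001 corresponds to z = 3.09 (one-tailed)
  expect_equal(qnorm(1 - 0.001), 3.09, tolerance = 0.001)
  expect_equal(significance_cutoff(957), tanh(qnorm(0.999) / sqrt(954)))
  expect_equal(significance_cutoff(957), 0.100, tolerance = 5e-3)
  # r_crit vanishes as n grows
  expect_lt(significance_cutoff(1e8), 1e-3)
  expect_error(significance_cutoff(3), "exceed 3")
})

test_that("bandpass filtering is zero-phase with the designed stop band", {
  fs <- 2.5
  t <- (0:2999) / fs
  inband <- sin(2 * pi * 0.05 * t)
  out <- bandpass_standardize(cbind(inband), fs)
  # standardized: mean ~0, sd ~1
  expect_lt(abs(mean(out)), 1e-10)
  expect_equal(sd(out[, 1]), 1, tolerance = 1e-10)
  # zero phase: cross-correlation with the input peaks at lag 0 (mid-series)
  mid <- 500:2500
  lags <- -3:3
  cc <- sapply(lags, function(l)
    cor(inband[mid], out[mid + l]))
  expect_equal(lags[which.max(cc)], 0)
  # stop-band: 0.5 Hz attenuated by > 20 dB relative to 0.05 Hz
  stopb <- sin(2 * pi * 0.5 * t)
  flt <- signal::butter(4, c(0.01, 0.1) / (fs / 2), type = "pass")
  g_pass <- sd(signal::filtfilt(flt, inband)[mid])
  g_stop <- sd(signal::filtfilt(flt, stopb)[mid])
  expect_gt(20 * log10(g_pass / g_stop), 20)
  # constant columns cannot be standardized
  expect_error(bandpass_standardize(cbind(rep(3, 100)), fs),
               "zero variance")
  expect_error(bandpass_standardize(cbind(inband), fs, band = c(0.01, 2)),
               "band")
})

test_that("GSR residuals are orthogonal to the global mean", {
  set.seed(6)
  x <- matrix(rnorm(500), 100, 5)
  res <- global_signal_regression(x)
  g <- rowMeans(x)
  expect_true(all(abs(cor(res, g)) < 1e-10))
  # identical columns leave nothing
  xid <- matrix(rep(rnorm(100), 4), 100, 4)
  expect_lt(max(abs(global_signal_regression(xid))), 1e-10)
})

test_that("motion censoring drops only supra-threshold epochs", {
  set.seed(7)
  x <- matrix(rnorm(200), 100, 2)
  mo <- abs(rnorm(100))
  mo[c(10, 50)] <- 50
  cm <- censor_motion_epochs(x, mo, z_thresh = 3)
  expect_false(cm$kept_mask[10] || cm$kept_mask[50])
  expect_equal(nrow(cm$X_kept), sum(cm$kept_mask))
  # zero motion: nothing censored
  cm0 <- censor_motion_epochs(x, rep(0, 100))
  expect_true(all(cm0$kept_mask))
})
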