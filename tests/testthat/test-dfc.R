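test_that("instantaneous phase tracks a sinusoid's analytic phase", {
  fs <- 2.5
  t <- (0:999) / fs
  ph <- instantaneous_phase(cos(2 * pi * 0.05 * t))
  # unwrapped phase advances at 2*pi*f rad/s away from the edges
  mid <- 100:900
  slope <- mean(diff(ph[mid]) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 0.05, tolerance = 0.01 * 2 * pi * 0.05)
  # sine lags cosine by pi/2 mid-series
  ps <- instantaneous_phase(sin(2 * pi * 0.05 * t))
  dphi <- Arg(exp(1i * (ps[mid] - ph[mid])))
  expect_equal(mean(dphi), -pi / 2, tolerance = 1e-3)
  # amplitude invariance
  x <- cos(2 * pi * 0.03 * t + 0.7)
  expect_equal(instantaneous_phase(2 * x), instantaneous_phase(x),
               tolerance = 1e-10)
  expect_error(instantaneous_phase(rep(1, 100)), "constant")
  expect_error(instantaneous_phase(rnorm(10)), "16")
})

test_that("synchronicity coefficients encode in-phase, quadrature, antiphase", {
  fs <- 2.5
  t <- (0:799) / fs
  base <- cos(2 * pi * 0.05 * t)
  mid <- 200:600
  # identical signals: coefficient 1 everywhere
  st1 <- synchronicity_stack(cbind(a = base, b = base), fs)
  expect_equal(st1$stack[mid, 1, 2], rep(1, length(mid)), tolerance = 1e-9)
  # quarter-cycle offset: coefficient ~0 mid-series
  st0 <- synchronicity_stack(cbind(a = base, b = sin(2 * pi * 0.05 * t)), fs)
  expect_equal(st0$stack[mid, 1, 2], rep(0, length(mid)), tolerance = 1e-3)
  # antiphase: coefficient ~ -1
  stm <- synchronicity_stack(cbind(a = base, b = -base), fs)
  expect_equal(stm$stack[mid, 1, 2], rep(-1, length(mid)), tolerance = 1e-6)
  # slices are symmetric with unit diagonal and entries in [-1, 1]
  set.seed(1)
  str <- synchronicity_stack(matrix(rnorm(300), 100, 3), fs)
  expect_true(all(abs(str$stack) <= 1 + 1e-12))
  expect_equal(str$stack[17, , ], t(str$stack[17, , ]))
  expect_equal(diag(str$stack[42, , ]), rep(1, 3))
})

test_that("vectorize and matrixify are exact inverses", {
  expect_equal(ncol(sync_vectorize(array(1, c(5, 7, 7)))), 21)
  expect_equal(ncol(sync_vectorize(array(1, c(5, 2, 2)))), 1)
  set.seed(2)
  m <- cor(matrix(rnorm(700), 100, 7))
  v <- sync_vectorize(array(m, c(1, 7, 7)))
  expect_equal(sync_matrixify(v[1, ]), m, ignore_attr = TRUE)
  expect_error(sync_matrixify(1:5), "triangular")
})

test_that("L1 k-means recovers planted clusters with median centroids", {
  set.seed(3)
  centers <- matrix(c(0, 0, 0, 10, 10, 0, 10, 10), 4, 2, byrow = TRUE)
  truth <- rep(1:4, each = 50)
  x <- centers[truth, ] + matrix(rnorm(400, sd = 0.5), 200, 2)
  km <- kmeans_l1(x, K = 4, repetitions = 10, seed = 5)
  mt <- match_states(km$centroids, centers)
  expect_gte(mean(mt$perm[km$labels] == truth), 0.99)
  # centroids are component-wise medians of their members
  for (k in 1:4) {
    members <- x[km$labels == k, , drop = FALSE]
    expect_equal(km$centroids[k, ], apply(members, 2, median),
                 tolerance = 1e-12)
  }
  # K = 1: centroid is the global component-wise median
  km1 <- kmeans_l1(x, K = 1, repetitions = 2, seed = 6)
  expect_equal(km1$centroids[1, ], apply(x, 2, median))
  # duplicating every point leaves centroids unchanged
  km2 <- kmeans_l1(rbind(x, x), K = 4, repetitions = 10, seed = 5)
  expect_equal(sort(km2$centroids[, 1]), sort(km$centroids[, 1]),
               tolerance = 1e-8)
  expect_error(kmeans_l1(x[1:3, ], K = 4), "exceeds")
})

test_that("the clustering solution is a fixed point of reassignment", {
  set.seed(4)
  x <- matrix(rnorm(600), 200, 3)
  km <- kmeans_l1(x, K = 4, repetitions = 5, seed = 7)
  expect_identical(assign_l1(x, km$centroids), km$labels)
  # states come back sorted by increasing occurrence
  expect_true(!is.unsorted(km$occurrence))
  expect_equal(sum(km$occurrence), 200)
  # cost equals the summed L1 distance to assigned centroids
  D <- sonostate:::l1_dist_to_centroids(x, km$centroids)
  expect_equal(km$cost, sum(D[cbind(1:200, km$labels)]))
})

test_that("LOOCV centroids stay close to full-data centroids on shared structure", {
  set.seed(8)
  offs <- default_state_offsets()[, 1:5]
  centers <- theoretical_state_vectors(offs)
  per_animal <- lapply(1:4, function(a) {
    truth <- rep(sample(1:4), each = 40)
    centers[truth, ] + matrix(rnorm(160 * 10, sd = 0.3), 160, 10)
  })
  names(per_animal) <- paste0("m", 1:4)
  lv <- loocv_states(per_animal, K = 4, repetitions = 10, seed = 9)
  expect_true(all(lv$per_state_distance < 0.5 * lv$d_inter))
  expect_true(all(lv$scores > 95))
  # one animal repeated: the fold data never changes, distances ~ 0
  dup <- rep(per_animal[1], 4)
  names(dup) <- paste0("d", 1:4)
  lvd <- loocv_states(dup, K = 4, repetitions = 10, seed = 10)
  expect_lt(max(lvd$per_state_distance), 1e-8)
  expect_error(loocv_states(per_animal[1:2], K = 4), "at least 3")
})

test_that("PCA embedding orders variance and reproduces degenerate cases", {
  # 1-D line: first component explains everything
  set.seed(11)
  line <- outer(rnorm(50), c(1, 2, -1))
  emb <- pca_embedding(line, n_components = 1)
  expect_equal(emb$explained_variance[1], 1, tolerance = 1e-10)
  expect_error(pca_embedding(line, n_components = 3), "rank")
  # isotropic 3-D cloud: three roughly equal fractions
  iso <- matrix(rnorm(3 * 4000), 4000, 3)
  e3 <- pca_embedding(iso, 3)
  expect_equal(e3$explained_variance, rep(1 / 3, 3), tolerance = 0.05)
  expect_true(!is.unsorted(rev(e3$explained_variance)))
})

test_that("fractional occupancy counts states exactly", {
  expect_equal(fractional_occupancy(c(1, 1, 2, 2, 2, 1), 2), c(0.5, 0.5))
  expect_equal(fractional_occupancy(rep(3, 10), 4), c(0, 0, 1, 0))
  set.seed(12)
  lab <- sample(1:4, 1e5, replace = TRUE)
  expect_equal(fractional_occupancy(lab, 4), rep(0.25, 4), tolerance = 0.01)
  expect_equal(sum(fractional_occupancy(lab, 4)), 1)
  expect_error(fractional_occupancy(c(1, 5), 4), "1..4")
})

test_that("mean dwell time averages run lengths in seconds", {
  expect_equal(mean_dwell_time(c(1, 1, 2, 2, 2, 1), 2, 2.5), c(0.6, 1.2))
  expect_equal(mean_dwell_time(rep(2, 100), 3, 2.5), c(NA, 40, NA))
  # geometric dwells: mean run length 1/(1-p) samples
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  lab <- simulate_state_sequence(P, 1e5, seed = 13)
  mdt <- mean_dwell_time(lab, 2, 2.5)
  expect_equal(mdt, rep(10 / 2.5, 2), tolerance = 0.1)
  # bookkeeping identity: MDT * n_runs = FO * T / fs
  r <- rle(c(1, 1, 2, 2, 2, 1))
  expect_equal(mean_dwell_time(c(1, 1, 2, 2, 2, 1), 2, 2.5)[1] *
                 sum(r$values == 1),
               fractional_occupancy(c(1, 1, 2, 2, 2, 1), 2)[1] * 6 / 2.5)
})

test_that("transition probabilities renormalize the off-diagonal jumps", {
  tp <- transition_probabilities(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(tp[1, 2], 1)
  expect_equal(tp[2, 1], 1)
  expect_true(all(is.na(diag(tp))))
  # constant sequence: every row undefined
  expect_true(all(is.na(transition_probabilities(rep(2, 10), 3))))
  # long simulated chain matches the conditional jump matrix
  P <- default_transition_matrix("control")
  jump <- P; diag(jump) <- 0; jump <- jump / rowSums(jump)
  lab <- simulate_state_sequence(P, 1e5, seed = 14)
  tp2 <- transition_probabilities(lab, 4)
  expect_lt(max(abs(tp2 - jump), na.rm = TRUE), 0.05)
  # defined rows sum to 1
  expect_equal(rowSums(tp2, na.rm = TRUE), rep(1, 4), tolerance = 1e-12)
})

test_that("biomarker table has one tidy row per animal", {
  labs <- list(a1 = c(1, 1, 2, 2, 2, 1), a2 = rep(1, 6))
  bm <- dfc_biomarkers(labs, K = 2, fs = 2.5,
                       groups = c(a1 = "g1", a2 = "g2"))
  expect_equal(nrow(bm), 2)
  expect_equal(bm$FO_1, c(0.5, 1))
  expect_equal(bm$MDT_2, c(1.2, NA))
  expect_equal(bm$TP_1_2[1], 1)
  expect_true(all(c("animal", "group", "TP_2_1") %in% names(bm)))
})
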