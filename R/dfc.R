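#' Instantaneous phase via the analytic signal
#'
#' Returns the argument of the Hilbert analytic signal, the per-sample phase
#' of a narrowband oscillation. The analytic signal is built in the Fourier
#' domain (negative frequencies zeroed, positive doubled).
#'
#' @param x numeric vector, length >= 16, with temporal variation.
#' @return Phase in radians, values in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("need at least 16 samples for phase estimation")
  if (stats::sd(x) == 0) stop("constant input has no phase")
  x <- x - mean(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  Arg(z)
}

#' Per-time-point synchronicity matrices
#'
#' For every time sample, the synchronicity between regions i and j is the
#' cosine of their instantaneous phase difference: 1 when in phase, 0 in
#' quadrature, -1 in antiphase.
#'
#' @param roi_series time-by-region matrix of (filtered, standardized)
#'   region-averaged signals; >= 2 regions.
#' @param fs sampling frequency, Hz.
#' @return An object of class `fus_sync_stack` with `stack`
#'   (T x R x R array), `phases` (T x R), `roi_names`, `fs`.
#' @export
synchronicity_stack <- function(roi_series, fs) {
  m <- as.matrix(roi_series)
  r <- ncol(m)
  if (r < 2) stop("need at least 2 regions")
  phases <- apply(m, 2, instantaneous_phase)
  n <- nrow(m)
  stack <- array(1, dim = c(n, r, r))
  for (i in seq_len(r - 1))
    for (j in (i + 1):r) {
      cij <- cos(phases[, i] - phases[, j])
      stack[, i, j] <- cij
      stack[, j, i] <- cij
    }
  nms <- colnames(m)
  if (is.null(nms)) nms <- paste0("ROI", seq_len(r))
  structure(list(stack = stack, phases = phases, roi_names = nms, fs = fs),
            class = "fus_sync_stack")
}

#' @export
print.fus_sync_stack <- function(x, ...) {
  cat("<fus_sync_stack> ", dim(x$stack)[1], " time points x ",
      length(x$roi_names), " regions (", paste(x$roi_names, collapse = ", "),
      ") @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

## upper-triangle (column-major) index pairs for an R x R matrix
upper_pairs <- function(r) {
  idx <- which(upper.tri(diag(r)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' Vectorize a synchronicity stack / rebuild a matrix from a vector
#'
#' Clustering operates on the unique off-diagonal entries of each
#' synchronicity matrix (the diagonal is identically 1). `sync_vectorize`
#' extracts them in upper-triangle raster (column-major) order, giving
#' `R(R-1)/2` features; `sync_matrixify` is its exact inverse.
#'
#' @param stack a `fus_sync_stack` or a T x R x R array.
#' @return `sync_vectorize`: T x R(R-1)/2 matrix with `"i-j"` colnames.
#' @export
sync_vectorize <- function(stack) {
  nms <- NULL
  if (inherits(stack, "fus_sync_stack")) {
    nms <- stack$roi_names
    stack <- stack$stack
  }
  d <- dim(stack)
  if (length(d) != 3 || d[2] != d[3]) stop("expected a T x R x R array")
  r <- d[2]
  ut <- which(upper.tri(diag(r)))
  out <- matrix(stack, d[1], r * r)[, ut, drop = FALSE]
  if (is.null(nms)) nms <- paste0("ROI", seq_len(r))
  pr <- upper_pairs(r)
  colnames(out) <- paste0(nms[pr[, 1]], "-", nms[pr[, 2]])
  out
}

#' @rdname sync_vectorize
#' @param v numeric vector of length `R(R-1)/2`.
#' @return `sync_matrixify`: R x R symmetric matrix with unit diagonal.
#' @export
sync_matrixify <- function(v) {
  l <- length(v)
  r <- (1 + sqrt(1 + 8 * l)) / 2
  if (abs(r - round(r)) > 1e-9)
    stop("vector length ", l, " is not triangular (R(R-1)/2)")
  r <- round(r)
  m <- diag(r)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

## all permutations of 1..k (k! x k matrix); used for exact centroid matching
permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))))
}

#' L1-norm k-means clustering of synchronicity vectors
#'
#' Best-of-`repetitions` k-means under the L1 (cityblock) distance:
#' each repetition initializes centroids at `K` distinct random data points,
#' alternates nearest-centroid assignment (lowest-index tie-break) with
#' component-wise-median centroid updates, and the solution with the lowest
#' total points-to-centroid distance wins. States are relabeled in order of
#' increasing total occurrence.
#'
#' @param vectors n x d numeric matrix (rows = synchronicity vectors).
#' @param K number of states (default 4).
#' @param iterations maximum assignment/update iterations per repetition.
#' @param repetitions number of random restarts.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `fus_cluster_model`: `K`, `centroids`
#'   (K x d, rows ordered by increasing occurrence), `labels`, `cost`
#'   (total within-cluster L1 distance), `occurrence`.
#' @export
kmeans_l1 <- function(vectors, K = 4, iterations = 100, repetitions = 100,
                      seed = NULL) {
  x <- as.matrix(vectors)
  n <- nrow(x)
  if (K > n) stop("K = ", K, " exceeds the number of points (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (rep in seq_len(repetitions)) {
    init <- sample.int(n, K)
    ## insist on distinct initial centroids when duplicates were drawn
    tries <- 0
    while (anyDuplicated(x[init, , drop = FALSE]) && tries < 100) {
      init <- sample.int(n, K)
      tries <- tries + 1
    }
    run <- kmeans_l1_run(x, init, as.integer(iterations))
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  occ <- tabulate(best$labels, K)
  ord <- order(occ)                       # increasing total occurrence
  relabel <- integer(K)
  relabel[ord] <- seq_len(K)
  structure(list(K = K,
                 centroids = best$centroids[ord, , drop = FALSE],
                 labels = relabel[best$labels],
                 cost = best$cost,
                 occurrence = occ[ord],
                 iterations = best$iterations),
            class = "fus_cluster_model")
}

#' @export
print.fus_cluster_model <- function(x, ...) {
  cat("<fus_cluster_model> K = ", x$K, ", ", length(x$labels),
      " points, total L1 cost ", round(x$cost, 2), "\n  occurrences: ",
      paste(x$occurrence, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign vectors to the nearest centroid (L1)
#'
#' @param vectors n x d matrix.
#' @param centroids K x d matrix.
#' @return Integer labels (lowest-index tie-break).
#' @export
assign_l1 <- function(vectors, centroids) {
  D <- l1_dist_to_centroids(as.matrix(vectors), as.matrix(centroids))
  max.col(-D, ties.method = "first")
}

#' Match cluster states to reference states
#'
#' Exact one-to-one assignment (over all permutations) minimizing the total
#' L1 distance between centroid rows.
#'
#' @param centroids K x d matrix of states to relabel.
#' @param reference K x d matrix of reference states.
#' @return list with `perm` (`perm[k]` = reference state matched to state
#'   k), `per_state_distance` and `total_distance`.
#' @export
match_states <- function(centroids, reference) {
  a <- as.matrix(centroids); b <- as.matrix(reference)
  k <- nrow(a)
  stopifnot(nrow(b) == k, ncol(b) == ncol(a))
  D <- l1_dist_to_centroids(a, b)         # k x k: D[i, j] = |a_i - b_j|_1
  per <- permutations(k)
  costs <- apply(per, 1, function(p) sum(D[cbind(seq_len(k), p)]))
  p <- per[which.min(costs), ]
  list(perm = p, per_state_distance = D[cbind(seq_len(k), p)],
       total_distance = min(costs))
}

#' Leave-one-animal-out robustness of the brain states
#'
#' Reclusters the stack with each animal left out, matches the fold
#' centroids to the full-data centroids (exact minimum-total-L1 one-to-one
#' assignment), and records (i) the per-state centroid displacement, to be
#' compared with the mean inter-centroid distance `d_inter`, and (ii) the
#' left-out animal's classification score: the percentage of its
#' synchronicity matrices assigned (nearest fold centroid) to the same state
#' as under the full clustering.
#'
#' @param per_animal_vectors named list of per-animal synchronicity-vector
#'   matrices (>= 3 animals).
#' @param K number of states.
#' @param iterations,repetitions k-means settings (reused in every fold).
#' @param seed integer seed.
#' @return An object of class `fus_loocv`: `per_state_distance`
#'   (animals x K), `scores` (%), `d_inter`, `full_model`.
#' @export
loocv_states <- function(per_animal_vectors, K = 4, iterations = 100,
                         repetitions = 100, seed = NULL) {
  if (length(per_animal_vectors) < 3) stop("need at least 3 animals")
  ids <- names(per_animal_vectors)
  if (is.null(ids)) ids <- paste0("animal", seq_along(per_animal_vectors))
  nvec <- vapply(per_animal_vectors, nrow, integer(1))
  all_x <- do.call(rbind, per_animal_vectors)
  animal_of <- rep(seq_along(ids), nvec)
  if (!is.null(seed)) set.seed(seed)
  full <- kmeans_l1(all_x, K = K, iterations = iterations,
                    repetitions = repetitions)
  dC <- l1_dist_to_centroids(full$centroids, full$centroids)
  d_inter <- mean(dC[upper.tri(dC)])
  dists <- matrix(NA_real_, length(ids), K,
                  dimnames = list(ids, paste0("state", seq_len(K))))
  scores <- stats::setNames(numeric(length(ids)), ids)
  for (a in seq_along(ids)) {
    train <- all_x[animal_of != a, , drop = FALSE]
    if (nrow(unique(train)) < K)
      stop("fold leaving out ", ids[a], " has fewer than K distinct vectors")
    fold <- kmeans_l1(train, K = K, iterations = iterations,
                      repetitions = repetitions)
    mt <- match_states(fold$centroids, full$centroids)
    dists[a, mt$perm] <- mt$per_state_distance
    test <- all_x[animal_of == a, , drop = FALSE]
    pred <- mt$perm[assign_l1(test, fold$centroids)]
    scores[a] <- 100 * mean(pred == full$labels[animal_of == a])
  }
  structure(list(per_state_distance = dists, scores = scores,
                 d_inter = d_inter, full_model = full),
            class = "fus_loocv")
}

#' @export
print.fus_loocv <- function(x, ...) {
  cat("<fus_loocv> ", nrow(x$per_state_distance), " folds; mean per-state ",
      "centroid distance ", round(mean(x$per_state_distance, na.rm = TRUE), 3),
      " vs d_inter ", round(x$d_inter, 3), "; classification scores ",
      round(min(x$scores), 1), "-", round(max(x$scores), 1), "%\n", sep = "")
  invisible(x)
}

#' PCA embedding of synchronicity vectors
#'
#' Mean-centered projection onto the leading principal components, used to
#' visualize the clustered state structure in 3D.
#'
#' @param vectors n x d matrix.
#' @param n_components number of components (default 3).
#' @return list with `coordinates` (n x n_components) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_embedding <- function(vectors, n_components = 3) {
  x <- as.matrix(vectors)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tol <- max(dim(x)) * .Machine$double.eps * p$sdev[1]
  if (sum(p$sdev > tol) < n_components)
    stop("data rank is below ", n_components, " components")
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
}

check_labels <- function(labels, K) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("`labels` must be non-empty")
  if (any(labels < 1 | labels > K | is.na(labels)))
    stop("labels must lie in 1..", K)
  labels
}

#' Fractional occupancy of each state
#'
#' @param labels integer state sequence (values in `1..K`).
#' @param K number of states.
#' @return Numeric vector of length K summing to 1.
#' @export
fractional_occupancy <- function(labels, K) {
  labels <- check_labels(labels, K)
  tabulate(labels, K) / length(labels)
}

#' Mean dwell time of each state, in seconds
#'
#' Average length of uninterrupted visits to the state divided by the
#' sampling frequency; `NA` for states that never occur.
#'
#' @param labels integer state sequence.
#' @param K number of states.
#' @param fs sampling frequency, Hz.
#' @return Numeric vector of length K (seconds).
#' @export
mean_dwell_time <- function(labels, K, fs) {
  labels <- check_labels(labels, K)
  r <- rle(labels)
  vapply(seq_len(K), function(k) {
    len <- r$lengths[r$values == k]
    if (!length(len)) NA_real_ else mean(len) / fs
  }, numeric(1))
}

#' State transition probabilities
#'
#' Off-diagonal transition counts over consecutive distinct-label pairs,
#' normalized per row by the total number of departures from the state.
#' Self-transitions are excluded; the diagonal is `NA`, as are rows of
#' states with no departures.
#'
#' @param labels integer state sequence.
#' @param K number of states.
#' @return K x K matrix; each defined row sums to 1.
#' @export
transition_probabilities <- function(labels, K) {
  labels <- check_labels(labels, K)
  C <- matrix(0, K, K)
  if (length(labels) > 1) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    jump <- from != to
    if (any(jump))
      for (t in which(jump)) C[from[t], to[t]] <- C[from[t], to[t]] + 1
  }
  dep <- rowSums(C)
  TP <- C / dep                  # rows with 0 departures become NaN
  TP[dep == 0, ] <- NA_real_
  diag(TP) <- NA_real_
  TP
}

#' Per-animal dynamic connectivity biomarkers
#'
#' Computes fractional occupancy, mean dwell time and transition
#' probabilities for every animal's state-label sequence and returns one
#' tidy row per animal.
#'
#' @param labels_list named list of per-animal integer label sequences.
#' @param K number of states.
#' @param fs sampling frequency, Hz.
#' @param groups optional named character vector of group labels.
#' @return data.frame with columns `animal`, `group`, `FO_k`, `MDT_k`
#'   (seconds) and `TP_i_j` for all ordered pairs i != j.
#' @export
dfc_biomarkers <- function(labels_list, K, fs, groups = NULL) {
  ids <- names(labels_list)
  if (is.null(ids)) ids <- paste0("animal", seq_along(labels_list))
  rows <- lapply(seq_along(labels_list), function(a) {
    lab <- labels_list[[a]]
    fo <- fractional_occupancy(lab, K)
    mdt <- mean_dwell_time(lab, K, fs)
    tp <- transition_probabilities(lab, K)
    out <- c(fo, mdt)
    names(out) <- c(paste0("FO_", seq_len(K)), paste0("MDT_", seq_len(K)))
    for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
      out[paste0("TP_", i, "_", j)] <- tp[i, j]
    as.data.frame(as.list(out))
  })
  df <- do.call(rbind, rows)
  df <- cbind(animal = ids,
              group = if (is.null(groups)) NA_character_
                      else unname(groups[ids]),
              df)
  rownames(df) <- NULL
  df
}
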