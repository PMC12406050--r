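#' SVD whitening of a pixel time-series matrix
#'
#' Columns are temporally centered, the matrix is decomposed with an economy
#' SVD, and singular values below `max(dim(X)) * eps * sigma_max` are
#' truncated (standard numerical-rank rule). The whitened matrix
#' `U %*% t(V)` spans the same column space as `X` but carries no amplitude
#' information, so the subsequent common-basis search maximizes correlation
#' rather than covariance.
#'
#' @param X time-by-pixel numeric matrix (>= 2 time samples).
#' @return list with `Xw` (whitened matrix), `rank` (retained rank), `U`
#'   (time-by-rank temporal basis), `V`, `d` (retained singular values) and
#'   `tol` (truncation tolerance used).
#' @export
whiten <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 time samples")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < .Machine$double.eps * 100) )
    stop("matrix has no temporal variation: nothing to whiten")
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  list(Xw = U %*% t(V), rank = r, U = U, V = V, d = sv$d[seq_len(r)],
       tol = tol)
}

#' Fit the CCA common-noise basis for a functional / noise pixel pair
#'
#' Both matrices are whitened, column-concatenated and decomposed with an
#' SVD. The leading left singular vectors are the temporal components most
#' correlated between the two pixel populations — the common physiological
#' noise and motion artifacts. For component i, the implied canonical
#' correlation is `d[i]^2 - 1` (clipped to `[0, 1]`).
#'
#' @param Xf time-by-pixel matrix of functional-region pixels.
#' @param Xn time-by-pixel matrix of noise-region pixels, same rows.
#' @return An object of class `fus_cca_model`: `U` (temporal basis), `d`
#'   (singular values, non-increasing), `V`, ranks of both whitened inputs
#'   and `canonical_correlations`.
#' @export
fit_cca <- function(Xf, Xn) {
  if (nrow(as.matrix(Xf)) != nrow(as.matrix(Xn)))
    stop("functional and noise matrices must have the same number of time samples")
  wf <- whiten(Xf)
  wn <- whiten(Xn)
  sv <- svd(cbind(wf$Xw, wn$Xw))
  rho <- pmin(pmax(sv$d^2 - 1, 0), 1)
  structure(list(U = sv$u, d = sv$d, V = sv$v,
                 rank_f = wf$rank, rank_n = wn$rank,
                 canonical_correlations = rho[seq_len(min(wf$rank, wn$rank))]),
            class = "fus_cca_model")
}

#' @export
print.fus_cca_model <- function(x, ...) {
  cat("<fus_cca_model> ranks ", x$rank_f, " (functional) + ", x$rank_n,
      " (noise); leading canonical correlations: ",
      paste(sprintf("%.3f", utils::head(x$canonical_correlations, 5)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Remove the common-noise subspace from functional pixel data
#'
#' Orthogonally projects the (column-centered) functional data away from the
#' first `th` temporal components of the CCA basis. The projection is
#' idempotent and never increases column-wise energy.
#'
#' @param Xf original functional pixel matrix (centered internally).
#' @param model a `fus_cca_model` fitted on the same time axis.
#' @param th noise-subspace dimension, `0 <= th <= ncol(model$U)`.
#' @return Denoised, column-centered matrix of the same shape as `Xf`.
#' @export
remove_noise <- function(Xf, model, th) {
  stopifnot(inherits(model, "fus_cca_model"))
  th <- as.integer(th)
  if (th < 0 || th > ncol(model$U))
    stop("`th` must be between 0 and the CCA rank (", ncol(model$U), ")")
  Xc <- scale(as.matrix(Xf), center = TRUE, scale = FALSE)
  attr(Xc, "scaled:center") <- NULL
  if (th == 0) return(Xc)
  U <- model$U[, seq_len(th), drop = FALSE]
  Xc - U %*% crossprod(U, Xc)
}

#' Correlation between denoised signal and tissue motion
#'
#' Pearson correlation between the pixel-averaged denoised functional signal
#' and the rectified tissue-motion magnitude trace; the quantity minimized
#' when selecting the denoising threshold.
#'
#' @param denoised_Xf denoised functional pixel matrix.
#' @param motion per-sample motion magnitude, same length as `nrow`.
#' @return Pearson correlation coefficient.
#' @export
motion_correlation <- function(denoised_Xf, motion) {
  m <- rowMeans(as.matrix(denoised_Xf))
  if (length(motion) != length(m))
    stop("motion trace and signal must have equal length")
  a <- abs(motion)
  if (stats::sd(m) == 0 || stats::sd(a) == 0)
    stop("undefined correlation: zero-variance input")
  stats::cor(m, a)
}

## fit the CCA model of one acquisition against its noise region
acquisition_cca <- function(acq, roi_set) {
  fi <- functional_pixels(acq, roi_set)
  ni <- noise_pixels(acq, roi_set)
  if (!length(fi) || !length(ni))
    stop("acquisition needs both functional and noise pixels")
  fit_cca(acq$signal[, fi, drop = FALSE], acq$signal[, ni, drop = FALSE])
}

#' Select the CCA denoising threshold from motion correlation
#'
#' For every candidate noise-subspace dimension in `th_range`, each animal's
#' functional data is denoised and correlated with its rectified
#' tissue-motion trace. The selected threshold is the smallest one whose
#' correlation, averaged over animals, falls below `cutoff` — i.e. the
#' smallest subspace that removes all motion-linked common components.
#'
#' @param cohort a `fus_cohort`.
#' @param th_range integer candidates (default `1:20`).
#' @param cutoff correlation cutoff (default 0.1, the significance level of
#'   a Pearson correlation at p < 0.001 one-tailed for ~1000 effective
#'   samples; see [significance_cutoff()]).
#' @param per_animal if `TRUE`, additionally report the smallest admissible
#'   threshold for each animal separately.
#' @return An object of class `fus_denoising_report`: `th` (selected
#'   cohort-wide threshold), `curves` (animals x thresholds correlation
#'   matrix), `mean_curve`, `cutoff`, and `th_per_animal` when requested.
#' @export
select_threshold <- function(cohort, th_range = 1:20, cutoff = 0.1,
                             per_animal = FALSE) {
  stopifnot(inherits(cohort, "fus_cohort"))
  roi <- cohort$roi_set
  ids <- names(cohort$acquisitions)
  curves <- matrix(NA_real_, length(ids), length(th_range),
                   dimnames = list(ids, paste0("th", th_range)))
  for (id in ids) {
    acq <- cohort$acquisitions[[id]]
    model <- acquisition_cca(acq, roi)
    Xf <- acq$signal[, functional_pixels(acq, roi), drop = FALSE]
    for (j in seq_along(th_range))
      curves[id, j] <- motion_correlation(
        remove_noise(Xf, model, th_range[j]), acq$motion)
  }
  mean_curve <- colMeans(curves)
  ok <- which(mean_curve < cutoff)
  if (!length(ok))
    stop("no threshold in the range achieves mean motion correlation < ",
         cutoff, " (best achieved: ", round(min(mean_curve), 4), " at th = ",
         th_range[which.min(mean_curve)], ")")
  th <- th_range[min(ok)]
  rep <- list(th = th, curves = curves, mean_curve = mean_curve,
              cutoff = cutoff, th_range = th_range)
  if (per_animal)
    rep$th_per_animal <- apply(curves, 1, function(v) {
      i <- which(v < cutoff)
      if (length(i)) th_range[min(i)] else NA_integer_
    })
  structure(rep, class = "fus_denoising_report")
}

#' @export
print.fus_denoising_report <- function(x, ...) {
  cat("<fus_denoising_report> selected th = ", x$th, " (cutoff ", x$cutoff,
      "); mean motion correlation at th: ",
      round(x$mean_curve[match(x$th, x$th_range)], 4), "\n", sep = "")
  invisible(x)
}

#' Critical correlation for significance via Fisher's z-transform
#'
#' Smallest Pearson correlation significant at level `alpha` (one-tailed)
#' for `n_effective` independent samples:
#' `r_crit = tanh(z_(1-alpha) / sqrt(n_effective - 3))`.
#'
#' @param n_effective effective number of independent samples (> 3).
#' @param alpha one-tailed significance level (default 0.001, i.e. z > 3.09).
#' @return Critical correlation coefficient.
#' @export
significance_cutoff <- function(n_effective, alpha = 0.001) {
  if (n_effective <= 3) stop("`n_effective` must exceed 3")
  tanh(stats::qnorm(1 - alpha) / sqrt(n_effective - 3))
}

#' Zero-phase Butterworth bandpass filtering and standardization
#'
#' Applies an order-`order` Butterworth bandpass forward and backward
#' (zero phase lag) to every column, then z-scores each column. The default
#' 0.01-0.1 Hz band isolates the hemodynamic fluctuations carrying
#' resting-state connectivity.
#'
#' @param X time-by-channel numeric matrix.
#' @param fs sampling frequency, Hz (must exceed twice the upper band edge).
#' @param band length-2 numeric, band edges in Hz.
#' @param order Butterworth design order for the single-pass filter (the
#'   forward-backward application doubles the effective order).
#' @return Filtered, standardized matrix (column mean 0, sd 1).
#' @export
bandpass_standardize <- function(X, fs, band = c(0.01, 0.1), order = 4) {
  X <- as.matrix(X)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("`band` must satisfy 0 < low < high < fs/2")
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  ## remove the DC offset first: the forward-backward filter assumes
  ## zero-padded ends, and a large baseline would ring far into the series
  Y <- apply(X, 2, function(col) signal::filtfilt(flt, col - mean(col)))
  sds <- apply(Y, 2, stats::sd)
  bad <- which(sds < 1e-12)
  if (length(bad))
    stop("zero variance after filtering in column(s): ",
         paste(bad, collapse = ", "))
  scale(Y, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Global signal regression baseline
#'
#' Regresses every column on the spatial-mean time course (with intercept)
#' and returns the residuals, which are exactly uncorrelated with the global
#' mean. Provided as the conventional nuisance-regression baseline against
#' which CCA denoising is compared.
#'
#' @param X time-by-pixel numeric matrix.
#' @return Residual matrix of the same shape.
#' @export
global_signal_regression <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("`X` must be non-empty")
  G <- cbind(1, rowMeans(X))
  X - G %*% solve(crossprod(G), crossprod(G, X))
}

#' Censor high-motion epochs
#'
#' Drops time samples whose standardized motion magnitude exceeds
#' `z_thresh`; the kept-sample mask is returned so downstream stages can
#' account for the discontinuities this introduces.
#'
#' @param X time-by-channel matrix.
#' @param motion per-sample motion magnitude.
#' @param z_thresh z-score threshold (default 3).
#' @return list with `X_kept` (censored matrix) and `kept_mask` (logical).
#' @export
censor_motion_epochs <- function(X, motion, z_thresh = 3) {
  X <- as.matrix(X)
  stopifnot(length(motion) == nrow(X))
  s <- stats::sd(motion)
  z <- if (s == 0) rep(0, length(motion)) else (motion - mean(motion)) / s
  keep <- z <= z_thresh
  list(X_kept = X[keep, , drop = FALSE], kept_mask = keep)
}

#' Denoise every acquisition of a cohort
#'
#' Applies the chosen preprocessing to the functional pixels of each
#' acquisition: `"cca"` removes the common-noise subspace at threshold `th`
#' (selected via [select_threshold()] when `th = "auto"`), `"gsr"` applies
#' global signal regression, `"none"` only centers. Noise-region pixels are
#' centered but otherwise untouched.
#'
#' @param cohort a `fus_cohort`.
#' @param method `"cca"`, `"gsr"` or `"none"`.
#' @param th integer CCA threshold or `"auto"`.
#' @param th_range,cutoff passed to [select_threshold()] for `th = "auto"`.
#' @return list with `cohort` (denoised), `method`, `th` and `report` (the
#'   `fus_denoising_report`, CCA only).
#' @export
denoise_cohort <- function(cohort, method = c("cca", "gsr", "none"),
                           th = "auto", th_range = 1:20, cutoff = 0.1) {
  method <- match.arg(method)
  roi <- cohort$roi_set
  report <- NULL
  if (method == "cca") {
    if (identical(th, "auto")) {
      report <- select_threshold(cohort, th_range = th_range, cutoff = cutoff)
      th <- report$th
    }
    th <- as.integer(th)
  }
  out <- cohort
  for (id in names(cohort$acquisitions)) {
    acq <- cohort$acquisitions[[id]]
    fi <- functional_pixels(acq, roi)
    sig <- scale(acq$signal, center = TRUE, scale = FALSE)
    attr(sig, "scaled:center") <- NULL
    if (method == "cca") {
      model <- acquisition_cca(acq, roi)
      sig[, fi] <- remove_noise(acq$signal[, fi, drop = FALSE], model, th)
    } else if (method == "gsr") {
      sig[, fi] <- global_signal_regression(acq$signal[, fi, drop = FALSE])
    }
    out$acquisitions[[id]]$signal <- sig
  }
  list(cohort = out, method = method,
       th = if (method == "cca") th else NA_integer_, report = report)
}
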