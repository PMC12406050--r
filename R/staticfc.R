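#' Pixel-wise correlation matrix partitioned by region role
#'
#' Computes the full Pearson correlation matrix between pixel time courses
#' and partitions it into the functional-to-functional, functional-to-noise
#' and noise-to-noise sub-blocks used to quantify denoising efficacy.
#'
#' @param X time-by-pixel numeric matrix.
#' @param pixel_labels integer region id per pixel.
#' @param roi_set a `fus_roi_set`.
#' @return An object of class `fus_corr_partition` with the full matrix,
#'   the two index sets and the three sub-matrices `ff`, `fn`, `nn`.
#' @export
pixel_correlation_matrix <- function(X, pixel_labels, roi_set) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds == 0)
  if (length(bad))
    stop("zero-variance pixel column(s): ", paste(bad, collapse = ", "))
  R <- stats::cor(X)
  fi <- which(pixel_labels %in% functional_ids(roi_set))
  ni <- which(pixel_labels %in% noise_ids(roi_set))
  structure(list(full = R, functional_idx = fi, noise_idx = ni,
                 ff = R[fi, fi, drop = FALSE],
                 fn = R[fi, ni, drop = FALSE],
                 nn = R[ni, ni, drop = FALSE]),
            class = "fus_corr_partition")
}

#' Percentage of correlations above a threshold
#'
#' For a within-set (square, symmetric) sub-matrix each unordered pixel pair
#' is counted once and the diagonal is excluded; for a cross-set
#' (rectangular) sub-matrix every entry is one pair.
#'
#' @param submatrix correlation sub-matrix.
#' @param threshold count entries strictly above this value (default 0.1).
#' @param within treat as within-set matrix; default: `TRUE` when the matrix
#'   is square and symmetric.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_above <- function(submatrix, threshold = 0.1, within = NULL) {
  m <- as.matrix(submatrix)
  if (!length(m)) stop("`submatrix` must be non-empty")
  if (is.null(within))
    within <- nrow(m) == ncol(m) && isSymmetric(unname(m), tol = 1e-12)
  vals <- if (within) m[upper.tri(m)] else as.vector(m)
  if (!length(vals)) stop("no off-diagonal pairs in `submatrix`")
  100 * mean(vals > threshold)
}

#' Seed-based correlation map
#'
#' Gaussian-smooths every frame of the image stack (sigma = FWHM / 2.355,
#' converted to pixels) and correlates each pixel's time course with the
#' mean time course over the seed pixels.
#'
#' @param X time-by-pixel matrix; columns raster the image column-major.
#' @param seed_pixels integer column indices forming the seed.
#' @param dims image dimensions `c(ny, nx)` with `ny * nx == ncol(X)`.
#' @param pixel_size_mm pixel pitch in mm (required; scanners differ).
#' @param fwhm_mm full width at half maximum of the smoothing kernel, mm.
#' @return `ny` x `nx` matrix of correlations with the seed.
#' @export
seed_map <- function(X, seed_pixels, dims, pixel_size_mm, fwhm_mm = 0.5) {
  X <- as.matrix(X)
  if (missing(dims) || missing(pixel_size_mm))
    stop("`dims` and `pixel_size_mm` are required to define pixel geometry")
  if (prod(dims) != ncol(X))
    stop("`dims` (", dims[1], " x ", dims[2], ") incompatible with ",
         ncol(X), " pixels")
  if (!length(seed_pixels)) stop("`seed_pixels` must be non-empty")
  sigma_px <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / pixel_size_mm
  if (sigma_px > 1e-3) {
    for (t in seq_len(nrow(X))) {
      img <- matrix(X[t, ], dims[1], dims[2])
      X[t, ] <- as.vector(EBImage::gblur(img, sigma = sigma_px))
    }
  }
  seed_tc <- rowMeans(X[, seed_pixels, drop = FALSE])
  matrix(stats::cor(X, seed_tc), dims[1], dims[2])
}

#' Nodal strength of an ROI correlation matrix
#'
#' The static-connectivity summary: `strength_i = sum_{j != i} r_ij`.
#'
#' @param roi_corr_matrix square symmetric correlation matrix.
#' @return Named numeric vector of per-ROI strengths.
#' @export
nodal_strength <- function(roi_corr_matrix) {
  m <- as.matrix(roi_corr_matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  rowSums(m) - diag(m)
}

#' Two-factor ANOVA of correlation percentages with Tukey post hoc
#'
#' Compares the percentage of supra-threshold correlations across denoising
#' condition (pre/post) and sub-matrix family (functional-to-functional /
#' functional-to-noise), with interaction, followed by Tukey's HSD.
#'
#' @param percentages data.frame with columns `animal`, `condition`,
#'   `pair`, `pct`.
#' @return list with the `aov` fit, a tidy ANOVA table and a tidy data.frame
#'   of Tukey contrasts for the interaction.
#' @export
correlation_anova <- function(percentages) {
  stopifnot(all(c("animal", "condition", "pair", "pct") %in%
                names(percentages)))
  d <- percentages
  d$condition <- factor(d$condition)
  d$pair <- factor(d$pair)
  fit <- stats::aov(pct ~ condition * pair, data = d)
  tab <- as.data.frame(summary(fit)[[1]])
  tab$term <- trimws(rownames(tab))
  tk <- stats::TukeyHSD(fit, "condition:pair")[[1]]
  tukey <- data.frame(contrast = rownames(tk), as.data.frame(tk),
                      row.names = NULL, check.names = FALSE)
  list(fit = fit, anova = tab[, c("term", "Df", "Sum Sq", "Mean Sq",
                                  "F value", "Pr(>F)")],
       tukey = tukey)
}
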