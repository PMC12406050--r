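#' Construct a single fUS acquisition
#'
#' An acquisition holds one resting-state Power-Doppler recording as a
#' time-by-pixel matrix (one column per pixel, values proportional to
#' cerebral blood volume), the per-pixel region labels, and the tissue-motion
#' magnitude trace estimated by the scanner.
#'
#' @param signal numeric matrix, rows = time samples, columns = pixels.
#' @param fs sampling frequency in Hz (Power-Doppler frame rate); default 2.5.
#' @param pixel_labels integer vector of region ids, one per pixel (column).
#' @param motion non-negative numeric vector of per-sample tissue-motion
#'   magnitude (arbitrary units), same length as `nrow(signal)`.
#' @param animal_id character scalar identifying the animal.
#' @param group character scalar group label (e.g. `"control"`, `"treated"`).
#' @return An object of class `fus_acquisition`.
#' @export
fus_acquisition <- function(signal, fs = 2.5, pixel_labels, motion,
                            animal_id = "animal", group = "control") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || !all(is.finite(signal)))
    stop("`signal` must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  pixel_labels <- as.integer(pixel_labels)
  if (length(pixel_labels) != ncol(signal))
    stop("`pixel_labels` must have one entry per pixel (column of `signal`): ",
         length(pixel_labels), " labels for ", ncol(signal), " pixels")
  if (anyNA(pixel_labels))
    stop("`pixel_labels` must not contain NA: every pixel needs one region id")
  motion <- as.numeric(motion)
  if (length(motion) != nrow(signal))
    stop("`motion` length (", length(motion), ") must equal the number of ",
         "time samples (", nrow(signal), ")")
  if (!all(is.finite(motion)) || any(motion < 0))
    stop("`motion` must be finite and non-negative")
  structure(
    list(signal = signal, fs = fs, pixel_labels = pixel_labels,
         motion = motion, animal_id = as.character(animal_id),
         group = as.character(group)),
    class = "fus_acquisition")
}

#' @export
print.fus_acquisition <- function(x, ...) {
  cat("<fus_acquisition> ", x$animal_id, " [", x$group, "]\n", sep = "")
  cat("  ", nrow(x$signal), " samples x ", ncol(x$signal), " pixels @ ",
      x$fs, " Hz (", round(nrow(x$signal) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Define the region-of-interest set
#'
#' Maps integer region ids to names and roles. Functional regions are the
#' brain structures entering the connectivity analysis; the noise region is
#' the extracerebral reference used by CCA denoising.
#'
#' @param ids integer region ids.
#' @param names character region names, same length as `ids`.
#' @param roles character, `"functional"` or `"noise"`, same length as `ids`.
#' @return An object of class `fus_roi_set` with components `table`
#'   (data.frame id/name/role) and `functional_order` (functional region
#'   names in analysis order).
#' @examples
#' default_roi_set()
#' @export
fus_roi_set <- function(ids, names, roles) {
  ids <- as.integer(ids)
  roles <- match.arg(roles, c("functional", "noise"), several.ok = TRUE)
  if (length(ids) != length(names) || length(ids) != length(roles))
    stop("`ids`, `names` and `roles` must have equal length")
  if (anyDuplicated(ids)) stop("region ids must be unique")
  if (anyDuplicated(names)) stop("region names must be unique")
  if (!any(roles == "functional") || !any(roles == "noise"))
    stop("need at least one functional and one noise region")
  tab <- data.frame(id = ids, name = as.character(names), role = roles,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 functional_order = tab$name[tab$role == "functional"]),
            class = "fus_roi_set")
}

#' Default seven-region ROI set plus one noise region
#'
#' The seven functional regions follow the sagittal imaging plane commonly
#' used in mouse fUS connectivity work: primary somatosensory (S1), primary
#' motor (M1), agranular insula (Ins), striatum (Str), hippocampus (HPC),
#' thalamus (TH) and cerebellar cortex (CC). Region id 0 is the
#' extracerebral noise region.
#' @return A `fus_roi_set`.
#' @export
default_roi_set <- function() {
  fus_roi_set(ids = 0:7,
              names = c("noise", "S1", "M1", "Ins", "Str", "HPC", "TH", "CC"),
              roles = c("noise", rep("functional", 7)))
}

#' @export
print.fus_roi_set <- function(x, ...) {
  cat("<fus_roi_set> functional: ",
      paste(x$functional_order, collapse = ", "), "; noise: ",
      paste(x$table$name[x$table$role == "noise"], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

functional_ids <- function(roi_set)
  roi_set$table$id[roi_set$table$role == "functional"]
noise_ids <- function(roi_set)
  roi_set$table$id[roi_set$table$role == "noise"]

#' Indices of functional / noise pixels of an acquisition
#' @param acq a `fus_acquisition`.
#' @param roi_set a `fus_roi_set`.
#' @return Integer column indices into `acq$signal`.
#' @export
functional_pixels <- function(acq, roi_set)
  which(acq$pixel_labels %in% functional_ids(roi_set))

#' @rdname functional_pixels
#' @export
noise_pixels <- function(acq, roi_set)
  which(acq$pixel_labels %in% noise_ids(roi_set))

#' Assemble a cohort of acquisitions
#'
#' @param acquisitions list of `fus_acquisition` objects sharing `fs`.
#' @param roi_set a `fus_roi_set` valid for all acquisitions.
#' @return An object of class `fus_cohort`.
#' @export
fus_cohort <- function(acquisitions, roi_set) {
  if (!length(acquisitions) || !all(vapply(acquisitions, inherits,
                                           logical(1), "fus_acquisition")))
    stop("`acquisitions` must be a non-empty list of fus_acquisition objects")
  if (!inherits(roi_set, "fus_roi_set")) stop("`roi_set` must be a fus_roi_set")
  fss <- vapply(acquisitions, `[[`, numeric(1), "fs")
  if (length(unique(fss)) != 1L)
    stop("all acquisitions must share the same sampling frequency")
  known <- roi_set$table$id
  for (a in acquisitions)
    if (!all(a$pixel_labels %in% known))
      stop("acquisition ", a$animal_id, " has pixel labels outside the ROI set")
  ids <- vapply(acquisitions, `[[`, character(1), "animal_id")
  if (anyDuplicated(ids)) stop("animal ids must be unique within a cohort")
  names(acquisitions) <- ids
  structure(list(acquisitions = acquisitions, roi_set = roi_set),
            class = "fus_cohort")
}

#' @export
print.fus_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat("<fus_cohort> ", length(x$acquisitions), " animals (",
      paste(sprintf("%s: %d", names(table(g)), table(g)), collapse = ", "),
      "), fs = ", x$acquisitions[[1]]$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Group label of every animal in a cohort
#' @param cohort a `fus_cohort`.
#' @return Named character vector (names = animal ids).
#' @export
cohort_groups <- function(cohort)
  vapply(cohort$acquisitions, `[[`, character(1), "group")

#' Average pixel time series within each functional region
#'
#' Produces the region-averaged CBV time courses that feed the phase-based
#' dynamic connectivity analysis: column r is the arithmetic mean over all
#' pixels labeled with functional region r, in the order fixed by the ROI set.
#'
#' @param signal time-by-pixel numeric matrix.
#' @param pixel_labels integer region id per pixel.
#' @param roi_set a `fus_roi_set`.
#' @return time-by-region matrix with `roi_set$functional_order` as colnames.
#' @export
roi_average <- function(signal, pixel_labels, roi_set) {
  signal <- as.matrix(signal)
  fid <- functional_ids(roi_set)
  fnames <- roi_set$functional_order
  out <- matrix(NA_real_, nrow(signal), length(fid),
                dimnames = list(NULL, fnames))
  for (k in seq_along(fid)) {
    cols <- which(pixel_labels == fid[k])
    if (!length(cols))
      stop("functional region '", fnames[k], "' has no pixels")
    out[, k] <- rowMeans(signal[, cols, drop = FALSE])
  }
  out
}

#' Trim the start and end of an acquisition
#'
#' Removes `trim_seconds` from both ends of the recording (signal and motion
#' trace), the standard guard against filter edge effects and settling
#' transients before phase analysis.
#'
#' @param acq a `fus_acquisition`.
#' @param trim_seconds seconds to drop at each end (default 30).
#' @return The trimmed `fus_acquisition`.
#' @export
crop_window <- function(acq, trim_seconds = 30) {
  stopifnot(inherits(acq, "fus_acquisition"))
  n <- nrow(acq$signal)
  k <- floor(trim_seconds * acq$fs)
  if (n <= 2 * k)
    stop("acquisition too short (", n, " samples) to trim ", trim_seconds,
         " s at each end")
  if (k == 0) return(acq)
  keep <- (k + 1):(n - k)
  acq$signal <- acq$signal[keep, , drop = FALSE]
  acq$motion <- acq$motion[keep]
  acq
}
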