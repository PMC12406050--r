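#' Save / load a cohort container
#'
#' A cohort is stored as a single versioned RDS container mirroring the
#' logical hierarchy `animals/<id>/{signal, motion}` with per-animal
#' attributes `{fs, group}` and `rois/{labels_table, functional_order}`.
#' A JSON sidecar (`<path>.schema.json`) documents the layout and dtypes.
#' The round trip is lossless for every field.
#'
#' @param cohort a `fus_cohort`.
#' @param path file path for the container (conventionally `.rds`).
#' @return `save_cohort` invisibly returns `path`; `load_cohort` returns the
#'   `fus_cohort`.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fus_cohort"))
  animals <- lapply(cohort$acquisitions, function(a)
    list(signal = a$signal, motion = a$motion, pixel_labels = a$pixel_labels,
         fs = a$fs, group = a$group))
  container <- list(
    version = 1L,
    animals = animals,
    rois = list(labels_table = cohort$roi_set$table,
                functional_order = cohort$roi_set$functional_order))
  saveRDS(container, path)
  schema <- list(
    format = "sonostate-cohort", version = 1L,
    layout = list(
      animals = "map: animal_id -> {signal: float64[time, pixel], motion: float64[time], pixel_labels: int32[pixel], fs: float64, group: utf8}",
      rois = "{labels_table: table(id int32, name utf8, role utf8), functional_order: utf8[]}"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort container: ", path)
  container <- readRDS(path)
  for (field in c("version", "animals", "rois"))
    if (is.null(container[[field]]))
      stop("malformed cohort container: missing field '", field, "'")
  for (field in c("labels_table", "functional_order"))
    if (is.null(container$rois[[field]]))
      stop("malformed cohort container: missing field 'rois/", field, "'")
  tab <- container$rois$labels_table
  roi_set <- fus_roi_set(tab$id, tab$name, tab$role)
  if (!identical(roi_set$functional_order,
                 as.character(container$rois$functional_order)))
    stop("malformed cohort container: 'rois/functional_order' disagrees ",
         "with the labels table")
  acqs <- lapply(names(container$animals), function(id) {
    a <- container$animals[[id]]
    for (field in c("signal", "motion", "pixel_labels", "fs", "group"))
      if (is.null(a[[field]]))
        stop("malformed cohort container: missing field 'animals/", id, "/",
             field, "'")
    fus_acquisition(a$signal, fs = a$fs, pixel_labels = a$pixel_labels,
                    motion = a$motion, animal_id = id, group = a$group)
  })
  fus_cohort(acqs, roi_set)
}

#' Export ROI-averaged time series as CSV
#'
#' Writes one row per time sample with a `time_s` column followed by one
#' column per functional region.
#'
#' @param acq a `fus_acquisition`.
#' @param roi_set a `fus_roi_set`.
#' @param path output CSV path.
#' @return Invisibly, the exported data.frame.
#' @export
export_roi_csv <- function(acq, roi_set, path) {
  m <- roi_average(acq$signal, acq$pixel_labels, roi_set)
  df <- data.frame(time_s = (seq_len(nrow(m)) - 1) / acq$fs, m,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
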