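#' Phase-based dynamic connectivity analysis of a preprocessed cohort
#'
#' For every animal: region-average the (denoised) pixel signals, bandpass
#' filter and standardize, trim the window edges, build the synchronicity
#' stack and vectorize it. All animals' vectors are then clustered together
#' with L1-norm k-means and per-animal state sequences and biomarkers are
#' extracted.
#'
#' @param cohort a `fus_cohort` (typically `denoise_cohort(...)$cohort`).
#' @param band,order bandpass settings (Hz / design order).
#' @param trim_seconds seconds trimmed from both window ends before phase
#'   analysis.
#' @param K,iterations,repetitions,seed clustering settings, see
#'   [kmeans_l1()].
#' @param censor_z if non-`NULL`, censor samples whose standardized motion
#'   exceeds this z-score before clustering (the epoch-suppression baseline);
#'   default `NULL` keeps the continuous time course.
#' @return An object of class `fus_dfc_result`: `model`
#'   (`fus_cluster_model`), `vectors` and `labels` (named per-animal lists),
#'   `biomarkers` (tidy data.frame), `fs`, `roi_names`.
#' @export
dfc_analysis <- function(cohort, band = c(0.01, 0.1), order = 4,
                         trim_seconds = 30, K = 4, iterations = 100,
                         repetitions = 100, seed = NULL, censor_z = NULL) {
  stopifnot(inherits(cohort, "fus_cohort"))
  roi <- cohort$roi_set
  fs <- cohort$acquisitions[[1]]$fs
  vectors <- list()
  for (id in names(cohort$acquisitions)) {
    acq <- cohort$acquisitions[[id]]
    ra <- roi_average(acq$signal, acq$pixel_labels, roi)
    bp <- bandpass_standardize(ra, fs, band = band, order = order)
    k <- floor(trim_seconds * fs)
    n <- nrow(bp)
    if (n <= 2 * k)
      stop("acquisition ", id, " too short for a ", trim_seconds, " s trim")
    keep <- (k + 1):(n - k)
    bp <- bp[keep, , drop = FALSE]
    v <- sync_vectorize(synchronicity_stack(bp, fs))
    if (!is.null(censor_z)) {
      cm <- censor_motion_epochs(v, acq$motion[keep], z_thresh = censor_z)
      v <- cm$X_kept
    }
    vectors[[id]] <- v
  }
  all_x <- do.call(rbind, vectors)
  animal_of <- rep(names(vectors), vapply(vectors, nrow, integer(1)))
  model <- kmeans_l1(all_x, K = K, iterations = iterations,
                     repetitions = repetitions, seed = seed)
  labels <- split(model$labels, factor(animal_of, levels = names(vectors)))
  bm <- dfc_biomarkers(labels, K = K, fs = fs, groups = cohort_groups(cohort))
  structure(list(model = model, vectors = vectors, labels = labels,
                 biomarkers = bm, fs = fs,
                 roi_names = roi$functional_order),
            class = "fus_dfc_result")
}

#' @export
print.fus_dfc_result <- function(x, ...) {
  cat("<fus_dfc_result> ", length(x$labels), " animals, K = ", x$model$K,
      "; state occurrences: ", paste(x$model$occurrence, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Validates every stage's parameters up front so a run can only fail on
#' data, not on configuration, and is written verbatim into the manifest of
#' every run for provenance.
#'
#' @param generator a `fus_generator_config`.
#' @param n_per_group named integer vector of animals per group.
#' @param method preprocessing method: `"cca"`, `"gsr"` or `"none"`.
#' @param th CCA threshold policy: `"auto"` or an integer.
#' @param band,order bandpass settings.
#' @param trim_seconds edge trim before phase analysis.
#' @param K,iterations,repetitions clustering settings.
#' @param alpha significance level for the group comparisons.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return A validated list of class `fus_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            n_per_group = c(control = 18, treated = 17),
                            method = c("cca", "gsr", "none"),
                            th = "auto", band = c(0.01, 0.1), order = 4,
                            trim_seconds = 30, K = 4, iterations = 100,
                            repetitions = 100, alpha = 0.05, seed = 1,
                            out_dir = tempfile("sonostate_run_")) {
  method <- match.arg(method)
  generator <- validate_generator_config(generator)
  stopifnot(band[1] > 0, band[2] < generator$fs / 2, band[1] < band[2],
            K >= 2, iterations >= 1, repetitions >= 1,
            alpha > 0, alpha < 1)
  if (!identical(th, "auto")) th <- as.integer(th)
  structure(list(generator = generator, n_per_group = n_per_group,
                 method = method, th = th, band = band, order = order,
                 trim_seconds = trim_seconds, K = K, iterations = iterations,
                 repetitions = repetitions, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "fus_pipeline_config")
}

run_stage <- function(name, manifest_env, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

#' Run the full analysis pipeline
#'
#' simulate -> denoise -> static connectivity -> dynamic states ->
#' group statistics and classification, persisting every intermediate
#' artifact plus a manifest (stages, seeds, config, file checksums) under
#' `config$out_dir`. Reruns with the same config reproduce every output.
#'
#' @param config a `fus_pipeline_config`.
#' @return Invisibly, a report bundle: cohort, denoising report, static
#'   summary, dfc result, comparison tables, classifier, manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fus_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- new.env()
  man$stages <- character()
  pth <- function(f) file.path(config$out_dir, f)

  sim <- run_stage("simulate", man, {
    s <- simulate_cohort(config$generator, config$n_per_group,
                         seed = config$seed)
    save_cohort(s$cohort, pth("cohort.rds"))
    s
  })

  den <- run_stage("denoise", man, {
    d <- denoise_cohort(sim$cohort, method = config$method, th = config$th)
    if (!is.null(d$report))
      jsonlite::write_json(
        list(selected_th = d$report$th, cutoff = d$report$cutoff,
             mean_curve = as.list(stats::setNames(d$report$mean_curve,
                                                  paste0("th", d$report$th_range))),
             curves = as.data.frame(d$report$curves)),
        pth("denoising_report.json"), auto_unbox = TRUE, digits = NA)
    d
  })

  staticfc <- run_stage("staticfc", man, {
    roi <- sim$cohort$roi_set
    rows <- lapply(names(sim$cohort$acquisitions), function(id) {
      pre <- pixel_correlation_matrix(
        sim$cohort$acquisitions[[id]]$signal,
        sim$cohort$acquisitions[[id]]$pixel_labels, roi)
      post <- pixel_correlation_matrix(
        den$cohort$acquisitions[[id]]$signal,
        den$cohort$acquisitions[[id]]$pixel_labels, roi)
      data.frame(animal = id,
                 condition = rep(c("pre", "post"), each = 2),
                 pair = rep(c("ff", "fn"), 2),
                 pct = c(fraction_above(pre$ff), fraction_above(pre$fn),
                         fraction_above(post$ff), fraction_above(post$fn)))
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, pth("staticfc.csv"), row.names = FALSE)
    tab
  })

  dfc <- run_stage("dfc", man, {
    r <- dfc_analysis(den$cohort, band = config$band, order = config$order,
                      trim_seconds = config$trim_seconds, K = config$K,
                      iterations = config$iterations,
                      repetitions = config$repetitions,
                      seed = config$seed + 1L,
                      censor_z = if (config$method == "gsr") 3 else NULL)
    utils::write.csv(r$biomarkers, pth("biomarkers.csv"), row.names = FALSE)
    r
  })

  stats_out <- run_stage("stats", man, {
    cmp <- list(fo = compare_fo(dfc$biomarkers),
                mdt = compare_mdt(dfc$biomarkers),
                tp = compare_tp(dfc$biomarkers))
    all_cmp <- do.call(rbind, cmp)
    utils::write.csv(all_cmp, pth("group_comparisons.csv"), row.names = FALSE)
    sig <- all_cmp$biomarker[all_cmp$significant]
    feats <- if (length(sig) >= 1) sig else paste0("FO_", seq_len(config$K - 1))
    X <- dfc$biomarkers[, feats, drop = FALSE]
    keep <- stats::complete.cases(X)
    clf <- fit_classifier(X[keep, , drop = FALSE],
                          factor(dfc$biomarkers$group[keep]))
    jsonlite::write_json(
      list(features = clf$features, auc = clf$auc, lrt_p = clf$lrt_p,
           youden = clf$roc$youden, roc = clf$roc$curve),
      pth("classifier.json"), auto_unbox = TRUE, digits = NA)
    list(comparisons = all_cmp, classifier = clf)
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sonostate")),
    stages = man$stages, seed = config$seed,
    method = config$method,
    selected_th = if (!is.null(den$report)) den$report$th else config$th,
    config = config_to_list(config),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cohort = sim$cohort, truth = sim$truth,
                 denoising = den, staticfc = staticfc, dfc = dfc,
                 comparisons = stats_out$comparisons,
                 classifier = stats_out$classifier, manifest = manifest))
}

## JSON-serializable view of a pipeline config (matrices -> row lists)
config_to_list <- function(config) {
  g <- config$generator
  list(generator = list(
         K = g$K,
         transition = lapply(g$transition, function(m) as.data.frame(m)),
         state_offsets = as.data.frame(g$state_offsets),
         carrier_freq = g$carrier_freq, carrier_amp = g$carrier_amp,
         pixels_per_roi = g$pixels_per_roi, noise_pixels = g$noise_pixels,
         noise_sd = g$noise_sd, shared_amp = g$shared_amp,
         drift_amp = g$drift_amp, burst_rate = g$burst_rate,
         burst_amp = g$burst_amp,
         motion_coupling = as.list(g$motion_coupling),
         motion_floor = g$motion_floor,
         phase_jitter_sd = g$phase_jitter_sd,
         blend_samples = g$blend_samples,
         duration = g$duration, fs = g$fs),
       n_per_group = as.list(config$n_per_group),
       method = config$method, th = config$th, band = config$band,
       order = config$order, trim_seconds = config$trim_seconds,
       K = config$K, iterations = config$iterations,
       repetitions = config$repetitions, alpha = config$alpha,
       seed = config$seed)
}
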