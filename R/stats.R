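## shared scaffolding for the biomarker group comparisons
comparison_row <- function(biomarker, x, y, gnames, test, p_raw, factor) {
  data.frame(
    biomarker = biomarker,
    group1 = gnames[1], mean1 = mean(x, na.rm = TRUE),
    sd1 = stats::sd(x[!is.na(x)]),
    group2 = gnames[2], mean2 = mean(y, na.rm = TRUE),
    sd2 = stats::sd(y[!is.na(y)]),
    test = test, p_raw = p_raw, bonferroni_factor = factor,
    p_corrected = if (is.na(p_raw)) NA_real_ else min(1, p_raw * factor),
    significant = !is.na(p_raw) && min(1, p_raw * factor) < 0.05,
    stringsAsFactors = FALSE)
}

split_groups <- function(biomarkers, min_n = 2) {
  g <- biomarkers$group
  gnames <- sort(unique(g))
  if (length(gnames) != 2)
    stop("expected exactly 2 groups, found: ", paste(gnames, collapse = ", "))
  sizes <- table(g)
  if (any(sizes < min_n))
    stop("each group needs at least ", min_n, " animals")
  list(gnames = gnames, idx1 = g == gnames[1], idx2 = g == gnames[2])
}

#' Group comparison of fractional occupancies
#'
#' Per-state two-sided independent-samples t-tests between the two groups,
#' Bonferroni-corrected with factor `K - 1` (the occupancies sum to one, so
#' only K - 1 are free).
#'
#' @param biomarkers data.frame from [dfc_biomarkers()] with a `group`
#'   column.
#' @param var_equal use the classic equal-variance t-test (default `TRUE`);
#'   set `FALSE` for Welch.
#' @return data.frame, one row per state, with group summaries, raw and
#'   corrected p-values and the Bonferroni factor applied.
#' @export
compare_fo <- function(biomarkers, var_equal = TRUE) {
  sg <- split_groups(biomarkers)
  K <- sum(grepl("^FO_", names(biomarkers)))
  factor <- K - 1
  out <- lapply(seq_len(K), function(k) {
    v <- biomarkers[[paste0("FO_", k)]]
    x <- v[sg$idx1]; y <- v[sg$idx2]
    p <- stats::t.test(x, y, var.equal = var_equal)$p.value
    comparison_row(paste0("FO_", k), x, y, sg$gnames, "t-test", p, factor)
  })
  do.call(rbind, out)
}

#' Group comparison of mean dwell times
#'
#' Per-state Mann-Whitney (Wilcoxon rank-sum) tests — dwell times are
#' bounded at zero and skewed — Bonferroni-corrected with factor `K`.
#' Animals whose state never occurred (missing MDT) are dropped pairwise;
#' a state missing in every animal is reported as not evaluable (`NA` p).
#'
#' @param biomarkers data.frame from [dfc_biomarkers()].
#' @return data.frame, one row per state.
#' @export
compare_mdt <- function(biomarkers) {
  sg <- split_groups(biomarkers)
  K <- sum(grepl("^MDT_", names(biomarkers)))
  out <- lapply(seq_len(K), function(k) {
    v <- biomarkers[[paste0("MDT_", k)]]
    x <- v[sg$idx1 & !is.na(v)]; y <- v[sg$idx2 & !is.na(v)]
    p <- if (!length(x) || !length(y)) NA_real_
         else suppressWarnings(stats::wilcox.test(x, y)$p.value)
    comparison_row(paste0("MDT_", k), x, y, sg$gnames, "mann-whitney", p, K)
  })
  do.call(rbind, out)
}

#' Group comparison of transition probabilities
#'
#' Per ordered state pair (i != j) two-sided independent t-tests,
#' Bonferroni-corrected with factor `(K - 1) * K` (the number of
#' off-diagonal transitions). Missing rows (states without departures in an
#' animal) are excluded pairwise.
#'
#' @inheritParams compare_fo
#' @return data.frame, one row per ordered pair.
#' @export
compare_tp <- function(biomarkers, var_equal = TRUE) {
  sg <- split_groups(biomarkers)
  tp_cols <- grep("^TP_\\d+_\\d+$", names(biomarkers), value = TRUE)
  K <- (1 + sqrt(1 + 4 * length(tp_cols))) / 2
  factor <- round((K - 1) * K)
  out <- lapply(tp_cols, function(cn) {
    v <- biomarkers[[cn]]
    x <- v[sg$idx1 & !is.na(v)]; y <- v[sg$idx2 & !is.na(v)]
    p <- if (length(x) < 2 || length(y) < 2) NA_real_
         else stats::t.test(x, y, var.equal = var_equal)$p.value
    comparison_row(cn, x, y, sg$gnames, "t-test", p, factor)
  })
  do.call(rbind, out)
}

#' ROC curve, AUC and Youden operating point
#'
#' Sweeps every threshold over the scores (predict positive when
#' `score >= threshold`). The AUC is computed by the trapezoid rule and
#' equals the Mann-Whitney concordance probability; the Youden point
#' maximizes `sensitivity + specificity - 1`, taking the lowest threshold
#' on ties.
#'
#' @param scores numeric classification scores (larger = more positive).
#' @param labels binary labels: logical, 0/1, or a 2-level factor whose
#'   second level is the positive class.
#' @return An object of class `fus_roc`: `curve` (data.frame threshold /
#'   fpr / tpr, from (0,0) to (1,1)), `auc`, `youden` (threshold,
#'   sensitivity, specificity, J).
#' @export
roc_analysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(th[best])]      # lowest threshold on ties
  structure(list(
    curve = data.frame(threshold = th, fpr = fpr, tpr = tpr),
    auc = auc,
    youden = list(threshold = th[best], sensitivity = tpr[best],
                  specificity = 1 - fpr[best], J = j[best])),
    class = "fus_roc")
}

#' @export
print.fus_roc <- function(x, ...) {
  cat("<fus_roc> AUC = ", round(x$auc, 3), "; Youden point: sensitivity ",
      round(100 * x$youden$sensitivity), "%, specificity ",
      round(100 * x$youden$specificity), "%\n", sep = "")
  invisible(x)
}

#' Logistic-regression biomarker classifier
#'
#' Fits a maximum-likelihood logistic regression of group membership on the
#' selected (standardized) biomarkers, tests it against the intercept-only
#' model with a likelihood-ratio chi-square, and evaluates the in-sample
#' classification with [roc_analysis()].
#'
#' @param features data.frame or matrix of numeric biomarker features
#'   (no missing values).
#' @param group_labels binary labels (2-level factor, logical or 0/1);
#'   for a factor, the second level is the positive class.
#' @return An object of class `fus_classifier`: `coefficients`
#'   (standardized scale), `coefficients_raw` (original scale), `lrt_p`,
#'   `roc` (a `fus_roc`), `auc`, `separation` flag, `fitted_probabilities`.
#' @export
fit_classifier <- function(features, group_labels) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("`features` must not contain missing values")
  if (is.factor(group_labels)) group_labels <- group_labels == levels(group_labels)[2]
  y <- as.numeric(as.logical(group_labels))
  if (length(unique(y)) != 2) stop("both classes must be present")
  mu <- colMeans(X); sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) stop("constant feature(s): ",
                           paste(colnames(X)[sdev == 0], collapse = ", "))
  Z <- scale(X, center = mu, scale = sdev)
  d <- data.frame(y = y, Z)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  null <- stats::glm(y ~ 1, family = stats::binomial(), data = d)
  lrt_p <- stats::pchisq(null$deviance - fit$deviance,
                         df = null$df.residual - fit$df.residual,
                         lower.tail = FALSE)
  beta <- stats::coef(fit)
  beta_raw <- beta
  beta_raw[-1] <- beta[-1] / sdev
  beta_raw[1] <- beta[1] - sum(beta[-1] * mu / sdev)
  probs <- stats::fitted(fit)
  if (all(pmin(probs, 1 - probs) < 1e-6)) separation <- TRUE
  roc <- roc_analysis(probs, y == 1)
  structure(list(features = colnames(X), coefficients = beta,
                 coefficients_raw = beta_raw, lrt_p = lrt_p, roc = roc,
                 auc = roc$auc, separation = separation,
                 fitted_probabilities = probs, fit = fit),
            class = "fus_classifier")
}

#' @export
print.fus_classifier <- function(x, ...) {
  cat("<fus_classifier> features: ", paste(x$features, collapse = ", "),
      "\n  LRT vs constant model: p = ", signif(x$lrt_p, 3),
      if (x$separation) "  (perfect separation flagged)" else "",
      "\n  AUC = ", round(x$auc, 3), "\n", sep = "")
  invisible(x)
}
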