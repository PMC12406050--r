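make_biomarkers <- function(fo1_a, fo1_b, seed = 1) {
  # two-group biomarker table with controlled FO_1; remaining mass split
  set.seed(seed)
  n_a <- length(fo1_a); n_b <- length(fo1_b)
  fo1 <- c(fo1_a, fo1_b)
  rest <- (1 - fo1) / 3
  labs <- NULL
  df <- data.frame(animal = paste0("m", seq_len(n_a + n_b)),
                   group = rep(c("g1", "g2"), c(n_a, n_b)),
                   FO_1 = fo1, FO_2 = rest, FO_3 = rest, FO_4 = rest)
  for (k in 1:4) df[[paste0("MDT_", k)]] <- abs(rnorm(n_a + n_b, 8, 2))
  for (i in 1:4) for (j in 1:4) if (i != j)
    df[[paste0("TP_", i, "_", j)]] <- runif(n_a + n_b, 0.2, 0.4)
  df
}

test_that("FO comparisons apply the K-1 Bonferroni factor", {
  set.seed(1)
  bm <- make_biomarkers(rnorm(6, 0.4, 0.05), rnorm(6, 0.4, 0.05))
  cmp <- compare_fo(bm)
  expect_equal(nrow(cmp), 4)
  expect_equal(unique(cmp$bonferroni_factor), 3)
  expect_equal(cmp$p_corrected, pmin(1, cmp$p_raw * 3))
  # identical groups on a noisy biomarker: not significant
  expect_false(any(cmp$significant[is.finite(cmp$p_raw)]))
  # a planted FO gap of 0.15 at sd 0.1 with n = 18/17 is usually flagged
  set.seed(2)
  hits <- 0
  for (r in 1:20) {
    bm2 <- make_biomarkers(pmin(0.95, pmax(0.01, rnorm(18, 0.37, 0.1))),
                           pmin(0.95, pmax(0.01, rnorm(17, 0.22, 0.1))),
                           seed = r)
    cmp2 <- compare_fo(bm2)
    if (cmp2$significant[1]) hits <- hits + 1
  }
  expect_gte(hits, 16)
  expect_error(compare_fo(make_biomarkers(0.4, c(0.4, 0.4))), "at least 2")
})

test_that("MDT comparisons use the exact rank-sum tail for separated groups", {
  set.seed(2)
  bm <- make_biomarkers(rnorm(8, 0.4, 0.05), rnorm(7, 0.4, 0.05))
  bm$MDT_1 <- c(11:18, 1:7)          # g1 strictly greater
  cmp <- compare_mdt(bm)
  expect_equal(unique(cmp$bonferroni_factor), 4)
  # exact two-sided rank-sum p for complete separation: 2 / choose(15, 8)
  expect_equal(cmp$p_raw[1], 2 / choose(15, 8))
  # a state missing everywhere is reported as not evaluable
  bm$MDT_3 <- NA_real_
  cmp2 <- compare_mdt(bm)
  expect_true(is.na(cmp2$p_raw[3]))
  expect_false(cmp2$significant[3])
})

test_that("TP comparisons cover the 12 ordered pairs with factor 12", {
  set.seed(3)
  bm <- make_biomarkers(rnorm(6, 0.4, 0.05), rnorm(6, 0.4, 0.05))
  cmp <- compare_tp(bm)
  expect_equal(nrow(cmp), 12)
  expect_equal(unique(cmp$bonferroni_factor), 12)
  expect_false(any(cmp$significant))
  # a planted difference in one entry is the one most often flagged
  set.seed(3)
  flags <- integer(12)
  for (r in 1:15) {
    bm2 <- make_biomarkers(rep(0.4, 18), rep(0.4, 17), seed = 100 + r)
    bm2$TP_1_2 <- c(rnorm(18, 0.36, 0.09), rnorm(17, 0.25, 0.09))
    cmp2 <- compare_tp(bm2)
    flags <- flags + cmp2$significant
  }
  expect_equal(which.max(flags), match("TP_1_2", cmp2$biomarker))
})

test_that("ROC analysis matches hand counts and the concordance oracle", {
  # separated toy scores: AUC 1 and a perfect Youden point
  r1 <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1)
  expect_equal(r1$youden$sensitivity, 1)
  expect_equal(r1$youden$specificity, 1)
  expect_equal(r1$youden$J, 1)
  # all-tied scores: AUC 1/2 by the tie convention
  r2 <- roc_analysis(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.5)
  # 6-point toy set: trapezoid AUC equals pair-counting concordance
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.6)
  lb <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  r3 <- roc_analysis(sc, lb)
  pos <- sc[lb]; neg <- sc[!lb]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(r3$auc, conc)
  # curve anchored at (0,0) and (1,1), monotone
  expect_equal(unlist(r3$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unname(unlist(r3$curve[nrow(r3$curve), c("fpr", "tpr")])),
               c(1, 1))
  expect_true(all(diff(r3$curve$fpr) >= 0) && all(diff(r3$curve$tpr) >= 0))
  expect_error(roc_analysis(sc, rep(TRUE, 6)), "both classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  set.seed(4)
  for (r in 1:5) {
    sc <- round(rnorm(40), 2)          # rounding forces ties
    lb <- rbinom(40, 1, 0.45) == 1
    if (length(unique(lb)) < 2) next
    ours <- roc_analysis(sc, lb)
    ref <- pROC::roc(response = lb, predictor = sc, quiet = TRUE,
                     direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("AUC flips under score negation and Youden satisfies its identity", {
  set.seed(5)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5) == 1
  lb[1:2] <- c(TRUE, FALSE)
  a1 <- roc_analysis(sc, lb); a2 <- roc_analysis(-sc, lb)
  expect_equal(a1$auc + a2$auc, 1)
  expect_equal(a1$youden$J, a1$youden$sensitivity + a1$youden$specificity - 1)
  expect_equal(a1$youden$J, max(a1$curve$tpr - a1$curve$fpr))
})

test_that("the logistic classifier separates, nulls, and flags separation", {
  # feature identical to the label: AUC 1 with separation flagged
  y <- factor(rep(c("a", "b"), each = 10))
  f <- data.frame(x = as.numeric(y) - 1)
  clf <- fit_classifier(f, y)
  expect_equal(clf$auc, 1)
  expect_true(clf$separation)
  # label-independent features: AUC near 1/2 and LRT non-significant on average
  set.seed(6)
  aucs <- c(); ps <- c()
  for (r in 1:20) {
    f0 <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
    y0 <- factor(rep(c("a", "b"), 20))
    c0 <- fit_classifier(f0, y0)
    aucs <- c(aucs, c0$auc); ps <- c(ps, c0$lrt_p)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_gt(mean(ps > 0.05), 0.6)
  # raw-scale coefficients reproduce the standardized fit
  set.seed(7)
  f1 <- data.frame(u = rnorm(60, sd = 3), v = rnorm(60, sd = 0.2))
  y1 <- factor(ifelse(f1$u + rnorm(60, sd = 2) > 0, "b", "a"))
  c1 <- fit_classifier(f1, y1)
  eta_raw <- c1$coefficients_raw[1] +
    as.matrix(f1) %*% c1$coefficients_raw[-1]
  expect_equal(as.numeric(1 / (1 + exp(-eta_raw))),
               unname(c1$fitted_probabilities), tolerance = 1e-8)
  expect_error(fit_classifier(data.frame(x = c(1, NA)), factor(c("a", "b"))),
               "missing")
})
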