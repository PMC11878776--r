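test_that("soft voting averages per-patch softmax probabilities", {
  z <- c(1.2, -0.3, 0.5, 2.0)
  one <- aggregate_slide(matrix(z, 1), "a")
  expect_equal(one$probs, exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_equal(one$n_patches, 1)
  # two extreme opposite patches average to (0.5, 0.5, 0, 0)
  two <- aggregate_slide(rbind(c(50, 0, 0, 0), c(0, 50, 0, 0)), "b")
  expect_equal(unname(two$probs), c(0.5, 0.5, 0, 0), tolerance = 1e-6)
  expect_error(aggregate_slide(matrix(0, 0, 4), "empty"), "empty")
})

test_that("aggregation matches brute-force mean-of-softmax and is
           permutation invariant", {
  set.seed(410)
  z <- matrix(rnorm(7 * 4, 0, 2), 7, 4)
  want <- rep(0, 4)
  for (i in 1:7) want <- want + exp(z[i, ]) / sum(exp(z[i, ]))
  want <- want / 7
  got <- aggregate_slide(z, "s")
  expect_equal(unname(got$probs), want, tolerance = 1e-12)
  expect_equal(sum(got$probs), 1, tolerance = 1e-9)
  shuf <- aggregate_slide(z[sample(7), ], "s")
  expect_equal(shuf$probs, got$probs, tolerance = 1e-12)
})

test_that("grouped splits partition slides with patients intact", {
  man <- toy_manifest(5, two_slide = FALSE)  # 20 single-slide patients
  folds <- kfold_split(man, k = 5, seed = 1)
  expect_length(folds, 5)
  test_sets <- lapply(folds, `[[`, "test_slide_ids")
  expect_equal(sort(unlist(test_sets)), sort(man$slide_id))
  for (f in folds) {
    expect_length(f$test_slide_ids, 4)
    expect_length(intersect(f$train_slide_ids, f$test_slide_ids), 0)
    expect_setequal(c(f$train_slide_ids, f$test_slide_ids), man$slide_id)
  }
  # a 2-slide patient never straddles the boundary
  man2 <- toy_manifest(4, two_slide = TRUE)
  for (f in kfold_split(man2, k = 4, seed = 3)) {
    for (p in unique(man2$patient_id)) {
      sl <- man2$slide_id[man2$patient_id == p]
      expect_true(all(sl %in% f$test_slide_ids) ||
                    all(sl %in% f$train_slide_ids))
    }
  }
  expect_error(kfold_split(toy_manifest(1, FALSE), k = 5, seed = 1),
               "folds")
})

test_that("fold class proportions stay within one slide of balance", {
  man <- toy_manifest(10, two_slide = FALSE)  # 40 slides, 10 per class
  folds <- kfold_split(man, k = 5, seed = 9)
  for (f in folds) for (cls in subtype_levels()) {
    n <- sum(vapply(f$test_slide_ids, function(s)
      man$subtype[man$slide_id == s] == cls, logical(1)))
    expect_true(abs(n - 2) <= 1)
  }
})

test_that("roc_auc handles perfect, tied and hand-counted cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                      FALSE)), 0.5)
  # 6 pairs with one tie: positives {0.9, 0.5, 0.3}, negatives
  # {0.5, 0.2, 0.1} -> pairs won: 3 + 1.5(tie 0.5) + ... enumerated
  s <- c(0.9, 0.5, 0.3, 0.5, 0.2, 0.1)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(s, l), auc_pair_oracle(s, l))
  expect_equal(auc_pair_oracle(s, l), (3 + 2.5 + 2) / 9)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both label values")
})

test_that("roc_auc equals the pair-counting oracle on random instances", {
  set.seed(411)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # provoke ties
    l <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    expect_equal(roc_auc(s, l), auc_pair_oracle(s, l), tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant to monotone transforms and flips with
           label complement", {
  set.seed(412)
  s <- runif(20); l <- c(TRUE, FALSE, runif(18) > 0.4)
  a <- roc_auc(s, l)
  expect_equal(roc_auc(exp(3 * s), l), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(s), l), a, tolerance = 1e-12)
  expect_equal(roc_auc(s, !l), 1 - a, tolerance = 1e-12)
})

test_that("roc_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(413)
  for (i in 1:20) {
    s <- round(runif(15), 2)
    l <- c(TRUE, FALSE, runif(13) > 0.5)
    ref <- as.numeric(pROC::auc(pROC::roc(as.integer(l), s,
                                          levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("macro AUROC is the arithmetic class mean", {
  expect_equal(macro_auroc(c(1, 1, 1, 1)), 1.0)
  expect_equal(macro_auroc(c(0.6, 0.7, 0.8, 0.9)), 0.75)
  set.seed(414)
  v <- runif(4)
  expect_equal(macro_auroc(v), sum(v) / 4, tolerance = 1e-12)
  expect_error(macro_auroc(c(0.5, NA, 0.5, 0.5)), "undefined")
})

test_that("fold CI follows the normal approximation and clips to [0,1]", {
  expect_equal(fold_ci(rep(0.8, 5)), c(mean = 0.8, low = 0.8, high = 0.8))
  v <- c(0.8, 0.9)
  half <- qnorm(0.975) * sd(v) / sqrt(2)
  expect_equal(fold_ci(v),
               c(mean = 0.85, low = 0.85 - half, high = 0.85 + half),
               tolerance = 1e-12)
  expect_lte(fold_ci(c(0.98, 1, 1))["high"], 1)
  expect_error(fold_ci(0.9), "at least 2")
})

test_that("threshold metrics recover a hand-built confusion", {
  classes <- subtype_levels()
  mk_preds <- function(calls) {
    p <- matrix(0.1, length(calls), 4,
                dimnames = list(NULL, paste0("p_", classes)))
    for (i in seq_along(calls)) p[i, paste0("p_", calls[i])] <- 0.7
    cbind(data.frame(slide_id = sprintf("s%d", seq_along(calls))),
          as.data.frame(p), n_patches = 1)
  }
  # MMRd one-vs-rest: TP=3, FP=1, FN=1, TN=5
  labels <- c(rep("MMRd", 4), rep("NSMP", 3), rep("p53abn", 3))
  calls <- c("MMRd", "MMRd", "MMRd", "NSMP",
             "MMRd", "NSMP", "NSMP", "p53abn", "p53abn", "p53abn")
  rep_ <- suppressWarnings(classification_metrics(mk_preds(calls), labels))
  row <- rep_$per_class[rep_$per_class$class == "MMRd", ]
  expect_equal(c(row$tp, row$fp, row$tn, row$fn), c(3, 1, 5, 1))
  expect_equal(row$precision, 0.75)
  expect_equal(row$recall, 0.75)
  expect_equal(row$sensitivity, 0.75)
  expect_equal(row$specificity, 5 / 6)
  expect_equal(row$npv, 5 / 6)
  expect_equal(rep_$accuracy, 8 / 10)
  # all-correct predictions give perfect scores
  perfect <- suppressWarnings(
    classification_metrics(mk_preds(labels), labels))
  expect_equal(perfect$accuracy, 1.0)
  expect_true(all(perfect$per_class$f1[1:3] == 1))
  # a class never predicted has undefined precision, reported NA
  expect_warning(classification_metrics(mk_preds(calls), labels),
                 "undefined")
  expect_true(is.na(rep_$per_class$precision[4]))
})

test_that("all metrics agree with an independent confusion tally", {
  classes <- subtype_levels()
  set.seed(415)
  n <- 20
  labels <- sample(classes, n, replace = TRUE)
  probs <- matrix(runif(n * 4), n, 4)
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("p_", classes)
  preds <- cbind(data.frame(slide_id = sprintf("s%d", 1:n)),
                 as.data.frame(probs), n_patches = 1)
  rep_ <- suppressWarnings(classification_metrics(preds, labels))
  hard <- classes[apply(probs, 1, which.max)]
  for (cls in classes) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in 1:n) {
      if (hard[i] == cls && labels[i] == cls) tp <- tp + 1
      if (hard[i] == cls && labels[i] != cls) fp <- fp + 1
      if (hard[i] != cls && labels[i] != cls) tn <- tn + 1
      if (hard[i] != cls && labels[i] == cls) fn <- fn + 1
    }
    row <- rep_$per_class[rep_$per_class$class == cls, ]
    expect_equal(c(row$tp, row$fp, row$tn, row$fn), c(tp, fp, tn, fn))
    if (tp + fp > 0) expect_equal(row$precision, tp / (tp + fp))
    if (tn + fp > 0) expect_equal(row$specificity, tn / (tn + fp))
  }
  expect_equal(rep_$accuracy, mean(hard == labels))
})

test_that("argmax ties resolve to the lowest class index", {
  classes <- subtype_levels()
  p <- matrix(0.25, 1, 4, dimnames = list(NULL, paste0("p_", classes)))
  preds <- cbind(data.frame(slide_id = "s1"), as.data.frame(p),
                 n_patches = 1)
  rep_ <- suppressWarnings(classification_metrics(preds, "MMRd"))
  expect_equal(rep_$accuracy, 1.0)  # tie went to MMRd, the first class
})

test_that("mean ROC interpolation pins endpoints and averages pointwise", {
  perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  m1 <- interp_roc(list(perfect))
  expect_equal(m1$tpr[m1$fpr > 0], rep(1, sum(m1$fpr > 0)))
  expect_equal(m1$tpr[m1$fpr == 0], 0)
  # two identical curves average to themselves
  c1 <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.4, 1))
  expect_equal(interp_roc(list(c1, c1)), interp_roc(list(c1)))
  # two hand-built curves: linear interpolation then pointwise mean
  c2 <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1))
  m <- interp_roc(list(c1, c2), grid = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(m$tpr, c(0, (0.2 + 0.4) / 2, (0.4 + 0.8) / 2,
                        (0.7 + 0.9) / 2, 1), tolerance = 1e-12)
  expect_error(interp_roc(list()), "no ROC")
})

test_that("roc_curve vertices integrate to the Mann-Whitney AUROC", {
  set.seed(416)
  s <- round(runif(25), 2)
  l <- c(TRUE, FALSE, runif(23) > 0.5)
  cv <- roc_curve(s, l)
  # trapezoidal integral of the step curve
  area <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
  expect_equal(area, roc_auc(s, l), tolerance = 1e-12)
})

test_that("bootstrap CI brackets the point estimate", {
  set.seed(417)
  s <- c(runif(15, 0.4, 1), runif(15, 0, 0.6))
  l <- rep(c(TRUE, FALSE), each = 15)
  ci <- bootstrap_ci(s, l, n_boot = 200, seed = 4)
  expect_lte(ci["low"], ci["mean"])
  expect_gte(ci["high"], ci["mean"])
})
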