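#' Soft-voting aggregation of patch logits into a slide prediction
#'
#' The slide-level probability of subtype j is the mean of the
#' per-patch softmax probabilities, `P_j = (1/N) sum_i softmax(z_i)_j`,
#' over the N hierarchical patches of the slide.
#'
#' @param logits `N x n_classes` matrix of patch logits for one slide.
#' @param slide_id slide identifier (used in error messages and the
#'   result).
#' @return an object of class `slide_prediction`: list with `slide_id`,
#'   `probs` (sums to 1) and `n_patches`.
#' @export
aggregate_slide <- function(logits, slide_id = "") {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (nrow(logits) == 0L)
    stop("no patch logits to aggregate for slide '", slide_id, "'")
  probs <- colMeans(softmax(logits))
  structure(list(slide_id = slide_id, probs = probs,
                 n_patches = nrow(logits)),
            class = "slide_prediction")
}

#' Aggregate patch logits into per-slide predictions
#'
#' @param logits matrix of patch logits.
#' @param slide_ids character vector (one entry per logit row).
#' @return data.frame with `slide_id`, one probability column per class
#'   (`p_<class>`) and `n_patches`, ordered by first appearance.
#' @export
aggregate_predictions <- function(logits, slide_ids) {
  stopifnot(nrow(logits) == length(slide_ids))
  ids <- unique(slide_ids)
  classes <- subtype_levels()[seq_len(ncol(logits))]
  out <- data.frame(slide_id = ids, stringsAsFactors = FALSE)
  pm <- matrix(0, length(ids), ncol(logits))
  np <- integer(length(ids))
  for (i in seq_along(ids)) {
    ag <- aggregate_slide(logits[slide_ids == ids[i], , drop = FALSE],
                          ids[i])
    pm[i, ] <- ag$probs
    np[i] <- ag$n_patches
  }
  colnames(pm) <- paste0("p_", classes)
  cbind(out, as.data.frame(pm), n_patches = np)
}

#' Patient-grouped stratified k-fold split
#'
#' Patients (never individual slides) are assigned to folds so that no
#' patient's slides ever straddle the train/test boundary; within each
#' subtype, patients are shuffled under the seed and dealt round-robin
#' to folds, which stratifies slide-level class counts as closely as
#' patient grouping allows.  Each fold's slides serve as the test set
#' exactly once (~20% at k = 5).
#'
#' @param manifest data.frame with `slide_id`, `patient_id`, `subtype`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of k `fold_split` objects with `fold_index` (0-based),
#'   `train_slide_ids`, `test_slide_ids`.
#' @export
kfold_split <- function(manifest, k = 5L, seed = 1L) {
  patients <- unique(manifest$patient_id)
  if (length(patients) < k)
    stop("cannot build ", k, " folds from ", length(patients), " patients")
  pat_class <- vapply(patients, function(p)
    manifest$subtype[manifest$patient_id == p][1L], character(1))
  fold_of <- integer(length(patients))
  names(fold_of) <- patients
  set_seed_pinned(derive_seed(seed, "kfold"))
  offset <- 0L
  for (cls in intersect(subtype_levels(), unique(pat_class))) {
    idx <- which(pat_class == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- (offset + seq_along(idx) - 1L) %% k
    offset <- offset + length(idx)
  }
  lapply(seq_len(k) - 1L, function(f) {
    test_pat <- patients[fold_of == f]
    test <- manifest$slide_id[manifest$patient_id %in% test_pat]
    structure(list(fold_index = f,
                   train_slide_ids = setdiff(manifest$slide_id, test),
                   test_slide_ids = test),
              class = "fold_split")
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted one half:
#' `P(s+ > s-) + 0.5 P(s+ = s-)`, computed from midranks.  Equivalent
#' to the trapezoidal integral of TPR over FPR.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a factor with the
#'   positive level equal to `positive`).
#' @param positive value of `labels` treated as positive.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both label values must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-average AUROC
#'
#' @param per_class numeric vector of class-wise AUROC values.
#' @return arithmetic mean.
#' @export
macro_auroc <- function(per_class) {
  if (anyNA(per_class)) stop("undefined class AUROC in macro average")
  mean(per_class)
}

#' Normal-approximation confidence interval over folds
#'
#' `mean +/- z * sd / sqrt(k)` across fold-level metric values, clipped
#' to `[0, 1]`.
#'
#' @param values k fold-level values (k >= 2).
#' @param conf confidence level.
#' @return named numeric: `mean`, `low`, `high`.
#' @export
fold_ci <- function(values, conf = 0.95) {
  k <- length(values)
  if (k < 2L) stop("need at least 2 fold values for a CI")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  m <- mean(values)
  half <- z * stats::sd(values) / sqrt(k)
  c(mean = m, low = max(0, m - half), high = min(1, m + half))
}

#' Bootstrap confidence interval over slides
#'
#' Percentile bootstrap of a metric over slide-level resamples; the
#' alternative to the across-fold normal approximation.
#'
#' @param scores,labels per-slide scores and binary labels.
#' @param metric function(scores, labels) -> value.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return named numeric: `mean`, `low`, `high`.
#' @export
bootstrap_ci <- function(scores, labels, metric = roc_auc,
                         n_boot = 1000L, conf = 0.95, seed = 1L) {
  set_seed_pinned(derive_seed(seed, "bootstrap"))
  n <- length(scores)
  vals <- numeric(n_boot)
  b <- 0L
  while (b < n_boot) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) next
    b <- b + 1L
    vals[b] <- metric(scores[idx], labels[idx])
  }
  a <- (1 - conf) / 2
  c(mean = metric(scores, labels),
    low = unname(stats::quantile(vals, a)),
    high = unname(stats::quantile(vals, 1 - a)))
}

#' ROC step curve
#'
#' @param scores,labels as in [roc_auc()].
#' @param positive positive label value.
#' @return data.frame with `fpr` and `tpr` step-curve vertices from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: both label values must be present")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tied scores to a single vertex
  last <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

#' Pointwise mean of ROC curves on a common FPR grid
#'
#' Each fold curve is linearly interpolated onto a fixed FPR grid and
#' the TPR values are averaged pointwise; endpoints are pinned to
#' (0, 0) and (1, 1).
#'
#' @param fold_curves list of data.frames with `fpr`, `tpr`.
#' @param grid FPR grid.
#' @return data.frame with `fpr` and mean `tpr`.
#' @export
interp_roc <- function(fold_curves, grid = seq(0, 1, by = 0.01)) {
  if (length(fold_curves) == 0L) stop("no ROC curves to interpolate")
  tprs <- vapply(fold_curves, function(cv) {
    if (nrow(cv) == 0L) stop("empty ROC curve")
    y <- stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max,
                       yleft = 0, yright = 1)$y
    y[grid == 0] <- 0
    y[grid == 1] <- 1
    y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

#' Threshold classification metrics from slide predictions
#'
#' Hard calls are the argmax of the slide probability vector (ties
#' resolved to the lowest class index).  Per class, one-vs-rest
#' confusion counts give precision, recall (= sensitivity),
#' specificity, NPV and F1; zero-denominator cells are reported as NA
#' (undefined), not zero, and excluded from macro averages with a
#' warning.
#'
#' @param preds prediction data.frame from [aggregate_predictions()].
#' @param labels character vector of true subtypes, aligned with
#'   `preds` rows.
#' @return list with `confusion` (4 x 4), `per_class` data.frame,
#'   `macro` named vector and `accuracy`.
#' @export
classification_metrics <- function(preds, labels) {
  if (nrow(preds) == 0L) stop("no predictions to score")
  classes <- subtype_levels()
  pcols <- paste0("p_", classes)
  probs <- as.matrix(preds[, pcols])
  hard <- classes[apply(probs, 1L, which.max)]
  confusion <- table(factor(labels, classes), factor(hard, classes))
  per <- lapply(classes, function(cls) {
    tp <- sum(hard == cls & labels == cls)
    fp <- sum(hard == cls & labels != cls)
    fn <- sum(hard != cls & labels == cls)
    tn <- sum(hard != cls & labels != cls)
    div <- function(a, b) if (b == 0) NA_real_ else a / b
    precision <- div(tp, tp + fp)
    recall <- div(tp, tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    data.frame(class = cls, tp = tp, fp = fp, tn = tn, fn = fn,
               precision = precision, recall = recall,
               sensitivity = recall,
               specificity = div(tn, tn + fp),
               npv = div(tn, tn + fn), f1 = f1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  metric_cols <- c("precision", "recall", "sensitivity", "specificity",
                   "npv", "f1")
  if (anyNA(per[, metric_cols]))
    warning("undefined metric cells (zero denominator) excluded from ",
            "macro averages")
  macro <- colMeans(per[, metric_cols], na.rm = TRUE)
  list(confusion = unclass(confusion), per_class = per, macro = macro,
       accuracy = mean(hard == labels))
}
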