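#' Extract patch-triple stem features for a whole cohort
#'
#' Streams the manifest slide by slide: reads image and mask, extracts
#' accepted tumor tiles, builds the three-scale triples (dropping tiles
#' whose selective sampling fails) and computes backbone stem features,
#' so that full-resolution pixel data never accumulates in memory.
#'
#' @param manifest cohort manifest data.frame.
#' @param filter a [filter_config()].
#' @param hierarchy a [hierarchy_config()].
#' @param backbone backbone registry key.
#' @param mask_downsample integer downsample factor of the stored masks.
#' @param verbose print per-slide tile accounting.
#' @return named list: feature matrices `l`, `m`, `s` and an `index`
#'   data.frame (`slide_id`, `x0`, `y0`, `ps_block_index`), plus a
#'   `log` data.frame of per-slide accepted/rejected tile counts.
#' @export
cohort_features <- function(manifest, filter = filter_config(),
                            hierarchy = hierarchy_config(),
                            backbone = "tiny", mask_downsample = 1L,
                            verbose = FALSE) {
  bb <- get_backbone(backbone)
  feats <- list(l = list(), m = list(), s = list())
  idx <- list()
  log_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    img <- read_slide_image(rec$image_path)
    msk <- read_mask(rec$mask_path)
    tiles <- extract_tiles(img, msk, filter, mask_downsample,
                           slide_id = rec$slide_id)
    n_disc <- 0L
    for (j in seq_len(nrow(tiles))) {
      x0 <- tiles$x0[j]; y0 <- tiles$y0[j]
      tile <- img[(y0 + 1L):(y0 + filter$tile_px),
                  (x0 + 1L):(x0 + filter$tile_px), , drop = FALSE]
      tr <- build_triple(tile, rec$slide_id, x0, y0, hierarchy)
      if (is.null(tr)) { n_disc <- n_disc + 1L; next }
      feats$l[[length(feats$l) + 1L]] <- bb$featurize(tr$p_l)
      feats$m[[length(feats$m) + 1L]] <- bb$featurize(tr$p_m)
      feats$s[[length(feats$s) + 1L]] <- bb$featurize(tr$p_s)
      idx[[length(idx) + 1L]] <- data.frame(
        slide_id = rec$slide_id, x0 = x0, y0 = y0,
        ps_block_index = tr$ps_block_index, stringsAsFactors = FALSE)
    }
    log_rows[[i]] <- data.frame(
      slide_id = rec$slide_id, n_accepted = nrow(tiles) - n_disc,
      n_rejected_background = attr(tiles, "n_rejected_background"),
      n_rejected_tumor = attr(tiles, "n_rejected_tumor"),
      n_discarded_ps = n_disc, stringsAsFactors = FALSE)
    if (verbose)
      message(rec$slide_id, ": ", nrow(tiles) - n_disc, " triples (",
              attr(tiles, "n_rejected_background"), " bg-rejected, ",
              attr(tiles, "n_rejected_tumor"), " tumor-rejected, ",
              n_disc, " quadrant-discarded)")
  }
  index <- if (length(idx)) do.call(rbind, idx) else
    data.frame(slide_id = character(), x0 = integer(), y0 = integer(),
               ps_block_index = integer())
  list(l = do.call(rbind, feats$l), m = do.call(rbind, feats$m),
       s = do.call(rbind, feats$s), index = index,
       log = do.call(rbind, log_rows))
}

#' Patient-grouped cross-validated training and evaluation
#'
#' Drives the split -> balance -> train -> predict -> evaluate loop:
#' class balancing is applied to the training fold only, a fresh model
#' is trained per fold, and test slides are scored by soft voting.
#' Fold-level class-wise and macro AUROCs are summarized with
#' across-fold normal-approximation CIs ([fold_ci()]).
#'
#' @param manifest cohort manifest data.frame.
#' @param features cohort feature set from [cohort_features()].
#' @param model_config a [hi_model_config()].
#' @param config a [train_config()].
#' @param k number of folds.
#' @param seed top-level seed; per-fold training and balancing seeds
#'   are derived from it.
#' @return an object of class `metrics_report`: list with `folds`
#'   (per-fold metrics), `summary` (per-class and macro AUROC mean/CI),
#'   `predictions` (pooled out-of-fold slide predictions),
#'   `threshold_metrics` (pooled [classification_metrics()]) and
#'   `roc_curves` (per-class mean interpolated curves).
#' @export
cross_validate <- function(manifest, features, model_config = hi_model_config(),
                           config = train_config(), k = 5L, seed = 1L) {
  folds <- kfold_split(manifest, k, seed)
  labeled <- inherit_labels(features$index, manifest)
  classes <- subtype_levels()
  fold_rows <- list()
  preds_all <- list()
  curves <- stats::setNames(vector("list", length(classes)), classes)
  for (fs in folds) {
    in_train <- labeled$slide_id %in% fs$train_slide_ids
    train_idx <- labeled[in_train, , drop = FALSE]
    train_idx$row <- which(in_train)
    balanced <- balance_patches(train_idx, config$balance_rates,
                                derive_seed(seed, paste0("balance_f",
                                                         fs$fold_index)))
    sub <- function(f, rows) f[rows, , drop = FALSE]
    tr_feats <- list(l = sub(features$l, balanced$row),
                     m = sub(features$m, balanced$row),
                     s = sub(features$s, balanced$row))
    mc <- model_config
    mc$seed <- derive_seed(seed, paste0("init_f", fs$fold_index))
    tc <- config
    tc$seed <- derive_seed(seed, paste0("train_f", fs$fold_index))
    fit <- train_model(hi_model(mc), tr_feats, balanced$label, tc)

    in_test <- labeled$slide_id %in% fs$test_slide_ids
    te_rows <- which(in_test)
    te_feats <- list(l = sub(features$l, te_rows),
                     m = sub(features$m, te_rows),
                     s = sub(features$s, te_rows))
    logits <- model_forward(fit$model, te_feats)$logits
    preds <- aggregate_predictions(logits, labeled$slide_id[te_rows])
    preds$label <- manifest$subtype[match(preds$slide_id,
                                          manifest$slide_id)]
    preds$fold <- fs$fold_index
    preds_all[[length(preds_all) + 1L]] <- preds

    # a fold whose test set misses a class (possible when patient
    # grouping fights stratification) gets NA for that class and for
    # its macro; summaries then average the defined folds
    auc <- vapply(classes, function(cls) {
      labs <- preds$label == cls
      if (length(unique(labs)) < 2L) {
        warning("fold ", fs$fold_index, ": class ", cls,
                " absent from the test set; AUROC undefined")
        return(NA_real_)
      }
      roc_auc(preds[[paste0("p_", cls)]], labs)
    }, numeric(1))
    for (cls in classes[!is.na(auc)])
      curves[[cls]][[length(curves[[cls]]) + 1L]] <-
        roc_curve(preds[[paste0("p_", cls)]], preds$label == cls)
    fold_rows[[length(fold_rows) + 1L]] <-
      data.frame(fold = fs$fold_index, t(auc),
                 macro = if (anyNA(auc)) NA_real_ else macro_auroc(auc),
                 check.names = FALSE)
  }
  fold_df <- do.call(rbind, fold_rows)
  ci_or_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(c(mean = NA_real_, low = NA_real_, high = NA_real_))
    if (length(v) == 1L) return(c(mean = v, low = NA_real_, high = NA_real_))
    fold_ci(v)
  }
  summary <- lapply(c(classes, "macro"), function(cl) ci_or_na(fold_df[[cl]]))
  names(summary) <- c(classes, "macro")
  preds_pooled <- do.call(rbind, preds_all)
  structure(list(
    folds = fold_df,
    summary = summary,
    predictions = preds_pooled,
    threshold_metrics = classification_metrics(preds_pooled,
                                               preds_pooled$label),
    roc_curves = lapply(curves, interp_roc)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-validated slide-level AUROC (mean [95% CI] over",
      nrow(x$folds), "folds)\n")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-8s %.3f [%.3f-%.3f]\n", nm, s["mean"], s["low"],
                s["high"]))
  }
  cat(sprintf("  pooled accuracy %.3f over %d slides\n",
              x$threshold_metrics$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' Assemble a run configuration
#'
#' A single container tying every stage configuration together with a
#' top-level seed; it round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]) and its stable hash
#' stamps every artifact a run writes.
#'
#' @param manifest_path path to the cohort manifest CSV.
#' @param workdir artifact directory.
#' @param filter a [filter_config()].
#' @param hierarchy a [hierarchy_config()].
#' @param model a [hi_model_config()].
#' @param train a [train_config()].
#' @param k folds.
#' @param seed top-level seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(manifest_path, workdir,
                       filter = filter_config(),
                       hierarchy = hierarchy_config(),
                       model = hi_model_config(),
                       train = train_config(),
                       k = 5L, seed = 1L) {
  structure(list(manifest_path = manifest_path, workdir = workdir,
                 filter = filter, hierarchy = hierarchy, model = model,
                 train = train, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Stable hash of a run configuration
#'
#' Fingerprints the analysis parameters (filtering, hierarchy, model,
#' training, folds, seed).  Artifact locations (`manifest_path`,
#' `workdir`) are excluded so that the same analysis run into two
#' directories produces identical, interchangeable artifacts.
#'
#' @param config a [run_config()] (or any list).
#' @return integer hash.
#' @export
config_hash <- function(config) {
  x <- unclass_rec(config)
  x$manifest_path <- NULL
  x$workdir <- NULL
  stable_hash(paste(deparse(x), collapse = ""))
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) return(lapply(x, unclass_rec))
  # integers widen to double so a JSON round trip is an exact identity
  if (is.integer(x)) storage.mode(x) <- "double"
  # named atomic vectors become JSON objects so their names survive
  if (!is.null(names(x))) return(as.list(x))
  x
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_rec(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    manifest_path = x$manifest_path, workdir = x$workdir,
    filter = do.call(filter_config, x$filter[setdiff(names(x$filter), NULL)]),
    hierarchy = hierarchy_config(
      source_px = x$hierarchy$source_px, mid_px = x$hierarchy$mid_px,
      block_px = x$hierarchy$block_px, target_px = x$hierarchy$target_px,
      color_filter = do.call(filter_config, x$hierarchy$color_filter)),
    model = do.call(hi_model_config, x$model),
    train = do.call(train_config, c(
      x$train[setdiff(names(x$train), "balance_rates")],
      list(balance_rates = unlist(x$train$balance_rates)))),
    k = x$k, seed = x$seed)
}

#' Run the full pipeline end to end
#'
#' Tile extraction, hierarchy and featurization, patient-grouped
#' cross-validation (balancing the training folds only), and metrics.
#' Artifacts written under `workdir`: `features_log.csv` (tile
#' accounting per slide), `predictions.csv` (pooled out-of-fold slide
#' probabilities), `metrics.json`, and `roc_<class>.csv` mean curves;
#' every artifact records the config hash and seed.  Re-running with an
#' identical configuration reproduces the metrics exactly.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the [cross_validate()] metrics report, invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$workdir) &&
      !dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create workdir: ", config$workdir)
  manifest <- read_manifest(config$manifest_path)
  if (length(unique(manifest$patient_id)) < config$k)
    stop("pipeline stage 'split': cannot build ", config$k,
         " folds from ", length(unique(manifest$patient_id)), " patients")
  hash <- config_hash(config)
  feats <- cohort_features(manifest, config$filter, config$hierarchy,
                           config$model$backbone, verbose = verbose)
  if (nrow(feats$index) == 0L)
    stop("pipeline stage 'hierarchy': no patch triples survived ",
         "filtering for any slide")
  report <- cross_validate(manifest, feats, config$model, config$train,
                           config$k, config$seed)
  stamp <- function(df) {
    df$config_hash <- hash; df$seed <- config$seed; df
  }
  utils::write.csv(stamp(feats$log),
                   file.path(config$workdir, "features_log.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(report$predictions),
                   file.path(config$workdir, "predictions.csv"),
                   row.names = FALSE)
  for (cls in names(report$roc_curves))
    utils::write.csv(report$roc_curves[[cls]],
                     file.path(config$workdir,
                               paste0("roc_", cls, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         folds = report$folds,
         summary = lapply(report$summary, as.list),
         accuracy = report$threshold_metrics$accuracy,
         macro_threshold_metrics =
           as.list(report$threshold_metrics$macro)),
    file.path(config$workdir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (verbose) print(report)
  invisible(report)
}
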