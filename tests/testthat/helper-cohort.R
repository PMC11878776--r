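# Shared fixtures, built in code.  The study cohort (40 slides, 10 per
# class) is expensive, so it is generated lazily once per test run and
# cached, together with its stem features, per-patch gray moments and
# the cross-validation results that several tests examine.

.cohort_cache <- new.env(parent = emptyenv())

study_cohort_spec <- function() {
  synthetic_cohort_spec(slides_per_class = 10, slide_px = 2048,
                        tumor_coverage = 0.85,
                        two_slide_patient_fraction = 0.3, seed = 11)
}

# gray-intensity first two moments of a patch: the feature space of the
# histogram-moment classifier used in the separability property test
patch_moments <- function(img) {
  g <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  c(mean(g), stats::sd(g))
}

study_cohort <- function() {
  if (!is.null(.cohort_cache$data)) return(.cohort_cache$data)
  spec <- study_cohort_spec()
  dir <- file.path(tempdir(), "hiwsi-study-cohort")
  manifest <- if (file.exists(file.path(dir, "manifest.csv")))
    read_manifest(file.path(dir, "manifest.csv"))
  else generate_cohort(spec, dir)

  feats <- list(l = list(), m = list(), s = list())
  idx <- list()
  moments <- list(l = list(), s = list())
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    img <- read_slide_image(rec$image_path)
    msk <- read_mask(rec$mask_path)
    tiles <- extract_tiles(img, msk, slide_id = rec$slide_id)
    for (j in seq_len(nrow(tiles))) {
      x0 <- tiles$x0[j]; y0 <- tiles$y0[j]
      tr <- build_triple(img[(y0 + 1):(y0 + 1024), (x0 + 1):(x0 + 1024), ],
                         rec$slide_id, x0, y0)
      if (is.null(tr)) next
      feats$l[[length(feats$l) + 1L]] <- stem_features(tr$p_l)
      feats$m[[length(feats$m) + 1L]] <- stem_features(tr$p_m)
      feats$s[[length(feats$s) + 1L]] <- stem_features(tr$p_s)
      moments$l[[length(moments$l) + 1L]] <- patch_moments(tr$p_l)
      moments$s[[length(moments$s) + 1L]] <- patch_moments(tr$p_s)
      idx[[length(idx) + 1L]] <- data.frame(
        slide_id = rec$slide_id, x0 = x0, y0 = y0,
        ps_block_index = tr$ps_block_index, stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, idx)
  .cohort_cache$data <- list(
    spec = spec, manifest = manifest,
    features = list(l = do.call(rbind, feats$l),
                    m = do.call(rbind, feats$m),
                    s = do.call(rbind, feats$s), index = index),
    moments = list(l = do.call(rbind, moments$l),
                   s = do.call(rbind, moments$s)),
    patch_class = sub("_[0-9]+$", "", index$slide_id),
    patch_slide = index$slide_id)
  .cohort_cache$data
}

# cross-validation of the full three-scale model and each single-scale
# variant on the study cohort, shared by the recovery and ablation tests
study_cv <- function() {
  if (!is.null(.cohort_cache$cv)) return(.cohort_cache$cv)
  co <- study_cohort()
  tc <- desk_profile(seed = 5)
  out <- list(three = cross_validate(co$manifest, co$features,
                                     hi_model_config(), tc, k = 5, seed = 5))
  for (sc in c("l", "m", "s"))
    out[[sc]] <- cross_validate(co$manifest, co$features,
                                hi_model_config(scales = sc), tc,
                                k = 5, seed = 5)
  .cohort_cache$cv <- out
  out
}

# uniform-intensity RGB patch
uniform_patch <- function(value, px = 64L) {
  array(value, c(px, px, 3L))
}

# 1024-px tile whose center-crop quadrants (scan order TL, TR, BL, BR)
# take the given uniform values; the outer margin takes `margin`
quadrant_tile <- function(values, margin = 150) {
  tile <- array(margin, c(1024L, 1024L, 3L))
  rows <- list(257:512, 257:512, 513:768, 513:768)
  cols <- list(257:512, 513:768, 257:512, 513:768)
  for (i in 1:4) tile[rows[[i]], cols[[i]], ] <- values[i]
  tile
}

# independent sort-based median oracle
median_oracle <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# independent O(n^2) pair-counting AUROC oracle
auc_pair_oracle <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# small in-memory manifest with two-slide patients, for split tests
toy_manifest <- function(n_per_class = 5L, two_slide = TRUE) {
  rows <- list()
  for (cls in subtype_levels()) {
    for (i in seq_len(n_per_class)) {
      pid <- sprintf("P_%s_%d", cls, if (two_slide) (i + 1L) %/% 2L else i)
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = sprintf("%s_%d", cls, i), patient_id = pid,
        image_path = "", mask_path = "", mpp = 0.549, subtype = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
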