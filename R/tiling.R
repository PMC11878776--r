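#' Tile filtering configuration
#'
#' Thresholds for the two tile-acceptance rules: the RGB median
#' background filter (reject tiles whose three channel medians all lie
#' above `median_high` -- white background -- or all below `median_low`
#' -- pen/black artifacts) and the strict majority tumor-fraction rule
#' (keep tiles with tumor fraction strictly greater than
#' `tumor_min_fraction`).
#'
#' The background-filter quantifier is configurable: the default
#' `"all"` rejects a tile only when all three channel medians violate
#' the same bound, which discards uniform white/black regions without
#' dropping eosin-dominant tissue where a single channel alone is
#' bright; `"any"` rejects on a single offending channel.
#'
#' @param median_low,median_high intensity bounds for the background
#'   filter (0--255 scale).
#' @param tumor_min_fraction minimum tumor fraction; the comparison is
#'   strict (`>`), so an exact 50/50 tile is rejected at the default.
#' @param tile_px tile side length at native resolution.
#' @param stride_px scan stride; equal to `tile_px` gives the default
#'   non-overlapping grid.
#' @param reject_quantifier `"all"` or `"any"` (see above).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(median_low = 100, median_high = 200,
                          tumor_min_fraction = 0.5,
                          tile_px = 1024L, stride_px = tile_px,
                          reject_quantifier = c("all", "any")) {
  reject_quantifier <- match.arg(reject_quantifier)
  stopifnot(median_low >= 0, median_low < median_high, median_high <= 255,
            tumor_min_fraction >= 0, tumor_min_fraction <= 1,
            tile_px >= 1, stride_px >= 1)
  structure(list(median_low = median_low, median_high = median_high,
                 tumor_min_fraction = tumor_min_fraction,
                 tile_px = as.integer(tile_px),
                 stride_px = as.integer(stride_px),
                 reject_quantifier = reject_quantifier),
            class = "filter_config")
}

#' Effective resolution after resampling
#'
#' Resampling a patch of `source_px` pixels down to `target_px` pixels
#' scales its microns-per-pixel by `source_px / target_px`.  At the
#' native 0.549 um/px this gives 2.509 um/px for the full-tile view
#' (1024 to 224), 1.255 for the center-crop view (512 to 224) and 0.627
#' for the quadrant view (256 to 224).
#'
#' @param native_mpp native resolution in microns per pixel.
#' @param source_px,target_px source and target side lengths in pixels.
#' @return effective microns per pixel.
#' @export
effective_mpp <- function(native_mpp, source_px, target_px) {
  if (any(c(native_mpp, source_px, target_px) <= 0))
    stop("effective_mpp arguments must be positive")
  native_mpp * source_px / target_px
}

#' Per-channel medians of an RGB patch
#'
#' @param patch H x W x 3 intensity array (0--255).
#' @return numeric vector of 3 channel medians.
#' @export
channel_medians <- function(patch) {
  check_rgb(patch)
  c(stats::median(patch[, , 1L]), stats::median(patch[, , 2L]),
    stats::median(patch[, , 3L]))
}

#' Background filter decision for one patch
#'
#' Computes the median of each RGB channel over all pixels and rejects
#' the patch when the medians exceed `median_high` (bright background)
#' or fall below `median_low` (dark artifact), under the configured
#' quantifier.
#'
#' @param patch H x W x 3 intensity array (0--255).
#' @param config a [filter_config()].
#' @return list with `keep` (logical) and `medians` (length-3 numeric,
#'   for logging).
#' @export
passes_background_filter <- function(patch, config = filter_config()) {
  med <- channel_medians(patch)
  list(keep = !medians_reject(med, config), medians = med)
}

medians_reject <- function(med, config) {
  comb <- if (config$reject_quantifier == "all") all else any
  comb(med > config$median_high) || comb(med < config$median_low)
}

#' Tumor fraction of a tile box on a mask
#'
#' Fraction of the tile box covered by the tumor mask, computed on the
#' mask's own grid: the level-0 box `[x0, x0 + tile_px) x [y0, y0 +
#' tile_px)` is mapped to mask pixels by nearest-pixel (floor) indexing
#' with the stated integer downsample factor -- no mask interpolation.
#'
#' @param mask 0/1 matrix (rows = y, cols = x).
#' @param x0,y0 0-based level-0 pixel coordinates of the tile origin.
#' @param tile_px tile side length in level-0 pixels.
#' @param downsample integer downsample factor of the mask relative to
#'   level 0 (1 = full resolution).
#' @return fraction in `[0, 1]`.
#' @export
tumor_fraction <- function(mask, x0, y0, tile_px = 1024L, downsample = 1L) {
  stopifnot(is.matrix(mask), downsample >= 1)
  rows <- (floor(y0 / downsample):floor((y0 + tile_px - 1) / downsample)) + 1L
  cols <- (floor(x0 / downsample):floor((x0 + tile_px - 1) / downsample)) + 1L
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > nrow(mask) || max(cols) > ncol(mask))
    stop("tile box [", x0, ", ", x0 + tile_px, ") x [", y0, ", ",
         y0 + tile_px, ") falls outside the mask extent")
  mean(mask[rows, cols])
}

#' Extract accepted tumor tiles from a slide
#'
#' Scans the non-overlapping tile grid in row-major order (y outer, x
#' inner; 0-based, half-open boxes) and keeps tiles that pass both the
#' background filter and the strict tumor-fraction rule.  The scan is
#' fully deterministic: the same slide and configuration always yield
#' the same tile list in the same order.
#'
#' @param image H x W x 3 intensity array (0--255).
#' @param mask 0/1 tumor mask matrix.
#' @param config a [filter_config()].
#' @param mask_downsample integer downsample factor of the mask.
#' @param slide_id slide identifier recorded in the output.
#' @return data.frame with columns `slide_id`, `x0`, `y0`,
#'   `tumor_fraction`, `med_r`, `med_g`, `med_b` (accepted tiles only),
#'   plus attributes `n_rejected_background` and `n_rejected_tumor`.
#' @export
extract_tiles <- function(image, mask, config = filter_config(),
                          mask_downsample = 1L, slide_id = "") {
  check_rgb(image, "slide image")
  d <- dim(image)
  tp <- config$tile_px
  if (d[1L] < tp || d[2L] < tp)
    stop("slide (", d[1L], " x ", d[2L], ") is smaller than one ",
         tp, "-px tile")
  ys <- seq(0L, d[1L] - tp, by = config$stride_px)
  xs <- seq(0L, d[2L] - tp, by = config$stride_px)
  out <- list()
  n_bg <- 0L; n_tum <- 0L
  for (y0 in ys) for (x0 in xs) {
    rows <- (y0 + 1L):(y0 + tp); cols <- (x0 + 1L):(x0 + tp)
    med <- c(stats::median(image[rows, cols, 1L]),
             stats::median(image[rows, cols, 2L]),
             stats::median(image[rows, cols, 3L]))
    if (medians_reject(med, config)) { n_bg <- n_bg + 1L; next }
    tf <- tumor_fraction(mask, x0, y0, tp, mask_downsample)
    if (!(tf > config$tumor_min_fraction)) { n_tum <- n_tum + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      slide_id = slide_id, x0 = x0, y0 = y0, tumor_fraction = tf,
      med_r = med[1L], med_g = med[2L], med_b = med[3L],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(slide_id = character(), x0 = integer(), y0 = integer(),
               tumor_fraction = numeric(), med_r = numeric(),
               med_g = numeric(), med_b = numeric())
  attr(res, "n_rejected_background") <- n_bg
  attr(res, "n_rejected_tumor") <- n_tum
  res
}

#' Extract tiles for one manifest record, reading from disk
#'
#' @param record one-row data.frame (or list) with `slide_id`,
#'   `image_path`, `mask_path`.
#' @param config a [filter_config()].
#' @param mask_downsample integer downsample factor of the stored mask.
#' @return as [extract_tiles()].
#' @export
extract_tiles_record <- function(record, config = filter_config(),
                                 mask_downsample = 1L) {
  img <- read_slide_image(record$image_path)
  msk <- read_mask(record$mask_path)
  extract_tiles(img, msk, config, mask_downsample,
                slide_id = record$slide_id)
}
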