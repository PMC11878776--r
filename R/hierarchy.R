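#' Patch hierarchy configuration
#'
#' Geometry of the three-scale patch hierarchy built from each accepted
#' 1024-px tile: the full tile (large view), its exact center 512-px
#' crop (medium view), and one of that crop's four 256-px quadrants
#' chosen by selective sampling (small view); all three are
#' area-averaged down to `target_px`.  The quadrant scan order is fixed
#' as row-major -- top-left, top-right, bottom-left, bottom-right -- and
#' the selective-sampling color criterion reuses the background filter
#' thresholds, the only intensity bounds the preprocessing defines.
#'
#' @param source_px source tile side (1024).
#' @param mid_px center-crop side (`source_px / 2`).
#' @param block_px quadrant side (`mid_px / 2`).
#' @param target_px model input side (224).
#' @param color_filter a [filter_config()] used as the quadrant color
#'   criterion.
#' @return an object of class `hierarchy_config`.
#' @export
hierarchy_config <- function(source_px = 1024L, mid_px = source_px / 2L,
                             block_px = mid_px / 2L, target_px = 224L,
                             color_filter = filter_config()) {
  stopifnot(mid_px == source_px / 2, block_px == mid_px / 2,
            target_px < block_px)
  structure(list(source_px = as.integer(source_px),
                 mid_px = as.integer(mid_px),
                 block_px = as.integer(block_px),
                 target_px = as.integer(target_px),
                 color_filter = color_filter),
            class = "hierarchy_config")
}

check_tile <- function(tile, px) {
  d <- dim(tile)
  if (length(d) != 3L || d[1L] != px || d[2L] != px || d[3L] != 3L)
    stop("tile must be ", px, " x ", px, " x 3, got [",
         paste(d, collapse = ", "), "]")
  invisible(tile)
}

#' Large-scale view: direct downsample of the full tile
#'
#' @param tile 1024 x 1024 x 3 intensity array.
#' @param config a [hierarchy_config()].
#' @return `target_px` x `target_px` x 3 array.
#' @export
make_p_l <- function(tile, config = hierarchy_config()) {
  check_tile(tile, config$source_px)
  resample_area(tile, config$target_px)
}

#' Medium-scale view: center crop then downsample
#'
#' Crops the exact center `mid_px` square (rows and columns
#' `[source_px/4, 3 source_px/4)` in 0-based coordinates) and
#' area-averages it down to `target_px`.
#'
#' @inheritParams make_p_l
#' @return `target_px` x `target_px` x 3 array.
#' @export
make_p_m <- function(tile, config = hierarchy_config()) {
  check_tile(tile, config$source_px)
  resample_area(center_crop(tile, config$mid_px), config$target_px)
}

center_crop <- function(tile, crop_px) {
  off <- (dim(tile)[1L] - crop_px) %/% 2L
  tile[(off + 1L):(off + crop_px), (off + 1L):(off + crop_px), , drop = FALSE]
}

# The four quadrants of the center crop, in the fixed scan order
# top-left, top-right, bottom-left, bottom-right, as 0-based (x, y)
# offsets relative to the tile origin.
quadrant_offsets <- function(config) {
  q <- config$source_px %/% 4L  # 256 at defaults
  list(c(q, q), c(2L * q, q), c(q, 2L * q), c(2L * q, 2L * q))
}

#' Small-scale view: selective sampling of one quadrant
#'
#' Splits the center crop into four `block_px` quadrants, scans them in
#' the fixed order (top-left, top-right, bottom-left, bottom-right) and
#' keeps the first one passing the color criterion; that quadrant is
#' downsampled to `target_px`.  If no quadrant passes, the whole sample
#' is discarded (`NULL`), dropping the tile from the hierarchy.
#'
#' @inheritParams make_p_l
#' @return list with `image` (`target_px` square array) and
#'   `block_index` (0-based index into the scan order), or `NULL` when
#'   every quadrant fails the color criterion.
#' @export
select_p_s <- function(tile, config = hierarchy_config()) {
  check_tile(tile, config$source_px)
  offs <- quadrant_offsets(config)
  bp <- config$block_px
  for (i in seq_along(offs)) {
    x0 <- offs[[i]][1L]; y0 <- offs[[i]][2L]
    block <- tile[(y0 + 1L):(y0 + bp), (x0 + 1L):(x0 + bp), , drop = FALSE]
    if (passes_background_filter(block, config$color_filter)$keep)
      return(list(image = resample_area(block, config$target_px),
                  block_index = i - 1L))
  }
  NULL
}

#' Build the three-scale patch triple for one tile
#'
#' Combines [make_p_l()], [make_p_m()] and [select_p_s()].  The large
#' and medium views are always computable; the triple stands or falls
#' with selective sampling -- if no quadrant passes the color criterion
#' the entire tile is discarded so that every retained sample carries
#' all three scales.
#'
#' @param tile 1024 x 1024 x 3 intensity array.
#' @param slide_id,x0,y0 provenance of the tile (level-0 origin).
#' @param config a [hierarchy_config()].
#' @return an object of class `patch_triple` with elements `slide_id`,
#'   `x0`, `y0`, `p_l`, `p_m`, `p_s`, `ps_block_index`, or `NULL` when
#'   the tile is discarded.
#' @export
build_triple <- function(tile, slide_id = "", x0 = 0L, y0 = 0L,
                         config = hierarchy_config()) {
  ps <- select_p_s(tile, config)
  if (is.null(ps)) return(NULL)
  structure(list(slide_id = slide_id, x0 = x0, y0 = y0,
                 p_l = make_p_l(tile, config),
                 p_m = make_p_m(tile, config),
                 p_s = ps$image,
                 ps_block_index = ps$block_index),
            class = "patch_triple")
}

#' @export
print.patch_triple <- function(x, ...) {
  cat("<patch_triple> slide", x$slide_id, "origin (", x$x0, ",", x$y0,
      ") quadrant", x$ps_block_index, "\n")
  invisible(x)
}
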