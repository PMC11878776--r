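#' Exact area-average (box) resampling weights
#'
#' Each output pixel `i` of a `dst`-pixel axis covers the source interval
#' `[(i-1) r, i r)` with `r = src/dst`; its value is the average of the
#' source pixels weighted by their fractional overlap with that interval.
#' The returned matrix `W` (`dst` x `src`) has rows summing to 1, so a
#' constant image is a fixed point and the overall mean intensity is
#' preserved exactly -- the anti-aliasing behaviour wanted for the
#' integer-like scale reductions used throughout the patch hierarchy.
#'
#' @param src,dst source and destination side lengths in pixels.
#' @return a `dst` x `src` dense weight matrix.
#' @export
box_weights <- function(src, dst) {
  stopifnot(src >= dst, dst >= 1)
  r <- src / dst
  W <- matrix(0, nrow = dst, ncol = src)
  for (i in seq_len(dst)) {
    a <- (i - 1) * r
    b <- i * r
    j0 <- floor(a) + 1           # first source pixel touched (1-based)
    j1 <- ceiling(b)             # last source pixel touched
    j <- j0:j1
    ov <- pmin(b, j) - pmax(a, j - 1)
    ov[ov < 0] <- 0
    W[i, j] <- ov / r
  }
  W
}

# memoised weight matrices; the same (src, dst) pair recurs for every tile
.weights_cache <- new.env(parent = emptyenv())

box_weights_cached <- function(src, dst) {
  key <- paste0(src, "_", dst)
  if (is.null(.weights_cache[[key]]))
    .weights_cache[[key]] <- box_weights(src, dst)
  .weights_cache[[key]]
}

#' Area-average downsampling of an image
#'
#' Separable box-average reduction: rows and columns are averaged with
#' [box_weights()], applied per channel.  Deterministic and exact (no
#' interpolation kernel choices beyond the box itself).
#'
#' @param img matrix or H x W x 3 array, square.
#' @param dst_px destination side length in pixels.
#' @return resampled matrix or array with side `dst_px`.
#' @export
resample_area <- function(img, dst_px) {
  d <- dim(img)
  if (length(d) == 2L) {
    W1 <- box_weights_cached(d[1L], dst_px)
    W2 <- box_weights_cached(d[2L], dst_px)
    return(W1 %*% img %*% t(W2))
  }
  check_rgb(img, "image")
  W1 <- box_weights_cached(d[1L], dst_px)
  W2 <- box_weights_cached(d[2L], dst_px)
  out <- array(0, c(dst_px, dst_px, 3L))
  for (ch in 1:3) out[, , ch] <- W1 %*% img[, , ch] %*% t(W2)
  out
}
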