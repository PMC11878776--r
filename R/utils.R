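#' hiwsi: hierarchical multi-scale weakly supervised whole-slide classification
#'
#' The package covers the full slide-to-metrics pipeline: synthetic cohort
#' generation ([generate_cohort()]), tumor-tile extraction
#' ([extract_tiles()]), the three-scale patch hierarchy ([build_triple()]),
#' the multi-branch encoder with partial freezing ([hi_model()]), weakly
#' supervised training ([train_model()]), soft-voting slide aggregation
#' ([aggregate_slide()]) and patient-grouped cross-validated evaluation
#' ([cross_validate()]).
#'
#' @keywords internal
"_PACKAGE"

#' Stable 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 bytes of a string, reduced
#' modulo 2^31.  Used to derive per-slide and per-stage random seeds from
#' a single top-level seed so that partial regeneration of a cohort (or a
#' single pipeline stage) is reproducible in isolation.
#'
#' @param x character scalar.
#' @return integer in `[0, 2^31)`.
#' @export
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483648
  as.integer(h)
}

#' Derive a stage or slide seed from a top-level seed
#'
#' XOR of the top-level seed with [stable_hash()] of a label.  All
#' randomness in the package flows through seeds derived this way, so a
#' single integer reproduces a whole run.
#'
#' @param seed integer top-level seed.
#' @param label character scalar naming the consumer (a slide id, a stage
#'   name such as `"train_fold2"`, ...).
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bitwXor(as.integer(seed %% 2147483648), stable_hash(label))
}

# Fully pinned RNG state: kind, normal kind and sample kind are set
# explicitly so results do not depend on the session's RNG configuration.
set_seed_pinned <- function(seed) {
  set.seed(as.integer(seed %% 2147483648), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Numerically stable softmax
#'
#' @param z numeric vector or matrix of logits (rows are observations).
#' @return probabilities with the same shape; rows sum to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zm <- z - apply(z, 1L, max)
    e <- exp(zm)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# Exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x)
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# subscript assignment beats pmin/pmax on multi-megapixel arrays
clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Validate an H x W x 3 intensity array in [0, 255]
check_rgb <- function(img, what = "patch") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(what, " must be an H x W x 3 array, got dims [",
         paste(dim(img), collapse = ", "), "]", call. = FALSE)
  invisible(img)
}
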