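#' Grid-statistics feature stem of the "tiny" backbone
#'
#' Deterministic tokenization stage of the compact CPU backbone: the
#' 224-px input is divided into a 4 x 4 grid of 56-px cells and each
#' cell contributes its three channel means plus the standard deviation
#' of its gray values, giving 4 x 4 x (3 + 1) = 64 features.  Cell
#' means carry low-frequency arrangement (what the wide views see);
#' cell standard deviations carry local contrast (what the near-native
#' view sees).  Features are affinely scaled to roughly unit range.
#'
#' @param img 224 x 224 x 3 intensity array (0--255).
#' @param grid cells per side.
#' @return numeric feature vector of length `grid^2 * 4`.
#' @export
stem_features <- function(img, grid = 4L) {
  check_rgb(img, "patch")
  px <- dim(img)[1L]
  stopifnot(px %% grid == 0L, dim(img)[2L] == px)
  cell <- px %/% grid
  idx <- rep(seq_len(grid), each = cell)
  means <- numeric(0)
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  for (ch in 1:3) {
    rs <- rowsum(img[, , ch], idx)                 # sum over row groups
    cs <- t(rowsum(t(rs), idx)) / (cell * cell)    # then column groups
    means <- c(means, as.vector(cs))
  }
  s1 <- t(rowsum(t(rowsum(gray, idx)), idx))
  s2 <- t(rowsum(t(rowsum(gray^2, idx)), idx))
  n <- cell * cell
  v <- pmax(s2 / n - (s1 / n)^2, 0)
  c((means - 150) / 40, (sqrt(as.vector(v)) - 12) / 12)
}

.backbones <- new.env(parent = emptyenv())

#' Register a backbone
#'
#' A backbone is any callable mapping a 224 x 224 x 3 image to a fixed
#' length feature vector, together with the width of the trainable
#' encoder built on top of it.  The shipped `"tiny"` backbone
#' ([stem_features()] + a 4-block residual MLP, embedding width 32) is
#' small enough to train on one CPU and is used by every test; external
#' feature extractors can be plugged in through this registry.
#'
#' @param name registry key.
#' @param featurize function(image) -> numeric vector.
#' @param feat_dim length of the featurize output.
#' @param embed_dim encoder embedding width D.
#' @param n_blocks number of residual encoder blocks B.
#' @export
register_backbone <- function(name, featurize, feat_dim, embed_dim,
                              n_blocks) {
  .backbones[[name]] <- list(name = name, featurize = featurize,
                             feat_dim = as.integer(feat_dim),
                             embed_dim = as.integer(embed_dim),
                             n_blocks = as.integer(n_blocks))
  invisible(name)
}

#' Look up a registered backbone
#' @param name registry key.
#' @return backbone spec list.
#' @export
get_backbone <- function(name) {
  b <- .backbones[[name]]
  if (is.null(b)) stop("unknown backbone '", name, "'; registered: ",
                       paste(ls(.backbones), collapse = ", "))
  b
}

# the default CPU-friendly backbone
register_backbone("tiny", stem_features, feat_dim = 64L,
                  embed_dim = 32L, n_blocks = 4L)

#' Model configuration
#'
#' Three parameter-independent encoder branches (one per scale view)
#' feed a fusion head `Linear(|scales| D -> hidden) -> GELU ->
#' Dropout -> Linear(hidden -> 4)`.  `freeze_ratio` controls partial
#' freezing of each branch: `floor(n_blocks * freeze_ratio)` leading
#' blocks plus the embedding layer are non-trainable (at ratio 0
#' nothing, including the embedding, is frozen).
#'
#' @param backbone registry key, see [register_backbone()].
#' @param freeze_ratio fraction of encoder blocks to freeze.
#' @param fusion_hidden fusion hidden width (default: embedding width).
#' @param dropout dropout rate in the fusion head.
#' @param n_classes number of output classes.
#' @param scales subset of `c("l", "m", "s")`; single-scale and
#'   two-scale variants support the ablation experiments.
#' @param seed seed for parameter initialization.
#' @return an object of class `hi_model_config`.
#' @export
hi_model_config <- function(backbone = "tiny", freeze_ratio = 0.6,
                            fusion_hidden = NULL, dropout = 0.25,
                            n_classes = 4L, scales = c("l", "m", "s"),
                            seed = 42L) {
  if (freeze_ratio < 0 || freeze_ratio > 1)
    stop("freeze_ratio must be in [0, 1], got ", freeze_ratio)
  stopifnot(all(scales %in% c("l", "m", "s")), length(scales) >= 1,
            dropout >= 0, dropout < 1)
  bb <- get_backbone(backbone)
  structure(list(backbone = backbone, freeze_ratio = freeze_ratio,
                 fusion_hidden = if (is.null(fusion_hidden)) bb$embed_dim
                                 else as.integer(fusion_hidden),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 scales = scales, seed = as.integer(seed)),
            class = "hi_model_config")
}

#' Number of frozen encoder blocks for a freeze ratio
#'
#' `floor(n_blocks * freeze_ratio)`: a 24-block encoder at ratio 0.6
#' freezes its first 14 blocks.
#'
#' @param n_blocks total encoder blocks.
#' @param freeze_ratio fraction in `[0, 1]`.
#' @return integer count.
#' @export
frozen_block_count <- function(n_blocks, freeze_ratio) {
  if (freeze_ratio < 0 || freeze_ratio > 1)
    stop("freeze_ratio must be in [0, 1], got ", freeze_ratio)
  as.integer(floor(n_blocks * freeze_ratio))
}

init_mat <- function(nr, nc, scale = 1 / sqrt(nr)) {
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

#' Build a multi-branch hierarchical model
#'
#' Each branch is an independent encoder over the backbone's feature
#' stem: an embedding layer `Linear(feat_dim -> D)` followed by
#' `n_blocks` residual blocks `h <- h + W2 tanh(W1 h + b1) + b2`.  The
#' residual form keeps randomly initialized frozen blocks close to the
#' identity, so partial freezing never destroys information.  Branch
#' parameters are initialized independently (no weight sharing) from a
#' small-variance normal scheme under the config seed; residual output
#' projections get a 0.1x scale so untrained blocks start near the
#' identity map.
#'
#' @param config a [hi_model_config()].
#' @return an object of class `hi_model`; the frozen parameter set is
#'   queryable with [frozen_parameters()].
#' @export
hi_model <- function(config = hi_model_config()) {
  bb <- get_backbone(config$backbone)
  D <- bb$embed_dim; Fd <- bb$feat_dim; B <- bb$n_blocks
  H <- config$fusion_hidden
  set_seed_pinned(config$seed)
  params <- list()
  for (sc in config$scales) {
    params[[paste0(sc, ".embed.W")]] <- init_mat(Fd, D)
    params[[paste0(sc, ".embed.b")]] <- numeric(D)
    for (i in seq_len(B)) {
      params[[paste0(sc, ".block", i, ".W1")]] <- init_mat(D, D)
      params[[paste0(sc, ".block", i, ".b1")]] <- numeric(D)
      params[[paste0(sc, ".block", i, ".W2")]] <- init_mat(D, D, 0.1 / sqrt(D))
      params[[paste0(sc, ".block", i, ".b2")]] <- numeric(D)
    }
  }
  params[["head.W1"]] <- init_mat(length(config$scales) * D, H)
  params[["head.b1"]] <- numeric(H)
  params[["head.W2"]] <- init_mat(H, config$n_classes)
  params[["head.b2"]] <- numeric(config$n_classes)
  model <- structure(list(config = config, backbone = bb, params = params,
                          frozen = character(0)),
                     class = "hi_model")
  apply_freeze(model, frozen_block_count(B, config$freeze_ratio))
}

#' Freeze the embedding layer and leading encoder blocks
#'
#' Marks the embedding layer and the first `count` blocks of every
#' branch as non-trainable.  Embedding freezing is coupled to
#' `count > 0`: at count 0 the model is fully trainable, embedding
#' included, so a 0% freeze ratio means an entirely unfrozen model.
#' The fusion head is never frozen.
#'
#' @param model a [hi_model()].
#' @param count number of leading blocks to freeze per branch.
#' @return the model with its frozen-parameter set updated.
#' @export
apply_freeze <- function(model, count) {
  B <- model$backbone$n_blocks
  if (count > B)
    stop("cannot freeze ", count, " blocks of a ", B, "-block encoder")
  frozen <- character(0)
  if (count > 0) {
    for (sc in model$config$scales) {
      frozen <- c(frozen, paste0(sc, ".embed.", c("W", "b")))
      for (i in seq_len(count))
        frozen <- c(frozen, paste0(sc, ".block", i, ".",
                                   c("W1", "b1", "W2", "b2")))
    }
  }
  model$frozen <- frozen
  model
}

#' Names of frozen / trainable parameters
#' @param model a [hi_model()].
#' @return character vector of parameter names.
#' @export
frozen_parameters <- function(model) model$frozen

#' @rdname frozen_parameters
#' @export
trainable_parameters <- function(model)
  setdiff(names(model$params), model$frozen)

# Forward pass of one branch on a feature matrix (n x feat_dim),
# returning the activations needed for backprop.
forward_branch <- function(params, sc, feats, n_blocks) {
  Hs <- vector("list", n_blocks + 1L)
  As <- vector("list", n_blocks)
  Ts <- vector("list", n_blocks)
  h <- feats %*% params[[paste0(sc, ".embed.W")]]
  h <- sweep(h, 2L, params[[paste0(sc, ".embed.b")]], "+")
  Hs[[1L]] <- h
  for (i in seq_len(n_blocks)) {
    p <- paste0(sc, ".block", i, ".")
    a <- sweep(h %*% params[[paste0(p, "W1")]], 2L,
               params[[paste0(p, "b1")]], "+")
    tn <- tanh(a)
    h <- sweep(h + tn %*% params[[paste0(p, "W2")]], 2L,
               params[[paste0(p, "b2")]], "+")
    As[[i]] <- a; Ts[[i]] <- tn; Hs[[i + 1L]] <- h
  }
  list(H = Hs, A = As, T = Ts, out = h)
}

#' Forward pass on precomputed stem features
#'
#' Evaluation is deterministic (dropout disabled); in training mode a
#' dropout mask is drawn from the current RNG stream.
#'
#' @param model a [hi_model()].
#' @param feats named list of `n x feat_dim` feature matrices, one per
#'   scale in `model$config$scales`.
#' @param train logical; enables dropout and returns backprop caches.
#' @return list with `logits` (`n x n_classes`) and, when `train`,
#'   `cache`.
#' @export
model_forward <- function(model, feats, train = FALSE) {
  cfg <- model$config
  B <- model$backbone$n_blocks
  branches <- lapply(cfg$scales, function(sc) {
    f <- feats[[sc]]
    if (is.null(f)) stop("missing features for scale '", sc, "'")
    forward_branch(model$params, sc, f, B)
  })
  names(branches) <- cfg$scales
  E <- do.call(cbind, lapply(branches, `[[`, "out"))
  U <- sweep(E %*% model$params[["head.W1"]], 2L,
             model$params[["head.b1"]], "+")
  G <- gelu(U)
  if (train && cfg$dropout > 0) {
    M <- matrix(stats::rbinom(length(G), 1L, 1 - cfg$dropout),
                nrow(G), ncol(G)) / (1 - cfg$dropout)
    Gd <- G * M
  } else {
    M <- NULL
    Gd <- G
  }
  Z <- sweep(Gd %*% model$params[["head.W2"]], 2L,
             model$params[["head.b2"]], "+")
  out <- list(logits = Z)
  if (train) out$cache <- list(branches = branches, E = E, U = U, G = G,
                               M = M, Gd = Gd, feats = feats)
  out
}

#' Compute stem features for a set of patch triples
#'
#' @param triples list of `patch_triple` objects.
#' @param backbone registry key.
#' @return named list of feature matrices (`l`, `m`, `s`), one row per
#'   triple, plus an `index` data.frame with provenance.
#' @export
featurize_triples <- function(triples, backbone = "tiny") {
  bb <- get_backbone(backbone)
  n <- length(triples)
  fl <- matrix(0, n, bb$feat_dim)
  fm <- matrix(0, n, bb$feat_dim)
  fs <- matrix(0, n, bb$feat_dim)
  idx <- data.frame(slide_id = character(n), x0 = integer(n),
                    y0 = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- triples[[i]]
    fl[i, ] <- bb$featurize(tr$p_l)
    fm[i, ] <- bb$featurize(tr$p_m)
    fs[i, ] <- bb$featurize(tr$p_s)
    idx$slide_id[i] <- tr$slide_id
    idx$x0[i] <- tr$x0; idx$y0[i] <- tr$y0
  }
  list(l = fl, m = fm, s = fs, index = idx)
}

#' Patch logits for triples or precomputed features (evaluation mode)
#'
#' @param model a [hi_model()].
#' @param x either a list of `patch_triple`s or the output of
#'   [featurize_triples()].
#' @return list with `logits` matrix and `index` data.frame.
#' @export
predict_logits <- function(model, x) {
  if (length(x) && inherits(x[[1L]], "patch_triple"))
    x <- featurize_triples(x, model$config$backbone)
  fw <- model_forward(model, x[c("l", "m", "s")], train = FALSE)
  list(logits = fw$logits, index = x$index)
}
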