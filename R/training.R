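#' Training configuration
#'
#' Defaults follow the study configuration: initial learning rate
#' 2e-4, batch size 12, dropout 0.25, cross-entropy loss, AdamW (the
#' decoupled weight-decay variant of Adam) and 20 000 iterations; the
#' decay constant (not stated for the original runs) defaults to the
#' optimizer family's conventional 0.01.  `balance_rates` are the
#' patch-level class resampling rates: MMRd patches kept at 70%, NSMP
#' at 50%, the two rarer classes untouched.  [desk_profile()] provides
#' a configuration sized for CPU-scale experiments on synthetic
#' cohorts.
#'
#' @param lr learning rate.
#' @param batch_size patches per optimization step.
#' @param iterations optimization steps.
#' @param dropout fusion-head dropout rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param seed seed for batch sampling and dropout.
#' @param balance_rates named class -> fraction map in `(0, 1]`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, batch_size = 12L, iterations = 20000L,
                         dropout = 0.25, weight_decay = 0.01, seed = 1L,
                         balance_rates = c(MMRd = 0.70, NSMP = 0.50,
                                           p53abn = 1.0, POLEmut = 1.0)) {
  stopifnot(lr >= 0, batch_size >= 1, iterations >= 0)
  if (any(balance_rates <= 0) || any(balance_rates > 1))
    stop("balance rates must lie in (0, 1]")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), dropout = dropout,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 balance_rates = balance_rates),
            class = "train_config")
}

#' Desk-scale run profile
#'
#' A configuration sized for a single CPU and the synthetic cohorts the
#' tests use: the tiny backbone trained from random initialization
#' needs a larger step size and far fewer iterations than fine-tuning a
#' large pretrained encoder, so the profile raises the learning rate to
#' 3e-3 and cuts the budget to 1000 iterations while keeping batch
#' size, dropout, freezing ratio and balance rates at their defaults.
#'
#' @param seed top-level seed.
#' @param iterations optimization steps.
#' @return a [train_config()].
#' @export
desk_profile <- function(seed = 1L, iterations = 1000L)
  train_config(lr = 3e-3, iterations = iterations, seed = seed)

#' Attach inherited slide labels to a triple index
#'
#' Weak supervision: every patch triple inherits the subtype of its
#' slide.  Slides with unknown subtype are excluded with a warning.
#'
#' @param index data.frame with a `slide_id` column (e.g. from
#'   [featurize_triples()]).
#' @param manifest cohort manifest with `slide_id`, `patient_id`,
#'   `subtype`.
#' @return `index` with `label` and `patient_id` columns appended.
#' @export
inherit_labels <- function(index, manifest) {
  if (nrow(index) == 0L)
    return(cbind(index, label = character(0), patient_id = character(0)))
  pos <- match(index$slide_id, manifest$slide_id)
  if (anyNA(pos))
    stop("slide ids missing from manifest: ",
         paste(unique(index$slide_id[is.na(pos)]), collapse = ", "))
  index$label <- manifest$subtype[pos]
  index$patient_id <- manifest$patient_id[pos]
  unknown <- is.na(index$label) | index$label == "unknown"
  if (any(unknown)) {
    warning(sum(unknown), " patches from slides with unknown subtype ",
            "were excluded")
    index <- index[!unknown, , drop = FALSE]
  }
  index
}

#' Class-balanced patch subsampling
#'
#' Independently subsamples each class without replacement down to
#' `round(rate * n_class)` patches; classes with rate 1 (or absent from
#' the map) are left untouched.  Deterministic under `seed`: classes
#' are processed in [subtype_levels()] order, each with its own derived
#' seed.
#'
#' @param index labeled patch index (see [inherit_labels()]).
#' @param rates named class -> fraction map in `(0, 1]`.
#' @param seed integer seed.
#' @return row-subset of `index` (original order preserved).
#' @export
balance_patches <- function(index, rates, seed = 1L) {
  if (any(rates <= 0) || any(rates > 1))
    stop("balance rates must lie in (0, 1]")
  keep <- rep(TRUE, nrow(index))
  for (cls in intersect(subtype_levels(), unique(index$label))) {
    rate <- if (cls %in% names(rates)) rates[[cls]] else 1.0
    if (rate >= 1) next
    rows <- which(index$label == cls)
    n_keep <- round(rate * length(rows))
    set_seed_pinned(derive_seed(seed, paste0("balance_", cls)))
    kept <- sample(rows, n_keep)
    keep[setdiff(rows, kept)] <- FALSE
  }
  index[keep, , drop = FALSE]
}

# One AdamW step over all trainable parameters.
adamw_step <- function(params, grads, state, frozen, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Backward pass: gradients of mean cross-entropy w.r.t. every parameter.
model_backward <- function(model, cache, probs, onehot) {
  cfg <- model$config
  p <- model$params
  n <- nrow(probs)
  grads <- list()
  dZ <- (probs - onehot) / n
  grads[["head.W2"]] <- t(cache$Gd) %*% dZ
  grads[["head.b2"]] <- colSums(dZ)
  dGd <- dZ %*% t(p[["head.W2"]])
  dG <- if (is.null(cache$M)) dGd else dGd * cache$M
  dU <- dG * gelu_grad(cache$U)
  grads[["head.W1"]] <- t(cache$E) %*% dU
  grads[["head.b1"]] <- colSums(dU)
  dE <- dU %*% t(p[["head.W1"]])
  D <- model$backbone$embed_dim
  B <- model$backbone$n_blocks
  for (k in seq_along(cfg$scales)) {
    sc <- cfg$scales[k]
    br <- cache$branches[[sc]]
    dH <- dE[, ((k - 1L) * D + 1L):(k * D), drop = FALSE]
    for (i in rev(seq_len(B))) {
      pre <- paste0(sc, ".block", i, ".")
      grads[[paste0(pre, "W2")]] <- t(br$T[[i]]) %*% dH
      grads[[paste0(pre, "b2")]] <- colSums(dH)
      dT <- dH %*% t(p[[paste0(pre, "W2")]])
      dA <- dT * (1 - br$T[[i]]^2)
      grads[[paste0(pre, "W1")]] <- t(br$H[[i]]) %*% dA
      grads[[paste0(pre, "b1")]] <- colSums(dA)
      dH <- dH + dA %*% t(p[[paste0(pre, "W1")]])
    }
    grads[[paste0(sc, ".embed.W")]] <- t(cache$feats[[sc]]) %*% dH
    grads[[paste0(sc, ".embed.b")]] <- colSums(dH)
  }
  grads
}

#' Weakly supervised training loop
#'
#' Cross-entropy optimization with AdamW over uniformly shuffled
#' batches: the labeled patch set is reshuffled every epoch-equivalent
#' and consumed in `batch_size` chunks.  Frozen parameters receive no
#' updates.  The loss trace has one entry per iteration; a fixed seed
#' yields a bit-identical trace and final parameters.
#'
#' @param model a [hi_model()].
#' @param feats named list of feature matrices per scale (rows =
#'   patches), e.g. from [featurize_triples()].
#' @param labels character vector of patch labels (subtype levels).
#' @param config a [train_config()].
#' @return list with `model` (trained) and `loss_trace` (numeric of
#'   length `iterations`).
#' @export
train_model <- function(model, feats, labels, config = train_config()) {
  cfg <- model$config
  n <- length(labels)
  if (n < config$batch_size)
    stop("need at least batch_size = ", config$batch_size,
         " labeled patches, got ", n)
  classes <- subtype_levels()[seq_len(cfg$n_classes)]
  y <- match(labels, classes)
  if (anyNA(y)) stop("labels outside known classes: ",
                     paste(unique(labels[is.na(y)]), collapse = ", "))
  if (length(unique(y)) < 2L)
    stop("training requires at least 2 classes, got only '",
         classes[unique(y)], "'")
  onehot_all <- diag(cfg$n_classes)[y, , drop = FALSE]

  state <- list(t = 0L,
                m = lapply(model$params, function(x) x * 0),
                v = lapply(model$params, function(x) x * 0))
  loss_trace <- numeric(config$iterations)
  set_seed_pinned(derive_seed(config$seed, "train"))
  order_ <- integer(0)
  for (it in seq_len(config$iterations)) {
    if (length(order_) < config$batch_size) order_ <- sample.int(n)
    idx <- order_[seq_len(config$batch_size)]
    order_ <- order_[-seq_len(config$batch_size)]
    bf <- lapply(feats[cfg$scales], function(f) f[idx, , drop = FALSE])
    fw <- model_forward(model, bf, train = TRUE)
    probs <- softmax(fw$logits)
    oh <- onehot_all[idx, , drop = FALSE]
    loss_trace[it] <- -mean(log(pmax(rowSums(probs * oh), 1e-12)))
    grads <- model_backward(model, fw$cache, probs, oh)
    upd <- adamw_step(model$params, grads, state, model$frozen,
                      config$lr, config$weight_decay)
    model$params <- upd$params
    state <- upd$state
  }
  list(model = model, loss_trace = loss_trace)
}
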