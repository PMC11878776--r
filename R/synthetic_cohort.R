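#' The four molecular subtype labels
#'
#' Class labels for the four endometrial-cancer molecular subtypes, in
#' the fixed order used for logits, probability vectors and metrics.
#'
#' @return character vector of length 4.
#' @export
subtype_levels <- function() c("MMRd", "NSMP", "p53abn", "POLEmut")

#' Specification of a synthetic slide cohort
#'
#' Describes a deterministic synthetic cohort with the statistical
#' structure the pipeline assumes: several slides per class, a fraction
#' of patients contributing two slides, bright non-tissue background,
#' a contiguous tumor region of controllable coverage, and class signal
#' injected at two distinct spatial scales:
#'
#' * the two `coarse_signal_classes` differ only in the spatial
#'   arrangement of large (`cell_px`, default 512 px) constant-intensity
#'   cells -- the first class carries a checkerboard (random per-slide
#'   phase), the second an independent random cell pattern.  Both share
#'   the same marginal
#'   intensity distribution, so the signal is visible only to views wide
#'   enough to see several cells at once (the full-tile path);
#' * the two `fine_signal_classes` differ only in the amplitude of
#'   single-pixel, zero-mean speckle, which area-averaging at the
#'   full-tile scale attenuates into the texture/noise floor but which
#'   survives the near-native quadrant path.
#'
#' All tissue additionally carries a shared 8-px block micro-texture
#' whose per-tile amplitude is drawn uniformly from
#' `texture_sd_range`, so that residual speckle leakage at coarse
#' scales is masked by between-tile texture variability.
#'
#' @param slides_per_class slides generated for each of the 4 classes.
#' @param two_slide_patient_fraction target fraction of patients with two
#'   slides (both slides of a patient share the subtype).
#' @param slide_px slide side length in pixels; must be a multiple of
#'   1024 so tiles align exactly.
#' @param mpp native resolution in microns per pixel.
#' @param tumor_coverage fraction of the tissue area covered by tumor.
#' @param coarse_signal_classes,fine_signal_classes partition of the four
#'   class names into the coarse-scale and fine-scale signal pairs.
#' @param noise_sd per-pixel Gaussian noise standard deviation
#'   (intensity units on the 0--255 scale).
#' @param seed top-level integer seed; per-slide seeds are derived via
#'   [derive_seed()].
#' @param cell_px coarse cell side length (pixels, multiple of 256).
#' @param cell_amplitude intensity offset of the coarse cells.
#' @param dot_amplitude named vector of speckle amplitudes per fine
#'   class; a zero entry means that class carries no speckle.
#' @param texture_px micro-texture block size in pixels.
#' @param texture_sd_range range of the per-tile texture amplitude.
#' @return an object of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(slides_per_class = 10,
                                  two_slide_patient_fraction = 0.25,
                                  slide_px = 4096,
                                  mpp = 0.549,
                                  tumor_coverage = 0.6,
                                  coarse_signal_classes = c("MMRd", "NSMP"),
                                  fine_signal_classes = c("p53abn", "POLEmut"),
                                  noise_sd = 6,
                                  seed = 1L,
                                  cell_px = 512,
                                  cell_amplitude = 20,
                                  dot_amplitude = c(p53abn = 18, POLEmut = 0),
                                  texture_px = 8,
                                  texture_sd_range = c(8, 16)) {
  classes <- subtype_levels()
  if (slide_px %% 1024 != 0)
    stop("slide_px must be a multiple of 1024, got ", slide_px)
  if (!setequal(union(coarse_signal_classes, fine_signal_classes), classes) ||
      length(intersect(coarse_signal_classes, fine_signal_classes)) > 0)
    stop("coarse_signal_classes and fine_signal_classes must partition {",
         paste(classes, collapse = ", "), "}")
  stopifnot(two_slide_patient_fraction >= 0, two_slide_patient_fraction <= 1,
            tumor_coverage >= 0, tumor_coverage <= 1,
            mpp > 0, slides_per_class >= 1,
            cell_px %% 256 == 0, slide_px %% cell_px == 0,
            slide_px %% texture_px == 0)
  if (!all(fine_signal_classes %in% names(dot_amplitude)))
    stop("dot_amplitude must name every fine-signal class")
  structure(list(
    n_classes = 4L, classes = classes,
    slides_per_class = as.integer(slides_per_class),
    two_slide_patient_fraction = two_slide_patient_fraction,
    slide_px = as.integer(slide_px), mpp = mpp,
    tumor_coverage = tumor_coverage,
    coarse_signal_classes = coarse_signal_classes,
    fine_signal_classes = fine_signal_classes,
    noise_sd = noise_sd, seed = as.integer(seed),
    cell_px = as.integer(cell_px), cell_amplitude = cell_amplitude,
    dot_amplitude = dot_amplitude,
    texture_px = as.integer(texture_px),
    texture_sd_range = texture_sd_range
  ), class = "cohort_spec")
}

# Intensity constants: pinkish tissue tint with all channel medians well
# inside the (100, 200) accepted band, and background bright enough that
# every channel median of a pure background tile exceeds 200.
.TISSUE_BASE <- c(175, 140, 165)
.BG_VALUE <- 245
.BG_FLOOR <- 231

#' Generate one synthetic slide and its tumor mask
#'
#' Deterministic given `(spec, subtype, slide_seed)`.  The slide layout
#' is: a 1024-px background strip across the top (when the slide is at
#' least 2 tiles tall), tissue below it, and a contiguous tumor region
#' occupying the leftmost `tumor_coverage` fraction of the tissue width.
#' Class signal is present only inside the tumor region; benign tissue
#' carries the shared texture and noise but no class signal.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param subtype one of [subtype_levels()].
#' @param slide_seed integer seed for this slide's random fields.
#' @return list with `image` (slide_px x slide_px x 3 integer-valued
#'   array in 0--255) and `mask` (slide_px x slide_px 0/1 matrix marking
#'   tumor).
#' @export
generate_slide <- function(spec, subtype, slide_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!subtype %in% spec$classes)
    stop("unknown subtype '", subtype, "'; expected one of ",
         paste(spec$classes, collapse = ", "))
  S <- spec$slide_px
  n_tiles <- S %/% 1024L
  bg_px <- if (n_tiles >= 2L) 1024L else 0L
  w_t <- as.integer(round(spec$tumor_coverage * S))

  set_seed_pinned(slide_seed)
  tr_rows <- if (bg_px < S) (bg_px + 1L):S else integer(0)  # tissue rows
  tu_cols <- if (w_t > 0L) seq_len(w_t) else integer(0)     # tumor cols

  # 1. coarse cell field (luminance offsets on the cell_px grid,
  #    aligned to absolute slide coordinates; tumor region only)
  cp <- spec$cell_px
  nc <- S %/% cp
  cell_sub <- NULL
  if (subtype %in% spec$coarse_signal_classes) {
    if (subtype == spec$coarse_signal_classes[1L]) {
      # checkerboard with a random per-slide phase: the cell-offset
      # marginal (half +a, half -a) then matches the random-cell class
      # exactly, so no single constant-offset window can tell the two
      # coarse classes apart -- only multi-cell arrangement can
      phase <- sample(c(-1, 1), 1L)
      ij <- outer(seq_len(nc) - 1L, seq_len(nc) - 1L, "+")
      cellval <- phase * spec$cell_amplitude * (1 - 2 * (ij %% 2L))
    } else {
      cellval <- spec$cell_amplitude *
        matrix(sample(c(-1, 1), nc * nc, replace = TRUE), nc, nc)
    }
    ri <- (seq_len(S) - 1L) %/% cp + 1L
    if (length(tr_rows) && length(tu_cols))
      cell_sub <- cellval[ri[tr_rows], ri[tu_cols], drop = FALSE]
  }

  # 2. shared micro-texture: 8-px blocks, amplitude drawn per 1024-tile
  tp <- spec$texture_px
  nb <- S %/% tp
  t_tile <- matrix(stats::runif(n_tiles * n_tiles,
                                spec$texture_sd_range[1L],
                                spec$texture_sd_range[2L]),
                   n_tiles, n_tiles)
  bi <- (seq_len(nb) - 1L) %/% (1024L %/% tp) + 1L   # block -> tile index
  blockval <- matrix(stats::rnorm(nb * nb), nb, nb) * t_tile[bi, bi]
  pi_ <- (seq_len(S) - 1L) %/% tp + 1L

  # 3. fine speckle (zero-mean, single-pixel, tumor only)
  amp <- 0
  if (subtype %in% spec$fine_signal_classes)
    amp <- unname(spec$dot_amplitude[subtype])
  speckle_sub <- NULL
  if (amp > 0 && length(tr_rows) && length(tu_cols))
    speckle_sub <- matrix(
      amp * sample(c(-1, 1), length(tr_rows) * length(tu_cols),
                   replace = TRUE),
      length(tr_rows), length(tu_cols))

  # 4. pixel noise everywhere
  noise <- matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)

  mask <- matrix(0L, S, S)
  if (length(tr_rows) && length(tu_cols)) mask[tr_rows, tu_cols] <- 1L

  lum <- blockval[pi_, pi_] + noise
  if (!is.null(cell_sub))
    lum[tr_rows, tu_cols] <- lum[tr_rows, tu_cols] + cell_sub
  if (!is.null(speckle_sub))
    lum[tr_rows, tu_cols] <- lum[tr_rows, tu_cols] + speckle_sub
  lum <- round(lum)
  # intensity components stay far from the 0/255 rails; clamp only when
  # an extreme noise draw would actually overflow a channel
  rng <- range(lum)
  base_lo <- min(.TISSUE_BASE); base_hi <- max(.TISSUE_BASE)
  if (rng[1L] < -base_lo || rng[2L] > 255 - base_hi)
    lum <- clamp(lum, -base_lo, 255 - base_hi)

  bg_plane <- NULL
  if (bg_px > 0L)
    bg_plane <- round(clamp(.BG_VALUE + noise[seq_len(bg_px), ],
                            .BG_FLOOR, 255))

  img <- array(0, c(S, S, 3L))
  for (ch in 1:3) {
    plane <- .TISSUE_BASE[ch] + lum
    if (!is.null(bg_plane)) plane[seq_len(bg_px), ] <- bg_plane
    img[, , ch] <- plane
  }
  list(image = img, mask = mask)
}

# Patient assignment for one class: with m slides and target fraction p
# of patients holding two slides, k = round(p * m / (1 + p)) patients get
# two slides (then k / (m - k) ~= p).  Slides are shuffled under a
# class-specific derived seed before pairing.
assign_patients <- function(slide_ids, fraction, seed, class) {
  m <- length(slide_ids)
  k <- round(fraction * m / (1 + fraction))
  set_seed_pinned(derive_seed(seed, paste0("patients_", class)))
  ord <- sample.int(m)
  pid <- character(m)
  j <- 0L
  for (i in seq_len(k)) {
    j <- j + 1L
    pid[ord[c(2L * i - 1L, 2L * i)]] <- sprintf("PT_%s_%02d", class, j)
  }
  for (i in seq_len(m - 2L * k)) {
    j <- j + 1L
    pid[ord[2L * k + i]] <- sprintf("PT_%s_%02d", class, j)
  }
  pid
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one single-level TIFF image and one full-resolution PNG tumor
#' mask per slide, plus a manifest CSV with header
#' `slide_id,patient_id,image_path,mask_path,mpp,subtype`.  Class counts
#' are exactly balanced; patient structure follows
#' `two_slide_patient_fraction`.  Regeneration with the same spec yields
#' byte-identical files.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (d in file.path(out_dir, c("", "images", "masks"))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", d)
  }
  rows <- list()
  for (cls in spec$classes) {
    ids <- sprintf("%s_%02d", cls, seq_len(spec$slides_per_class))
    pids <- assign_patients(ids, spec$two_slide_patient_fraction,
                            spec$seed, cls)
    for (i in seq_along(ids)) {
      sl <- generate_slide(spec, cls, derive_seed(spec$seed, ids[i]))
      ipath <- file.path(out_dir, "images", paste0(ids[i], ".tif"))
      mpath <- file.path(out_dir, "masks", paste0(ids[i], ".png"))
      tiff::writeTIFF(sl$image / 255, ipath, bits.per.sample = 8L,
                      compression = "LZW")
      png::writePNG(sl$mask + 0, mpath)   # writePNG wants doubles
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = ids[i], patient_id = pids[i],
        image_path = ipath, mask_path = mpath,
        mpp = spec$mpp, subtype = cls, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a slide image from disk
#'
#' @param path TIFF (or PNG) raster path.
#' @return H x W x 3 intensity array on the 0--255 scale.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) stop("cannot read slide image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3]
  round(img * 255)
}

#' Read a binary mask from disk
#'
#' @param path PNG (or TIFF) mask path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) + 0L
}

#' Read a cohort manifest CSV
#'
#' @param path manifest CSV with columns
#'   `slide_id,patient_id,image_path,mask_path,mpp,subtype`.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "patient_id", "image_path", "mask_path",
            "mpp", "subtype")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  m
}
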