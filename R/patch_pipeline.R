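#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the standard luma weights 0.2989 R + 0.5870 G + 0.1140 B and rounds
#' to integer gray levels. A 2-D input is treated as already grayscale and
#' returned unchanged, so the conversion is idempotent.
#'
#' @param img either a 2-D matrix (already gray) or an H x W x 3 array with
#'   channel values in 0..255.
#' @return integer matrix of gray levels in 0..255.
#' @examples
#' rgb <- array(c(100, 150, 200), c(2, 2, 3))
#' rgb[, , 1] <- 100; rgb[, , 2] <- 150; rgb[, , 3] <- 200
#' to_grayscale(rgb)[1, 1]  # round(.2989*100 + .587*150 + .114*200)
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    out <- round(img)
    storage.mode(out) <- "integer"
    return(out)
  }
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected a 2-D matrix or an H x W x 3 RGB array", call. = FALSE)
  g <- 0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
  g <- round(g)
  storage.mode(g) <- "integer"
  g
}

#' Tissue-filter configuration
#'
#' Stained tissue is darker than the near-white glass background, so pixels
#' below `tissue_threshold` count as tissue. Patches qualify when the tissue
#' fraction reaches `min_tissue_fraction` and the fraction of saturated
#' pixels (gray level 0 or 255) stays at or below `saturation_fraction_max`
#' (a stand-in for the artifact screen of manual review).
#'
#' @param tissue_threshold gray-level cutoff; pixels strictly below it are
#'   tissue (default 220 on the 8-bit scale).
#' @param min_tissue_fraction minimum tissue coverage per patch (default 0.5).
#' @param saturation_fraction_max maximum tolerated saturated-pixel fraction
#'   (default 0.05).
#' @return an object of class `tissue_filter_config`.
#' @export
tissue_filter_config <- function(tissue_threshold = 220,
                                 min_tissue_fraction = 0.5,
                                 saturation_fraction_max = 0.05) {
  if (min_tissue_fraction <= 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must be in (0, 1]", call. = FALSE)
  structure(
    list(tissue_threshold = tissue_threshold,
         min_tissue_fraction = min_tissue_fraction,
         saturation_fraction_max = saturation_fraction_max),
    class = "tissue_filter_config"
  )
}

#' Fraction of patch pixels classified as tissue
#'
#' @param patch matrix of gray levels.
#' @param cfg a [tissue_filter_config()].
#' @return proportion in \[0, 1\] of pixels strictly darker than the
#'   tissue threshold.
#' @export
tissue_fraction <- function(patch, cfg = tissue_filter_config()) {
  mean(patch < cfg$tissue_threshold)
}

saturated_fraction <- function(patch) {
  mean(patch <= 0 | patch >= 255)
}

#' Extract qualifying patches from a slide image
#'
#' Samples candidate patch origins uniformly at random (seeded), keeping
#' patches whose tissue coverage and saturated-pixel fraction pass the
#' filter; if random sampling cannot supply `n_patches`, a half-patch-stride
#' grid sweep tops the set up. Origins are unique; patches are half-open
#' windows `[r, r+size) x [c, c+size)` with 0-based origins reported.
#' Returns fewer than `n_patches` with a warning when the slide cannot
#' supply enough qualifying patches.
#'
#' @param slide matrix of gray levels (use [to_grayscale()] first for RGB).
#' @param n_patches number of patches requested (the study design uses 100
#'   per slide).
#' @param patch_size patch side length, px (slide must be at least this big).
#' @param cfg a [tissue_filter_config()].
#' @param rng_seed integer seed for candidate sampling.
#' @return list of patches, each a list with elements `pixels` (matrix),
#'   `origin` (0-based c(row, col)) and `tissue_fraction`; the list carries
#'   attribute `patch_size`.
#' @export
extract_patches <- function(slide, n_patches = 100L, patch_size = 1024L,
                            cfg = tissue_filter_config(), rng_seed = 1L) {
  nr <- nrow(slide); nc <- ncol(slide)
  if (nr < patch_size || nc < patch_size)
    stop("slide is smaller than patch_size in at least one dimension",
         call. = FALSE)
  max_r <- nr - patch_size + 1L
  max_c <- nc - patch_size + 1L
  qualifies <- function(p) {
    tissue_fraction(p, cfg) >= cfg$min_tissue_fraction &&
      saturated_fraction(p) <= cfg$saturation_fraction_max
  }
  out <- list()
  seen <- character(0)
  local_seed_eval(rng_seed, {
    n_cand <- min(max_r * max_c, max(2000L, 50L * n_patches))
    r_cand <- sample.int(max_r, n_cand, replace = TRUE)
    c_cand <- sample.int(max_c, n_cand, replace = TRUE)
    for (i in seq_len(n_cand)) {
      if (length(out) >= n_patches) break
      key <- paste(r_cand[i], c_cand[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      p <- slide[r_cand[i]:(r_cand[i] + patch_size - 1L),
                 c_cand[i]:(c_cand[i] + patch_size - 1L)]
      if (qualifies(p)) {
        out[[length(out) + 1L]] <- list(
          pixels = p,
          origin = c(row = r_cand[i] - 1L, col = c_cand[i] - 1L),
          tissue_fraction = tissue_fraction(p, cfg)
        )
      }
    }
  })
  if (length(out) < n_patches) {
    stride <- max(1L, patch_size %/% 2L)
    grid_r <- unique(c(seq(1L, max_r, by = stride), max_r))
    grid_c <- unique(c(seq(1L, max_c, by = stride), max_c))
    for (r in grid_r) {
      for (cc in grid_c) {
        if (length(out) >= n_patches) break
        key <- paste(r, cc)
        if (key %in% seen) next
        seen <- c(seen, key)
        p <- slide[r:(r + patch_size - 1L), cc:(cc + patch_size - 1L)]
        if (qualifies(p)) {
          out[[length(out) + 1L]] <- list(
            pixels = p,
            origin = c(row = r - 1L, col = cc - 1L),
            tissue_fraction = tissue_fraction(p, cfg)
          )
        }
      }
    }
  }
  if (length(out) < n_patches)
    warning(sprintf("slide supplied only %d of %d qualifying patches",
                    length(out), n_patches), call. = FALSE)
  attr(out, "patch_size") <- as.integer(patch_size)
  out
}

#' Manifest table for an extracted patch set
#'
#' @param patches result of [extract_patches()].
#' @param patient_id identifier recorded in every row.
#' @return data.frame with columns patient_id, patch_id, row, col,
#'   tissue_fraction (origins 0-based).
#' @export
patch_manifest <- function(patches, patient_id = "unknown") {
  if (length(patches) == 0L)
    return(data.frame(patient_id = character(0), patch_id = character(0),
                      row = integer(0), col = integer(0),
                      tissue_fraction = numeric(0)))
  data.frame(
    patient_id = patient_id,
    patch_id = sprintf("%s_%03d", patient_id, seq_along(patches)),
    row = vapply(patches, function(p) unname(p$origin["row"]), integer(1)),
    col = vapply(patches, function(p) unname(p$origin["col"]), integer(1)),
    tissue_fraction = vapply(patches, function(p) p$tissue_fraction,
                             numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a slide image from PNG or TIFF
#'
#' Values are rescaled to 0..255 and converted to grayscale if RGB; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return integer matrix of gray levels.
#' @export
read_slide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3, drop = FALSE]
  img <- img * 255
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  to_grayscale(img)
}
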