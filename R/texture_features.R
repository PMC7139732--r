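#' Quantize a patch to a small number of gray levels
#'
#' Equal-width binning of the patch's own intensity range \[min, max\] into
#' `levels` bins (per-patch normalization). A constant patch maps to level 0
#' everywhere. Output levels are 0-based indices `0..levels-1` and preserve
#' intensity order.
#'
#' @param patch matrix of gray levels.
#' @param levels number of quantization levels (default 16, >= 2).
#' @return integer matrix of level indices with attribute `levels`.
#' @export
quantize_patch <- function(patch, levels = 16L) {
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  levels <- as.integer(levels)
  lo <- min(patch); hi <- max(patch)
  if (lo == hi) {
    q <- matrix(0L, nrow(patch), ncol(patch))
  } else {
    q <- floor((patch - lo) / (hi - lo) * levels)
    q[q == levels] <- levels - 1L
    storage.mode(q) <- "integer"
  }
  attr(q, "levels") <- levels
  q
}

glcm_offset <- function(direction) {
  switch(as.character(direction),
    "0"   = c(0L, 1L),
    "45"  = c(-1L, 1L),
    "90"  = c(-1L, 0L),
    "135" = c(-1L, -1L),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Build a symmetric, normalized gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized levels at offset distance 1 in the
#' given direction (the distance-1 neighbors within a pixel's 3x3
#' neighborhood), symmetrizes by adding the transpose, and normalizes to a
#' probability matrix.
#'
#' @param q quantized patch from [quantize_patch()].
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param levels number of gray levels; defaults to the `levels` attribute.
#' @return L x L matrix of probabilities summing to 1, with attributes
#'   `direction` and `levels`.
#' @export
build_glcm <- function(q, direction = 0, levels = attr(q, "levels")) {
  if (is.null(levels)) levels <- max(q) + 1L
  if (nrow(q) < 2 && ncol(q) < 2)
    stop("patch must be at least 2 pixels in one dimension", call. = FALSE)
  off <- glcm_offset(direction)
  nr <- nrow(q); nc <- ncol(q)
  rows <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
  cols <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1L], cols + off[2L], drop = FALSE]
  counts <- tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                     nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)  # m[i+1, j+1] = #(i, j)
  m <- m + t(m)
  p <- m / sum(m)
  attr(p, "direction") <- direction
  attr(p, "levels") <- levels
  p
}

#' Haralick-style features of one GLCM
#'
#' Computes, over the normalized co-occurrence probabilities `p(i, j)` with
#' `i, j` the 0-based level values: contrast, correlation, energy
#' (angular second moment), homogeneity (inverse difference moment), entropy
#' (bits; 0 log 0 = 0), cluster shade, cluster prominence, and
#' autocorrelation. Correlation of a zero-variance GLCM (single occupied
#' level) is defined as 1.
#'
#' @param glcm normalized GLCM from [build_glcm()] (probabilities sum to 1).
#' @return named numeric vector of 8 values, names prefixed `glcm_`.
#' @export
glcm_features <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8)
    stop("GLCM must be normalized to probabilities", call. = FALSE)
  L <- nrow(glcm)
  I <- matrix(0:(L - 1), L, L)
  J <- t(I)
  p <- glcm
  mu_i <- sum(I * p); mu_j <- sum(J * p)
  var_i <- sum((I - mu_i)^2 * p); var_j <- sum((J - mu_j)^2 * p)
  correlation <- if (var_i <= 0 || var_j <= 0) 1 else
    sum((I - mu_i) * (J - mu_j) * p) / sqrt(var_i * var_j)
  pos <- p > 0
  c(
    glcm_contrast = sum((I - J)^2 * p),
    glcm_correlation = correlation,
    glcm_energy = sum(p^2),
    glcm_homogeneity = sum(p / (1 + abs(I - J))),
    glcm_entropy = -sum(p[pos] * log2(p[pos])),
    glcm_cluster_shade = sum((I + J - mu_i - mu_j)^3 * p),
    glcm_cluster_prominence = sum((I + J - mu_i - mu_j)^4 * p),
    glcm_autocorrelation = sum(I * J * p)
  )
}

# Scan lines of a quantized patch in one of the four directions, each line a
# vector of levels in scan order.
glrlm_scan_lines <- function(q, direction) {
  m <- matrix(as.integer(q), nrow(q), ncol(q))
  switch(as.character(direction),
    "0"   = split(m, row(m)),            # rows, left to right
    "90"  = split(m, col(m)),            # columns, top to bottom
    "45"  = split(m, row(m) + col(m)),   # anti-diagonals, up-right
    "135" = split(m, col(m) - row(m)),   # diagonals, down-right
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Build a gray-level run-length matrix
#'
#' Counts maximal runs of equal quantized level along scan lines of the given
#' direction. Entry `r[i, j]` is the number of runs of level `i-1` (0-based
#' levels, matrix rows 1-based) with length `j`.
#'
#' @inheritParams build_glcm
#' @return L x Rmax integer matrix of run counts with attributes `direction`
#'   and `levels`; Rmax is the longest possible run for the patch shape.
#' @export
build_glrlm <- function(q, direction = 0, levels = attr(q, "levels")) {
  if (is.null(levels)) levels <- max(q) + 1L
  if (length(q) == 0L) stop("empty patch", call. = FALSE)
  lines <- glrlm_scan_lines(q, direction)
  rmax <- max(lengths(lines))
  vals <- integer(0); lens <- integer(0)
  for (ln in lines) {
    r <- rle(ln)
    vals <- c(vals, r$values)
    lens <- c(lens, r$lengths)
  }
  counts <- tabulate(vals * rmax + lens, nbins = levels * rmax)
  m <- matrix(counts, levels, rmax, byrow = TRUE)  # m[i+1, j] = runs(i, j)
  attr(m, "direction") <- direction
  attr(m, "levels") <- levels
  m
}

#' Run-length emphasis features of one GLRLM
#'
#' The ten standard run-length statistics, normalized by the total number of
#' runs `Nr`: long/short run emphasis (LRE/SRE), run-length and gray-level
#' non-uniformity (RLN/GLN), high/low gray-level run emphasis (HGLRE/LGLRE),
#' and the four joint emphases (SRHGLE, SRLGLE, LRHGLE, LRLGLE). Gray levels
#' enter the emphasis formulas 1-based so low-gray-level terms stay finite
#' at level 0.
#'
#' @param glrlm run-count matrix from [build_glrlm()].
#' @return named numeric vector of 10 values, names prefixed `glrlm_`.
#' @export
glrlm_features <- function(glrlm) {
  nr_runs <- sum(glrlm)
  if (nr_runs == 0) stop("GLRLM contains no runs", call. = FALSE)
  L <- nrow(glrlm); R <- ncol(glrlm)
  I <- matrix(seq_len(L), L, R)        # 1-based gray level index
  J <- matrix(seq_len(R), L, R, byrow = TRUE)
  g <- glrlm
  c(
    glrlm_LRE = sum(g * J^2) / nr_runs,
    glrlm_SRE = sum(g / J^2) / nr_runs,
    glrlm_RLN = sum(colSums(g)^2) / nr_runs,
    glrlm_GLN = sum(rowSums(g)^2) / nr_runs,
    glrlm_HGLRE = sum(g * I^2) / nr_runs,
    glrlm_LGLRE = sum(g / I^2) / nr_runs,
    glrlm_SRHGLE = sum(g * I^2 / J^2) / nr_runs,
    glrlm_SRLGLE = sum(g / (I^2 * J^2)) / nr_runs,
    glrlm_LRHGLE = sum(g * I^2 * J^2) / nr_runs,
    glrlm_LRLGLE = sum(g * J^2 / I^2) / nr_runs
  )
}

#' All 18 texture features of a patch
#'
#' Quantizes the patch to `levels` gray levels, computes the 8 GLCM and 10
#' GLRLM features independently in each of the four main directions
#' (0, 45, 90, 135 degrees), and averages over directions.
#'
#' @param patch matrix of gray levels.
#' @param levels quantization levels (default 16).
#' @return named numeric vector of 18 values, names prefixed `tex_`.
#' @export
extract_texture <- function(patch, levels = 16L) {
  q <- quantize_patch(patch, levels)
  dirs <- c(0, 45, 90, 135)
  acc <- vapply(dirs, function(d) {
    c(glcm_features(build_glcm(q, d)), glrlm_features(build_glrlm(q, d)))
  }, numeric(18))
  stats::setNames(rowMeans(acc), paste0("tex_", rownames(acc)))
}
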