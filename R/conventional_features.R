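#' Whole-patch statistical intensity features
#'
#' Sixteen first-order statistics over all pixels: mean, standard deviation
#' (sample, n-1), median, skewness and kurtosis (standardized 3rd/4th central
#' moments; kurtosis is non-excess, so a normal sample is near 3), maximum,
#' minimum, and the nine deciles (10th..90th percentiles, linear
#' interpolation). On a constant patch the degenerate skewness/kurtosis are
#' reported as 0 so downstream feature matrices stay finite.
#'
#' @param patch matrix of gray levels.
#' @return named numeric vector of 16 values, names prefixed `conv_`.
#' @export
statistical_features <- function(patch) {
  px <- as.numeric(patch)
  if (length(px) == 0L) stop("empty patch", call. = FALSE)
  m <- mean(px)
  d <- px - m
  m2 <- mean(d^2)
  skew <- if (m2 == 0) 0 else mean(d^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean(d^4) / m2^2
  qs <- stats::quantile(px, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                        names = FALSE)
  out <- c(
    mean = m,
    std = stats::sd(px),
    median = stats::median(px),
    skewness = skew,
    kurtosis = kurt,
    max = max(px),
    min = min(px),
    stats::setNames(qs, paste0("p", seq(10, 90, by = 10)))
  )
  stats::setNames(out, paste0("conv_", names(out)))
}

#' Segment a patch into nuclear connected components
#'
#' K-means clustering (k = 2) of pixel intensities with deterministic
#' initialization at the 25th/75th intensity percentiles; the darker cluster
#' is taken as foreground (hematoxylin-stained nuclei). Foreground pixels are
#' labeled into 8-connected components and components with area (pixel
#' count) less than or equal to `area_threshold` are discarded.
#'
#' @param patch matrix of gray levels with at least 2 distinct values.
#' @param k number of intensity clusters (fixed at 2).
#' @param area_threshold retain only components with area strictly greater
#'   than this (default 100 px at the 1024-px patch scale).
#' @return an object of class `component_set`: list with `labels` (integer
#'   matrix, 0 = background, retained components relabeled 1..K),
#'   `components` (list of 2-column pixel coordinate matrices, row/col),
#'   `area_threshold`, and `n_components`.
#' @export
segment_components <- function(patch, k = 2L, area_threshold = 100L) {
  if (k != 2L) stop("only k = 2 segmentation is supported", call. = FALSE)
  px <- as.numeric(patch)
  ctrs <- unname(stats::quantile(px, c(0.25, 0.75), type = 7))
  if (ctrs[1] == ctrs[2]) ctrs <- range(px)
  if (ctrs[1] == ctrs[2])
    stop("patch has fewer than 2 distinct intensity values; cannot segment",
         call. = FALSE)
  km <- stats::kmeans(px, centers = matrix(ctrs, ncol = 1), iter.max = 100L)
  dark_cluster <- which.min(km$centers)
  mask <- matrix(km$cluster == dark_cluster, nrow(patch), ncol(patch))
  lab <- label_components(mask, connectivity = 8)
  ncomp <- max(lab)
  comps <- list()
  if (ncomp > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which(areas > area_threshold)
    relab <- matrix(0L, nrow(patch), ncol(patch))
    for (i in seq_along(keep)) {
      sel <- which(lab == keep[i])
      relab[sel] <- i
      comps[[i]] <- cbind(row = (sel - 1L) %% nrow(patch) + 1L,
                          col = (sel - 1L) %/% nrow(patch) + 1L)
    }
    lab <- relab
  }
  structure(
    list(labels = lab, components = comps,
         area_threshold = area_threshold, n_components = length(comps)),
    class = "component_set"
  )
}

# Sobel gradient magnitude of an image matrix (edge-replicated borders).
sobel_magnitude <- function(img) {
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  pad <- rbind(img[1, , drop = FALSE], img, img[nrow(img), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  nr <- nrow(img); nc <- ncol(img)
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Area of the convex hull of a component, computed over pixel *corners*
# (each pixel treated as a unit square) so that convex_area >= pixel count
# for convex shapes, matching the usual filled-convex-image convention.
convex_area_px <- function(coords) {
  pts <- rbind(
    cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] + 0.5)
  )
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(nrow(coords))
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Euler number (objects minus holes) of one component: 1 - number of
# background regions fully enclosed by the component (4-connected background
# complements 8-connected foreground).
euler_number_component <- function(coords, labels, comp_id) {
  r0 <- min(coords[, 1]); r1 <- max(coords[, 1])
  c0 <- min(coords[, 2]); c1 <- max(coords[, 2])
  sub <- labels[r0:r1, c0:c1, drop = FALSE] == comp_id
  padded <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  bg <- label_components(!padded, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  n_holes <- length(setdiff(unique(bg[bg > 0L]), border_labels))
  1L - n_holes
}

# Perimeter of each labeled component as the closed chain length of its
# outer contour (EBImage boundary tracer); floor of 4 for degenerate
# single-pixel contours (a unit square's perimeter).
component_perimeters <- function(labels) {
  oc <- EBImage::ocontour(labels)
  vapply(oc, function(pts) {
    if (is.null(pts) || nrow(pts) < 2) return(4)
    nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
    max(4, sum(sqrt(rowSums((pts - nxt)^2))))
  }, numeric(1))
}

#' Component-averaged morphological features
#'
#' Ten shape descriptors averaged over the retained components of a
#' [segment_components()] result: area (px), perimeter (outer-contour chain
#' length), eccentricity, convex area, Euler number (1 minus holes),
#' orientation of the major axis in degrees (-90, 90], compactness
#' `4*pi*area / perimeter^2`, major/minor axis lengths (4 sqrt of the
#' second-moment eigenvalues, with the 1/12 pixel-extent correction), and
#' edge sharpness (mean Sobel gradient magnitude over component boundary
#' pixels).
#'
#' @param components a `component_set` from [segment_components()].
#' @param patch the gray-level matrix the components were segmented from
#'   (used for edge sharpness).
#' @return named numeric vector of 10 values, names prefixed `conv_`.
#' @export
morphological_features <- function(components, patch) {
  stopifnot(inherits(components, "component_set"))
  if (components$n_components == 0L)
    stop("no retained components; morphological features undefined",
         call. = FALSE)
  labels <- components$labels
  grad <- sobel_magnitude(patch)
  perims <- component_perimeters(labels)
  n <- components$n_components
  feats <- matrix(NA_real_, n, 10)
  colnames(feats) <- c("edge_sharpness", "perimeter", "area", "eccentricity",
                       "convex_area", "euler_number", "orientation",
                       "compactness", "major_axis_length", "minor_axis_length")
  for (i in seq_len(n)) {
    coords <- components$components[[i]]
    area <- nrow(coords)
    mr <- mean(coords[, 1]); mc <- mean(coords[, 2])
    dr <- coords[, 1] - mr; dc <- coords[, 2] - mc
    mu_rr <- mean(dr^2) + 1 / 12
    mu_cc <- mean(dc^2) + 1 / 12
    mu_rc <- mean(dr * dc)
    common <- sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)
    l1 <- (mu_rr + mu_cc + common) / 2
    l2 <- (mu_rr + mu_cc - common) / 2
    major <- 4 * sqrt(l1)
    minor <- 4 * sqrt(max(0, l2))
    ecc <- sqrt(max(0, 1 - l2 / l1))
    orient <- 0.5 * atan2(2 * mu_rc, mu_cc - mu_rr) * 180 / pi
    if (orient <= -90) orient <- orient + 180
    if (orient > 90) orient <- orient - 180
    per <- perims[i]
    # boundary pixels: any 8-neighbor outside the component
    bnd <- boundary_pixels(coords, labels, i)
    feats[i, ] <- c(
      mean(grad[bnd]),
      per,
      area,
      ecc,
      convex_area_px(coords),
      euler_number_component(coords, labels, i),
      orient,
      4 * pi * area / per^2,
      major,
      minor
    )
  }
  out <- colMeans(feats)
  stats::setNames(out, paste0("conv_", names(out)))
}

# Linear indices of a component's boundary pixels (any of the 8 neighbors is
# outside the component or outside the image).
boundary_pixels <- function(coords, labels, comp_id) {
  nr <- nrow(labels); nc <- ncol(labels)
  is_bnd <- logical(nrow(coords))
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1]; cc <- coords[k, 2]
    if (r == 1L || r == nr || cc == 1L || cc == nc) { is_bnd[k] <- TRUE; next }
    nb <- labels[(r - 1L):(r + 1L), (cc - 1L):(cc + 1L)]
    is_bnd[k] <- any(nb != comp_id)
  }
  (coords[is_bnd, 2] - 1L) * nr + coords[is_bnd, 1]
}

#' All 26 conventional features of a patch
#'
#' Concatenates [statistical_features()] (16 values) with
#' [morphological_features()] (10 values) computed on the K-means dark
#' cluster components.
#'
#' @inheritParams segment_components
#' @return named numeric vector of 26 values, names prefixed `conv_`.
#' @export
conventional_features <- function(patch, area_threshold = 100L) {
  comps <- segment_components(patch, 2L, area_threshold)
  c(statistical_features(patch), morphological_features(comps, patch))
}
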