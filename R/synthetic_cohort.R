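#' Per-class rendering parameters for synthetic histology patches
#'
#' Describes one grade class (LGG or HGG) in terms of the visual properties
#' the grading literature associates with it: nuclear density and size,
#' elongation (axis ratio), stain intensity of nuclei vs stroma, spatial
#' heterogeneity (additive noise), necrosis-like bright holes, and boundary
#' irregularity of nuclei.
#'
#' @param nucleus_density expected nuclei per 10,000 px^2 (a 100x100 window).
#' @param nucleus_major_axis_mean mean full major-axis length of nuclei, px.
#' @param nucleus_axis_ratio_mean mean major/minor axis ratio (>= 1;
#'   1 = circular).
#' @param nucleus_intensity_mean mean nuclear gray level (0-255; hematoxylin
#'   makes nuclei darker than stroma).
#' @param stroma_intensity_mean background tissue gray level (0-255).
#' @param heterogeneity_noise_sd sd of additive Gaussian intensity noise.
#' @param necrosis_hole_rate probability that a patch contains one bright
#'   necrosis-like focus.
#' @param edge_jaggedness amplitude (>= 0) of smooth periodic perturbation of
#'   the nuclear boundary radius; 0 = perfect ellipses.
#' @return an object of class `class_params`.
#' @seealso [lgg_params()], [hgg_params()] for the default grade profiles.
#' @export
class_params <- function(nucleus_density,
                         nucleus_major_axis_mean,
                         nucleus_axis_ratio_mean,
                         nucleus_intensity_mean,
                         stroma_intensity_mean,
                         heterogeneity_noise_sd,
                         necrosis_hole_rate = 0,
                         edge_jaggedness = 0) {
  p <- list(
    nucleus_density = nucleus_density,
    nucleus_major_axis_mean = nucleus_major_axis_mean,
    nucleus_axis_ratio_mean = nucleus_axis_ratio_mean,
    nucleus_intensity_mean = nucleus_intensity_mean,
    stroma_intensity_mean = stroma_intensity_mean,
    heterogeneity_noise_sd = heterogeneity_noise_sd,
    necrosis_hole_rate = necrosis_hole_rate,
    edge_jaggedness = edge_jaggedness
  )
  class(p) <- "class_params"
  validate_class_params(p)
  p
}

validate_class_params <- function(p) {
  stopifnot(inherits(p, "class_params"))
  if (p$nucleus_intensity_mean < 0 || p$nucleus_intensity_mean > 255 ||
      p$stroma_intensity_mean < 0 || p$stroma_intensity_mean > 255)
    stop("intensity means must lie in [0, 255]", call. = FALSE)
  if (p$nucleus_density < 0) stop("nucleus_density must be >= 0", call. = FALSE)
  if (p$nucleus_axis_ratio_mean < 1)
    stop("nucleus_axis_ratio_mean must be >= 1", call. = FALSE)
  if (p$heterogeneity_noise_sd < 0 || p$necrosis_hole_rate < 0 ||
      p$necrosis_hole_rate > 1 || p$edge_jaggedness < 0)
    stop("invalid noise/necrosis/jaggedness parameters", call. = FALSE)
  invisible(p)
}

#' Default low-grade (LGG) rendering profile
#'
#' Small, round, sharp-edged nuclei on a relatively homogeneous stroma:
#' the coherent, organized tissue appearance of low-grade tumors.
#' @return a `class_params` object.
#' @export
lgg_params <- function() {
  class_params(
    nucleus_density = 8,
    nucleus_major_axis_mean = 11,
    nucleus_axis_ratio_mean = 1.3,
    nucleus_intensity_mean = 95,
    stroma_intensity_mean = 185,
    heterogeneity_noise_sd = 6,
    necrosis_hole_rate = 0.02,
    edge_jaggedness = 0.08
  )
}

#' Default high-grade (HGG) rendering profile
#'
#' Larger, elongated, irregular nuclei, stronger spatial heterogeneity and
#' necrosis-like foci: the hallmarks of glioblastoma histology.
#' @return a `class_params` object.
#' @export
hgg_params <- function() {
  class_params(
    nucleus_density = 13,
    nucleus_major_axis_mean = 17,
    nucleus_axis_ratio_mean = 2.1,
    nucleus_intensity_mean = 80,
    stroma_intensity_mean = 175,
    heterogeneity_noise_sd = 16,
    necrosis_hole_rate = 0.35,
    edge_jaggedness = 0.35
  )
}

# Draw a filled (possibly jagged) ellipse onto an image matrix.
# Boundary radius is modulated by two low-order sinusoids of the polar angle,
# giving a smooth, closed, irregular outline whose amplitude scales with
# `jaggedness`. Consumes RNG draws for the modulation phases/amplitudes.
draw_ellipse <- function(img, cr, cc, a, b, theta, value, jaggedness) {
  n <- nrow(img)
  ext <- a * (1 + jaggedness) + 1
  r0 <- max(1L, floor(cr - ext)); r1 <- min(n, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(ncol(img), ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(img)
  amp1 <- stats::runif(1, 0.3, 1); ph1 <- stats::runif(1, 0, 2 * pi)
  amp2 <- stats::runif(1, 0.3, 1); ph2 <- stats::runif(1, 0, 2 * pi)
  rr <- r0:r1; cc_ <- c0:c1
  dr <- matrix(rr - cr, length(rr), length(cc_))
  dc <- matrix(cc_ - cc, length(rr), length(cc_), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  rad <- sqrt((u / a)^2 + (v / b)^2)
  ang <- atan2(v, u)
  lim <- 1 + jaggedness * 0.5 * (amp1 * sin(3 * ang + ph1) +
                                 amp2 * sin(7 * ang + ph2))
  inside <- rad <= lim
  sub <- img[rr, cc_, drop = FALSE]
  sub[inside] <- value
  img[rr, cc_] <- sub
  img
}

#' Generate one synthetic grayscale histology patch
#'
#' Renders darker elliptical "nuclei" on a brighter stroma, with optional
#' necrosis-like bright focus, jagged nuclear boundaries and additive
#' intensity noise, according to a [class_params()] profile. Deterministic
#' given `rng_seed`.
#'
#' @param params a [class_params()] object.
#' @param patch_size side length in pixels (>= 64).
#' @param rng_seed integer seed.
#' @return integer matrix `patch_size` x `patch_size` with values in 0..255.
#' @examples
#' p <- generate_patch(lgg_params(), 96, rng_seed = 1)
#' range(p)
#' @export
generate_patch <- function(params, patch_size = 1024, rng_seed = 1L) {
  validate_class_params(params)
  if (patch_size < 64) stop("patch_size must be >= 64", call. = FALSE)
  patch_size <- as.integer(patch_size)
  local_seed_eval(rng_seed, {
    img <- matrix(as.numeric(params$stroma_intensity_mean),
                  patch_size, patch_size)
    n_nuclei <- stats::rpois(1, params$nucleus_density * patch_size^2 / 1e4)
    if (n_nuclei > 0) {
      for (k in seq_len(n_nuclei)) {
        cr <- stats::runif(1, 1, patch_size)
        cc <- stats::runif(1, 1, patch_size)
        half_major <- params$nucleus_major_axis_mean / 2
        a <- max(1.5, stats::rnorm(1, half_major, 0.15 * half_major))
        ratio <- max(1, stats::rnorm(1, params$nucleus_axis_ratio_mean, 0.1))
        b <- a / ratio
        th <- stats::runif(1, 0, pi)
        val <- min(255, max(0, stats::rnorm(1, params$nucleus_intensity_mean, 8)))
        img <- draw_ellipse(img, cr, cc, a, b, th, val, params$edge_jaggedness)
      }
    }
    if (stats::runif(1) < params$necrosis_hole_rate) {
      cr <- stats::runif(1, 1, patch_size)
      cc <- stats::runif(1, 1, patch_size)
      a <- stats::runif(1, 0.10, 0.25) * patch_size
      b <- a * stats::runif(1, 0.6, 1)
      th <- stats::runif(1, 0, pi)
      img <- draw_ellipse(img, cr, cc, a, b, th, 235, 0.5)
    }
    if (params$heterogeneity_noise_sd > 0)
      img <- img + matrix(stats::rnorm(patch_size^2, 0,
                                       params$heterogeneity_noise_sd),
                          patch_size, patch_size)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    img
  })
}

#' Generate a synthetic whole-slide-like image
#'
#' A larger raster rendered with the same nucleus model as
#' [generate_patch()], surrounded by a near-white "glass" margin so that
#' tissue-coverage filtering in [extract_patches()] has something to reject.
#'
#' @param params a [class_params()] profile.
#' @param slide_size side length in pixels.
#' @param rng_seed integer seed.
#' @param margin_frac fraction of each border occupied by background glass.
#' @param background_intensity gray level of the glass margin.
#' @return integer matrix with values in 0..255.
#' @export
generate_slide <- function(params, slide_size = 512, rng_seed = 1L,
                           margin_frac = 0.15, background_intensity = 245) {
  validate_class_params(params)
  tissue <- generate_patch(params, slide_size, rng_seed)
  m <- floor(margin_frac * slide_size)
  if (m > 0) {
    tissue[seq_len(m), ] <- background_intensity
    tissue[slide_size - seq_len(m) + 1L, ] <- background_intensity
    tissue[, seq_len(m)] <- background_intensity
    tissue[, slide_size - seq_len(m) + 1L] <- background_intensity
  }
  tissue
}

#' Configuration of a synthetic patient cohort
#'
#' Bundles cohort composition, per-class rendering profiles and the
#' class-conditional clinical model (age, gender). Defaults follow the
#' study design this package models: 100 patches of 1024 px per patient,
#' low-grade patients about 43 years old on average versus 57 for
#' high-grade, a common age spread of 12 years, and a male-leaning cohort.
#'
#' @param n_patients number of patients (>= 2).
#' @param hgg_fraction proportion of patients labeled HGG (strictly in (0,1)).
#' @param patches_per_patient patches rendered per patient.
#' @param patch_size patch side length in pixels (>= 64).
#' @param lgg_params,hgg_params [class_params()] profiles for the two grades.
#' @param age_mean_lgg,age_mean_hgg class-conditional mean ages, years.
#' @param age_sd common age standard deviation, years.
#' @param male_fraction baseline probability of male gender.
#' @param gender_logodds_shift additive log-odds shift of male gender for HGG
#'   patients (default 0: gender carries no label signal).
#' @param seed master integer seed for the cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          hgg_fraction = 0.5,
                          patches_per_patient = 100L,
                          patch_size = 1024L,
                          lgg_params = gliopath::lgg_params(),
                          hgg_params = gliopath::hgg_params(),
                          age_mean_lgg = 43.19,
                          age_mean_hgg = 56.79,
                          age_sd = 12,
                          male_fraction = 0.581,
                          gender_logodds_shift = 0,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    hgg_fraction = hgg_fraction,
    patches_per_patient = as.integer(patches_per_patient),
    patch_size = as.integer(patch_size),
    lgg_params = lgg_params,
    hgg_params = hgg_params,
    age_mean_lgg = age_mean_lgg,
    age_mean_hgg = age_mean_hgg,
    age_sd = age_sd,
    male_fraction = male_fraction,
    gender_logodds_shift = gender_logodds_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 2)
    stop("n_patients must be >= 2 (cross-validation undefined otherwise)",
         call. = FALSE)
  if (cfg$hgg_fraction <= 0 || cfg$hgg_fraction >= 1)
    stop("hgg_fraction must be strictly between 0 and 1", call. = FALSE)
  n_hgg <- round(cfg$n_patients * cfg$hgg_fraction)
  if (n_hgg < 1 || n_hgg > cfg$n_patients - 1)
    stop("cohort would be single-class; adjust n_patients or hgg_fraction",
         call. = FALSE)
  if (cfg$patches_per_patient < 1)
    stop("patches_per_patient must be >= 1", call. = FALSE)
  if (cfg$patch_size < 64) stop("patch_size must be >= 64", call. = FALSE)
  validate_class_params(cfg$lgg_params)
  validate_class_params(cfg$hgg_params)
  invisible(cfg)
}

#' Generate a synthetic cohort of patients with patches and clinical records
#'
#' Exactly `round(n_patients * hgg_fraction)` patients are labeled HGG.
#' Ages are drawn from the class-specific normal distribution (truncated at
#' 1 year), gender from a Bernoulli whose log-odds may shift with grade, and
#' each patient receives `patches_per_patient` patches rendered from the
#' class profile. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()] object.
#' @return a list with elements:
#'   \describe{
#'     \item{clinical}{data.frame with columns patient_id, age, gender, grade}
#'     \item{patches}{named list (by patient_id) of lists of patch matrices}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' cfg <- cohort_config(n_patients = 4, patches_per_patient = 2,
#'                      patch_size = 64, seed = 7)
#' coh <- generate_cohort(cfg)
#' coh$clinical
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  n_hgg <- round(n * config$hgg_fraction)
  local_seed_eval(config$seed, {
    grade <- c(rep("HGG", n_hgg), rep("LGG", n - n_hgg))
    grade <- sample(grade)  # shuffle class order across patient ids
    ids <- sprintf("P%03d", seq_len(n))
    age_mean <- ifelse(grade == "HGG", config$age_mean_hgg, config$age_mean_lgg)
    age <- pmax(1, stats::rnorm(n, age_mean, config$age_sd))
    p_male <- stats::plogis(stats::qlogis(config$male_fraction) +
                            config$gender_logodds_shift * (grade == "HGG"))
    gender <- ifelse(stats::runif(n) < p_male, "male", "female")
    patch_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, n * config$patches_per_patient),
      nrow = n
    )
    patches <- vector("list", n)
    names(patches) <- ids
    for (i in seq_len(n)) {
      prm <- if (grade[i] == "HGG") config$hgg_params else config$lgg_params
      patches[[i]] <- lapply(seq_len(config$patches_per_patient), function(j) {
        generate_patch(prm, config$patch_size, patch_seeds[i, j])
      })
    }
    clinical <- data.frame(
      patient_id = ids, age = age, gender = gender, grade = grade,
      stringsAsFactors = FALSE
    )
    list(clinical = clinical, patches = patches, config = config)
  })
}

#' Write a cohort to disk as PNG patches plus a clinical CSV
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed); patches go to
#'   `out_dir/patches/<patient_id>_<k>.png`, the clinical table to
#'   `out_dir/clinical.csv` with header `patient_id,age,gender,grade`.
#' @return invisibly, a data.frame manifest (patient_id, patch_id, path).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "patches"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  rows <- list()
  for (id in names(cohort$patches)) {
    pl <- cohort$patches[[id]]
    for (k in seq_along(pl)) {
      path <- file.path(out_dir, "patches", sprintf("%s_%03d.png", id, k))
      png::writePNG(pl[[k]] / 255, path)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = id, patch_id = sprintf("%s_%03d", id, k), path = path,
        stringsAsFactors = FALSE
      )
    }
  }
  invisible(do.call(rbind, rows))
}
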