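#' Configuration for an end-to-end pipeline run
#'
#' Either point `slide_dir` at a directory of PNG/TIFF slides named
#' `<patient_id>.png`/`.tif` with a matching clinical CSV, or leave it NULL
#' to simulate a cohort with [generate_cohort()].
#'
#' @param out_dir output directory for all artifacts.
#' @param slide_dir optional directory of slide images; NULL = simulate.
#' @param clinical_csv path to a clinical table (patient_id,age,gender,grade);
#'   required when `slide_dir` is given and a model using the clinical layer
#'   is requested.
#' @param cohort a [cohort_config()] used when simulating (ignored otherwise).
#' @param n_patches patches per slide when extracting from `slide_dir`.
#' @param patch_size patch side length for extraction.
#' @param filter a [tissue_filter_config()].
#' @param area_threshold component area threshold for morphology.
#' @param levels texture quantization levels.
#' @param models character vector of [model_spec()] ids to evaluate.
#' @param comparisons list of 2-element character vectors of model ids to
#'   compare by permuted runs; NULL = none.
#' @param n_iterations permuted runs per compared model.
#' @param outer_folds,inner_folds cross-validation structure.
#' @param seed master seed for the run.
#' @param write_patches write extracted/simulated patches as PNGs (default
#'   FALSE; the manifest is always written).
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       slide_dir = NULL,
                       clinical_csv = NULL,
                       cohort = cohort_config(n_patients = 20,
                                              patches_per_patient = 10,
                                              patch_size = 96),
                       n_patches = 100L,
                       patch_size = 1024L,
                       filter = tissue_filter_config(),
                       area_threshold = 100L,
                       levels = 16L,
                       models = c("Ia", "Ib", "Ic", "IIa", "IIb", "IIc", "IIIa"),
                       comparisons = NULL,
                       n_iterations = 50L,
                       outer_folds = 10L,
                       inner_folds = 5L,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  bad <- setdiff(cfg$models, c("Ia", "Ib", "Ic", "IIa", "IIb", "IIc", "IIIa"))
  if (length(bad)) stop("unknown model ids: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(cfg$slide_dir)) {
    if (!dir.exists(cfg$slide_dir))
      stop("slide_dir does not exist: ", cfg$slide_dir, call. = FALSE)
    uses_clinical <- any(vapply(cfg$models, function(id)
      "clinical" %in% model_spec(id)$layers, logical(1)))
    if (uses_clinical &&
        (is.null(cfg$clinical_csv) || !file.exists(cfg$clinical_csv)))
      stop("a model using the clinical layer is requested but clinical_csv ",
           "is missing", call. = FALSE)
  }
  for (cmp in cfg$comparisons %||% list())
    if (length(cmp) != 2 || !all(cmp %in% cfg$models))
      stop("each comparison must name two requested model ids", call. = FALSE)
  invisible(cfg)
}

#' Compute the full per-patch feature row set for a list of patches
#'
#' @param patches list of gray-level matrices.
#' @param patient_id id recorded in each row.
#' @param area_threshold morphology component area threshold.
#' @param levels texture quantization levels.
#' @return data.frame with `patient_id` plus 26 `conv_` and 18 `tex_`
#'   columns; patches whose segmentation yields no retained component are
#'   dropped with a warning.
#' @export
patch_feature_rows <- function(patches, patient_id, area_threshold = 100L,
                               levels = 16L) {
  rows <- lapply(seq_along(patches), function(k) {
    p <- patches[[k]]
    feats <- tryCatch(
      c(conventional_features(p, area_threshold), extract_texture(p, levels)),
      error = function(e) NULL
    )
    if (is.null(feats)) return(NULL)
    cbind(data.frame(patient_id = patient_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%s: dropped %d patch(es) with undefined features",
                    patient_id, dropped), call. = FALSE)
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Run the complete pipeline: simulate/extract, featurize, train, compare
#'
#' Executes the stages in order and writes all artifacts under
#' `config$out_dir`: `clinical.csv`, `manifest.csv`, `features.csv` (per
#' patch), `feature_table.csv` (per patient), `results/model_<id>.json` for
#' each requested model, `results/comparison_<A>_vs_<B>.json` for each
#' requested comparison, and `run_metadata.json` (seed, parameters, package
#' version). Re-running with the same config reproduces identical metrics.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `feature_table`, `cv_results` (named by
#'   model id), and `comparisons`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(file.path(config$out_dir, "results"), recursive = TRUE,
             showWarnings = FALSE)

  if (is.null(config$slide_dir)) {
    coh <- generate_cohort(config$cohort)
    clinical <- coh$clinical
    patient_patches <- coh$patches
    manifest <- do.call(rbind, lapply(names(patient_patches), function(id) {
      data.frame(patient_id = id,
                 patch_id = sprintf("%s_%03d", id,
                                    seq_along(patient_patches[[id]])),
                 row = NA_integer_, col = NA_integer_,
                 tissue_fraction = NA_real_, stringsAsFactors = FALSE)
    }))
  } else {
    paths <- list.files(config$slide_dir, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(paths) == 0) stop("no slides found in ", config$slide_dir,
                                 call. = FALSE)
    clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
    patient_patches <- list()
    manifest <- NULL
    for (path in paths) {
      id <- tools::file_path_sans_ext(basename(path))
      slide <- read_slide(path)
      ps <- extract_patches(slide, config$n_patches, config$patch_size,
                            config$filter, rng_seed = config$seed)
      patient_patches[[id]] <- lapply(ps, `[[`, "pixels")
      manifest <- rbind(manifest, patch_manifest(ps, id))
    }
  }

  utils::write.csv(clinical, file.path(config$out_dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)

  patch_rows <- do.call(rbind, lapply(names(patient_patches), function(id) {
    patch_feature_rows(patient_patches[[id]], id,
                       config$area_threshold, config$levels)
  }))
  utils::write.csv(patch_rows, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  table <- aggregate_patient_features(patch_rows, clinical)
  utils::write.csv(table, file.path(config$out_dir, "feature_table.csv"),
                   row.names = FALSE)

  cv_results <- list()
  for (id in config$models) {
    res <- run_cv(table, model_spec(id), outer_folds = config$outer_folds,
                  seed = config$seed, inner_folds = config$inner_folds)
    cv_results[[id]] <- res
    jsonlite::write_json(
      list(model = id,
           accuracy = res$accuracy, sensitivity = res$sensitivity,
           specificity = res$specificity, auc = res$auc,
           selected_features = res$selected, cost = res$C,
           scores = as.list(res$scores), seed = config$seed),
      file.path(config$out_dir, "results", paste0("model_", id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }

  comparisons <- list()
  run_cache <- list()
  for (cmp in config$comparisons %||% list()) {
    for (id in cmp) {
      if (is.null(run_cache[[id]]))
        run_cache[[id]] <- permuted_runs(
          table, model_spec(id), n_iterations = config$n_iterations,
          base_seed = config$seed, outer_folds = config$outer_folds,
          inner_folds = config$inner_folds)
    }
    res <- compare_models(run_cache[[cmp[1]]], run_cache[[cmp[2]]])
    key <- paste0(cmp[1], "_vs_", cmp[2])
    comparisons[[key]] <- res
    jsonlite::write_json(
      list(model_a = res$model_a, model_b = res$model_b,
           mean_auc_diff = res$mean_auc_diff,
           ci95 = unname(res$ci95), p_value = res$p_value,
           significant = res$significant, n_iterations = res$n_iterations),
      file.path(config$out_dir, "results",
                paste0("comparison_", key, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("gliopath")),
         seed = config$seed,
         models = config$models,
         outer_folds = config$outer_folds,
         inner_folds = config$inner_folds,
         n_iterations = config$n_iterations,
         area_threshold = config$area_threshold,
         levels = config$levels,
         simulated = is.null(config$slide_dir)),
    file.path(config$out_dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(feature_table = table, cv_results = cv_results,
                 comparisons = comparisons))
}
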