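#' Repeated cross-validation over permuted dataset orderings
#'
#' Applies [run_cv()] `n_iterations` times; at iteration `t` the rows of the
#' feature table are permuted with seed `base_seed + t` (which also reseeds
#' the fold assignment), and the pooled AUC is recorded. Two models run with
#' the same `base_seed` see identical permutations, so their AUC vectors are
#' paired by iteration.
#'
#' @param table feature table from [aggregate_patient_features()].
#' @param spec a [model_spec()].
#' @param n_iterations number of permuted runs (the study design uses 1000).
#' @param base_seed integer seed; iteration `t` uses `base_seed + t`.
#' @param ... further arguments passed to [run_cv()] (e.g. `outer_folds`,
#'   `c_grid`).
#' @return an object of class `permutation_runs`: list with `model_id`,
#'   `aucs` (length `n_iterations`), `seeds`.
#' @export
permuted_runs <- function(table, spec, n_iterations = 1000L, base_seed = 1L,
                          ...) {
  seeds <- base_seed + seq_len(n_iterations)
  aucs <- vapply(seeds, function(s) {
    perm <- local_seed_eval(s, sample(nrow(table)))
    run_cv(table[perm, , drop = FALSE], spec, seed = s, ...)$auc
  }, numeric(1))
  structure(list(model_id = spec$id, aucs = aucs, seeds = seeds),
            class = "permutation_runs")
}

#' Compare two models by their paired AUC differences
#'
#' Differences `d_t = aucA_t - aucB_t` are taken iteration-wise (the run sets
#' must be paired: equal length and matching seeds). Reports the mean
#' difference, the 95 percent percentile interval (2.5th and 97.5th
#' percentiles of the differences), a one-sided empirical p-value for "A
#' better than B" with add-one correction and ties at half weight,
#' `p = (1 + #\{d < 0\} + 0.5 #\{d = 0\}) / (n + 1)`, and a significance flag
#' set when the percentile interval excludes zero.
#'
#' @param runs_a,runs_b `permutation_runs` objects from [permuted_runs()].
#' @return an object of class `comparison_result`: list with `model_a`,
#'   `model_b`, `mean_auc_diff`, `ci95` (lo, hi), `p_value`, `significant`,
#'   `n_iterations`.
#' @export
compare_models <- function(runs_a, runs_b) {
  if (length(runs_a$aucs) != length(runs_b$aucs))
    stop("run sets have different lengths; differences cannot be paired",
         call. = FALSE)
  if (!is.null(runs_a$seeds) && !is.null(runs_b$seeds) &&
      !identical(runs_a$seeds, runs_b$seeds))
    stop("run sets were produced with different seeds; not paired",
         call. = FALSE)
  d <- runs_a$aucs - runs_b$aucs
  n <- length(d)
  ci <- unname(stats::quantile(d, c(0.025, 0.975), type = 7))
  p <- (1 + sum(d < 0) + 0.5 * sum(d == 0)) / (n + 1)
  structure(list(
    model_a = runs_a$model_id,
    model_b = runs_b$model_id,
    mean_auc_diff = mean(d),
    ci95 = c(lo = ci[1], hi = ci[2]),
    p_value = p,
    significant = ci[1] > 0 || ci[2] < 0,
    n_iterations = n
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: mean AUC diff %.3f, 95%% CI (%.3f, %.3f), p = %.3f%s\n",
              x$model_a, x$model_b, x$mean_auc_diff, x$ci95[1], x$ci95[2],
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Standardized between-class effect size (Cohen's d) of one feature
#'
#' `d = (mean_HGG - mean_LGG) / pooled sd`; positive values mean the feature
#' is higher in high-grade tumors. A zero pooled standard deviation yields 0
#' with a warning.
#'
#' @param values numeric feature vector.
#' @param labels factor or character vector of grades (LGG/HGG); both classes
#'   must be present.
#' @return signed numeric effect size.
#' @export
effect_size <- function(values, labels) {
  labels <- as.character(labels)
  a <- values[labels == "HGG"]
  b <- values[labels == "LGG"]
  if (length(a) < 2 || length(b) < 2)
    stop("both classes must be present with at least 2 samples", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    warning("zero pooled standard deviation; effect size undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Effect sizes of every feature in a table, ranked
#'
#' @param table feature table from [aggregate_patient_features()].
#' @return data.frame with columns `feature`, `effect_size`, sorted by
#'   decreasing absolute effect size.
#' @export
effect_size_table <- function(table) {
  feats <- setdiff(names(table), c("patient_id", "grade"))
  es <- vapply(feats, function(f) {
    tryCatch(effect_size(table[[f]], table$grade),
             warning = function(w) 0)
  }, numeric(1))
  out <- data.frame(feature = feats, effect_size = unname(es),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$effect_size)), , drop = FALSE]
}

#' Pearson correlation of two models' AUCs across permuted runs
#'
#' @inheritParams compare_models
#' @return list with `correlation` (NA when either run set has zero
#'   variance) and `defined` flag.
#' @export
auc_correlation <- function(runs_a, runs_b) {
  if (length(runs_a$aucs) != length(runs_b$aucs))
    stop("run sets have different lengths", call. = FALSE)
  if (stats::sd(runs_a$aucs) == 0 || stats::sd(runs_b$aucs) == 0) {
    warning("zero variance in at least one AUC vector; correlation undefined",
            call. = FALSE)
    return(list(correlation = NA_real_, defined = FALSE))
  }
  list(correlation = stats::cor(runs_a$aucs, runs_b$aucs), defined = TRUE)
}
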