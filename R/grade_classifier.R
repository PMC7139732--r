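#' Layered model specifications
#'
#' The seven models differ only in which feature layers they see:
#' Ia = conventional, Ib = texture, Ic = clinical, IIa = conventional+texture,
#' IIb = conventional+clinical, IIc = texture+clinical, IIIa = all three.
#' Forward feature selection is applied in every model except Ic, whose two
#' clinical features are too few to select among.
#'
#' @param id one of "Ia", "Ib", "Ic", "IIa", "IIb", "IIc", "IIIa".
#' @return an object of class `model_spec` with fields `id`, `layers`,
#'   `do_feature_selection`.
#' @export
model_spec <- function(id = c("Ia", "Ib", "Ic", "IIa", "IIb", "IIc", "IIIa")) {
  id <- match.arg(id)
  layers <- switch(id,
    Ia = "conventional",
    Ib = "texture",
    Ic = "clinical",
    IIa = c("conventional", "texture"),
    IIb = c("conventional", "clinical"),
    IIc = c("texture", "clinical"),
    IIIa = c("conventional", "texture", "clinical")
  )
  structure(list(id = id, layers = layers,
                 do_feature_selection = id != "Ic"),
            class = "model_spec")
}

layer_prefix <- c(conventional = "conv_", texture = "tex_", clinical = "clin_")

# Column names of `table` belonging to the spec's layers.
layer_columns <- function(table, layers) {
  pref <- layer_prefix[layers]
  nm <- names(table)
  nm[grepl(paste0("^(", paste(pref, collapse = "|"), ")"), nm)]
}

#' Aggregate per-patch features to one row per patient
#'
#' Patient-level imaging features are the mean over that patient's patches;
#' clinical covariates (age, gender with male = 1, female = 0) and the grade
#' label are joined from the clinical table. Patients present in the clinical
#' table but without any valid patch rows are excluded with a warning.
#'
#' @param patch_features data.frame with a `patient_id` column and numeric
#'   feature columns (prefixes `conv_`/`tex_`).
#' @param clinical data.frame with columns patient_id, age, gender, grade.
#' @return a feature table: data.frame with `patient_id`, `grade` (factor
#'   LGG/HGG), `clin_age`, `clin_gender`, and the aggregated feature columns.
#' @export
aggregate_patient_features <- function(patch_features, clinical) {
  stopifnot("patient_id" %in% names(patch_features))
  feat_cols <- setdiff(names(patch_features), "patient_id")
  groups <- split(patch_features[feat_cols],
                  factor(patch_features$patient_id,
                         levels = unique(patch_features$patient_id)))
  agg <- do.call(rbind, lapply(groups, function(g) colMeans(as.matrix(g))))
  agg <- data.frame(patient_id = names(groups), agg,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing <- setdiff(clinical$patient_id, agg$patient_id)
  if (length(missing))
    warning("excluding patients with no valid patches: ",
            paste(missing, collapse = ", "), call. = FALSE)
  clin <- clinical[clinical$patient_id %in% agg$patient_id, , drop = FALSE]
  out <- merge(clin, agg, by = "patient_id", sort = TRUE)
  out$clin_age <- out$age
  out$clin_gender <- as.numeric(out$gender == "male")
  out$grade <- factor(out$grade, levels = c("LGG", "HGG"))
  out$age <- NULL
  out$gender <- NULL
  # stable column order: id, label, clinical, imaging layers
  feat <- setdiff(names(out), c("patient_id", "grade"))
  out[c("patient_id", "grade",
        feat[order(match(substr(feat, 1, 4),
                         c("clin", "conv", "tex_")))])]
}

# Stratified fold assignment: within each class, shuffle and deal out folds
# round-robin. Deterministic given seed.
make_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("need at least ", k, " samples per class for ", k,
         "-fold stratification", call. = FALSE)
  fold <- integer(length(y))
  local_seed_eval(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Decision values of a fitted binary linear SVM, computed directly from the
# support-vector expansion f(x) = x.w - rho with w = SV' alpha. Equivalent to
# predict.svm with decision.values = TRUE (asserted in the test suite) but
# without its per-call data-frame overhead, which dominates at small n.
linear_decision_values <- function(fit, xte) {
  w <- crossprod(fit$SV, fit$coefs)
  dv <- as.numeric(xte %*% w) - fit$rho
  first <- fit$levels[fit$labels[1]]  # positive decision value -> this class
  list(dv = dv, first = first,
       second = fit$levels[fit$labels[2]])
}

# Fit a linear SVM and return decision scores oriented so that larger values
# favor the HGG class, plus predicted labels.
svm_fit_score <- function(xtr, ytr, xte, cost) {
  # inputs are validated NA-free upstream; identity skips the costly
  # na.omit round-trip inside svm.default
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE,
                    fitted = FALSE, na.action = identity)
  d <- linear_decision_values(fit, xte)
  pred <- factor(ifelse(d$dv > 0, d$first, d$second), levels = levels(ytr))
  score <- if (d$first == "HGG") d$dv else -d$dv
  list(pred = pred, score = score)
}

# Pooled inner-CV accuracy of a linear SVM on a feature subset.
inner_cv_accuracy <- function(x, y, feats, folds, cost) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    fit <- e1071::svm(x[tr, feats, drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE, fitted = FALSE,
                      na.action = identity)
    d <- linear_decision_values(fit, x[te, feats, drop = FALSE])
    correct <- correct + sum(ifelse(d$dv > 0, d$first, d$second) ==
                               as.character(y[te]))
  }
  correct / length(y)
}

#' Greedy forward feature selection under inner cross-validation
#'
#' Starting from the empty set, repeatedly adds the feature that maximizes
#' pooled inner k-fold accuracy of a linear SVM on the training data. The
#' first feature (the best single feature) is always kept; thereafter the
#' search stops as soon as the best achievable improvement over the current
#' accuracy is at most `tol` (steady state) or negative (performance drop).
#'
#' @param x numeric matrix of training features (already scaled).
#' @param y factor of labels (levels LGG, HGG).
#' @param inner_folds folds for the inner CV (default 5).
#' @param cost SVM cost parameter used during the search (default 1).
#' @param tol minimum accuracy improvement to continue (default 0.001).
#' @param seed integer seed for the fold assignment.
#' @return character vector of selected feature names, in selection order.
#' @export
forward_select <- function(x, y, inner_folds = 5L, cost = 1, tol = 0.001,
                           seed = 1L) {
  folds <- make_folds(y, inner_folds, seed)
  remaining <- colnames(x)
  selected <- character(0)
  current <- -Inf
  while (length(remaining) > 0) {
    accs <- vapply(remaining, function(f) {
      inner_cv_accuracy(x, y, c(selected, f), folds, cost)
    }, numeric(1))
    best <- which.max(accs)
    improvement <- accs[best] - current
    if (length(selected) > 0 && improvement <= tol) break
    selected <- c(selected, remaining[best])
    current <- accs[best]
    remaining <- remaining[-best]
  }
  selected
}

#' Grid search for the SVM cost parameter
#'
#' Evaluates each candidate cost by pooled inner k-fold accuracy and returns
#' the best; ties are broken toward the smallest cost (the grid is scanned in
#' increasing order and only strict improvements replace the incumbent).
#'
#' @inheritParams forward_select
#' @param grid candidate costs; the default is the 11-point dyadic grid
#'   `2^(-5:5)`.
#' @return list with `C` (chosen cost) and `accuracy` (its inner-CV accuracy).
#' @export
tune_C <- function(x, y, inner_folds = 5L, grid = 2^(-5:5), seed = 1L) {
  folds <- make_folds(y, inner_folds, seed)
  grid <- sort(grid)
  best_c <- grid[1]; best_acc <- -Inf
  for (cost in grid) {
    acc <- inner_cv_accuracy(x, y, colnames(x), folds, cost)
    if (acc > best_acc) { best_acc <- acc; best_c <- cost }
  }
  list(C = best_c, accuracy = best_acc)
}

#' Nested cross-validated evaluation of one layered model
#'
#' Stratified `outer_folds`-fold cross-validation. Within each training
#' fold: feature-wise z-scaling (training mean/sd; zero-sd features are
#' centered only), forward feature selection (unless the spec disables it),
#' cost tuning on the dyadic grid, and a final linear SVM fit. Test-fold
#' decision scores are pooled across folds; accuracy, sensitivity and
#' specificity come from the pooled confusion matrix with HGG as the
#' positive class, and AUC from the pooled scores.
#'
#' @param table feature table from [aggregate_patient_features()].
#' @param spec a [model_spec()].
#' @param outer_folds number of outer folds (default 10).
#' @param seed integer seed governing all fold assignments.
#' @param inner_folds inner folds for selection/tuning (default 5).
#' @param c_grid cost grid; pass a single value to fix the cost.
#' @param select_cost cost used during forward selection (default 1).
#' @param tol forward-selection improvement tolerance.
#' @param folds optional externally supplied fold assignment (integer vector
#'   in 1..outer_folds), overriding the seeded stratified assignment.
#' @return an object of class `cv_result`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percent), `auc`, `scores` (per-patient
#'   pooled decision scores, named), `predicted`, `fold`, `selected`
#'   (per-fold selected features), `C` (per-fold cost), `spec`, `seed`.
#' @export
run_cv <- function(table, spec, outer_folds = 10L, seed = 1L,
                   inner_folds = 5L, c_grid = 2^(-5:5), select_cost = 1,
                   tol = 0.001, folds = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y <- table$grade
  if (!is.factor(y)) y <- factor(y, levels = c("LGG", "HGG"))
  cols <- layer_columns(table, spec$layers)
  if (length(cols) == 0) stop("no feature columns for layers: ",
                              paste(spec$layers, collapse = ", "),
                              call. = FALSE)
  x <- as.matrix(table[cols])
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  if (is.null(folds)) folds <- make_folds(y, outer_folds, seed)
  if (any(vapply(seq_len(outer_folds),
                 function(f) length(unique(y[folds != f])) < 2, logical(1))))
    stop("a training fold lost one class; stratification failed",
         call. = FALSE)
  n <- nrow(x)
  scores <- numeric(n)
  predicted <- factor(rep(NA_character_, n), levels = levels(y))
  selected <- vector("list", outer_folds)
  cost_used <- numeric(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- folds != f
    te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1  # zero-sd features: center only
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    inner_seed <- (seed * 131L + f) %% .Machine$integer.max
    feats <- if (spec$do_feature_selection)
      forward_select(xtr, y[tr], inner_folds, select_cost, tol, inner_seed)
    else colnames(xtr)
    cost <- if (length(c_grid) > 1)
      tune_C(xtr[, feats, drop = FALSE], y[tr], inner_folds, c_grid,
             inner_seed)$C
    else c_grid
    fit <- svm_fit_score(xtr[, feats, drop = FALSE], y[tr],
                         xte[, feats, drop = FALSE], cost)
    scores[te] <- fit$score
    predicted[te] <- fit$pred
    selected[[f]] <- feats
    cost_used[f] <- cost
  }
  tp <- sum(predicted == "HGG" & y == "HGG")
  tn <- sum(predicted == "LGG" & y == "LGG")
  fp <- sum(predicted == "HGG" & y == "LGG")
  fn <- sum(predicted == "LGG" & y == "HGG")
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        levels = c("LGG", "HGG"),
                                        direction = "<", quiet = TRUE)))
  structure(list(
    accuracy = 100 * (tp + tn) / n,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    auc = auc,
    scores = stats::setNames(scores, table$patient_id),
    predicted = predicted,
    fold = folds,
    selected = selected,
    C = cost_used,
    spec = spec,
    seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Model %s: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
    x$spec$id, x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
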