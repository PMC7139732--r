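test_that("model specs encode the seven layer combinations", {
  expect_equal(model_spec("Ia")$layers, "conventional")
  expect_equal(model_spec("Ib")$layers, "texture")
  expect_equal(model_spec("Ic")$layers, "clinical")
  expect_false(model_spec("Ic")$do_feature_selection)
  expect_equal(model_spec("IIa")$layers, c("conventional", "texture"))
  expect_setequal(model_spec("IIIa")$layers,
                  c("conventional", "texture", "clinical"))
  expect_true(model_spec("IIIa")$do_feature_selection)
  expect_error(model_spec("IV"))
})

test_that("patient aggregation is the per-patient mean plus clinical join", {
  clin <- data.frame(patient_id = c("A", "B"), age = c(40, 60),
                     gender = c("male", "female"), grade = c("LGG", "HGG"))
  rows <- data.frame(patient_id = c("A", "A", "B"),
                     conv_x = c(2, 4, 10), tex_y = c(1, 3, 5))
  tab <- aggregate_patient_features(rows, clin)
  expect_equal(tab$conv_x[tab$patient_id == "A"], 3)
  expect_equal(tab$tex_y[tab$patient_id == "A"], 2)
  expect_equal(tab$conv_x[tab$patient_id == "B"], 10)
  expect_equal(tab$clin_gender, c(1, 0))
  expect_equal(tab$clin_age, c(40, 60))
  expect_s3_class(tab$grade, "factor")

  # identical patches: patient row equals the patch row
  rows1 <- data.frame(patient_id = c("A", "A"), conv_x = c(7, 7))
  tab1 <- aggregate_patient_features(rows1, clin[1, ])
  expect_equal(tab1$conv_x, 7)

  # random cohort equals brute-force group means
  set.seed(5)
  rnd <- data.frame(patient_id = sample(c("A", "B"), 30, TRUE),
                    conv_u = rnorm(30), tex_v = rnorm(30))
  tab2 <- aggregate_patient_features(rnd, clin)
  for (id in c("A", "B")) {
    expect_equal(tab2$conv_u[tab2$patient_id == id],
                 mean(rnd$conv_u[rnd$patient_id == id]))
    expect_equal(tab2$tex_v[tab2$patient_id == id],
                 mean(rnd$tex_v[rnd$patient_id == id]))
  }

  expect_warning(
    aggregate_patient_features(rows,
      rbind(clin, data.frame(patient_id = "C", age = 50, gender = "male",
                             grade = "LGG"))),
    "no valid patches")
})

test_that("forward selection finds a separating feature and prunes duplicates", {
  set.seed(2)
  n <- 40
  y <- factor(rep(c("LGG", "HGG"), each = n / 2), c("LGG", "HGG"))
  x <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(NULL, c(paste0("noise", 1:10), "signal")))
  x[, "signal"] <- ifelse(y == "HGG", 1, -1) + rnorm(n, 0, 0.05)
  sel <- forward_select(x, y, seed = 3)
  expect_equal(sel[1], "signal")

  xdup <- cbind(x, signal_copy = x[, "signal"])
  sel2 <- forward_select(xdup, y, seed = 3)
  expect_equal(sum(sel2 %in% c("signal", "signal_copy")), 1)
})

test_that("forward selection stays short on pure noise", {
  n <- 40
  y <- factor(rep(c("LGG", "HGG"), each = n / 2), c("LGG", "HGG"))
  lens <- sapply(1:10, function(s) {
    x <- withr::with_seed(s, matrix(rnorm(n * 10), n, 10,
                                    dimnames = list(NULL, paste0("f", 1:10))))
    length(forward_select(x, y, seed = s))
  })
  expect_gte(mean(lens <= 2), 0.9)
})

test_that("cost tuning searches the dyadic grid with small-C tie-breaking", {
  n <- 30
  y <- factor(rep(c("LGG", "HGG"), each = n / 2), c("LGG", "HGG"))
  x <- matrix(ifelse(y == "HGG", 5, -5) + rnorm(n, 0, 0.01), ncol = 1,
              dimnames = list(NULL, "f"))
  res <- tune_C(x, y, seed = 1)
  expect_equal(res$C, 2^-5)  # all grid points perfect; tie broken downward
  expect_true(res$C %in% 2^(-5:5))
  set.seed(9)
  x2 <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_true(tune_C(x2, y, seed = 1)$C %in% 2^(-5:5))
})

test_that("run_cv is deterministic and exposes the layered feature matrix", {
  tab <- make_feature_table(30, seed = 4)
  r1 <- run_cv(tab, model_spec("IIIa"), outer_folds = 5, seed = 7,
               c_grid = 1)
  r2 <- run_cv(tab, model_spec("IIIa"), outer_folds = 5, seed = 7,
               c_grid = 1)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(length(layer_columns <- setdiff(names(tab),
                                               c("patient_id", "grade"))), 46)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 100))
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  # sensitivity/specificity consistent with pooled confusion matrix
  cm_sens <- 100 * sum(r1$predicted == "HGG" & tab$grade == "HGG") /
    sum(tab$grade == "HGG")
  expect_equal(r1$sensitivity, cm_sens)
})

test_that("run_cv separates an informative cohort and stays at chance on noise", {
  tab <- make_feature_table(60, d_conv = 3, d_tex = 3, d_clin = 1, seed = 6)
  res <- run_cv(tab, model_spec("IIIa"), outer_folds = 5, seed = 2,
                c_grid = 2^c(-3, 0, 3))
  expect_gte(res$accuracy, 90)
  expect_gte(res$auc, 0.95)

  null_tab <- make_feature_table(60, d_conv = 0, d_tex = 0, d_clin = 0,
                                 seed = 8)
  res0 <- run_cv(null_tab, model_spec("Ic"), outer_folds = 5, seed = 2,
                 c_grid = 1)
  expect_gte(res0$accuracy, 25)
  expect_lte(res0$accuracy, 75)
})

test_that("training-fold pipelines never see test-fold labels", {
  tab <- make_feature_table(30, seed = 10)
  y <- factor(tab$grade, c("LGG", "HGG"))
  folds <- withr::with_seed(1, {
    f <- integer(nrow(tab))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(1:5, length(idx))
    }
    f
  })
  base <- run_cv(tab, model_spec("Ia"), outer_folds = 5, seed = 3,
                 c_grid = 1, folds = folds)
  for (f in 1:5) {
    corrupted <- tab
    te <- folds == f
    corrupted$grade[te] <- ifelse(corrupted$grade[te] == "HGG", "LGG", "HGG")
    res <- run_cv(corrupted, model_spec("Ia"), outer_folds = 5, seed = 3,
                  c_grid = 1, folds = folds)
    expect_identical(res$scores[te], base$scores[te])
  }
})

test_that("direct linear decision values agree with predict.svm", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(12:30, 1); d <- sample(1:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- factor(c(sample(c("LGG", "HGG"), 1),
                  sample(c("LGG", "HGG"), n - 1, TRUE)), c("LGG", "HGG"))
    if (length(unique(y)) < 2) next
    fit <- e1071::svm(x, y, kernel = "linear", cost = 2^sample(-5:5, 1),
                      scale = FALSE, fitted = FALSE)
    xt <- matrix(rnorm(6 * d), 6, d)
    ref <- predict(fit, xt, decision.values = TRUE)
    man <- gliopath:::linear_decision_values(fit, xt)
    expect_equal(man$dv, unname(attr(ref, "decision.values")[, 1]),
                 tolerance = 1e-10)
    expect_equal(ifelse(man$dv > 0, man$first, man$second),
                 unname(as.character(ref)))
  }
})
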