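test_that("train/test split follows the floor convention and partitions", {
  sp <- split_train_test(11019, 0.8, seed = 1)
  expect_length(sp$train, 8816)
  expect_length(sp$test, 2203)
  expect_equal(split_train_test(10, seed = 2)$test |> length(), 2)
  expect_length(split_train_test(5, seed = 3)$test, 1)
  expect_setequal(c(sp$train, sp$test), seq_len(11019))
  expect_length(intersect(sp$train, sp$test), 0)
  # different seeds shuffle differently, same seed identically
  expect_identical(split_train_test(100, seed = 7),
                   split_train_test(100, seed = 7))
  expect_false(identical(split_train_test(100, seed = 7),
                         split_train_test(100, seed = 8)))
})

test_that("labelling rules build the three published contrasts", {
  tsp <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                        tsp = c(0.9, 0.8, 0.5, 0.2, -0.2, -0.6))
  rest <- label_genes(tsp, "specific_vs_rest")
  expect_equal(rest$label, c(1, 1, 0, 0, 0, 0))
  under <- label_genes(tsp, "specific_vs_under")
  expect_equal(under$gene_id, c("g1", "g2", "g6"))
  expect_equal(under$label, c(1, 1, 0))
  gen <- label_genes(tsp, "specific_vs_general")
  expect_equal(gen$gene_id, c("g1", "g2", "g4"))
  tg <- label_genes(tsp, "target_set", targets = c("g3", "g5"))
  expect_equal(tg$label, c(0, 0, 1, 0, 1, 0))
})

test_that("SMOTE balances classes with points inside the minority hull", {
  withr::with_seed(31, {
    x <- rbind(matrix(stats::rnorm(200, 0, 1), ncol = 2),
               matrix(stats::rnorm(20, 5, 0.5), ncol = 2))
    y <- c(rep(0, 100), rep(1, 10))
  })
  out <- smote_oversample(x, y, k = 5, seed = 1)
  expect_equal(sum(out$y == 0), sum(out$y == 1))
  synth <- out$x[-seq_len(nrow(x)), ]
  mino <- x[y == 1, ]
  # interpolation keeps every coordinate inside the minority bounding box
  expect_true(all(synth[, 1] >= min(mino[, 1]) &
                    synth[, 1] <= max(mino[, 1])))
  expect_true(all(synth[, 2] >= min(mino[, 2]) &
                    synth[, 2] <= max(mino[, 2])))
  expect_identical(smote_oversample(x, y, seed = 4),
                   smote_oversample(x, y, seed = 4))
  expect_error(smote_oversample(x, rep(1, nrow(x))),
               class = "testistools_parameter_error")
})

test_that("SMOTE with one neighbour forces collinear synthetic points", {
  x <- rbind(matrix(stats::rnorm(40, 10, 0.1), ncol = 2),
             c(0, 0), c(2, 2))
  y <- c(rep(0, 20), 1, 1)
  out <- smote_oversample(x, y, k = 1, seed = 2)
  synth <- out$x[-seq_len(nrow(x)), ]
  # every synthetic point lies on the segment (0,0)-(2,2)
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-12))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 2))
})

test_that("AUC matches hand cases, ties, and the pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)),
               class = "testistools_parameter_error")
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(10:200, 1)
      scores <- round(stats::runif(n), sample(c(1, 3), 1))  # force ties
      labels <- stats::rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels)$auc,
                   auc_pairwise_oracle(scores, labels))
    }
  })
})

test_that("confusion metrics match hand arithmetic and flag degeneracies", {
  pred <- c(rep(1, 100), rep(0, 900))
  act <- c(rep(1, 90), rep(0, 10), rep(1, 10), rep(0, 890))
  m <- confusion_metrics(pred, act)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9889, tolerance = 1e-4)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$npv, 0.9889, tolerance = 1e-4)
  expect_equal(m$tp + m$fp + m$fn + m$tn, 1000)

  perfect <- confusion_metrics(act, act)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), rep(1, 4))
  nopos <- confusion_metrics(rep(0, 4), c(1, 0, 1, 0))
  expect_true(is.na(nopos$ppv))
  expect_false(is.na(nopos$npv))
  expect_error(confusion_metrics(1, c(1, 0)),
               class = "testistools_parameter_error")
})

test_that("boosting separates a separable toy and recovers the signal", {
  withr::with_seed(41, {
    x <- cbind(info = c(stats::rnorm(100, 0), stats::rnorm(100, 4)),
               matrix(stats::rnorm(200 * 9), 200, 9,
                      dimnames = list(NULL, paste0("noise", 1:9))))
    y <- rep(c(0, 1), each = 100)
  })
  fit <- train_gbt(x, y, nrounds = 50, seed = 1)
  train_scores <- predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
  expect_equal(roc_auc(train_scores, y)$auc, 1)
  imp <- feature_importances(fit, colnames(x))
  expect_equal(imp$feature[1], "info")
  expect_true(all(imp$weight >= 0))
  expect_type(imp$weight, "integer")
  tree <- xgboost::xgb.model.dt.tree(model = fit)
  expect_equal(sum(imp$weight), sum(tree$Feature != "Leaf"))
  unused <- imp[imp$feature == "noise1", ]
  if (nrow(unused) && unused$weight == 0) {
    expect_equal(unname(unlist(unused[c("gain", "weight", "cover")])),
                 c(0, 0, 0))
  }
  expect_error(feature_importances("not a model"),
               class = "testistools_parameter_error")
})

test_that("pure-noise features give chance-level test AUC", {
  aucs <- vapply(1:6, function(s) {
    withr::with_seed(100 + s, {
      x <- matrix(stats::rnorm(500 * 10), 500, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
      y <- stats::rbinom(500, 1, 0.5)
    })
    sp <- split_train_test(500, seed = s)
    fit <- train_gbt(x[sp$train, ], y[sp$train], nrounds = 30, seed = s)
    sc <- predict(fit, xgboost::xgb.DMatrix(x[sp$test, ], nthread = 1))
    roc_auc(sc, y[sp$test])$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("random-search tuning stays in bounds and improves monotonically", {
  withr::with_seed(53, {
    x <- cbind(a = stats::rnorm(120), b = stats::rnorm(120))
    y <- as.integer(x[, 1] + 0.5 * stats::rnorm(120) > 0)
  })
  p1 <- tune_gbt(x, y, budget = 1, seed = 5, nrounds = 20)
  expect_true(p1$eta >= 0.03 && p1$eta <= 0.3)
  expect_true(p1$max_depth %in% 3:8)
  expect_true(p1$subsample >= 0.6 && p1$subsample <= 1)
  p4 <- tune_gbt(x, y, budget = 4, seed = 5, nrounds = 20)
  expect_gte(attr(p4, "cv_auc"), attr(p1, "cv_auc"))
  # the budget-1 configuration is the first of the budget-4 trace
  expect_equal(attr(p4, "trace")$cv_auc[1], attr(p1, "cv_auc"))
  expect_error(tune_gbt(x, y, budget = 0),
               class = "testistools_parameter_error")
})
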