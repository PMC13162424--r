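#' Shuffled train/test split with a floor convention for the test set
#'
#' The test set receives `floor(n * (1 - train_fraction))` records and the
#' training set the remainder, so 11019 records at an 80:20 ratio split
#' into 8816 training and 2203 testing records.
#'
#' @param n Number of records (>= 2).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, train_fraction = 0.8, seed = 1) {
  if (!is_count(n) || n < 2) abort_param("n must be an integer >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_param("train_fraction must be in (0, 1)")
  }
  n_test <- floor(n * (1 - train_fraction) + 1e-9)
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n - n_test)]),
       test = sort(perm[seq_len(n_test) + (n - n_test)]))
}

#' Label genes for a testis-specificity contrast
#'
#' Builds the binary labels of the three classification contrasts from the
#' testis-specificity index: positives are genes with `tsp >= 0.8`
#' (testis-specific); negatives are the rest (`specific_vs_rest`), the
#' under-represented genes `tsp < -0.45` (`specific_vs_under`), or the
#' generally expressed genes `-0.1 < tsp < 0.4` (`specific_vs_general`).
#' Genes matching neither predicate are excluded.
#'
#' @param tsp Tibble `gene_id`, `tsp`.
#' @param rule Contrast name, or `"target_set"` with `targets` supplied to
#'   label membership in an explicit gene list (e.g. TF targets).
#' @param targets Character vector of positive gene ids for
#'   `rule = "target_set"`.
#' @return A tibble `gene_id`, `label` (1 = positive), with attribute
#'   `rule`.
#' @export
label_genes <- function(tsp, rule = c("specific_vs_rest", "specific_vs_under",
                                      "specific_vs_general", "target_set"),
                        targets = NULL) {
  rule <- match.arg(rule)
  tsp <- tsp[!is.na(tsp$tsp), ]
  if (rule == "target_set") {
    if (is.null(targets)) abort_param("target_set rule requires `targets`")
    out <- tibble::tibble(gene_id = tsp$gene_id,
                          label = as.integer(tsp$gene_id %in% targets))
  } else {
    pos <- tsp$tsp >= 0.8
    neg <- switch(rule,
      specific_vs_rest = tsp$tsp < 0.8,
      specific_vs_under = tsp$tsp < -0.45,
      specific_vs_general = tsp$tsp > -0.1 & tsp$tsp < 0.4)
    keep <- pos | neg
    out <- tibble::tibble(gene_id = tsp$gene_id[keep],
                          label = as.integer(pos[keep]))
  }
  attr(out, "rule") <- rule
  out
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by interpolating synthetic minority
#' points: each synthetic point lies uniformly on the segment between a
#' minority point and one of its `k` nearest minority neighbours
#' (Euclidean). Intended for training data only — apply after the
#' train/test split.
#'
#' @param x Numeric feature matrix (rows = records).
#' @param y Binary label vector (two classes required).
#' @param k Number of minority neighbours (reduced with a warning when the
#'   minority class has <= k members).
#' @param seed Integer seed.
#' @return A list `x`, `y` with classes balanced to the majority count.
#' @export
smote_oversample <- function(x, y, k = 5, seed = 1) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) abort_param("SMOTE requires exactly two classes")
  n_by <- table(factor(y, levels = classes))
  minority <- classes[which.min(n_by)]
  n_min <- min(n_by)
  n_new <- max(n_by) - n_min
  if (n_new == 0) return(list(x = x, y = y))
  if (n_min < 2) abort_param("minority class too small for SMOTE")
  if (k >= n_min) {
    warning(sprintf("k reduced from %d to %d (minority size %d)",
                    k, n_min - 1, n_min), call. = FALSE)
    k <- n_min - 1
  }
  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k)]))
  synth <- withr::with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    lambda <- stats::runif(n_new)
    xm[base, , drop = FALSE] +
      lambda * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  list(x = rbind(x, synth), y = c(y, rep(minority, n_new)))
}

#' Train a gradient-boosted tree classifier
#'
#' Thin deterministic wrapper around xgboost's binary logistic objective
#' (single thread, fixed seed). Hyperparameters not supplied fall back to
#' `eta = 0.1`, `max_depth = 6`, `subsample = 1`, `colsample_bytree = 1`,
#' `min_child_weight = 1`.
#'
#' @param x Numeric feature matrix with column names.
#' @param y Binary 0/1 label vector.
#' @param params Named list of xgboost parameters to override.
#' @param nrounds Boosting rounds (default 200).
#' @param seed Integer seed.
#' @return An `xgb.Booster`.
#' @export
train_gbt <- function(x, y, params = list(), nrounds = 200, seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) abort_param("feature matrix contains missing values")
  defaults <- list(objective = "binary:logistic", eval_metric = "auc",
                   eta = 0.1, max_depth = 6, subsample = 1,
                   colsample_bytree = 1, min_child_weight = 1,
                   nthread = 1, seed = seed)
  params <- utils::modifyList(defaults, params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  withr::with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
}

#' Random-search hyperparameter tuning by cross-validated AUC
#'
#' Samples `budget` configurations from a bounded space (learning rate,
#' tree depth, row/column subsampling, minimum child weight) and scores
#' each by 3-fold cross-validated AUC. Configuration `i` is derived from a
#' per-iteration child seed, so enlarging the budget never changes — and
#' never worsens — the configurations already visited.
#'
#' @param x,y Training features and binary labels.
#' @param budget Number of configurations (>= 1).
#' @param seed Integer seed.
#' @param nrounds Boosting rounds per evaluation (default 100).
#' @return The best parameter list, with attributes `cv_auc` and `trace`
#'   (tibble of all evaluated configurations).
#' @export
tune_gbt <- function(x, y, budget = 10, seed = 1, nrounds = 100) {
  if (!is_count(budget) || budget < 1) abort_param("budget must be >= 1")
  x <- as.matrix(x)
  best <- NULL
  best_auc <- -Inf
  trace <- vector("list", budget)
  for (i in seq_len(budget)) {
    si <- child_seed(seed, i)
    cand <- withr::with_seed(si, list(
      eta = exp(stats::runif(1, log(0.03), log(0.3))),
      max_depth = sample(3:8, 1),
      subsample = stats::runif(1, 0.6, 1),
      colsample_bytree = stats::runif(1, 0.6, 1),
      min_child_weight = sample(1:10, 1)))
    auc <- cv_auc(x, y, cand, nrounds = nrounds, nfold = 3, seed = si)
    trace[[i]] <- tibble::tibble(iter = i, cv_auc = auc,
                                 eta = cand$eta, max_depth = cand$max_depth,
                                 subsample = cand$subsample,
                                 colsample_bytree = cand$colsample_bytree,
                                 min_child_weight = cand$min_child_weight)
    if (auc > best_auc) {
      best_auc <- auc
      best <- cand
    }
  }
  attr(best, "cv_auc") <- best_auc
  attr(best, "trace") <- dplyr::bind_rows(trace)
  best
}

# k-fold cross-validated AUC for one configuration
cv_auc <- function(x, y, params, nrounds, nfold, seed) {
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(nfold), length(y))))
  aucs <- vapply(seq_len(nfold), function(f) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2) return(NA_real_)
    fit <- train_gbt(x[tr, , drop = FALSE], y[tr], params = params,
                     nrounds = nrounds, seed = seed)
    sc <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                            nthread = 1))
    roc_auc(sc, y[!tr])$auc
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (tied scores collapsed), returns the ROC
#' curve and the area under it by trapezoidal integration — equivalent to
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`, with ties
#' counting one half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary 0/1 (or logical) true labels; both classes must be
#'   present.
#' @return A list: `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort_param("length mismatch")
  if (length(unique(labels)) < 2) abort_param("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n_pos <- sum(l == 1)
  n_neg <- sum(l == 0)
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied-score run
  tp <- cumsum(l == 1)[keep]
  fp <- cumsum(l == 0)[keep]
  curve <- tibble::tibble(threshold = c(Inf, s[keep]),
                          fpr = c(0, fp / n_neg),
                          tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Confusion-matrix metrics
#'
#' @param predicted,actual Binary 0/1 vectors of equal length.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`
#'   (TP/(TP+FN)), `specificity` (TN/(TN+FP)), `ppv` (TP/(TP+FP)), `npv`
#'   (TN/(TN+FN)); ratios with zero denominators are `NA`.
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort_param("length mismatch")
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  tp <- sum(predicted == 1 & actual == 1)
  fp <- sum(predicted == 1 & actual == 0)
  fn <- sum(predicted == 0 & actual == 1)
  tn <- sum(predicted == 0 & actual == 0)
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = rate(tp, fn), specificity = rate(tn, fp),
                 ppv = rate(tp, fp), npv = rate(tn, fn))
}

#' Gain, weight and cover feature importances
#'
#' Extracts per-feature totals from the fitted trees: `gain` is the summed
#' loss improvement of the feature's splits, `weight` the integer number of
#' splits using the feature, and `cover` the summed number of observations
#' covered by those splits. Features never used in a split score 0.
#'
#' @param model A fitted `xgb.Booster` from [train_gbt()].
#' @param feature_names Optional feature names to report (defaults to the
#'   model's).
#' @return A tibble `feature`, `gain`, `weight`, `cover`, sorted by gain.
#' @export
feature_importances <- function(model, feature_names = NULL) {
  if (!inherits(model, "xgb.Booster")) abort_param("not a fitted booster")
  tree <- xgboost::xgb.model.dt.tree(model = model)
  splits <- tree[tree$Feature != "Leaf", ]
  agg <- splits |>
    dplyr::group_by(feature = .data$Feature) |>
    dplyr::summarise(gain = sum(.data$Gain), weight = dplyr::n(),
                     cover = sum(.data$Cover), .groups = "drop")
  feature_names <- feature_names %||% agg$feature
  out <- tibble::tibble(feature = feature_names) |>
    dplyr::left_join(agg, by = "feature") |>
    dplyr::mutate(dplyr::across(c("gain", "weight", "cover"),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  out$weight <- as.integer(out$weight)
  out
}

#' Classify testis-enriched genes from testis-only features
#'
#' The full classification pipeline for one contrast: label genes by the
#' testis-specificity rule, split 80:20 (floor convention on the test set),
#' balance the training data with SMOTE, fit a gradient-boosted tree
#' classifier, and evaluate on the held-out test set (ROC/AUC from scores;
#' confusion metrics at a 0.5 score cutoff).
#'
#' @param features Standardized feature tibble (`gene_id` + numeric
#'   columns).
#' @param tsp Tibble `gene_id`, `tsp`.
#' @param rule Contrast passed to [label_genes()].
#' @param targets Positive gene list for `rule = "target_set"`.
#' @param train_fraction Training fraction (default 0.8).
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param params Optional xgboost parameter overrides; when `tune_budget >
#'   0` they are found by [tune_gbt()] instead.
#' @param nrounds Boosting rounds (default 200).
#' @param tune_budget Random-search budget (0 = no tuning).
#' @param seed Integer seed driving split, SMOTE, tuning and training.
#' @return A `testis_gbt` object: the fitted booster plus report metrics,
#'   ROC curve, importances and split sizes. Supports [glance()], [tidy()],
#'   [autoplot()].
#' @export
classify_testis <- function(features, tsp, rule = "specific_vs_rest",
                            targets = NULL, train_fraction = 0.8,
                            smote_k = 5, params = NULL, nrounds = 200,
                            tune_budget = 0, seed = 1) {
  lab <- label_genes(tsp, rule = rule, targets = targets)
  df <- dplyr::inner_join(lab, features, by = "gene_id")
  if (length(unique(df$label)) < 2) {
    abort_param("labelling rule produced a single class")
  }
  x <- as.matrix(df[setdiff(names(df), c("gene_id", "label"))])
  y <- df$label
  sp <- split_train_test(nrow(df), train_fraction, seed = seed)
  bal <- smote_oversample(x[sp$train, , drop = FALSE], y[sp$train],
                          k = smote_k, seed = child_seed(seed, 11))
  if (tune_budget > 0) {
    params <- tune_gbt(bal$x, bal$y, budget = tune_budget,
                       seed = child_seed(seed, 13), nrounds = nrounds)
  }
  model <- train_gbt(bal$x, bal$y, params = params %||% list(),
                     nrounds = nrounds, seed = child_seed(seed, 17))
  scores <- predict(model, xgboost::xgb.DMatrix(x[sp$test, , drop = FALSE],
                                                nthread = 1))
  roc <- roc_auc(scores, y[sp$test])
  conf <- confusion_metrics(as.integer(scores >= 0.5), y[sp$test])
  structure(list(
    model = model,
    rule = attr(lab, "rule"),
    auc = roc$auc,
    roc_curve = roc$curve,
    metrics = conf,
    importances = feature_importances(model, colnames(x)),
    split_sizes = c(n_train = length(sp$train), n_test = length(sp$test)),
    test = tibble::tibble(gene_id = df$gene_id[sp$test],
                          score = scores, label = y[sp$test]),
    params = params,
    seed = seed), class = "testis_gbt")
}

#' @exportS3Method base::print
print.testis_gbt <- function(x, ...) {
  cat("<testis_gbt> contrast:", x$rule, "\n")
  cat(sprintf("  train/test: %d/%d   AUC: %.4f\n",
              x$split_sizes["n_train"], x$split_sizes["n_test"], x$auc))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %.3f  npv %.3f\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$ppv, x$metrics$npv))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the feature importances of a fitted classifier
#' @param x A `testis_gbt`.
#' @param ... Unused.
#' @return Tibble `feature`, `gain`, `weight`, `cover`.
#' @export
tidy.testis_gbt <- function(x, ...) x$importances

#' One-row performance summary of a fitted classifier
#' @param x A `testis_gbt`.
#' @param ... Unused.
#' @return Tibble with rule, AUC, confusion counts and rates, split sizes.
#' @export
glance.testis_gbt <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(rule = x$rule, auc = x$auc), x$metrics,
                   tibble::tibble(n_train = unname(x$split_sizes["n_train"]),
                                  n_test = unname(x$split_sizes["n_test"])))
}

#' Classification report as a JSON string
#'
#' @param x A `testis_gbt`.
#' @param path Optional output path; when given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
report_json <- function(x, path = NULL) {
  obj <- list(rule = x$rule, auc = x$auc,
              metrics = as.list(x$metrics),
              split_sizes = as.list(x$split_sizes),
              seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
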