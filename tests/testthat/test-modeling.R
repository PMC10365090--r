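make_separable <- function(n = 40, margin = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(f1 = ifelse(y == 1, margin, -margin) + rnorm(n, 0, 0.3),
             f2 = ifelse(y == 1, -margin, margin) + rnorm(n, 0, 0.3))
  list(ft = zscore_normalize(feature_table_from_matrix(X)), y = y)
}

test_that("all three classifiers fit a separable toy to 100% and are
           deterministic under fixed seeds", {
  d <- make_separable()
  for (clf in c("svm_linear", "mlp", "tree_ensemble")) {
    cfg <- model_config(clf)
    m1 <- train_model(d$ft, d$y, cfg)
    p1 <- predict_scores(m1, d$ft)
    expect_equal(mean(p1$decision == d$y), 1)
    m2 <- train_model(d$ft, d$y, cfg)
    p2 <- predict_scores(m2, d$ft)
    expect_identical(p1$score, p2$score)
  }
})

test_that("single decision tree (ensemble size 1) respects the split cap", {
  d <- make_separable(60)
  m <- train_model(d$ft, d$y, model_config("tree_ensemble", n_trees = 1,
                                           max_splits = 10))
  expect_equal(length(m$fit), 1)
  n_internal <- sum(!vapply(m$fit[[1]], `[[`, logical(1), "leaf"))
  expect_lte(n_internal, 10)
})

test_that("single-class training input errors", {
  d <- make_separable()
  expect_error(train_model(d$ft, rep(1, length(d$y)), model_config()),
               "single class")
})

test_that("AUROC equals exhaustive pair counting, handles ties, and is
           invariant to monotone transforms", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "single-class")
  for (seed in 1:5) {
    set.seed(seed)
    s <- sample(round(rnorm(30), 1))   # rounded -> ties occur
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auroc(s, y), oracle_auroc(s, y))
    expect_equal(auroc(exp(2 * s) + 5, y), auroc(s, y))
  }
})

test_that("evaluation report identities hold", {
  set.seed(40)
  y <- rbinom(50, 1, 0.6)
  scores <- rnorm(50) + y
  dec <- as.integer(scores > 0.5)
  rep <- evaluation_report(scores, dec, y, "train")
  expect_equal(rep$accuracy, 100 - rep$misclassification_rate)
  expect_equal(rep$n_misclassified,
               round(rep$misclassification_rate * rep$n / 100))
  expect_gte(rep$auroc, 0); expect_lte(rep$auroc, 1)
  expect_equal(rep$sensitivity,
               100 * sum(dec == 1 & y == 1) / sum(y == 1))
  expect_equal(rep$specificity,
               100 * sum(dec == 0 & y == 0) / sum(y == 0))
})

test_that("hold-out split arithmetic is stratified 75/25", {
  set.seed(41)
  X <- matrix(rnorm(100 * 20), 100, 20)
  y <- rep(c(0, 1), c(45, 55))
  ft <- feature_table_from_matrix(X)
  cv <- holdout_cv(ft, y, model_config("svm_linear", cv_seed = 3),
                   selection_config(n_select = 5))
  expect_lte(abs(cv$train_report$n - 75), 1)
  expect_lte(abs(cv$validation_report$n - 25), 1)
  expect_equal(cv$train_report$accuracy,
               100 - cv$train_report$misclassification_rate)
  # split indices are stratified: class balance preserved within 1 subject
  expect_equal(sum(y[cv$split] == 1) / length(cv$split), 0.55,
               tolerance = 0.02)
})

test_that("label-permuted data stays null through selection + hold-out: the
           leakage guard (20 seeds, n = 100)", {
  aurocs <- vapply(1:20, function(seed) {
    set.seed(seed * 7)
    X <- matrix(rnorm(100 * 60), 100, 60)
    y <- sample(rep(c(0, 1), each = 50))
    ft <- feature_table_from_matrix(X)
    cv <- holdout_cv(ft, y, model_config("svm_linear", cv_seed = seed),
                     selection_config(n_select = 10))
    cv$validation_report$auroc
  }, numeric(1))
  expect_gte(median(aurocs), 0.35)
  expect_lte(median(aurocs), 0.65)
})

test_that("external validation: identity data reproduces training metrics;
           same-process cohorts agree; null cohorts stay null", {
  set.seed(42)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  gen <- function(n, y, signal = 1.5, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 1:3] <- X[, 1:3] + signal * y
    colnames(X) <- paste0("f", 1:20)
    feature_table_from_matrix(X)
  }
  ft <- gen(n, y, seed = 1)
  ftn <- zscore_normalize(ft)
  model <- train_model(ftn, y, model_config("svm_linear"))
  ext_same <- external_validate(model, ft, y)
  tr <- predict_scores(model, ftn)
  expect_equal(ext_same$auroc,
               evaluation_report(tr$score, tr$decision, y)$auroc)

  set.seed(99)
  y2 <- rbinom(n, 1, 0.5); y2[1:2] <- c(0, 1)
  diffs <- vapply(1:10, function(seed) {
    ft2 <- gen(n, y2, seed = 100 + seed)
    abs(external_validate(model, ft2, y2)$auroc - ext_same$auroc)
  }, numeric(1))
  expect_lt(median(diffs), 0.1)

  nulls <- vapply(1:10, function(seed) {
    ft0 <- gen(n, y2, signal = 0, seed = 200 + seed)
    external_validate(model, ft0, y2)$auroc
  }, numeric(1))
  expect_gte(median(nulls), 0.35)
  expect_lte(median(nulls), 0.65)

  ft_missing <- feature_table_from_matrix(ft$x[, 1:10])
  expect_error(external_validate(model, ft_missing, y), "lacks")
})
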