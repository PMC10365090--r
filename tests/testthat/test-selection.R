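test_that("ReliefF puts a label-equal feature first (10 seeds)", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    y <- rep(c(0, 1), each = 30)
    X <- cbind(ifelse(y == 1, 1, -1) + rnorm(60, 0, 0.1),
               matrix(rnorm(60 * 9), 60, 9))
    colnames(X) <- c("signal", paste0("noise", 1:9))
    res <- relieff_rank(zscore_normalize(feature_table_from_matrix(X)), y, 10)
    if (res$name[1] == "signal") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("a label-independent feature has a null-compatible ReliefF weight", {
  set.seed(30)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x_ind <- rnorm(n)
  X <- cbind(ind = x_ind, matrix(rnorm(n * 4), n, 4))
  w_obs <- relieff_rank(feature_table_from_matrix(X), y, 10)
  w_ind <- w_obs$weight[w_obs$name == "ind"]
  null_w <- vapply(1:200, function(b) {
    yp <- sample(y)
    res <- relieff_rank(feature_table_from_matrix(X), yp, 10)
    res$weight[res$name == "ind"]
  }, numeric(1))
  expect_lt(abs(w_ind - mean(null_w)), 3 * sd(null_w))
})

test_that("ReliefF equals the literal brute-force transcription on toy data", {
  set.seed(31)
  X <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_warning(res <- relieff_rank(feature_table_from_matrix(X), y, 10),
                 "truncated")
  W <- oracle_relieff(X, y, 3)   # 4 per class -> k truncated to 3
  expect_equal(setNames(res$weight, res$name)[c("a", "b", "c")],
               setNames(W, c("a", "b", "c")), tolerance = 1e-12)
})

test_that("statistical ranking: first pick is max |Z|; rho penalizes the
           duplicate; alpha = 0 reduces to |Z| sorting", {
  # effect sizes chosen so the hand computation is robust: |Z| scales with
  # the mean shift (equal noise), rho(strong, weaker) ~ r_s * r_w ~ 0.5,
  # so S_weaker ~ 1.8 * 0.64 = 1.15 beats S_dup = 2.4 * 0.3 = 0.72
  set.seed(32)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  strong <- ifelse(y == 1, 1.2, -1.2) + rnorm(n)
  weaker <- ifelse(y == 1, 0.9, -0.9) + rnorm(n)
  X <- cbind(strong = strong, dup = strong, weaker = weaker)
  ft <- zscore_normalize(feature_table_from_matrix(X))
  res <- statistical_rank(ft, y, selection_config("statistical", "t_test",
                                                  n_select = 3))
  expect_equal(res$rho[1], 0)
  expect_equal(res$S[1], abs(res$Z[1]))
  expect_true(res$name[1] %in% c("strong", "dup"))
  # with alpha = 0.7 the duplicate (rho = 1, penalty 0.3) loses to the
  # independent weaker feature; verify against exhaustive score evaluation
  expect_equal(res$name[2], "weaker")
  z <- vapply(colnames(X), function(j)
    abs(unname(t.test(ft$x[y == 1, j], ft$x[y == 0, j])$statistic)),
    numeric(1))
  first <- res$name[1]
  rho2 <- vapply(setdiff(colnames(X), first), function(j)
    abs(cor(ft$x[, j], ft$x[, first])), numeric(1))
  s2 <- z[names(rho2)] * (1 - 0.7 * rho2)
  expect_equal(res$name[2], names(which.max(s2)))

  res0 <- statistical_rank(ft, y, selection_config("statistical", "t_test",
                                                   alpha = 0, n_select = 3))
  expect_equal(res0$name, names(sort(z, decreasing = TRUE)))
})

test_that("all three Z statistics rank a planted feature above noise", {
  set.seed(33)
  n <- 50
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sig = ifelse(y == 1, 1.5, 0) + rnorm(n),
             matrix(rnorm(n * 20), n, 20))
  ft <- zscore_normalize(feature_table_from_matrix(X))
  for (zs in c("t_test", "wilcoxon", "auroc")) {
    res <- statistical_rank(ft, y, selection_config("statistical", zs,
                                                    n_select = 1))
    expect_equal(res$name[1], "sig")
  }
})

test_that("select_top honours rank order and bounds", {
  set.seed(34)
  X <- matrix(rnorm(30 * 40), 30, 40)
  y <- rep(c(0, 1), 15)
  ft <- zscore_normalize(feature_table_from_matrix(X))
  res <- statistical_rank(ft, y, selection_config(n_select = 40))
  expect_equal(select_top(res, 1), res$name[1])
  expect_setequal(select_top(res, 40), colnames(ft$x))
  expect_error(select_top(res, 41), "exceeds")
  r30 <- statistical_rank(ft, y, selection_config(n_select = 30))
  expect_equal(length(select_top(r30, 30)), 30)
})

test_that("redundancy suppression: one member per correlated block when
           alpha >= 0.5", {
  # Exact construction so the property is a theorem, not a sampling
  # accident: each block latent is y' + d_k with the d_k mutually
  # orthogonal, orthogonal to y', and balanced within class. All latents
  # then have exactly equal two-sample t statistics and exactly equal
  # cross-block correlation 1/(1 + c^2) = 0.5, while within-block
  # correlation is 1. A duplicate's mean-|cor| penalty therefore always
  # exceeds a fresh block's, for any alpha > 0.
  yc <- rep(c(-1, 1), each = 4)
  d1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  d2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  d3 <- c(1, -1, -1, 1, 1, -1, -1, 1)
  tile <- function(v) rep(v, times = 5)          # n = 40
  y <- as.integer(tile(yc) == 1)
  b <- 3
  lat <- cbind(tile(yc + d1), tile(yc + d2), tile(yc + d3))
  X <- lat[, rep(1:b, each = 3)]                 # 3 perfect copies per block
  colnames(X) <- paste0("blk", rep(1:b, each = 3), "_", rep(1:3, b))
  ft <- zscore_normalize(feature_table_from_matrix(X))
  for (alpha in c(0.5, 0.7)) {
    res <- statistical_rank(ft, y, selection_config(alpha = alpha,
                                                    n_select = b))
    blocks <- sub("_.*", "", res$name)
    expect_equal(anyDuplicated(blocks), 0)
  }
})

test_that("planted-feature recovery: >= 4/5 informative features in the top 30
           of 342 (median over 10 seeds, n = 110)", {
  recovered <- vapply(1:10, function(seed) {
    set.seed(seed * 13)
    n <- 110
    y <- rbinom(n, 1, 60 / 110)
    X <- matrix(rnorm(n * 342), n, 342)
    planted <- sprintf("V%d", c(5, 50, 150, 250, 340))
    colnames(X) <- sprintf("V%d", 1:342)
    for (p in planted) X[, p] <- X[, p] + 1.5 * y
    ft <- zscore_normalize(feature_table_from_matrix(X))
    res <- statistical_rank(ft, y, selection_config(n_select = 30))
    sum(planted %in% select_top(res, 30))
  }, numeric(1))
  expect_gte(median(recovered), 4)
})

test_that("permutation-null sanity: selected mean |Z| sits inside the null
           band under label shuffling", {
  set.seed(36)
  n <- 60; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  ft <- zscore_normalize(feature_table_from_matrix(X))
  mean_abs_z <- function(labels) {
    res <- statistical_rank(ft, labels,
                            selection_config(n_select = 10))
    mean(abs(res$Z))
  }
  obs <- mean_abs_z(sample(y))
  null_dist <- vapply(1:200, function(b) mean_abs_z(sample(y)), numeric(1))
  expect_gte(obs, quantile(null_dist, 0.025))
  expect_lte(obs, quantile(null_dist, 0.975))
})

test_that("the literal printed score formula is available and differs", {
  set.seed(37)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  strong <- ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.5)
  X <- cbind(a = strong, b = strong + rnorm(n, 0, 0.01),
             c = rnorm(n))
  ft <- zscore_normalize(feature_table_from_matrix(X))
  lit <- statistical_rank(ft, y, selection_config(n_select = 2,
                                                  literal_formula = TRUE))
  # literal S = |Z| (1 - alpha) rho rewards correlation: the near-duplicate
  # wins the second slot
  expect_setequal(lit$name, c("a", "b"))
})
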