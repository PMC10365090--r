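# The two dimension-reduction procedures: ReliefF (k nearest hits/misses)
# and the greedy relevancy-redundancy ranking S = |Z| * (1 - alpha * rho).
#
# The source prints the score as S = Z x [(1 - alpha) rho], which rewards
# redundancy and contradicts its own stated purpose; the corrected
# correlation-weighted form is the default here and the literal printed form
# is available behind `literal_formula = TRUE` for comparison.

#' Selection configuration
#'
#' @param method `"relieff"` or `"statistical"`
#' @param z_statistic relevancy statistic for the statistical method:
#'   `"t_test"`, `"wilcoxon"` or `"auroc"`
#' @param alpha redundancy weighting factor in `[0, 1]` (default 0.7)
#' @param k_neighbors ReliefF neighbor count (default 10)
#' @param n_select number of features to retain
#' @param force_include feature names always included in the selection
#'   (counted toward `n_select`)
#' @param literal_formula use the literal printed score `|Z|*(1-alpha)*rho`
#'   instead of the corrected `|Z|*(1-alpha*rho)`
#' @export
selection_config <- function(method = c("statistical", "relieff"),
                             z_statistic = c("t_test", "wilcoxon", "auroc"),
                             alpha = 0.7, k_neighbors = 10L, n_select = 30L,
                             force_include = character(0),
                             literal_formula = FALSE) {
  method <- match.arg(method)
  z_statistic <- match.arg(z_statistic)
  stopifnot(alpha >= 0, alpha <= 1, n_select >= 1, k_neighbors >= 1)
  structure(list(method = method, z_statistic = z_statistic, alpha = alpha,
                 k_neighbors = as.integer(k_neighbors),
                 n_select = as.integer(n_select),
                 force_include = force_include,
                 literal_formula = literal_formula),
            class = "selection_config")
}

#' Relevancy statistic |Z| for one feature against a binary label
#' @keywords internal
z_relevancy <- function(x, y, type) {
  if (sd(x) == 0) return(0)
  a <- x[y == 1]; b <- x[y == 0]
  switch(type,
    t_test = {
      tt <- tryCatch(t.test(a, b)$statistic, error = function(e) 0)
      abs(unname(tt))
    },
    wilcoxon = {
      n1 <- length(a); n0 <- length(b)
      r <- rank(c(a, b))
      W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
      mu <- n1 * n0 / 2
      # normal approximation with tie correction
      ties <- table(c(a, b))
      sig2 <- n1 * n0 / 12 *
        ((n1 + n0 + 1) - sum(ties^3 - ties) / ((n1 + n0) * (n1 + n0 - 1)))
      if (sig2 <= 0) 0 else abs((W - mu) / sqrt(sig2))
    },
    auroc = {
      2 * abs(auroc(x, y) - 0.5)
    },
    stopf("unknown z statistic '%s'", type))
}

#' Greedy relevancy-redundancy ranking
#'
#' Step 1 selects the feature with maximal |Z|. Each later step computes,
#' for every remaining candidate, rho = mean |Pearson correlation| with the
#' already-selected set and the composite score S = |Z| (1 - alpha rho), and
#' selects the maximizer, until `n_select` features are ranked.
#' Zero-variance features get Z = 0 and rho = 0.
#'
#' @param table a [feature_table()] (normalize first)
#' @param labels binary vector (1 = positive class), length = subjects
#' @param cfg a [selection_config()] with `method = "statistical"`
#' @return a `selection_result`: data.frame with `name`, `Z`, `rho`, `S`,
#'   `rank`, plus the config as attribute
#' @export
statistical_rank <- function(table, labels, cfg = selection_config()) {
  x <- table$x
  y <- as.integer(labels)
  if (length(unique(y)) != 2) stopf("labels must contain both classes")
  if (cfg$n_select > ncol(x))
    stopf("n_select (%d) exceeds feature count (%d)", cfg$n_select, ncol(x))
  p <- ncol(x)
  zv <- apply(x, 2, sd) == 0
  Z <- numeric(p)
  Z[!zv] <- vapply(which(!zv), function(j) z_relevancy(x[, j], y,
                                                       cfg$z_statistic),
                   numeric(1))
  names(Z) <- colnames(x)
  forced <- intersect(cfg$force_include, colnames(x))
  selected <- forced
  rho_sel <- setNames(rep(0, length(forced)), forced)
  s_sel <- setNames(Z[forced], forced)
  rho_sum <- numeric(p)  # running sum of |cor| with selected set
  names(rho_sum) <- colnames(x)
  add_cor <- function(rho_sum, new) {
    cc <- abs(suppressWarnings(cor(x, x[, new])))
    cc[!is.finite(cc)] <- 0
    rho_sum + as.numeric(cc)
  }
  for (f in forced) rho_sum <- add_cor(rho_sum, f)
  while (length(selected) < cfg$n_select) {
    cand <- setdiff(colnames(x), selected)
    rho <- if (length(selected) == 0) setNames(rep(0, length(cand)), cand)
           else rho_sum[cand] / length(selected)
    S <- if (cfg$literal_formula && length(selected) > 0)
      Z[cand] * (1 - cfg$alpha) * rho
    else Z[cand] * (1 - cfg$alpha * rho)
    pick <- cand[which.max(S)]  # ties: first in registry/column order
    selected <- c(selected, pick)
    rho_sel[pick] <- rho[pick]
    s_sel[pick] <- S[pick]
    if (length(selected) < cfg$n_select) rho_sum <- add_cor(rho_sum, pick)
  }
  res <- data.frame(name = selected, Z = unname(Z[selected]),
                    rho = unname(rho_sel[selected]),
                    S = unname(s_sel[selected]),
                    rank = seq_along(selected), stringsAsFactors = FALSE)
  attr(res, "config") <- cfg
  class(res) <- c("selection_result", "data.frame")
  res
}

#' ReliefF feature weights
#'
#' Standard ReliefF on a binary-labelled table: every subject is an anchor;
#' its `k` nearest hits and `k` nearest misses (Manhattan distance on
#' range-normalized features) move each feature weight by the mean
#' miss-minus-hit difference. If a class has `k` or fewer members, `k` is
#' truncated with a warning.
#'
#' @param table a [feature_table()] (normalize first)
#' @param labels binary vector
#' @param k neighbor count (default 10)
#' @return a `selection_result` data.frame with `name`, `weight`, `rank`,
#'   sorted by descending weight (ties keep column order)
#' @export
relieff_rank <- function(table, labels, k = 10L) {
  x <- table$x
  y <- as.integer(labels)
  if (length(unique(y)) != 2) stopf("labels must contain both classes")
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  xn <- sweep(x, 2, rng, `/`)
  kmax <- min(table(y)) - 1L
  if (k > kmax) {
    warning(sprintf("k = %d truncated to %d (smallest class size minus one)",
                    k, kmax), call. = FALSE)
    k <- max(1L, kmax)
  }
  D <- as.matrix(stats::dist(xn, method = "manhattan"))
  W <- numeric(p)
  for (i in seq_len(n)) {
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(D[i, hits])][seq_len(min(k, length(hits)))]
    misses <- misses[order(D[i, misses])][seq_len(min(k, length(misses)))]
    dh <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ], `-`))
    dm <- abs(sweep(xn[misses, , drop = FALSE], 2, xn[i, ], `-`))
    W <- W + colMeans(dm) - colMeans(dh)
  }
  W <- W / n
  ord <- order(-W)
  res <- data.frame(name = colnames(x)[ord], weight = W[ord],
                    rank = seq_len(p), stringsAsFactors = FALSE)
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Top-n feature names from a ranking
#'
#' @param result a `selection_result` (from [statistical_rank()] or
#'   [relieff_rank()])
#' @param n number of features (defaults to all ranked)
#' @return character vector of the first `n` names in rank order
#' @export
select_top <- function(result, n = nrow(result)) {
  if (n > nrow(result))
    stopf("n (%d) exceeds the number of ranked features (%d)", n,
          nrow(result))
  result$name[seq_len(n)]
}

#' Run the configured selector on a table
#' @keywords internal
run_selection <- function(table, labels, cfg) {
  if (cfg$method == "relieff") {
    res <- relieff_rank(table, labels, cfg$k_neighbors)
    if (length(cfg$force_include) > 0) {
      forced <- intersect(cfg$force_include, colnames(table$x))
      rest <- setdiff(res$name, forced)
      res <- res[match(c(forced, rest), res$name), ]
      res$rank <- seq_len(nrow(res))
    }
    res
  } else {
    statistical_rank(table, labels, cfg)
  }
}

#' Write a ranking to TSV
#' @param result a `selection_result`
#' @param path output path
#' @export
write_selection <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
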