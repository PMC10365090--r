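# Classifier grid and evaluation. The offline toolchain ships no SVM/MLP/
# tree packages, so the three classifiers are implemented here:
#   - svm_linear: primal L2-regularized squared-hinge SVM (box constraint C
#     weights the loss), deterministic BFGS from zero init;
#   - mlp: one hidden layer of logistic units trained by BFGS with seeded
#     random init, cross-entropy loss plus a small L2 penalty;
#   - tree_ensemble: bagged CART trees grown best-first with a cap on the
#     number of splits ("random forests with a split of 10"); ensemble size
#     1 recovers a single decision tree.
# The positive class (label 1) is disease control throughout.

#' Model configuration
#'
#' @param classifier `"svm_linear"`, `"mlp"` or `"tree_ensemble"`
#' @param box_constraint SVM misclassification penalty C (default 1)
#' @param hidden_units MLP hidden layer width (default 10)
#' @param mlp_seed seed for MLP weight init
#' @param max_splits per-tree split cap (default 10)
#' @param n_trees ensemble size (default 50; 1 = single decision tree)
#' @param tree_seed seed for bootstrap draws
#' @param train_fraction hold-out training fraction (default 0.75)
#' @param cv_seed seed for the hold-out split
#' @export
model_config <- function(classifier = c("svm_linear", "mlp", "tree_ensemble"),
                         box_constraint = 1, hidden_units = 10L,
                         mlp_seed = 11L, max_splits = 10L, n_trees = 50L,
                         tree_seed = 13L, train_fraction = 0.75,
                         cv_seed = 42L) {
  classifier <- match.arg(classifier)
  stopifnot(box_constraint > 0, train_fraction > 0, train_fraction < 1)
  structure(list(classifier = classifier, box_constraint = box_constraint,
                 hidden_units = as.integer(hidden_units),
                 mlp_seed = as.integer(mlp_seed),
                 max_splits = as.integer(max_splits),
                 n_trees = as.integer(n_trees),
                 tree_seed = as.integer(tree_seed),
                 train_fraction = train_fraction,
                 cv_seed = as.integer(cv_seed)),
            class = "model_config")
}

fit_svm_linear <- function(X, y01, C) {
  y <- ifelse(y01 == 1, 1, -1)
  p <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- 1 - y * (X %*% w + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- as.numeric(1 - y * (X %*% w + b))
    act <- m > 0
    gw <- w - 2 * C * as.numeric(t(X[act, , drop = FALSE]) %*%
                                   (y[act] * m[act]))
    gb <- -2 * C * sum(y[act] * m[act])
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

fit_mlp <- function(X, y01, hidden, seed, lambda = 1e-4, maxit = 300) {
  n <- nrow(X); p <- ncol(X)
  n_par <- hidden * p + hidden + hidden + 1
  unpack <- function(par) {
    W1 <- matrix(par[seq_len(hidden * p)], hidden, p)
    b1 <- par[hidden * p + seq_len(hidden)]
    w2 <- par[hidden * p + hidden + seq_len(hidden)]
    b2 <- par[n_par]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  fwd <- function(pp) {
    H <- sigmoid(X %*% t(pp$W1) + matrix(pp$b1, n, hidden, byrow = TRUE))
    list(H = H, yhat = as.numeric(sigmoid(H %*% pp$w2 + pp$b2)))
  }
  obj <- function(par) {
    pp <- unpack(par)
    f <- fwd(pp)
    eps <- 1e-12
    -sum(y01 * log(f$yhat + eps) + (1 - y01) * log(1 - f$yhat + eps)) / n +
      lambda * sum(par^2)
  }
  grad <- function(par) {
    pp <- unpack(par)
    f <- fwd(pp)
    d2 <- (f$yhat - y01) / n                     # n
    gw2 <- as.numeric(t(f$H) %*% d2)             # hidden
    gb2 <- sum(d2)
    D1 <- (d2 %*% t(pp$w2)) * f$H * (1 - f$H)    # n x hidden
    gW1 <- t(D1) %*% X                           # hidden x p
    gb1 <- colSums(D1)
    c(as.numeric(gW1), gb1, gw2, gb2) + 2 * lambda * par
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  init <- runif(n_par, -0.5, 0.5) / sqrt(p)
  fit <- optim(init, obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-9))
  unpack(fit$par)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

gini_impurity <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 1 - (n1 / n)^2 - (n0 / n)^2)
}

best_split <- function(X, y, idx) {
  n <- length(idx)
  if (n < 2) return(NULL)
  y_i <- y[idx]
  parent <- gini_impurity(sum(y_i), n - sum(y_i)) * n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[idx, j]
    o <- order(v)
    vs <- v[o]; ys <- y_i[o]
    cum1 <- cumsum(ys); cumn <- seq_len(n)
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) next
    lg <- gini_impurity(cum1[distinct], cumn[distinct] - cum1[distinct]) *
      cumn[distinct]
    rg <- gini_impurity(sum(ys) - cum1[distinct],
                        (n - cumn[distinct]) - (sum(ys) - cum1[distinct])) *
      (n - cumn[distinct])
    gain <- parent - (lg + rg)
    k <- which.max(gain)
    if (is.null(best) || gain[k] > best$gain + 1e-12) {
      best <- list(feature = j,
                   threshold = (vs[distinct[k]] + vs[distinct[k] + 1]) / 2,
                   gain = gain[k])
    }
  }
  best
}

fit_cart <- function(X, y, max_splits) {
  nodes <- list(list(idx = seq_len(nrow(X)), leaf = TRUE,
                     prob = mean(y), split = NULL, kids = NULL))
  n_splits <- 0
  repeat {
    if (n_splits >= max_splits) break
    cand <- lapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      if (!nd$leaf) return(NULL)
      s <- best_split(X, y, nd$idx)
      if (is.null(s) || s$gain <= 1e-12) NULL else c(list(node = i), s)
    })
    cand <- Filter(Negate(is.null), cand)
    if (length(cand) == 0) break
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    s <- cand[[which.max(gains)]]
    nd <- nodes[[s$node]]
    left <- nd$idx[X[nd$idx, s$feature] <= s$threshold]
    right <- setdiff(nd$idx, left)
    nodes[[s$node]]$leaf <- FALSE
    nodes[[s$node]]$split <- list(feature = s$feature,
                                  threshold = s$threshold)
    nodes[[length(nodes) + 1]] <- list(idx = left, leaf = TRUE,
                                       prob = mean(y[left]))
    nodes[[s$node]]$kids <- c(length(nodes), NA)
    nodes[[length(nodes) + 1]] <- list(idx = right, leaf = TRUE,
                                       prob = mean(y[right]))
    nodes[[s$node]]$kids[2] <- length(nodes)
    n_splits <- n_splits + 1
  }
  nodes
}

predict_cart <- function(nodes, X) {
  vapply(seq_len(nrow(X)), function(i) {
    k <- 1
    while (!nodes[[k]]$leaf) {
      s <- nodes[[k]]$split
      k <- if (X[i, s$feature] <= s$threshold) nodes[[k]]$kids[1]
           else nodes[[k]]$kids[2]
    }
    nodes[[k]]$prob
  }, numeric(1))
}

#' Train a classifier
#'
#' @param table a [feature_table()] restricted to the selected, normalized
#'   features
#' @param labels binary vector (1 = positive class / disease control)
#' @param cfg a [model_config()]
#' @return a `trained_model` exposing a continuous score and a binary
#'   decision via [predict_scores()]
#' @export
train_model <- function(table, labels, cfg = model_config()) {
  X <- table$x
  y <- as.integer(labels)
  if (length(unique(y)) != 2)
    stopf("degenerate input: training labels contain a single class")
  fit <- switch(cfg$classifier,
    svm_linear = fit_svm_linear(X, y, cfg$box_constraint),
    mlp = fit_mlp(X, y, cfg$hidden_units, cfg$mlp_seed),
    tree_ensemble = {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(cfg$tree_seed)
      lapply(seq_len(cfg$n_trees), function(b) {
        idx <- if (cfg$n_trees == 1) seq_len(nrow(X)) else {
          repeat {
            idx <- sample(nrow(X), replace = TRUE)
            if (length(unique(y[idx])) == 2) break
          }
          idx
        }
        fit_cart(X[idx, , drop = FALSE], y[idx], cfg$max_splits)
      })
    })
  structure(list(classifier = cfg$classifier, fit = fit, config = cfg,
                 features = colnames(X)),
            class = "trained_model")
}

#' Continuous scores and binary decisions from a trained model
#'
#' @param model a `trained_model`
#' @param table a [feature_table()] containing the model's features
#' @return list with `score` (continuous, larger = more positive) and
#'   `decision` (0/1)
#' @export
predict_scores <- function(model, table) {
  missing <- setdiff(model$features, colnames(table$x))
  if (length(missing) > 0)
    stopf("missing feature columns: %s", paste(missing, collapse = ", "))
  X <- table$x[, model$features, drop = FALSE]
  score <- switch(model$classifier,
    svm_linear = as.numeric(X %*% model$fit$w + model$fit$b),
    mlp = {
      pp <- model$fit
      H <- sigmoid(X %*% t(pp$W1) +
                     matrix(pp$b1, nrow(X), length(pp$b1), byrow = TRUE))
      as.numeric(sigmoid(H %*% pp$w2 + pp$b2))
    },
    tree_ensemble = rowMeans(vapply(model$fit,
                                    function(tree) predict_cart(tree, X),
                                    numeric(nrow(X)))))
  threshold <- if (model$classifier == "svm_linear") 0 else 0.5
  list(score = score, decision = as.integer(score > threshold))
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half (rank formulation; equal to exhaustive pair counting).
#'
#' @param scores numeric scores
#' @param labels binary labels (1 = positive)
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("AUROC undefined: single-class labels")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metric panel for one evaluation split
#'
#' @param scores continuous scores
#' @param decisions 0/1 decisions
#' @param labels 0/1 truth (1 = disease control, the positive class)
#' @param split split name
#' @return one-row data.frame: AUROC, accuracy, sensitivity, specificity,
#'   misclassification rate (all percent except AUROC) and count
#' @export
evaluation_report <- function(scores, decisions, labels, split = "train") {
  y <- as.integer(labels)
  n <- length(y)
  mis <- sum(decisions != y)
  sens <- if (sum(y == 1) > 0) 100 * sum(decisions == 1 & y == 1) / sum(y == 1)
          else NA_real_
  spec <- if (sum(y == 0) > 0) 100 * sum(decisions == 0 & y == 0) / sum(y == 0)
          else NA_real_
  data.frame(split = split, auroc = auroc(scores, y),
             accuracy = 100 * (n - mis) / n,
             sensitivity = sens, specificity = spec,
             misclassification_rate = 100 * mis / n,
             n_misclassified = mis, n = n,
             stringsAsFactors = FALSE)
}

stratified_split <- function(y, fraction, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(length(idx) * fraction)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Hold-out validation with selection refit inside the training partition
#'
#' Single stratified split (default 75/25) controlled by `cfg$cv_seed`.
#' Normalization and feature selection are performed on the training
#' partition only; the validation partition is normalized independently
#' with its own statistics (the separate-normalization protocol). A split
#' that leaves a partition single-class is redrawn with an incremented
#' seed (message logged).
#'
#' @param table an unnormalized [feature_table()]
#' @param labels binary vector
#' @param cfg a [model_config()]
#' @param sel_cfg a [selection_config()]
#' @return list: `train_report`, `validation_report`, `model`, `selection`,
#'   `split` (training indices)
#' @export
holdout_cv <- function(table, labels, cfg = model_config(),
                       sel_cfg = selection_config()) {
  y <- as.integer(labels)
  if (length(y) < 8) stopf("hold-out validation needs at least 8 subjects")
  seed <- cfg$cv_seed
  repeat {
    tr <- stratified_split(y, cfg$train_fraction, seed)
    va <- setdiff(seq_along(y), tr)
    if (length(unique(y[tr])) == 2 && length(unique(y[va])) == 2) break
    message("single-class partition at seed ", seed, "; resplitting")
    seed <- seed + 1L
  }
  sub_table <- function(idx) feature_table(
    table$x[idx, , drop = FALSE],
    labels = if (!is.null(table$labels)) table$labels[idx, , drop = FALSE]
             else NULL,
    provenance = unname(table$provenance[colnames(table$x)]))
  tr_norm <- zscore_normalize(sub_table(tr))
  ranking <- run_selection(tr_norm, y[tr], sel_cfg)
  keep <- select_top(ranking, sel_cfg$n_select)
  restrict <- function(ft) feature_table(
    ft$x[, keep, drop = FALSE], labels = ft$labels,
    provenance = unname(ft$provenance[keep]))
  model <- train_model(restrict(tr_norm), y[tr], cfg)
  pr_tr <- predict_scores(model, restrict(tr_norm))
  va_norm <- zscore_normalize(sub_table(va))
  pr_va <- predict_scores(model, restrict(va_norm))
  list(train_report = evaluation_report(pr_tr$score, pr_tr$decision, y[tr],
                                        "train"),
       validation_report = evaluation_report(pr_va$score, pr_va$decision,
                                             y[va], "internal_cv"),
       model = model, selection = ranking, split = tr)
}

#' Inference on an untouched external cohort
#'
#' The external table is normalized independently (its own Z-scores) and
#' scored with the frozen model; no refitting.
#'
#' @param model a `trained_model`
#' @param external unnormalized [feature_table()] of the external cohort
#' @param labels binary vector for the external subjects
#' @return an [evaluation_report()] row with split `"external"`
#' @export
external_validate <- function(model, external, labels) {
  missing <- setdiff(model$features, colnames(external$x))
  if (length(missing) > 0)
    stopf("external table lacks selected features: %s",
          paste(missing, collapse = ", "))
  ext_norm <- zscore_normalize(external)
  keep <- feature_table(ext_norm$x[, model$features, drop = FALSE],
                        labels = ext_norm$labels,
                        provenance = unname(ext_norm$provenance[model$features]))
  pr <- predict_scores(model, keep)
  evaluation_report(pr$score, pr$decision, as.integer(labels), "external")
}
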