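# Random-forest regression of SRGH on the scale scores, with unconditional
# and Strobl-style conditional permutation importance. Base learners are
# CART variance-reduction trees grown on bootstrap samples (compiled in
# src/forest.cpp); all randomness flows through R's RNG.

#' Fit a regression random forest
#'
#' Each tree is grown on a bootstrap sample (with replacement); at every
#' node `mtry` predictors are drawn without replacement as split
#' candidates and the best split minimizes the weighted child variance.
#' SRGH is treated as numeric (1 very good ... 5 very bad).
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response (no missing values).
#' @param ntree number of trees (default 1000).
#' @param mtry split candidates per node (default 2; with exactly two
#'   predictors both are always candidates).
#' @param min_node nodes of at most this size are not split (default 5).
#' @param seed integer seed; the forest is a pure function of
#'   (`X`, `y`, settings, `seed`).
#' @return object of class `rf_model`: `trees`, `inbag` (n x ntree bootstrap
#'   counts), `oob_pred` (out-of-bag prediction per case), `oob_mse`,
#'   and the call settings.
#' @export
fit_random_forest <- function(X, y, ntree = 1000L, mtry = 2L, min_node = 5L,
                              seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop_invalid("X", "missing values not allowed")
  if (length(y) != nrow(X)) stop_invalid("y", "length must match nrow(X)")
  mtry <- check_count(mtry, "mtry", min = 1L)
  if (mtry > ncol(X))
    stop_invalid("mtry", "cannot exceed the number of predictors")
  ntree <- check_count(ntree, "ntree", min = 1L)
  min_node <- check_count(min_node, "min_node", min = 1L)
  set.seed(seed)
  grown <- rf_grow_cpp(X, as.numeric(y), ntree, mtry, min_node)
  # out-of-bag predictions
  n <- nrow(X)
  acc <- numeric(n)
  cnt <- integer(n)
  for (b in seq_len(ntree)) {
    oob <- grown$inbag[, b] == 0L
    if (!any(oob)) next
    acc[oob] <- acc[oob] + tree_predict_cpp(grown$trees[[b]],
                                            X[oob, , drop = FALSE])
    cnt[oob] <- cnt[oob] + 1L
  }
  oob_pred <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  oob_mse <- mean((y - oob_pred)^2, na.rm = TRUE)
  structure(list(trees = grown$trees, inbag = grown$inbag,
                 oob_pred = oob_pred, oob_mse = oob_mse,
                 ntree = ntree, mtry = mtry, min_node = min_node,
                 seed = seed, predictors = colnames(X)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry=%d, OOB MSE %.4f\n",
              x$ntree, x$mtry, x$oob_mse))
  invisible(x)
}

#' Predict from a fitted forest
#' @param object an `rf_model`.
#' @param newdata numeric matrix with the model's predictor columns.
#' @param ... unused.
#' @return numeric vector: mean of the per-tree predictions.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  out <- numeric(nrow(newdata))
  for (b in seq_along(object$trees))
    out <- out + tree_predict_cpp(object$trees[[b]], newdata)
  out / length(object$trees)
}

# split points a tree uses on predictor v (1-based column index)
tree_split_points <- function(tree, v) {
  sort(unique(tree$split_val[tree$split_var == v]))
}

# permutations consumed in a fixed order so the brute-force oracle can
# reproduce them exactly: per tree, per predictor (column order), one
# sample() of the OOB size.
importance_engine <- function(model, X, y, seed, conditional,
                              cond_threshold = 0.2) {
  X <- as.matrix(X)[, model$predictors, drop = FALSE]
  p <- ncol(X)
  ntree <- model$ntree
  per_tree <- matrix(NA_real_, ntree, p, dimnames = list(NULL, colnames(X)))
  cond_sets <- vector("list", p)
  names(cond_sets) <- colnames(X)
  if (conditional && p > 1) {
    cm <- suppressWarnings(cor(X))
    for (v in seq_len(p))
      cond_sets[[v]] <- which(abs(cm[v, ]) > cond_threshold & seq_len(p) != v)
  } else {
    for (v in seq_len(p)) cond_sets[[v]] <- integer(0)
  }
  set.seed(seed)
  for (b in seq_len(ntree)) {
    oob <- which(model$inbag[, b] == 0L)
    if (length(oob) < 2L) {
      next
    }
    Xo <- X[oob, , drop = FALSE]
    yo <- y[oob]
    base <- tree_predict_cpp(model$trees[[b]], Xo)
    mse0 <- mean((yo - base)^2)
    for (v in seq_len(p)) {
      perm <- sample.int(length(oob))
      cs <- cond_sets[[v]]
      if (length(cs) == 0L) {
        new_v <- Xo[perm, v]
      } else {
        # cells from the tree's own split points on conditioning variables
        cell <- rep("", length(oob))
        for (w in cs) {
          spw <- tree_split_points(model$trees[[b]], w)
          cell <- paste(cell, findInterval(Xo[, w], spw), sep = "|")
        }
        new_v <- Xo[, v]
        for (cl in unique(cell)) {
          members <- which(cell == cl)
          if (length(members) < 2L) next  # size-1 cell: nothing to permute
          # within-cell order induced by the tree-level permutation
          sub <- members[order(match(members, perm))]
          new_v[members] <- Xo[sub, v]
        }
      }
      Xp <- Xo
      Xp[, v] <- new_v
      mse1 <- mean((yo - tree_predict_cpp(model$trees[[b]], Xp))^2)
      per_tree[b, v] <- mse1 - mse0
    }
  }
  imp <- colMeans(per_tree, na.rm = TRUE)
  structure(list(importance = imp, per_tree = per_tree,
                 conditioning = lapply(cond_sets, function(s)
                   colnames(X)[s]),
                 conditional = conditional, seed = seed),
            class = "importance_result")
}

#' Unconditional permutation importance
#'
#' Per tree, the increase in out-of-bag mean squared error after permuting
#' the predictor among the OOB cases, averaged over trees.
#'
#' @param model an [fit_random_forest()] model.
#' @param X,y the training data.
#' @param seed integer seed for the permutations.
#' @return object of class `importance_result` with `importance` (per
#'   predictor), `per_tree` values and the seed.
#' @export
permutation_importance <- function(model, X, y, seed = 1L) {
  importance_engine(model, X, y, seed, conditional = FALSE)
}

#' Conditional permutation importance (Strobl scheme)
#'
#' Controls for correlated predictors: the conditioning set of a predictor
#' holds every other predictor with absolute Pearson correlation above
#' `cond_threshold`; per tree, the OOB cases are partitioned into cells
#' defined by the tree's own split points on the conditioning variables and
#' the target predictor is permuted within cells only. Cells of size one
#' contribute no permutation. With the two scale scores as predictors each
#' conditions on the other.
#'
#' @inheritParams permutation_importance
#' @param cond_threshold correlation threshold for conditioning-set
#'   membership (default 0.2).
#' @return an `importance_result`; `conditioning` records the sets used.
#' @export
conditional_permutation_importance <- function(model, X, y,
                                               cond_threshold = 0.2,
                                               seed = 1L) {
  importance_engine(model, X, y, seed, conditional = TRUE,
                    cond_threshold = cond_threshold)
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> %s permutation importance\n",
              if (x$conditional) "conditional" else "unconditional"))
  print(round(x$importance, 5))
  invisible(x)
}

#' Association summary: correlations and box-plot statistics
#'
#' Spearman correlation (average-rank ties) of each scale score with SRGH
#' and the Pearson correlation between the two scores, per population, plus
#' five-number summaries (min, Q1, median, Q3, max) of each score within
#' each SRGH category.
#'
#' @param scores_bhs,scores_lhs numeric score vectors (0-100 scale).
#' @param srgh integer vector in 1..5.
#' @param population population label per respondent.
#' @return list of class `association_summary`: `correlations` (data frame
#'   `population`, `statistic`, `value`; constant inputs yield `NA` with an
#'   `"undefined"` marker) and `boxplot_stats` (data frame per population,
#'   scale and SRGH category).
#' @export
association_summary <- function(scores_bhs, scores_lhs, srgh, population) {
  n <- length(srgh)
  if (length(scores_bhs) != n || length(scores_lhs) != n ||
      length(population) != n)
    stop_invalid("srgh", "all inputs must have equal length")
  if (!all(srgh %in% 1:5 | is.na(srgh)))
    stop_invalid("srgh", "values must be in 1..5")
  safe_cor <- function(x, y, method) {
    if (sd(x, na.rm = TRUE) < 1e-12 || sd(y, na.rm = TRUE) < 1e-12)
      return(NA_real_)
    cor(x, y, method = method, use = "complete.obs")
  }
  cors <- NULL
  box <- NULL
  for (pop in sort(unique(population))) {
    sel <- population == pop
    cors <- rbind(cors, data.frame(
      population = pop,
      statistic = c("spearman_bhs_srgh", "spearman_lhs_srgh",
                    "pearson_bhs_lhs"),
      value = c(safe_cor(scores_bhs[sel], srgh[sel], "spearman"),
                safe_cor(scores_lhs[sel], srgh[sel], "spearman"),
                safe_cor(scores_bhs[sel], scores_lhs[sel], "pearson")),
      stringsAsFactors = FALSE))
    for (scale in c("bhs", "lhs")) {
      sc <- if (scale == "bhs") scores_bhs else scores_lhs
      for (k in 1:5) {
        v <- sc[sel & srgh == k & !is.na(sc)]
        if (length(v) == 0L) next
        q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        box <- rbind(box, data.frame(
          population = pop, scale = scale, srgh = k, n = length(v),
          min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
          stringsAsFactors = FALSE))
      }
    }
  }
  cors$undefined <- is.na(cors$value)
  structure(list(correlations = cors, boxplot_stats = box),
            class = "association_summary")
}
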