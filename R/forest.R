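# Phase 2 (wrapper half): an ensemble of Gini-impurity classification
# trees, built natively so that split enumeration, importance accounting
# and tie-breaking are fully specified and testable against brute-force
# enumeration. Each tree trains on a uniform 2/3 subsample drawn WITHOUT
# replacement; the held-out third supplies the out-of-bag error estimate.

#' Gini impurity of a two-class node
#'
#' `1 - p1^2 - p2^2` for class proportions `p1`, `p2`; ranges over
#' \[0, 0.5\] for two classes (0 = pure node, 0.5 = perfect mixture).
#'
#' @param class_counts length-2 vector of non-negative class counts, not
#'   both zero.
#' @return impurity value.
#' @export
gini_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n == 0) cp_stop("empty node has no impurity", "codephen_input_error")
  p <- class_counts / n
  1 - sum(p^2)
}

#' Forest configuration
#'
#' @param n_trees number of trees (>= 1). The default of 500 follows common
#'   forest practice; the pipeline and tests use fewer where the signal is
#'   strong.
#' @param train_fraction fraction of patients subsampled (without
#'   replacement) to grow each tree, in (0, 1]; default 2/3, with the
#'   remaining third held out for the error estimate.
#' @param features_per_split `"sqrt"` (default: floor of the square root of
#'   the feature count, at least 1) or a positive integer.
#' @param max_depth maximum tree depth (`Inf` = unlimited).
#' @param min_leaf minimum patients per leaf (>= 1).
#' @param seed integer seed; a fixed seed reproduces the forest exactly.
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, train_fraction = 2 / 3,
                          features_per_split = "sqrt", max_depth = Inf,
                          min_leaf = 1L, seed = 1L) {
  stopifnot(n_trees >= 1L, train_fraction > 0, train_fraction <= 1,
            min_leaf >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 train_fraction = train_fraction,
                 features_per_split = features_per_split,
                 max_depth = max_depth, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "forest_config")
}

# Best "count >= t" split for one feature within a node.
# Candidate thresholds are midpoints between consecutive distinct observed
# values; children below min_leaf are inadmissible. Returns NULL or
# list(threshold, decrease).
best_split_feature <- function(x, y_case, min_leaf) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  f <- match(x, ux)
  k <- length(ux)
  c1 <- tabulate(f[y_case], nbins = k)        # cases per value
  c2 <- tabulate(f[!y_case], nbins = k)       # controls per value
  cl1 <- cumsum(c1)[-k]; cl2 <- cumsum(c2)[-k]  # left child (x < t) counts
  t1 <- sum(c1); t2 <- sum(c2); n <- t1 + t2
  nl <- cl1 + cl2; nr <- n - nl
  ok <- nl >= min_leaf & nr >= min_leaf
  if (!any(ok)) return(NULL)
  gl <- 1 - (cl1 / nl)^2 - (cl2 / nl)^2
  cr1 <- t1 - cl1; cr2 <- t2 - cl2
  gr <- 1 - (cr1 / nr)^2 - (cr2 / nr)^2
  gparent <- 1 - (t1 / n)^2 - (t2 / n)^2
  dec <- gparent - (nl * gl + nr * gr) / n
  dec[!ok] <- -Inf
  # ties in decrease broken by the lower threshold
  best <- which.max(dec)
  if (!is.finite(dec[best]) || dec[best] <= 0) return(NULL)
  list(threshold = (ux[best] + ux[best + 1L]) / 2, decrease = dec[best])
}

mtry_size <- function(features_per_split, p) {
  if (identical(features_per_split, "sqrt")) max(1L, floor(sqrt(p)))
  else min(p, max(1L, as.integer(features_per_split)))
}

# Grow one Gini tree on rows `idx` of X. Importance contributions are
# accumulated into `imp` (decrease x node fraction, relative to the tree's
# own training size). Returns a flat node table.
grow_tree <- function(X, y_case, idx, config, imp_env) {
  p <- ncol(X)
  mtry <- mtry_size(config$features_per_split, p)
  n_train <- length(idx)
  nodes <- list()
  # stack of (row indices, depth, parent slot to fill, which child)
  new_node <- function() length(nodes) + 1L
  stack <- list(list(idx = idx, depth = 0L, slot = NA))
  while (length(stack)) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rows <- task$idx
    n1 <- sum(y_case[rows]); n0 <- length(rows) - n1
    id <- new_node()
    node <- list(feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 n_case = n1, n_control = n0,
                 pred = if (n1 >= n0) "RA" else "nonRA")
    split <- NULL
    if (n1 > 0L && n0 > 0L && task$depth < config$max_depth &&
        length(rows) >= 2L * config$min_leaf) {
      feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
      # deterministic tie-break across features: lower threshold, then
      # feature name; scan in name order so strict '>' keeps the winner
      feats <- feats[order(colnames(X)[feats], method = "radix")]
      best <- NULL
      for (j in feats) {
        s <- best_split_feature(X[rows, j], y_case[rows], config$min_leaf)
        if (!is.null(s) &&
            (is.null(best) || s$decrease > best$decrease + 1e-12 ||
             (abs(s$decrease - best$decrease) <= 1e-12 &&
              s$threshold < best$threshold)))
          best <- list(feature = j, threshold = s$threshold,
                       decrease = s$decrease)
      }
      split <- best
    }
    if (!is.null(split)) {
      node$feature <- split$feature
      node$threshold <- split$threshold
      imp_env$imp[split$feature] <- imp_env$imp[split$feature] +
        split$decrease * length(rows) / n_train
      go_right <- X[rows, split$feature] >= split$threshold
      # push right first so the left child is processed (and numbered) first
      stack[[length(stack) + 1L]] <- list(idx = rows[go_right],
                                          depth = task$depth + 1L,
                                          slot = c(id, 2L))
      stack[[length(stack) + 1L]] <- list(idx = rows[!go_right],
                                          depth = task$depth + 1L,
                                          slot = c(id, 1L))
    }
    nodes[[id]] <- node
    if (!any(is.na(task$slot))) {
      side <- if (task$slot[2] == 1L) "left" else "right"
      nodes[[task$slot[1]]][[side]] <- id
    }
  }
  nodes
}

tree_predict <- function(nodes, X) {
  out <- character(nrow(X))
  assign_rows <- vector("list", length(nodes))
  assign_rows[[1]] <- seq_len(nrow(X))
  for (id in seq_along(nodes)) {
    rows <- assign_rows[[id]]
    if (is.null(rows) || !length(rows)) next
    nd <- nodes[[id]]
    if (is.na(nd$feature)) {
      out[rows] <- nd$pred
    } else {
      go_right <- X[rows, nd$feature] >= nd$threshold
      assign_rows[[nd$left]] <- c(assign_rows[[nd$left]], rows[!go_right])
      assign_rows[[nd$right]] <- c(assign_rows[[nd$right]], rows[go_right])
    }
  }
  out
}

#' Fit the subsampled Gini-tree ensemble and rank features
#'
#' Grows `n_trees` classification trees, each on a uniform random
#' `train_fraction` subsample of patients drawn without replacement, with
#' threshold splits of the form `count >= t` chosen to maximise the
#' weighted Gini impurity decrease over a random feature subset at each
#' node. A feature's importance is the impurity decrease of its splits
#' weighted by the fraction of the tree's training patients reaching the
#' split, summed within each tree and averaged over trees. Out-of-bag
#' accuracy is the majority vote of each tree on its own held-out patients
#' (ties vote `RA`).
#'
#' @param fm a [feature_matrix()] with both classes present.
#' @param config a [forest_config()].
#' @return object of class `code_forest`: list with `trees`, `importance`
#'   (data.frame `feature`, `importance`, `rank`; ranks are a permutation
#'   of `1..n_features`, ties in importance broken by feature name),
#'   `oob_accuracy`, and the `config`.
#' @export
fit_forest <- function(fm, config = forest_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "forest_config"))
  X <- fm$values
  if (ncol(X) < 1L || nrow(X) < 2L)
    cp_stop("degenerate feature matrix", "codephen_input_error")
  y_case <- fm$labels == "RA"
  if (!any(y_case) || all(y_case))
    cp_stop("forest needs both classes present", "codephen_input_error")
  n <- nrow(X)
  n_sub <- max(1L, floor(config$train_fraction * n))
  with_seed(config$seed, {
    imp_env <- new.env()
    trees <- vector("list", config$n_trees)
    total_imp <- numeric(ncol(X))
    votes_ra <- numeric(n); votes_any <- numeric(n)
    for (t in seq_len(config$n_trees)) {
      idx <- sort(sample.int(n, n_sub))
      imp_env$imp <- numeric(ncol(X))
      nodes <- grow_tree(X, y_case, idx, config, imp_env)
      total_imp <- total_imp + imp_env$imp
      trees[[t]] <- list(nodes = nodes, in_bag = idx)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob)) {
        pred <- tree_predict(nodes, X[oob, , drop = FALSE])
        votes_ra[oob] <- votes_ra[oob] + (pred == "RA")
        votes_any[oob] <- votes_any[oob] + 1
      }
    }
    importance <- total_imp / config$n_trees
    ord <- order(-importance, colnames(X), method = "radix")
    imp_df <- data.frame(feature = colnames(X)[ord],
                         importance = importance[ord],
                         rank = seq_along(ord), stringsAsFactors = FALSE)
    seen <- votes_any > 0
    oob_pred <- ifelse(votes_ra[seen] >= votes_any[seen] / 2, "RA", "nonRA")
    oob_acc <- if (any(seen))
      mean(oob_pred == c("nonRA", "RA")[y_case[seen] + 1L]) else NA_real_
    structure(list(trees = trees, importance = imp_df,
                   oob_accuracy = oob_acc, config = config,
                   feature_names = colnames(X)),
              class = "code_forest")
  })
}

#' @export
print.code_forest <- function(x, ...) {
  cat(sprintf("<code_forest> %d trees, %d features, OOB accuracy %.3f\n",
              length(x$trees), length(x$feature_names), x$oob_accuracy))
  invisible(x)
}

#' Majority-vote prediction from a fitted forest
#'
#' @param object a `code_forest`.
#' @param newdata a `feature_matrix` or plain matrix with the forest's
#'   feature columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.code_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  X <- X[, object$feature_names, drop = FALSE]
  votes <- numeric(nrow(X))
  for (tr in object$trees)
    votes <- votes + (tree_predict(tr$nodes, X) == "RA")
  factor(ifelse(votes >= length(object$trees) / 2, "RA", "nonRA"),
         levels = VALID_LABELS)
}

#' Select the top-ranked features
#'
#' @param importance a `code_forest` or its `importance` data.frame.
#' @param k number of features to keep, `1 <= k <= n_features`.
#' @return character vector of feature names in rank order.
#' @export
select_top <- function(importance, k) {
  if (inherits(importance, "code_forest")) importance <- importance$importance
  if (k < 1L || k > nrow(importance))
    cp_stop(sprintf("k must be in 1..%d", nrow(importance)),
            "codephen_input_error")
  importance$feature[order(importance$rank)][seq_len(k)]
}
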