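# Phase 3: single-tree induction with gain-ratio splitting and pessimistic
# pruning, plus flattening of the tree into an ordered, transparent
# if-then ruleset. Implemented natively so the splitting criterion,
# admissibility rule, pruning bound and tie-breaks are fully specified.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain ratio of a two-way split
#'
#' Gain ratio is the information gain of the split (parent entropy minus
#' size-weighted child entropy, in bits) divided by the split information
#' (entropy of the branch-size distribution). Splits that send everything
#' one way have split information 0 and return 0.
#'
#' @param parent_counts length-2 vector of class counts at the parent.
#' @param split_counts 2x2 matrix, rows = children, columns = classes;
#'   row sums must add to the parent counts.
#' @return the gain ratio (bits/bits, dimensionless).
#' @export
information_gain_ratio <- function(parent_counts, split_counts) {
  n <- sum(parent_counts)
  if (n == 0) cp_stop("empty parent node", "codephen_input_error")
  if (!isTRUE(all.equal(colSums(split_counts), as.numeric(parent_counts),
                        check.attributes = FALSE)))
    cp_stop("split does not partition the parent", "codephen_input_error")
  sizes <- rowSums(split_counts)
  gain <- entropy_bits(parent_counts) -
    sum(sizes / n * apply(split_counts, 1, entropy_bits))
  split_info <- entropy_bits(sizes)
  if (split_info == 0) return(0)
  gain / split_info
}

info_gain <- function(parent_counts, split_counts) {
  n <- sum(parent_counts)
  sizes <- rowSums(split_counts)
  entropy_bits(parent_counts) -
    sum(sizes / n * apply(split_counts, 1, entropy_bits))
}

# Pessimistic upper bound on the true error rate of a leaf that
# misclassifies E of its N training cases: the upper confidence limit of
# the binomial error at confidence factor cf (smaller cf = harsher bound,
# more pruning). Equals the textbook special cases, e.g. E = 0 gives
# 1 - cf^(1/N).
ucb_error <- function(E, N, cf) {
  if (N == 0) return(0)
  if (E >= N) return(1)
  stats::qbeta(1 - cf, E + 1, N - E)
}

# Best threshold for one feature by information gain; ties by lower
# threshold. Returns NULL or list(threshold, gain, split_counts).
# m_attr = number of features competing at the node, for the MDL charge.
best_gain_split <- function(x, y_case, min_leaf, m_attr = 1L) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  f <- match(x, ux); k <- length(ux)
  c1 <- tabulate(f[y_case], nbins = k)
  c2 <- tabulate(f[!y_case], nbins = k)
  cl1 <- cumsum(c1)[-k]; cl2 <- cumsum(c2)[-k]
  t1 <- sum(c1); t2 <- sum(c2); n <- t1 + t2
  nl <- cl1 + cl2; nr <- n - nl
  ok <- nl >= min_leaf & nr >= min_leaf
  if (!any(ok)) return(NULL)
  hp <- entropy_bits(c(t1, t2))
  h2 <- function(a, b) {
    s <- a + b
    h <- numeric(length(s))
    pos <- s > 0
    pa <- a[pos] / s[pos]; pb <- b[pos] / s[pos]
    term <- function(p) ifelse(p > 0, -p * log2(p), 0)
    h[pos] <- term(pa) + term(pb)
    h
  }
  gain <- hp - (nl * h2(cl1, cl2) + nr * h2(t1 - cl1, t2 - cl2)) / n
  # MDL correction: charge the per-case coding cost of naming the chosen
  # cut point AND the chosen attribute, so thresholds that look good only
  # through multiplicity (many cuts x many features) do not pay their way
  gain <- gain - (log2(k - 1L) + log2(m_attr)) / n
  gain[!ok] <- -Inf
  best <- which.max(gain)           # which.max takes the lowest threshold
  if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(NULL)
  list(threshold = (ux[best] + ux[best + 1L]) / 2, gain = gain[best],
       split_counts = rbind(c(cl1[best], cl2[best]),
                            c(t1 - cl1[best], t2 - cl2[best])))
}

leaf_node <- function(n_case, n_control) {
  list(leaf = TRUE, n_case = n_case, n_control = n_control,
       pred = if (n_case >= n_control) "RA" else "nonRA")
}

grow_c45 <- function(X, y_case, rows, min_leaf) {
  n1 <- sum(y_case[rows]); n0 <- length(rows) - n1
  if (n1 == 0L || n0 == 0L || length(rows) < 2L * min_leaf)
    return(leaf_node(n1, n0))
  # per-feature best-gain candidate thresholds, scanned in name order
  feats <- colnames(X)[order(colnames(X), method = "radix")]
  cand <- list()
  for (fn in feats) {
    s <- best_gain_split(X[rows, fn], y_case[rows], min_leaf, ncol(X))
    if (!is.null(s)) { s$feature <- fn; cand[[length(cand) + 1L]] <- s }
  }
  if (!length(cand)) return(leaf_node(n1, n0))
  gains <- vapply(cand, `[[`, 0, "gain")
  # C4.5 admissibility: only splits with at least average gain compete,
  # then the gain ratio decides; ties by (feature name, lower threshold),
  # realised by the name-ordered scan with a strict '>' update
  admissible <- gains >= mean(gains) - 1e-12
  best <- NULL; best_ratio <- -Inf
  for (i in which(admissible)) {
    ratio <- cand[[i]]$gain / entropy_bits(rowSums(cand[[i]]$split_counts))
    if (ratio > best_ratio + 1e-12) { best <- cand[[i]]; best_ratio <- ratio }
  }
  if (is.null(best) || best_ratio <= 1e-12) return(leaf_node(n1, n0))
  go_right <- X[rows, best$feature] >= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n_case = n1, n_control = n0,
       left = grow_c45(X, y_case, rows[!go_right], min_leaf),
       right = grow_c45(X, y_case, rows[go_right], min_leaf))
}

# Bottom-up pessimistic pruning: collapse a subtree to a leaf whenever the
# leaf's predicted error count is no worse than the sum over its leaves.
# Branch grafting is not performed.
prune_c45 <- function(node, cf) {
  if (node$leaf) {
    node$est_errors <- sum(node$n_case, node$n_control) *
      ucb_error(min(node$n_case, node$n_control),
                node$n_case + node$n_control, cf)
    return(node)
  }
  node$left <- prune_c45(node$left, cf)
  node$right <- prune_c45(node$right, cf)
  subtree_err <- node$left$est_errors + node$right$est_errors
  n <- node$n_case + node$n_control
  leaf_err <- n * ucb_error(min(node$n_case, node$n_control), n, cf)
  if (leaf_err <= subtree_err + 1e-8) {
    node <- leaf_node(node$n_case, node$n_control)
    node$est_errors <- leaf_err
  } else {
    node$est_errors <- subtree_err
  }
  node
}

#' Induce a pruned decision tree by gain-ratio splitting
#'
#' Greedy recursive partitioning of the labelled feature matrix: at each
#' node, every feature's best information-gain threshold is a candidate,
#' with the gain charged an MDL correction of
#' `(log2(cuts) + log2(features)) / n` for the multiplicity of thresholds
#' and attributes examined (the continuous-attribute refinement of late
#' C4.5 releases, extended to the attribute choice) so spurious splits on
#' noise do not pay their way; candidates with at least average gain
#' compete on gain ratio (the classic C4.5 admissibility convention,
#' which protects against the ratio's bias toward unbalanced splits);
#' ties are broken by feature name then lower threshold. Nodes become leaves when pure, smaller than
#' `2 * min_leaf`, or without an admissible split. The grown tree is then
#' pruned bottom-up by the pessimistic binomial error bound at confidence
#' factor `cf`. Degenerate input (single class) yields a single majority
#' leaf, not an error. Induction is deterministic: no randomness is used.
#'
#' @param fm a [feature_matrix()].
#' @param min_leaf minimum patients per leaf (default 5).
#' @param cf pruning confidence factor in (0,1); smaller prunes harder
#'   (default 0.25, the customary value).
#' @param prune set `FALSE` to keep the unpruned tree.
#' @return object of class `decision_tree`.
#' @export
induce_tree <- function(fm, min_leaf = 5L, cf = 0.25, prune = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"), min_leaf >= 1L, cf > 0, cf < 1)
  X <- fm$values
  y_case <- fm$labels == "RA"
  root <- grow_c45(X, y_case, seq_len(nrow(X)), as.integer(min_leaf))
  if (prune) root <- prune_c45(root, cf)
  structure(list(root = root, feature_names = colnames(X),
                 min_leaf = as.integer(min_leaf), cf = cf),
            class = "decision_tree")
}

count_leaves <- function(node) {
  if (node$leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree> %d leaves (min_leaf %d, cf %.2f)\n",
              count_leaves(x$root), x$min_leaf, x$cf))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s=> %s (%d RA / %d nonRA)\n", pad, node$pred,
                  node$n_case, node$n_control))
    } else {
      cat(sprintf("%s%s < %g:\n", pad, node$feature, node$threshold))
      print_node(node$left, indent + 1L)
      cat(sprintf("%s%s >= %g:\n", pad, node$feature, node$threshold))
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x$root, 0L)
  invisible(x)
}

tree_classify <- function(tree, X) {
  walk <- function(node, rows, out) {
    if (!length(rows)) return(out)
    if (node$leaf) { out[rows] <- node$pred; return(out) }
    go_right <- X[rows, node$feature] >= node$threshold
    out <- walk(node$left, rows[!go_right], out)
    walk(node$right, rows[go_right], out)
  }
  walk(tree$root, seq_len(nrow(X)), character(nrow(X)))
}

new_rule <- function(conditions, conclusion, confidence) {
  structure(list(conditions = conditions, conclusion = conclusion,
                 confidence = confidence), class = "phen_rule")
}

empty_conditions <- function() {
  data.frame(feature = character(0), op = character(0), value = numeric(0),
             stringsAsFactors = FALSE)
}

#' Flatten a decision tree into an ordered ruleset
#'
#' Each root-to-leaf branch becomes one if-then rule, with conditions in
#' root-to-leaf order and the leaf's majority class as the conclusion;
#' rule confidence is the leaf's majority fraction. Rules extracted from a
#' tree are mutually exclusive and exhaustive, so the ruleset's decision
#' function is identical to the tree's on every input. A single-leaf tree
#' yields one empty-condition rule. The ruleset default is the tree root's
#' majority class.
#'
#' @param tree a [induce_tree()] result.
#' @return object of class `ruleset`.
#' @export
extract_rules <- function(tree) {
  rules <- list()
  walk <- function(node, conds) {
    if (node$leaf) {
      n <- node$n_case + node$n_control
      conf <- if (n > 0) max(node$n_case, node$n_control) / n else 1
      rules[[length(rules) + 1L]] <<- new_rule(conds, node$pred, conf)
      return(invisible())
    }
    walk(node$left, rbind(conds, data.frame(
      feature = node$feature, op = "<", value = node$threshold)))
    walk(node$right, rbind(conds, data.frame(
      feature = node$feature, op = ">=", value = node$threshold)))
  }
  walk(tree$root, empty_conditions())
  root <- tree$root
  ruleset(rules, default = if (root$n_case >= root$n_control) "RA" else "nonRA")
}

#' Construct a ruleset
#'
#' A ruleset is an ordered list of if-then rules evaluated first-match:
#' each rule is a conjunction of conditions `(feature, op, value)` with
#' `op` one of `>=`, `<`, `=`, concluding `RA` or `nonRA`; a record
#' matching no rule receives the default conclusion. Features missing from
#' a record are treated as count 0.
#'
#' @param rules list of rules (see [extract_rules()] for the structure).
#' @param default fallback conclusion.
#' @return object of class `ruleset`.
#' @export
ruleset <- function(rules, default = "nonRA") {
  default <- match.arg(default, VALID_LABELS)
  structure(list(rules = rules, default = default), class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(format_ruleset(x))
  invisible(x)
}

#' Classify records with a ruleset
#'
#' @param rs a [ruleset()].
#' @param record named numeric vector of feature values (missing features
#'   are 0), or a matrix / `feature_matrix` for many records at once.
#' @return single label, or character vector for matrix input.
#' @export
rule_classify <- function(rs, record) {
  stopifnot(inherits(rs, "ruleset"))
  if (inherits(record, "feature_matrix")) record <- record$values
  if (is.matrix(record)) return(rule_classify_matrix(rs, record))
  feats <- unique(unlist(lapply(rs$rules, function(r) r$conditions$feature)))
  vals <- stats::setNames(rep(0, length(feats)), feats)
  known <- intersect(names(record), feats)
  vals[known] <- record[known]
  for (r in rs$rules) {
    if (rule_matches(r, vals)) return(r$conclusion)
  }
  rs$default
}

rule_matches <- function(rule, vals) {
  cond <- rule$conditions
  if (nrow(cond) == 0L) return(TRUE)
  x <- vals[cond$feature]
  ok <- ifelse(cond$op == ">=", x >= cond$value,
        ifelse(cond$op == "<", x < cond$value, x == cond$value))
  all(ok)
}

rule_classify_matrix <- function(rs, X) {
  out <- rep(NA_character_, nrow(X))
  feats <- unique(unlist(lapply(rs$rules, function(r) r$conditions$feature)))
  missing <- setdiff(feats, colnames(X))
  if (length(missing)) {
    X <- cbind(X, matrix(0, nrow(X), length(missing),
                         dimnames = list(NULL, missing)))
  }
  open <- seq_len(nrow(X))
  for (r in rs$rules) {
    if (!length(open)) break
    cond <- r$conditions
    match_rows <- rep(TRUE, length(open))
    if (nrow(cond) > 0L) {
      for (i in seq_len(nrow(cond))) {
        x <- X[open, cond$feature[i]]
        match_rows <- match_rows & switch(cond$op[i],
          ">=" = x >= cond$value[i],
          "<" = x < cond$value[i],
          "=" = x == cond$value[i])
      }
    }
    out[open[match_rows]] <- r$conclusion
    open <- open[!match_rows]
  }
  out[open] <- rs$default
  out
}

format_ruleset <- function(rs) {
  fmt_rule <- function(r) {
    lhs <- if (nrow(r$conditions) == 0L) "TRUE" else
      paste(sprintf("%s %s %g", r$conditions$feature, r$conditions$op,
                    r$conditions$value), collapse = " AND ")
    sprintf("IF %s THEN %s [confidence %.6f]\n", lhs, r$conclusion,
            r$confidence)
  }
  paste0("# codephen ruleset v1\n", sprintf("default: %s\n", rs$default),
         paste(vapply(rs$rules, fmt_rule, ""), collapse = ""))
}

#' Write / read a ruleset as human-readable text
#'
#' The serialisation is an ordered list of `IF ... THEN ...` lines plus a
#' default conclusion; it round-trips through [read_ruleset()] byte for
#' byte.
#'
#' @param rs a [ruleset()].
#' @param path file path.
#' @export
write_ruleset <- function(rs, path) {
  writeLines(sub("\n$", "", format_ruleset(rs)), path)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  def_line <- grep("^default:", lines, value = TRUE)
  if (length(def_line) != 1L)
    cp_stop("ruleset file needs exactly one 'default:' line",
            "codephen_format_error")
  default <- trimws(sub("^default:", "", def_line))
  rule_lines <- grep("^IF ", lines, value = TRUE)
  rules <- lapply(rule_lines, function(ln) {
    m <- regmatches(ln, regexec(
      "^IF (.+) THEN (RA|nonRA)(?: \\[confidence ([0-9.]+)\\])?$", ln))[[1]]
    if (length(m) == 0L)
      cp_stop(sprintf("unparseable rule line: %s", ln),
              "codephen_format_error")
    lhs <- m[2]
    conf <- if (nzchar(m[4])) as.numeric(m[4]) else 1
    if (trimws(lhs) == "TRUE") {
      conds <- empty_conditions()
    } else {
      parts <- strsplit(lhs, " AND ", fixed = TRUE)[[1]]
      pm <- regmatches(parts, regexec(
        "^\\s*(\\S+)\\s*(>=|<|=)\\s*(-?[0-9.]+)\\s*$", parts))
      if (any(lengths(pm) == 0L))
        cp_stop(sprintf("unparseable condition in: %s", ln),
                "codephen_format_error")
      conds <- data.frame(
        feature = vapply(pm, `[[`, "", 2),
        op = vapply(pm, `[[`, "", 3),
        value = as.numeric(vapply(pm, `[[`, "", 4)),
        stringsAsFactors = FALSE)
    }
    new_rule(conds, m[3], conf)
  })
  ruleset(rules, default = default)
}

#' Training accuracy of a tree on a feature matrix
#'
#' @param tree a `decision_tree`.
#' @param fm a `feature_matrix`.
#' @return fraction of patients classified correctly.
#' @export
tree_accuracy <- function(tree, fm) {
  mean(tree_classify(tree, fm$values) == as.character(fm$labels))
}
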