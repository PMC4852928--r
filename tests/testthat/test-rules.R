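test_that("gain ratio matches hand-computed entropies", {
  # symmetric case: two pure equal halves of a 50/50 parent
  expect_equal(information_gain_ratio(c(4, 4), rbind(c(4, 0), c(0, 4))), 1)
  # a split that separates nothing has ratio 0
  expect_equal(information_gain_ratio(c(4, 4), rbind(c(2, 2), c(2, 2))), 0)
  # parent (6 RA, 2 nonRA) -> (4,0) and (2,2):
  # gain = 0.8113 - 0.5 = 0.3113 bits, split-info = 1 bit
  expect_equal(information_gain_ratio(c(6, 2), rbind(c(4, 0), c(2, 2))),
               0.31127812, tolerance = 1e-6)
  # degenerate split (all cases one side) has split-info 0 -> ratio 0
  expect_equal(information_gain_ratio(c(6, 2), rbind(c(6, 2), c(0, 0))), 0)
  expect_error(information_gain_ratio(c(0, 0), rbind(c(0, 0), c(0, 0))),
               class = "codephen_input_error")
})

test_that("gain ratio agrees with an independent entropy oracle on random splits", {
  set.seed(55)
  for (i in 1:25) {
    parent <- c(sample(1:10, 1), sample(1:10, 1))
    l1 <- sample(0:parent[1], 1); l2 <- sample(0:parent[2], 1)
    split <- rbind(c(l1, l2), parent - c(l1, l2))
    if (any(rowSums(split) == 0)) next
    sizes <- rowSums(split)
    gain <- oracle_entropy(parent) -
      sum(sizes / sum(parent) * apply(split, 1, oracle_entropy))
    expect_equal(information_gain_ratio(parent, split),
                 gain / oracle_entropy(sizes), tolerance = 1e-10)
  }
})

test_that("perfectly separable data induces a depth-1 tree with full accuracy", {
  X <- cbind(A = c(0, 0, 0, 1, 2, 3, 0, 1), B = c(1, 1, 0, 0, 1, 0, 1, 1))
  rownames(X) <- paste0("p", 1:8)
  fm <- feature_matrix(X, ifelse(X[, "A"] >= 1, "RA", "nonRA"))
  tree <- induce_tree(fm, min_leaf = 1)
  expect_equal(length(extract_rules(tree)$rules), 2)
  expect_equal(tree_accuracy(tree, fm), 1)
  # degenerate single-class input: a single majority leaf, not an error
  fm1 <- feature_matrix(X, rep("nonRA", 8))
  t1 <- induce_tree(fm1)
  expect_length(extract_rules(t1)$rules, 1)
  expect_equal(rule_classify(extract_rules(t1), c(A = 3)), "nonRA")
})

test_that("pure-noise features mostly prune to a single leaf", {
  singles <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rpois(200 * 5, 1), 200, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- sample(c("RA", "nonRA"), 200, replace = TRUE)
    tree <- induce_tree(feature_matrix(X, y), min_leaf = 5, cf = 0.25)
    singles <- singles + (length(extract_rules(tree)$rules) == 1L)
  }
  expect_gte(singles / 20, 0.8)
})

test_that("pruning never increases training accuracy", {
  for (s in 1:10) {
    fm <- random_fm(n = 60, p = 4, seed = 500 + s)
    unpruned <- induce_tree(fm, min_leaf = 2, prune = FALSE)
    pruned <- induce_tree(fm, min_leaf = 2, prune = TRUE)
    expect_gte(tree_accuracy(unpruned, fm), tree_accuracy(pruned, fm))
  }
})

test_that("extracted rulesets are functionally identical to their tree", {
  # exhaustive equivalence over the full grid of small count vectors
  grid <- as.matrix(expand.grid(f1 = 0:3, f2 = 0:3, f3 = 0:3, f4 = 0:3))
  rownames(grid) <- sprintf("g%03d", seq_len(nrow(grid)))
  for (s in 1:8) {
    fm <- random_fm(n = 40, p = 4, seed = 600 + s)
    tree <- induce_tree(fm, min_leaf = 2)
    rs <- extract_rules(tree)
    expect_equal(rule_classify(rs, grid),
                 codephen:::tree_classify(tree, grid))
    # tree rules are mutually exclusive and exhaustive: every grid row
    # matches exactly one rule
    n_match <- rowSums(vapply(rs$rules, function(r) {
      apply(grid, 1, function(v) codephen:::rule_matches(r, v))
    }, logical(nrow(grid))))
    expect_true(all(n_match == 1))
  }
  # structural count: a hand-built depth-2 tree with 4 leaves gives 4
  # rules, conditions in root-to-leaf order
  leaf <- function(n1, n0) list(leaf = TRUE, n_case = n1, n_control = n0,
                                pred = if (n1 >= n0) "RA" else "nonRA")
  split <- function(f, t, l, r) list(leaf = FALSE, feature = f,
                                     threshold = t,
                                     n_case = l$n_case + r$n_case,
                                     n_control = l$n_control + r$n_control,
                                     left = l, right = r)
  hand <- structure(list(root = split("a", 0.5,
                                      split("b", 1.5, leaf(0, 5), leaf(4, 1)),
                                      split("b", 0.5, leaf(3, 0), leaf(1, 6))),
                         feature_names = c("a", "b")),
                    class = "decision_tree")
  hand_rs <- extract_rules(hand)
  expect_length(hand_rs$rules, 4)
  expect_equal(hand_rs$rules[[2]]$conditions$feature, c("a", "b"))
  expect_equal(hand_rs$rules[[2]]$conditions$op, c("<", ">="))
  expect_equal(hand_rs$rules[[2]]$confidence, 4 / 5)
})

test_that("classification is first-match and treats missing features as zero", {
  rs <- ruleset(list(
    codephen:::new_rule(data.frame(feature = "PSA", op = ">=", value = 1),
                        "nonRA", 1),
    codephen:::new_rule(data.frame(feature = "RAcode", op = ">=", value = 1),
                        "RA", 0.9)), default = "nonRA")
  expect_equal(rule_classify(rs, c(PSA = 1, RAcode = 5)), "nonRA")
  expect_equal(rule_classify(rs, c(RAcode = 1)), "RA")
  expect_equal(rule_classify(rs, c(OTHER = 7)), "nonRA")   # all-zero record
  # reordering rules ABOVE the first match, when they do not match,
  # cannot change the outcome
  rs2 <- ruleset(rev(rs$rules), default = "nonRA")
  expect_equal(rule_classify(rs2, c(RAcode = 1)), "RA")
})

test_that("rulesets serialise to text and round-trip byte-identically", {
  fm <- random_fm(n = 40, p = 3, seed = 71)
  rs <- extract_rules(induce_tree(fm, min_leaf = 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ruleset(rs, path)
  first <- readLines(path)
  back <- read_ruleset(path)
  # identical decision function and identical re-serialisation
  grid <- as.matrix(expand.grid(f1 = 0:3, f2 = 0:3, f3 = 0:3))
  rownames(grid) <- sprintf("g%03d", seq_len(nrow(grid)))
  expect_equal(rule_classify(back, grid), rule_classify(rs, grid))
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_ruleset(back, path2)
  expect_identical(readLines(path2), first)
  # empty-condition rule round-trips too
  single <- extract_rules(induce_tree(
    feature_matrix(matrix(0L, 4, 1, dimnames = list(paste0("p", 1:4), "f")),
                   rep("nonRA", 4))))
  write_ruleset(single, path)
  expect_equal(read_ruleset(path)$rules[[1]]$conditions,
               codephen:::empty_conditions())
})

test_that("trees induced from a known 3-rule process recover its decision function", {
  agreements <- vapply(1:20, function(s) {
    set.seed(700 + s)
    Xtr <- recovery_features(2000)
    ytr <- recovery_truth(Xtr)
    flip <- runif(2000) < 0.05
    ytr[flip] <- ifelse(ytr[flip] == "RA", "nonRA", "RA")
    rs <- extract_rules(induce_tree(feature_matrix(Xtr, ytr),
                                    min_leaf = 5, cf = 0.25))
    Xte <- recovery_features(2000)
    mean(rule_classify(rs, Xte) == recovery_truth(Xte))
  }, 0)
  expect_gte(mean(agreements >= 0.95), 0.95)
})

test_that("induction is deterministic: identical input, identical serialised ruleset", {
  fm <- random_fm(n = 50, p = 4, seed = 81)
  r1 <- codephen:::format_ruleset(extract_rules(induce_tree(fm)))
  r2 <- codephen:::format_ruleset(extract_rules(induce_tree(fm)))
  expect_identical(r1, r2)
})
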