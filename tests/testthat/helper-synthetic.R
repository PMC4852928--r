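# Shared fixtures and independent oracles used across the suite.

# A tiny, fully hand-checkable event table: 3 patients, mixed codes.
tiny_events <- function() {
  data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    code = c("N0400", "N0400", "bd3z1", "N0400", "M16z1", "X01za"),
    date = as.Date(c("2005-01-02", "2005-01-02", "2006-03-04",
                     "2004-07-08", "2009-10-11", "2010-12-13")),
    source = "primary", stringsAsFactors = FALSE)
}

tiny_labels <- function() c(p1 = "RA", p2 = "nonRA", p3 = "nonRA")

# Random small feature matrix for property loops.
random_fm <- function(n = 12, p = 3, seed = 1, max_count = 3) {
  set.seed(seed)
  X <- matrix(sample(0:max_count, n * p, replace = TRUE), n, p,
              dimnames = list(sprintf("p%02d", seq_len(n)),
                              sprintf("f%d", seq_len(p))))
  labs <- sample(c("RA", "nonRA"), n, replace = TRUE)
  # guarantee both classes
  labs[1] <- "RA"; labs[2] <- "nonRA"
  feature_matrix(X, labs)
}

# --- independent oracles -------------------------------------------------

# Brute-force best split by Gini decrease: plain loops, mirrors the
# documented tie-break (ties in decrease -> lower threshold, then feature
# name) but shares no code with the implementation.
oracle_gini <- function(cnt) 1 - sum((cnt / sum(cnt))^2)

oracle_best_split <- function(X, y, min_leaf = 1) {
  best <- NULL
  for (fn in sort(colnames(X))) {
    v <- sort(unique(X[, fn]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      t <- (v[i] + v[i + 1]) / 2
      l <- X[, fn] < t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      parent <- c(sum(y == "RA"), sum(y == "nonRA"))
      lc <- c(sum(y[l] == "RA"), sum(y[l] == "nonRA"))
      rc <- parent - lc
      dec <- oracle_gini(parent) -
        (sum(lc) * oracle_gini(lc) + sum(rc) * oracle_gini(rc)) / sum(parent)
      if (dec <= 0) next
      if (is.null(best) || dec > best$dec + 1e-12 ||
          (abs(dec - best$dec) <= 1e-12 && t < best$t - 1e-12)) {
        best <- list(feature = fn, t = t, dec = dec)
      }
    }
  }
  best
}

# Full single-tree importance by exhaustive recursive enumeration,
# importance = sum over splits of decrease * node fraction.
oracle_tree_importance <- function(X, y, min_leaf = 1) {
  imp <- setNames(numeric(ncol(X)), colnames(X))
  n_total <- nrow(X)
  recurse <- function(X, y) {
    if (length(unique(y)) < 2 || nrow(X) < 2 * min_leaf) return(invisible())
    b <- oracle_best_split(X, y, min_leaf)
    if (is.null(b)) return(invisible())
    imp[b$feature] <<- imp[b$feature] + b$dec * nrow(X) / n_total
    l <- X[, b$feature] < b$t
    recurse(X[l, , drop = FALSE], y[l])
    recurse(X[!l, , drop = FALSE], y[!l])
  }
  recurse(X, y)
  imp
}

# Entropy in bits via an independent formulation (natural log rescaled).
oracle_entropy <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p)) / log(2)
}

# 3-rule generating process used for ruleset-recovery experiments:
# psoriatic-arthritis style exclusion, diagnosis+drug conjunction, and a
# severity threshold, over Poisson count features.
recovery_truth <- function(X) {
  ifelse(X[, "PSA"] >= 1, "nonRA",
  ifelse(X[, "RAcode"] >= 1 & X[, "MTX"] >= 1, "RA",
  ifelse(X[, "SERO"] >= 2, "RA", "nonRA")))
}

recovery_features <- function(n) {
  X <- cbind(PSA = stats::rpois(n, 0.3), RAcode = stats::rpois(n, 0.8),
             MTX = stats::rpois(n, 0.7), SERO = stats::rpois(n, 0.9),
             NOISE = stats::rpois(n, 1))
  rownames(X) <- sprintf("r%05d", seq_len(n))
  X
}

# every planted member code of a simulation config
planted_member_codes <- function(cfg) {
  unique(unlist(lapply(cfg$planted_groups, `[[`, "member_codes")))
}
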