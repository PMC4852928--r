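# Phase 2 (aggregation half): expand screened seed codes into groups of
# related codes by hierarchy prefix and shared active ingredient, then
# merge overlapping groups into disjoint variables.

default_prefix_depth <- function(code) {
  # medication chapters are lower-case letters; diagnosis/condition
  # chapters upper-case. Drug hierarchies converge one level earlier.
  ifelse(grepl("^[a-z]", code), 3L, 4L)
}

#' Expand seed codes into groups of related codes
#'
#' Each selected (seed) code recruits every code in the dataset universe
#' that shares its hierarchy prefix, plus every code with the same active
#' ingredient when an ingredient map is given. A seed is always a member
#' of its own group. Expansion is independent of the order in which seeds
#' are supplied.
#'
#' @param selected character vector of seed codes (the screened-in set).
#' @param universe character vector of all codes in the dataset.
#' @param prefix_depth integer 1..5, or `NULL` for the chapter-aware
#'   default (3 characters for medication codes, which start with a
#'   lower-case chapter letter; 4 for diagnosis codes).
#' @param ingredients optional named character vector mapping code to
#'   active-ingredient name (see [read_ingredient_map()]).
#' @return named list (one element per seed) of character vectors of codes.
#' @export
expand_seeds <- function(selected, universe, prefix_depth = NULL,
                         ingredients = NULL) {
  if (!is.null(prefix_depth) &&
      (prefix_depth < 1L || prefix_depth > 5L))
    cp_stop("prefix_depth must be in 1..5", "codephen_format_error")
  universe <- unique(c(as.character(universe), as.character(selected)))
  selected <- unique(as.character(selected))
  groups <- lapply(selected, function(seed) {
    depth <- if (is.null(prefix_depth)) default_prefix_depth(seed)
             else as.integer(prefix_depth)
    pre <- substr(seed, 1L, depth)
    members <- universe[substr(universe, 1L, depth) == pre]
    if (!is.null(ingredients) && seed %in% names(ingredients)) {
      ing <- ingredients[[seed]]
      members <- c(members,
                   intersect(universe, names(ingredients)[ingredients == ing]))
    }
    sort(unique(c(seed, members)), method = "radix")
  })
  stats::setNames(groups, selected)[order(selected, method = "radix")]
}

#' Merge overlapping code groups into disjoint variables
#'
#' Groups sharing any code are unioned transitively (connected components
#' of the code-sharing graph) until the result is pairwise disjoint --
#' e.g. codes for laboratory tests normally performed together collapse to
#' one variable. The merged group keeps the lexicographically first of the
#' contributing names; kinds follow the first contributing group.
#'
#' @param groups named list of character vectors (from [expand_seeds()]) or
#'   list of [code_group()] objects.
#' @param kind kind assigned to merged groups built from plain vectors.
#' @return list of pairwise-disjoint [code_group()] objects, sorted by name.
#' @export
merge_groups <- function(groups, kind = "other") {
  if (length(groups) == 0L) return(list())
  if (inherits(groups[[1]], "code_group")) {
    nms <- vapply(groups, `[[`, "", "name")
    sets <- lapply(groups, `[[`, "codes")
    kinds <- vapply(groups, `[[`, "", "kind")
  } else {
    nms <- names(groups)
    sets <- lapply(groups, as.character)
    kinds <- rep(kind, length(groups))
  }
  # union-find over groups, linked through shared codes
  parent <- seq_along(sets)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  codes <- unique(unlist(sets))
  owner <- integer(length(codes))
  names(owner) <- codes
  for (i in seq_along(sets)) {
    for (cd in sets[[i]]) {
      j <- owner[[cd]]
      if (j == 0L) owner[[cd]] <- i
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(sets), find, 1L)
  merged <- lapply(split(seq_along(sets), roots), function(idx) {
    code_group(min(nms[idx]), sort(unique(unlist(sets[idx])), method = "radix"),
               kinds[[idx[1]]])
  })
  merged <- merged[order(vapply(merged, `[[`, "", "name"), method = "radix")]
  names(merged) <- vapply(merged, `[[`, "", "name")
  merged
}

#' Read a code-to-ingredient map
#'
#' Delimited text with header `code,ingredient`; each code maps to exactly
#' one active ingredient.
#'
#' @param path file path.
#' @return named character vector (code -> ingredient).
#' @export
read_ingredient_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("code", "ingredient") %in% names(df)))
    cp_stop("ingredient map needs columns code, ingredient",
            "codephen_format_error")
  if (anyDuplicated(df$code))
    cp_stop("each code may map to exactly one ingredient",
            "codephen_format_error")
  stats::setNames(df$ingredient, df$code)
}

#' Compare classification accuracy before and after an expansion
#'
#' Fits the subsampled tree ensemble to the feature matrices before and
#' after a proposed aggregation step and compares their out-of-bag
#' accuracies; the expansion is accepted if accuracy does not drop by more
#' than `tolerance` (default 0: never accept a loss).
#'
#' @param fm_before,fm_after feature matrices over the same patients and
#'   labels.
#' @param config a [forest_config()]; kept small by default since this is
#'   a screening comparison, not a final fit.
#' @param tolerance maximum tolerated OOB accuracy decrease.
#' @return list with `oob_before`, `oob_after`, `difference`
#'   (after - before) and `accepted`.
#' @export
evaluate_expansion <- function(fm_before, fm_after,
                               config = forest_config(n_trees = 50L),
                               tolerance = 0) {
  if (!identical(fm_before$patient_ids, fm_after$patient_ids) ||
      !identical(as.character(fm_before$labels),
                 as.character(fm_after$labels)))
    cp_stop("matrices must share patients and labels", "codephen_input_error")
  if (identical(fm_before$values, fm_after$values)) {
    acc <- fit_forest(fm_before, config)$oob_accuracy
    return(list(oob_before = acc, oob_after = acc, difference = 0,
                accepted = TRUE))
  }
  before <- fit_forest(fm_before, config)$oob_accuracy
  after <- fit_forest(fm_after, config)$oob_accuracy
  diff <- after - before
  list(oob_before = before, oob_after = after, difference = diff,
       accepted = diff >= -tolerance)
}
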