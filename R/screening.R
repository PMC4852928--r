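# Phase 1: preliminary predictor selection by relative code frequency.

#' Screen codes by relative frequency in cases versus controls
#'
#' For each feature (raw code or code group) the statistic compares how
#' often the code appears in patients with the gold-standard diagnosis
#' against patients without it. Presence means an occurrence count of at
#' least 1. Writing `N_x1` for the number of cases carrying code `x`,
#' `N_x2` for the carrying controls, and `N` for all labelled patients:
#'
#' * `denominator = "population"` (the default): `rfeq = (N_x1 - N_x2) / N`,
#'   a difference of population-wide frequencies. This convention lets
#'   rare but highly case-specific codes surface with a small positive
#'   score rather than being swamped by common codes.
#' * `denominator = "carriers"`: `rfeq = N_x1/(N_x1+N_x2) - N_x2/(N_x1+N_x2)`,
#'   a difference of conditional proportions among carriers of the code.
#'
#' Both conventions are positive exactly when `N_x1 > N_x2`, so the
#' *selected* set is identical under either; only the ranking magnitudes
#' differ. A feature is selected when its score is strictly positive
#' (more frequent in cases than controls). Features carried by no patient
#' score 0 and are retained (not dropped), so downstream joins stay total.
#'
#' @param fm a [feature_matrix()] containing at least one case and one
#'   control.
#' @param denominator `"population"` or `"carriers"`.
#' @return data.frame with columns `code`, `n_case`, `n_control`, `rfeq`,
#'   `selected`, sorted by `rfeq` descending with ties broken by code
#'   (lexicographic), so output order is deterministic.
#' @export
screen <- function(fm, denominator = c("population", "carriers")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(fm, "feature_matrix"))
  if (nlevels(droplevels(fm$labels)) < 2L)
    cp_stop("screening needs at least one case and one control",
            "codephen_input_error")
  present <- fm$values >= 1L
  is_case <- fm$labels == "RA"
  n_case <- as.integer(colSums(present[is_case, , drop = FALSE]))
  n_control <- as.integer(colSums(present[!is_case, , drop = FALSE]))
  n <- nrow(fm$values)
  carriers <- n_case + n_control
  rfeq <- switch(denominator,
    population = (n_case - n_control) / n,
    carriers = ifelse(carriers == 0, 0, (n_case - n_control) / carriers))
  out <- data.frame(code = fm$feature_names, n_case = n_case,
                    n_control = n_control, rfeq = rfeq,
                    selected = rfeq > 0, stringsAsFactors = FALSE)
  out <- out[order(-out$rfeq, out$code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a screening result table
#'
#' @param screened data.frame from [screen()].
#' @param path output path.
#' @export
write_screening <- function(screened, path) {
  utils::write.csv(screened, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
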