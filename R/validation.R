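# Diagnostic-accuracy evaluation: plain confusion-matrix metrics, and
# best/worst-case scenario bounds on 3x3 linkage tables where some
# patients have no record in the gold-standard (or no primary-care)
# system.

#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return list with `sensitivity` (tp/(tp+fn)), `specificity`
#'   (tn/(tn+fp)), `ppv` (tp/(tp+fp)), `accuracy` ((tp+tn)/total). A
#'   metric with a zero denominator is reported as `NA` (undefined), not
#'   an error.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp),
       accuracy = safe(tp + tn, tp + fp + fn + tn))
}

#' Construct a 3x3 linkage contingency table
#'
#' Rows are the algorithm's call on the primary-care record (`RA`,
#' `notRA`, `no_gp_data`), columns the gold-standard secondary-care
#' reference (`RA`, `notRA`, `no_ref_data`). The (`no_gp_data`,
#' `no_ref_data`) cell is undefined (patients in neither system are
#' unobservable) and is not stored.
#'
#' @param a predicted RA, reference RA (true positives among linked).
#' @param b predicted RA, reference notRA (false positives among linked).
#' @param e predicted RA, no reference record (unlinked flagged patients).
#' @param c_ predicted notRA, reference RA (false negatives among linked).
#' @param d predicted notRA, reference notRA (true negatives among linked).
#' @param f predicted notRA, no reference record.
#' @param g no primary-care data, reference RA.
#' @param h no primary-care data, reference notRA.
#' @param population_size optional registered-population denominator for
#'   prevalence.
#' @return object of class `linkage_table`.
#' @export
linkage_table <- function(a, b, e, c_, d, f, g = 0L, h = 0L,
                          population_size = NULL) {
  cells <- c(a = a, b = b, e = e, c = c_, d = d, f = f, g = g, h = h)
  if (any(cells < 0)) cp_stop("cell counts must be non-negative",
                              "codephen_format_error")
  structure(list(cells = cells, population_size = population_size),
            class = "linkage_table")
}

#' @export
print.linkage_table <- function(x, ...) {
  k <- x$cells
  m <- matrix(c(k["a"], k["b"], k["e"],
                k["c"], k["d"], k["f"],
                k["g"], k["h"], NA),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("pred_RA", "pred_notRA", "no_gp_data"),
                              c("ref_RA", "ref_notRA", "no_ref_data")))
  cat("<linkage_table>\n")
  print(m)
  if (!is.null(x$population_size))
    cat(sprintf("population_size: %d\n", x$population_size))
  invisible(x)
}

#' Read / write a linkage table (delimited text, 3x3 layout)
#'
#' Columns `ref_RA`, `ref_notRA`, `no_ref_data`; rows `pred_RA`,
#' `pred_notRA`, `no_gp_data` (the last cell of the last row is left
#' empty). An optional `population_size` can be supplied separately or via
#' a `# population_size: N` comment line.
#'
#' @param path file path.
#' @param population_size optional integer, overrides any comment line.
#' @return a [linkage_table()].
#' @export
read_linkage_table <- function(path, population_size = NULL) {
  lines <- readLines(path)
  pop_line <- grep("^#\\s*population_size:", lines, value = TRUE)
  if (is.null(population_size) && length(pop_line))
    population_size <- as.integer(sub(".*population_size:\\s*", "", pop_line[1]))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], row.names = 1,
                        check.names = FALSE)
  need_r <- c("pred_RA", "pred_notRA", "no_gp_data")
  need_c <- c("ref_RA", "ref_notRA", "no_ref_data")
  if (!all(need_r %in% rownames(df)) || !all(need_c %in% names(df)))
    cp_stop("linkage table needs rows pred_RA/pred_notRA/no_gp_data and columns ref_RA/ref_notRA/no_ref_data",
            "codephen_format_error")
  df <- df[need_r, need_c]
  linkage_table(a = df[1, 1], b = df[1, 2], e = df[1, 3],
                c_ = df[2, 1], d = df[2, 2], f = df[2, 3],
                g = df[3, 1], h = df[3, 2],
                population_size = population_size)
}

#' @rdname read_linkage_table
#' @param table a [linkage_table()].
#' @export
write_linkage_table <- function(table, path) {
  k <- table$cells
  lines <- c(
    if (!is.null(table$population_size))
      sprintf("# population_size: %d", table$population_size),
    ",ref_RA,ref_notRA,no_ref_data",
    sprintf("pred_RA,%d,%d,%d", k["a"], k["b"], k["e"]),
    sprintf("pred_notRA,%d,%d,%d", k["c"], k["d"], k["f"]),
    sprintf("no_gp_data,%d,%d,", k["g"], k["h"]))
  writeLines(lines, path)
  invisible(path)
}

#' Best/worst-case scenario analysis of a linkage table
#'
#' Patients flagged by the algorithm but absent from the gold-standard
#' system (`e`) could be false positives (treated elsewhere is false;
#' worst case) or true positives treated elsewhere (best case); the same
#' assumption applies to the unlinked not-flagged stratum (`f`). Writing
#' `a,b,e` for the predicted-RA row and `c,d,f` for the predicted-notRA
#' row:
#'
#' * worst case: sensitivity `a/(a+c)`, PPV `a/(a+b+e)`, specificity
#'   `(d+f)/((d+f)+(b+e))`;
#' * best case: sensitivity `(a+e)/((a+e)+c)`, PPV `(a+e)/(a+b+e)`,
#'   specificity `(d+f)/((d+f)+b)`.
#'
#' The `no_gp_data` row is reported but excluded from all metric
#' denominators (the algorithm makes no call on patients without a
#' primary-care record). When `population_size` is present, the
#' worst-case prevalence `(a+c)/population_size` is included. When the
#' unlinked cells are zero, both scenarios coincide with the plain
#' confusion metrics. Zero denominators yield `NA` for that metric only.
#'
#' @param table a [linkage_table()].
#' @return data.frame with one row per scenario (`worst`, `best`) and
#'   columns `sensitivity`, `specificity`, `ppv`, plus attribute
#'   `prevalence_worst` when computable.
#' @export
scenario_analysis <- function(table) {
  stopifnot(inherits(table, "linkage_table"))
  k <- as.list(table$cells)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  worst <- c(sensitivity = safe(k$a, k$a + k$c),
             specificity = safe(k$d + k$f, k$d + k$f + k$b + k$e),
             ppv = safe(k$a, k$a + k$b + k$e))
  best <- c(sensitivity = safe(k$a + k$e, k$a + k$e + k$c),
            specificity = safe(k$d + k$f, k$d + k$f + k$b),
            ppv = safe(k$a + k$e, k$a + k$b + k$e))
  out <- data.frame(scenario = c("worst", "best"),
                    rbind(worst, best), row.names = NULL)
  if (!is.null(table$population_size) && table$population_size > 0)
    attr(out, "prevalence_worst") <- (k$a + k$c) / table$population_size
  out
}

#' Compare several algorithms' linkage tables
#'
#' @param tables named list of [linkage_table()] objects (one per
#'   algorithm).
#' @return data.frame with one row per algorithm per scenario, in the
#'   order the tables are supplied (worst before best), with a
#'   `prevalence_worst` column where computable.
#' @export
compare_algorithms <- function(tables) {
  if (length(tables) < 1L) cp_stop("need at least one table",
                                   "codephen_input_error")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    cp_stop("tables must be named by algorithm", "codephen_input_error")
  rows <- lapply(names(tables), function(nm) {
    sa <- scenario_analysis(tables[[nm]])
    prev <- attr(sa, "prevalence_worst")
    sa$algorithm <- nm
    sa$prevalence_worst <- c(if (is.null(prev)) NA_real_ else prev, NA_real_)
    sa
  })
  out <- do.call(rbind, rows)
  out[c("algorithm", "scenario", "sensitivity", "specificity", "ppv",
        "prevalence_worst")]
}

#' Bundled ABMU-style validation contingency tables
#'
#' The three published 3x3 linkage tables validating RA algorithms on the
#' ABMU registered population (475,580 adults): the data-driven
#' algorithm, the QOF register definition, and the expert-derived
#' Thomas-style algorithm. Shipped as plain-text fixtures under
#' `inst/extdata/`.
#'
#' @return named list of [linkage_table()] objects
#'   (`datadriven`, `qof`, `thomas`).
#' @export
ra_validation_tables <- function() {
  dir <- system.file("extdata", package = "codephen")
  stats::setNames(
    lapply(c("datadriven", "qof", "thomas"), function(nm)
      read_linkage_table(file.path(dir, sprintf("abmu_%s_linkage.csv", nm)))),
    c("datadriven", "qof", "thomas"))
}

#' Cross-tabulate cohort phenotype calls against gold-standard labels
#'
#' Builds the 3x3 linkage table from per-patient phenotype calls and the
#' (possibly partial) gold-standard label map; unlinked patients fall in
#' the `no_ref_data` column.
#'
#' @param phenotypes data.frame `patient_id`, `phenotype` (from
#'   [cohort_classify()]).
#' @param labels named character vector (patient -> RA/nonRA) covering the
#'   linked patients only.
#' @param population_size optional denominator for prevalence.
#' @return a [linkage_table()].
#' @export
tabulate_linkage <- function(phenotypes, labels, population_size = NULL) {
  ref <- labels[phenotypes$patient_id]
  ref[is.na(ref)] <- "nodata"
  pred <- phenotypes$phenotype
  n <- function(p, r) sum(pred == p & ref == r)
  extra <- setdiff(names(labels), phenotypes$patient_id)
  linkage_table(a = n("RA", "RA"), b = n("RA", "nonRA"),
                e = n("RA", "nodata"),
                c_ = n("nonRA", "RA"), d = n("nonRA", "nonRA"),
                f = n("nonRA", "nodata"),
                g = sum(labels[extra] == "RA"),
                h = sum(labels[extra] == "nonRA"),
                population_size = population_size)
}

#' Cumulative yearly prevalence under a phenotyping ruleset
#'
#' For each calendar year, classifies every patient using only events
#' dated on or before 31 December of that year and reports the flagged
#' fraction of the registered cohort (all patients appearing in the event
#' stream). Under a cumulative-code definition with a monotone ruleset
#' the curve is non-decreasing; exclusion rules can in principle lower
#' it.
#'
#' @param events coded-event data.frame (see [read_events()]).
#' @param years integer vector of calendar years.
#' @param predictors an [ra_predictors()] object.
#' @param rs a [ruleset()].
#' @return data.frame `year`, `n_patients`, `n_flagged`, `prevalence`
#'   (empty for an empty cohort).
#' @export
prevalence_by_year <- function(events, years,
                               predictors = default_ra_predictors(),
                               rs = ra_default_ruleset()) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(year = integer(0), n_patients = integer(0),
                      n_flagged = integer(0), prevalence = numeric(0)))
  ids <- sort(unique(as.character(events$patient_id)), method = "radix")
  out <- lapply(years, function(yr) {
    cutoff <- as.Date(sprintf("%d-12-31", yr))
    sub <- events[as.Date(events$date) <= cutoff, , drop = FALSE]
    recs <- build_records(sub)
    # keep the full registered cohort as the denominator
    flagged <- if (nrow(sub) == 0L) 0L else {
      cc <- cohort_classify(recs, predictors, rs)
      sum(cc$labels$phenotype == "RA")
    }
    data.frame(year = yr, n_patients = length(ids), n_flagged = flagged,
               prevalence = flagged / length(ids))
  })
  do.call(rbind, out)
}
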