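# The eight-predictor rheumatoid-arthritis phenotyping engine: seven code
# groups counted directly plus a derived categorical severity (intensity)
# variable, evaluated by an ordered if-then ruleset. Code lists are
# user-editable configuration; the bundled defaults are synthetic
# placeholder codes (aligned with the package's simulator) because the
# real register lists are local terminology configuration, not part of the
# method.

RA_GROUP_NAMES <- c("RARTH_COD", "PSORIATIC_CD", "ALTERNATIVE_RA",
                    "PREDNISOLONE", "METHOTREXATE_CD", "SULPHASALAZINE_CD",
                    "LEFLUNOMIDE_CD")
RA_FEATURES <- c(RA_GROUP_NAMES, "INTENSITY_RA")
DMARD_FEATURES <- c("METHOTREXATE_CD", "SULPHASALAZINE_CD",
                    "LEFLUNOMIDE_CD", "PREDNISOLONE")

#' Configure the eight RA predictors
#'
#' The predictor set comprises seven counted code groups -- QOF-register RA
#' diagnosis codes (`RARTH_COD`), psoriatic-arthritis exclusion codes
#' (`PSORIATIC_CD`), alternative-arthropathy exclusion codes
#' (`ALTERNATIVE_RA`), prednisolone at any dosage (`PREDNISOLONE`), and the
#' DMARDs methotrexate, sulphasalazine and leflunomide grouped by active
#' ingredient -- plus `INTENSITY_RA`, a severity class derived from an
#' ordered map of code sets (see [derive_intensity()]).
#'
#' @param groups named list of [code_group()] objects covering all seven
#'   group names above.
#' @param intensity_map named list with elements `"1"`..`"4"`, each a
#'   character vector of codes: 1 = sero-positive (most severe),
#'   2 = RA classification codes, 3 = related conditions (e.g. rheumatoid
#'   nodule), 4 = sero-negative; class 9 (no RA history) needs no codes.
#' @return object of class `ra_predictors`.
#' @export
ra_predictors <- function(groups, intensity_map) {
  missing_grp <- setdiff(RA_GROUP_NAMES, names(groups))
  if (length(missing_grp))
    cp_stop(sprintf("incomplete predictor configuration, missing: %s",
                    paste(missing_grp, collapse = ", ")),
            "codephen_config_error")
  if (!all(as.character(1:4) %in% names(intensity_map)))
    cp_stop("intensity_map must cover classes 1-4", "codephen_config_error")
  structure(list(groups = groups[RA_GROUP_NAMES],
                 intensity_map = intensity_map[as.character(1:4)]),
            class = "ra_predictors")
}

#' Default (synthetic placeholder) RA predictor configuration
#'
#' Placeholder code lists matching the synthetic simulator's planted
#' prefixes, intended for demonstrations and tests; real deployments load
#' locally curated register code lists via [read_ra_predictors()].
#'
#' @return an [ra_predictors()] object.
#' @export
default_ra_predictors <- function() {
  g <- list(
    RARTH_COD = code_group("RARTH_COD", sprintf("N04z%d", 1:4), "diagnosis"),
    PSORIATIC_CD = code_group("PSORIATIC_CD", sprintf("M16z%d", 1:3),
                              "exclusion"),
    ALTERNATIVE_RA = code_group("ALTERNATIVE_RA", sprintf("N06z%d", 1:3),
                                "exclusion"),
    PREDNISOLONE = code_group("PREDNISOLONE", sprintf("bd3z%d", 1:5),
                              "medication"),
    METHOTREXATE_CD = code_group("METHOTREXATE_CD", sprintf("j61z%d", 1:4),
                                 "medication"),
    SULPHASALAZINE_CD = code_group("SULPHASALAZINE_CD", sprintf("j62z%d", 1:3),
                                   "medication"),
    LEFLUNOMIDE_CD = code_group("LEFLUNOMIDE_CD", sprintf("j63z%d", 1:3),
                                "medication"))
  ra_predictors(g, list(`1` = c("N05z1", "N05z2"),
                        `2` = c("N04z1", "N04z2", "N04z3"),
                        `3` = "N05z3",
                        `4` = "N04z4"))
}

#' Read / write an RA predictor configuration (YAML)
#'
#' @param path configuration path.
#' @return for the reader, an [ra_predictors()] object.
#' @export
read_ra_predictors <- function(path) {
  cfg <- yaml::read_yaml(path)
  groups <- lapply(names(cfg$groups), function(nm)
    code_group(nm, unlist(cfg$groups[[nm]]$codes),
               if (is.null(cfg$groups[[nm]]$kind)) "other"
               else cfg$groups[[nm]]$kind))
  names(groups) <- names(cfg$groups)
  imap <- lapply(cfg$intensity, function(x) as.character(unlist(x)))
  ra_predictors(groups, imap)
}

#' @rdname read_ra_predictors
#' @param predictors an [ra_predictors()] object.
#' @export
write_ra_predictors <- function(predictors, path) {
  cfg <- list(
    groups = lapply(predictors$groups, function(g)
      list(kind = g$kind, codes = as.list(g$codes))),
    intensity = lapply(predictors$intensity_map, as.list))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Derive the RA intensity (severity) class
#'
#' Returns the lowest-numbered (most severe) class whose code set
#' intersects the patient's recorded codes: 1 sero-positive RA, 2 RA
#' classification codes, 3 related conditions, 4 sero-negative RA; 9 when
#' no class matches (no history of RA). Adding codes to a record can only
#' keep the class or move it toward 1, never toward 9.
#'
#' @param code_counts named integer vector of code occurrence counts.
#' @param class_code_map named list `"1"`..`"4"` of code vectors.
#' @return integer in `{1, 2, 3, 4, 9}`.
#' @export
derive_intensity <- function(code_counts, class_code_map) {
  present <- names(code_counts)[code_counts >= 1]
  for (lvl in as.character(1:4)) {
    if (length(intersect(class_code_map[[lvl]], present)))
      return(as.integer(lvl))
  }
  9L
}

#' Build the 8-dimensional RA feature vector for one patient
#'
#' @param code_counts named integer vector of code occurrence counts.
#' @param predictors an [ra_predictors()] object.
#' @return named numeric vector: counts for the seven groups plus
#'   `INTENSITY_RA`.
#' @export
ra_feature_vector <- function(code_counts, predictors) {
  v <- vapply(predictors$groups, function(g) {
    sum(code_counts[intersect(names(code_counts), g$codes)])
  }, 0)
  c(v, INTENSITY_RA = derive_intensity(code_counts, predictors$intensity_map))
}

#' The default published-logic RA ruleset
#'
#' Encodes the prevalence algorithm's decision logic as an ordered
#' first-match ruleset over the eight predictors:
#' any psoriatic-arthritis code excludes RA outright; alternative
#' arthropathy codes without RA diagnosis evidence exclude RA; a
#' QOF-register RA code, or a severe intensity class (1 or 2), combined
#' with any DMARD or prednisolone evidence classifies RA; everything else
#' is nonRA. All count thresholds are presence (>= 1); `INTENSITY_RA < 3`
#' captures classes 1 and 2.
#'
#' @return a [ruleset()].
#' @export
ra_default_ruleset <- function() {
  cond <- function(...) {
    v <- list(...)
    data.frame(feature = vapply(v, `[[`, "", 1),
               op = vapply(v, `[[`, "", 2),
               value = as.numeric(vapply(v, `[[`, "", 3)),
               stringsAsFactors = FALSE)
  }
  rules <- list(
    new_rule(cond(c("PSORIATIC_CD", ">=", 1)), "nonRA", 1),
    new_rule(cond(c("ALTERNATIVE_RA", ">=", 1), c("RARTH_COD", "<", 1),
                  c("INTENSITY_RA", ">=", 3)), "nonRA", 1))
  for (evidence in c("RARTH_COD", "INTENSITY_RA")) {
    gate <- if (evidence == "RARTH_COD") c("RARTH_COD", ">=", 1)
            else c("INTENSITY_RA", "<", 3)
    for (drug in DMARD_FEATURES) {
      rules[[length(rules) + 1L]] <-
        new_rule(cond(gate, c(drug, ">=", 1)), "RA", 1)
    }
  }
  ruleset(rules, default = "nonRA")
}

#' Classify one patient with the RA rule engine
#'
#' Builds the eight-predictor feature vector from the patient's code
#' counts and applies the ruleset (first match wins).
#'
#' @param code_counts named integer vector of code occurrence counts (as
#'   from [record_counts()]).
#' @param predictors an [ra_predictors()] object.
#' @param rs a [ruleset()]; the published-logic default if omitted.
#' @return `"RA"` or `"nonRA"`.
#' @export
classify_ra <- function(code_counts, predictors = default_ra_predictors(),
                        rs = ra_default_ruleset()) {
  rule_classify(rs, ra_feature_vector(code_counts, predictors))
}

#' Classify a whole cohort and summarise the flagged fraction
#'
#' Applies the rule engine to every patient (labelled or not) and reports
#' the number and fraction flagged as RA. The per-patient output is
#' independent of cohort order.
#'
#' @param records a `patient_records` object.
#' @param predictors an [ra_predictors()] object.
#' @param rs a [ruleset()].
#' @return list with `labels` (data.frame `patient_id`, `phenotype`) and
#'   `summary` (list `n`, `flagged`, `fraction`; `fraction` is `NA` for an
#'   empty cohort).
#' @export
cohort_classify <- function(records, predictors = default_ra_predictors(),
                            rs = ra_default_ruleset()) {
  ids <- records$patients$patient_id
  if (length(ids) == 0L)
    return(list(labels = data.frame(patient_id = character(0),
                                    phenotype = character(0)),
                summary = list(n = 0L, flagged = 0L, fraction = NA_real_)))
  # assemble the 8-feature matrix for the whole cohort in one pass
  counts <- records$counts
  feat <- matrix(0, nrow = length(ids), ncol = length(RA_FEATURES),
                 dimnames = list(ids, RA_FEATURES))
  for (gname in RA_GROUP_NAMES) {
    g <- predictors$groups[[gname]]
    sel <- counts$code %in% g$codes
    if (any(sel)) {
      agg <- tapply(counts$count[sel], counts$patient_id[sel], sum)
      feat[names(agg), gname] <- as.numeric(agg)
    }
  }
  feat[, "INTENSITY_RA"] <- 9
  for (lvl in rev(as.character(1:4))) {
    sel <- counts$code %in% predictors$intensity_map[[lvl]]
    if (any(sel))
      feat[unique(counts$patient_id[sel]), "INTENSITY_RA"] <- as.numeric(lvl)
  }
  phen <- rule_classify_matrix(rs, feat)
  flagged <- sum(phen == "RA")
  list(labels = data.frame(patient_id = ids, phenotype = phen,
                           stringsAsFactors = FALSE),
       summary = list(n = length(ids), flagged = flagged,
                      fraction = flagged / length(ids)))
}
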