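#' @keywords internal
"_PACKAGE"

# Typed condition helper: all user-facing input failures carry class
# "codephen_error" plus a specific subclass, so callers can test for them.
cp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "codephen_error", "error")))
}

VALID_LABELS <- c("RA", "nonRA")

#' Validate clinical code strings
#'
#' Codes are treated as opaque 5-character hierarchical identifiers:
#' non-empty, at most 5 characters, alphanumeric with '.' allowed as
#' hierarchy padding. No external terminology dictionary is consulted.
#'
#' @param codes character vector.
#' @return logical vector, `TRUE` where the code is well formed.
#' @export
is_valid_code <- function(codes) {
  nzchar(codes) & nchar(codes) <= 5L & grepl("^[A-Za-z0-9.]+$", codes)
}

#' Read coded events from a delimited file
#'
#' Expects a comma-delimited UTF-8 file with header
#' `patient_id,code,date,source`, one clinical event per row. Dates must be
#' ISO-8601 (`YYYY-MM-DD`); `source` is `"primary"` or `"secondary"`.
#' Malformed rows abort with a message naming the offending line numbers.
#'
#' @param path path to the event file.
#' @return data.frame with columns `patient_id` (character), `code`
#'   (character), `date` (`Date`), `source` (character).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) cp_stop(sprintf("event file not found: %s", path),
                                  "codephen_io_error")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  required <- c("patient_id", "code", "date", "source")
  if (!all(required %in% names(raw)))
    cp_stop(sprintf("missing header column(s): %s",
                    paste(setdiff(required, names(raw)), collapse = ", ")),
            "codephen_format_error")
  if (nrow(raw) == 0L)
    cp_stop("event file has a header but no data rows", "codephen_format_error")
  raw <- raw[required]

  # +1 for the header line so reported numbers match the file
  line_no <- seq_len(nrow(raw)) + 1L
  bad_code <- !is_valid_code(raw$code)
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- is.na(date)
  bad_source <- !raw$source %in% c("primary", "secondary")
  bad_id <- !nzchar(raw$patient_id)
  bad <- bad_code | bad_date | bad_source | bad_id
  if (any(bad)) {
    what <- character(0)
    if (any(bad_code)) what <- c(what, sprintf(
      "invalid code on line(s) %s", paste(line_no[bad_code], collapse = ", ")))
    if (any(bad_date)) what <- c(what, sprintf(
      "unparseable ISO date on line(s) %s",
      paste(line_no[bad_date], collapse = ", ")))
    if (any(bad_source)) what <- c(what, sprintf(
      "unknown source on line(s) %s",
      paste(line_no[bad_source], collapse = ", ")))
    if (any(bad_id)) what <- c(what, sprintf(
      "empty patient_id on line(s) %s",
      paste(line_no[bad_id], collapse = ", ")))
    cp_stop(paste(what, collapse = "; "), "codephen_format_error")
  }
  data.frame(patient_id = raw$patient_id, code = raw$code,
             date = date, source = raw$source, stringsAsFactors = FALSE)
}

#' Write coded events to a delimited file
#'
#' Inverse of [read_events()]; the two round-trip losslessly.
#'
#' @param events data.frame as returned by [read_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(patient_id = as.character(events$patient_id),
                    code = as.character(events$code),
                    date = format(as.Date(events$date), "%Y-%m-%d"),
                    source = as.character(events$source))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build per-patient code-count records
#'
#' Collapses an event stream into one record per patient: a bag of clinical
#' codes with occurrence counts, the gold-standard label where one exists,
#' and a linkage flag. Every event is counted; repeat codes on the same date
#' are *not* deduplicated. Patients present in `labels` but absent from the
#' events are retained with zero counts (they mirror the "no primary-care
#' data" stratum of the linkage tables). Patients absent from `labels` are
#' `unlabelled` and `linked = FALSE`.
#'
#' @param events data.frame of coded events (see [read_events()]); may be
#'   empty.
#' @param labels named character vector mapping patient_id to `"RA"` or
#'   `"nonRA"`, or `NULL` for a fully unlabelled cohort.
#' @return object of class `patient_records`: a list with `counts`
#'   (data.frame `patient_id`, `code`, `count`) and `patients` (data.frame
#'   `patient_id`, `label`, `linked`).
#' @export
build_records <- function(events, labels = NULL) {
  if (!is.null(labels)) {
    if (is.null(names(labels)) || any(!nzchar(names(labels))))
      cp_stop("labels must be a named vector (patient_id -> label)",
              "codephen_format_error")
    if (!all(labels %in% VALID_LABELS))
      cp_stop("labels must be 'RA' or 'nonRA'", "codephen_format_error")
  }
  if (is.null(events) || nrow(events) == 0L) {
    counts <- data.frame(patient_id = character(0), code = character(0),
                         count = integer(0))
    ids <- character(0)
  } else {
    agg <- stats::aggregate(
      list(count = rep(1L, nrow(events))),
      by = list(patient_id = as.character(events$patient_id),
                code = as.character(events$code)),
      FUN = sum)
    counts <- agg[order(agg$patient_id, agg$code, method = "radix"), , drop = FALSE]
    rownames(counts) <- NULL
    ids <- unique(as.character(events$patient_id))
  }
  all_ids <- sort(unique(c(ids, names(labels))), method = "radix")
  lab <- rep("unlabelled", length(all_ids))
  names(lab) <- all_ids
  if (!is.null(labels)) lab[names(labels)] <- unname(labels)
  patients <- data.frame(patient_id = all_ids, label = unname(lab),
                         linked = unname(lab) != "unlabelled",
                         stringsAsFactors = FALSE)
  structure(list(counts = counts, patients = patients),
            class = "patient_records")
}

#' @export
print.patient_records <- function(x, ...) {
  n_lab <- sum(x$patients$label != "unlabelled")
  cat(sprintf(
    "<patient_records> %d patients (%d labelled), %d distinct codes, %d events\n",
    nrow(x$patients), n_lab, length(unique(x$counts$code)),
    sum(x$counts$count)))
  invisible(x)
}

#' Extract one patient's code-count vector
#'
#' @param records a `patient_records` object.
#' @param patient_id single patient identifier.
#' @return named integer vector of occurrence counts (codes with zero
#'   occurrences are absent).
#' @export
record_counts <- function(records, patient_id) {
  rows <- records$counts[records$counts$patient_id == patient_id, , drop = FALSE]
  stats::setNames(as.integer(rows$count), rows$code)
}

#' Define a named group of clinical codes
#'
#' A code group aggregates several raw codes (for example, every dose
#' variant of one drug, identified by a shared active ingredient) into a
#' single analysis variable.
#'
#' @param name group name (unique within a configuration).
#' @param codes non-empty character vector of member codes (deduplicated).
#' @param kind one of `"diagnosis"`, `"medication"`, `"exclusion"`, `"other"`.
#' @return object of class `code_group`.
#' @export
code_group <- function(name, codes, kind = "other") {
  kind <- match.arg(kind, c("diagnosis", "medication", "exclusion", "other"))
  codes <- unique(as.character(codes))
  if (length(codes) == 0L || !nzchar(name))
    cp_stop("a code group needs a name and at least one code",
            "codephen_format_error")
  structure(list(name = name, codes = sort(codes, method = "radix"), kind = kind),
            class = "code_group")
}

#' @export
print.code_group <- function(x, ...) {
  cat(sprintf("<code_group> %s (%s): %s\n", x$name, x$kind,
              paste(x$codes, collapse = " ")))
  invisible(x)
}

#' Read / write code-group configuration files
#'
#' The configuration is YAML mapping each group name to `kind` and a list of
#' member `codes`.
#'
#' @param path configuration file path.
#' @return for `read_code_groups`, a named list of [code_group()] objects.
#' @export
read_code_groups <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) cp_stop("empty code-group configuration",
                                 "codephen_format_error")
  if (anyDuplicated(names(cfg)))
    cp_stop("duplicate group names in configuration", "codephen_format_error")
  groups <- lapply(names(cfg), function(nm) {
    code_group(nm, unlist(cfg[[nm]]$codes),
               if (is.null(cfg[[nm]]$kind)) "other" else cfg[[nm]]$kind)
  })
  stats::setNames(groups, names(cfg))
}

#' @rdname read_code_groups
#' @param groups list of [code_group()] objects.
#' @export
write_code_groups <- function(groups, path) {
  cfg <- lapply(groups, function(g) list(kind = g$kind, codes = as.list(g$codes)))
  names(cfg) <- vapply(groups, `[[`, "", "name")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a patients-by-features count matrix
#'
#' Materialises the variables entering screening, ranking, and rule
#' induction: one row per *labelled* patient, one column per raw code (or,
#' when `groups` is supplied, per code group, with the group value being the
#' sum of its member-code counts). Absence of a code is a count of 0; the
#' matrix has no missing cells. Feature values are occurrence counts, not
#' presence flags (screening derives presence as count >= 1 downstream).
#'
#' @param records a `patient_records` object (see [build_records()]).
#' @param groups optional list of [code_group()] objects; when given, codes
#'   not belonging to any group are dropped.
#' @return object of class `feature_matrix`: list with `values` (integer
#'   matrix), `patient_ids`, `feature_names`, and `labels` (factor with
#'   levels `RA`, `nonRA`).
#' @export
build_feature_matrix <- function(records, groups = NULL) {
  pts <- records$patients[records$patients$label != "unlabelled", , drop = FALSE]
  if (nrow(pts) == 0L)
    cp_stop("no labelled patients: cannot build a feature matrix",
            "codephen_input_error")
  counts <- records$counts[records$counts$patient_id %in% pts$patient_id, ,
                           drop = FALSE]
  if (is.null(groups)) {
    feats <- sort(unique(counts$code), method = "radix")
    fcol <- match(counts$code, feats)
    fcount <- counts$count
    frow <- match(counts$patient_id, pts$patient_id)
  } else {
    if (any(vapply(groups, function(g) length(g$codes) == 0L, NA)))
      cp_stop("empty code group", "codephen_format_error")
    feats <- sort(vapply(groups, `[[`, "", "name"), method = "radix")
    if (anyDuplicated(feats))
      cp_stop("duplicate group names", "codephen_format_error")
    code2grp <- do.call(rbind, lapply(groups, function(g)
      data.frame(code = g$codes, grp = g$name)))
    m <- match(counts$code, code2grp$code)
    keep <- !is.na(m)
    fcol <- match(code2grp$grp[m[keep]], feats)
    fcount <- counts$count[keep]
    frow <- match(counts$patient_id[keep], pts$patient_id)
  }
  values <- matrix(0L, nrow = nrow(pts), ncol = length(feats),
                   dimnames = list(pts$patient_id, feats))
  if (length(frow))
    for (i in seq_along(frow))
      values[frow[i], fcol[i]] <- values[frow[i], fcol[i]] + as.integer(fcount[i])
  feature_matrix(values, factor(pts$label, levels = VALID_LABELS))
}

#' Construct a feature matrix directly
#'
#' @param values integer matrix (patients x features) with dimnames.
#' @param labels factor (or character) of per-patient labels, levels
#'   `RA`/`nonRA`.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels) {
  labels <- factor(as.character(labels), levels = VALID_LABELS)
  if (nrow(values) != length(labels))
    cp_stop("row count must equal number of labels", "codephen_format_error")
  if (anyNA(labels))
    cp_stop("labels must be 'RA' or 'nonRA'", "codephen_format_error")
  if (any(values < 0)) cp_stop("counts must be non-negative",
                               "codephen_format_error")
  structure(list(values = values,
                 patient_ids = rownames(values),
                 feature_names = colnames(values),
                 labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d RA, %d nonRA)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == "RA"),
              sum(x$labels == "nonRA")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Read / write a feature matrix as delimited text
#'
#' Layout: first column `patient_id`, last column `label`, one feature per
#' intermediate column.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- data.frame(patient_id = fm$patient_ids,
                    fm$values, check.names = FALSE)
  out$label <- as.character(fm$labels)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (!identical(names(df)[1], "patient_id") ||
      !identical(names(df)[ncol(df)], "label"))
    cp_stop("feature-matrix file must start with patient_id and end with label",
            "codephen_format_error")
  vals <- as.matrix(df[, setdiff(names(df), c("patient_id", "label")),
                       drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- as.character(df$patient_id)
  feature_matrix(vals, df$label)
}
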