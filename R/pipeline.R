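# End-to-end orchestration: simulate (or load) -> screen -> aggregate ->
# rank -> induce -> classify -> validate, with every intermediate artifact
# serialised and a manifest recording seeds and the code funnel.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to generate data, or `NULL` to read from
#'   `events_path` / `labels_path`.
#' @param events_path,labels_path input files used when `sim` is `NULL`
#'   (labels file: CSV `patient_id,label`).
#' @param out_dir directory for artifacts (created if needed).
#' @param denominator screening convention, see [screen()].
#' @param prefix_depth see [expand_seeds()].
#' @param ingredient_map_path optional code-to-ingredient file.
#' @param forest a [forest_config()].
#' @param top_k predictors passed from ranking to rule induction
#'   (default 40; capped at the number of groups).
#' @param min_leaf,cf tree-induction controls, see [induce_tree()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), events_path = NULL,
                            labels_path = NULL, out_dir = tempfile("codephen"),
                            denominator = "population", prefix_depth = NULL,
                            ingredient_map_path = NULL,
                            forest = forest_config(n_trees = 100L),
                            top_k = 40L, min_leaf = 5L, cf = 0.25) {
  if (is.null(sim) && (is.null(events_path) || is.null(labels_path)))
    cp_stop("need either a sim config or events/labels paths",
            "codephen_config_error")
  structure(list(sim = sim, events_path = events_path,
                 labels_path = labels_path, out_dir = out_dir,
                 denominator = denominator, prefix_depth = prefix_depth,
                 ingredient_map_path = ingredient_map_path, forest = forest,
                 top_k = as.integer(top_k), min_leaf = as.integer(min_leaf),
                 cf = cf),
            class = "pipeline_config")
}

#' Run the phenotyping pipeline end-to-end
#'
#' Executes the three derivation phases in order -- relative-frequency
#' screening, seed aggregation plus forest ranking, and rule induction --
#' then validates the induced ruleset against the gold-standard labels
#' with a best/worst-case linkage table. Each stage writes its artifact to
#' `out_dir` and consumes only serialised inputs of the previous stage, so
#' runs are resumable and deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly also written to
#'   `out_dir/manifest.yaml`): versions, seeds, stage counts
#'   (`n_codes_total`, `n_selected`, `n_groups`, `n_top`,
#'   `n_rule_features`) and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) cp_stop(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      "codephen_pipeline_error"))
  }

  # stage 0: data
  dat <- run_stage("data", {
    if (!is.null(config$sim)) {
      d <- simulate_ehr(config$sim)
      write_events(d$events, art("events.csv"))
      utils::write.csv(data.frame(patient_id = names(d$labels),
                                  label = unname(d$labels)),
                       art("labels.csv"), row.names = FALSE, quote = FALSE)
      d
    } else {
      lab_df <- utils::read.csv(config$labels_path, colClasses = "character")
      list(events = read_events(config$events_path),
           labels = stats::setNames(lab_df$label, lab_df$patient_id),
           truth = NULL)
    }
  })
  records <- build_records(dat$events, dat$labels)
  fm_raw <- build_feature_matrix(records)

  # phase 1: screening
  screened <- run_stage("screening", screen(fm_raw, config$denominator))
  write_screening(screened, art("screened.csv"))
  selected <- screened$code[screened$selected]

  # phase 2a: aggregation
  groups <- run_stage("aggregation", {
    ingredients <- if (!is.null(config$ingredient_map_path))
      read_ingredient_map(config$ingredient_map_path) else NULL
    merge_groups(expand_seeds(selected, unique(records$counts$code),
                              config$prefix_depth, ingredients))
  })
  write_code_groups(groups, art("groups.yaml"))
  fm_grouped <- build_feature_matrix(records, groups)

  # phase 2b: forest ranking
  forest <- run_stage("ranking", fit_forest(fm_grouped, config$forest))
  utils::write.csv(forest$importance, art("importance.csv"),
                   row.names = FALSE, quote = FALSE)
  k <- min(config$top_k, length(groups))
  top <- select_top(forest, k)

  # phase 3: rule induction on the top-ranked groups
  fm_top <- feature_matrix(fm_grouped$values[, top, drop = FALSE],
                           fm_grouped$labels)
  tree <- run_stage("induction",
                    induce_tree(fm_top, config$min_leaf, config$cf))
  rs <- extract_rules(tree)
  write_ruleset(rs, art("ruleset.txt"))
  rule_feats <- unique(unlist(lapply(rs$rules,
                                     function(r) r$conditions$feature)))

  # validation: classify the whole cohort (linked and unlinked) and
  # cross-tabulate against the gold standard
  report <- run_stage("validation", {
    all_ids <- records$patients$patient_id
    full <- build_feature_matrix(
      build_records(dat$events,
                    stats::setNames(rep("nonRA", length(all_ids)), all_ids)),
      groups)
    pred <- rule_classify_matrix(rs, full$values[, top, drop = FALSE])
    phen <- data.frame(patient_id = full$patient_ids, phenotype = pred,
                       stringsAsFactors = FALSE)
    tab <- tabulate_linkage(phen, dat$labels,
                            population_size = length(all_ids))
    write_linkage_table(tab, art("linkage_table.csv"))
    scenario_analysis(tab)
  })
  utils::write.csv(report, art("validation_report.csv"), row.names = FALSE,
                   quote = FALSE)

  manifest <- list(
    package = "codephen",
    version = as.character(utils::packageVersion("codephen")),
    seeds = list(simulation = if (!is.null(config$sim)) config$sim$seed,
                 forest = config$forest$seed),
    counts = list(n_patients = nrow(records$patients),
                  n_labelled = sum(records$patients$label != "unlabelled"),
                  n_codes_total = ncol(fm_raw$values),
                  n_selected = length(selected),
                  n_groups = length(groups),
                  n_top = k,
                  n_rule_features = length(rule_feats)),
    oob_accuracy = forest$oob_accuracy,
    artifacts = list(events = "events.csv", labels = "labels.csv",
                     screened = "screened.csv", groups = "groups.yaml",
                     importance = "importance.csv", ruleset = "ruleset.txt",
                     linkage_table = "linkage_table.csv",
                     validation_report = "validation_report.csv"))
  yaml::write_yaml(manifest, art("manifest.yaml"))
  invisible(manifest)
}
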