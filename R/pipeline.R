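# End-to-end pipeline: design -> (synthetic) results -> comparisons ->
# aggregates -> ratings, with provenance.

#' Parameter-of-interest label of a plan
#'
#' A parameter of interest is one perturbation axis, per ligament for the
#' per-structure axes (e.g. `prestretch:MCL`); its runs share an analysis
#' time and are aggregated together.
#'
#' @param axis,structure Columns of the design table.
#' @return Character vector of labels.
#' @export
parameter_label <- function(axis, structure) {
  ifelse(is.na(structure), axis, paste(axis, structure, sep = ":"))
}

#' Compare every run of a study against its baselines
#'
#' Groups the study's runs by parameter of interest and direction, marks
#' exclusions, selects each group's analysis time, and computes the four
#' comparison metrics of every run (see [analyze_parameter()]).
#'
#' @param study A [simulate_study()] result, or any list with elements
#'   `plans`, `results` (named `<plan_id>::<direction>`), `baselines`
#'   (list `varus`/`valgus`) and `model`.
#' @param threshold Convergence threshold (default
#'   [ANALYSIS_TIME_THRESHOLD]).
#' @return Comparison data.frame with `model_id`, `parameter`, `category`
#'   prepended to the [compare_run()] columns.
#' @export
compare_study <- function(study, threshold = ANALYSIS_TIME_THRESHOLD) {
  plans <- study$plans
  plans$parameter <- parameter_label(plans$axis, plans$structure)
  out <- list()
  for (param in unique(plans$parameter)) {
    ids <- plans$plan_id[plans$parameter == param]
    category <- plans$category[plans$parameter == param][1]
    for (dir in c("varus", "valgus")) {
      baseline <- study$baselines[[dir]]
      if (is.null(baseline)) {
        stop(sprintf("missing baseline bundle for model %s, direction %s",
                     plans$model_id[1], dir), call. = FALSE)
      }
      keys <- paste(ids, dir, sep = "::")
      missing <- keys[!keys %in% names(study$results)]
      if (length(missing)) {
        stop(sprintf("missing result bundle(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      comp <- analyze_parameter(study$results[keys], baseline, threshold)
      comp <- cbind(
        data.frame(model_id = plans$model_id[1], parameter = param,
                   category = category, stringsAsFactors = FALSE),
        comp)
      out[[paste(param, dir, sep = "::")]] <- comp
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a study's comparisons per parameter and direction
#'
#' @param comparisons Output of [compare_study()].
#' @return Data.frame with one row per (model, parameter, direction) and
#'   the four mean metrics (see [aggregate_parameter()]).
#' @export
aggregate_study <- function(comparisons) {
  groups <- split(comparisons,
                  list(comparisons$model_id, comparisons$parameter),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    agg <- aggregate_parameter(g)
    cbind(data.frame(model_id = g$model_id[1], parameter = g$parameter[1],
                     category = g$category[1], stringsAsFactors = FALSE),
          agg)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$model_id, out$parameter, out$direction), ]
  rownames(out) <- NULL
  out
}

#' Run the full sensitivity pipeline on a synthetic study
#'
#' Enumerates the design, simulates the study, computes comparisons,
#' aggregates, and ratings; optionally writes all tables plus a provenance
#' record. Every source of randomness sits behind `seed`, and reruns with
#' the same configuration produce identical tables.
#'
#' @param model A [synthetic_model_config()].
#' @param baselines Calibrated baselines for [enumerate_design()].
#' @param effects An [effect_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory for `design.csv`,
#'   `comparisons.csv`, `aggregates.csv`, `ratings.csv` and
#'   `provenance.json`.
#' @param scale Rating scale (default [default_rating_scale()]).
#' @param dt Synthetic time-grid step.
#' @param write_bundles Also write every simulation bundle under
#'   `out_dir/bundles` (slower; off by default).
#' @return List with `plans`, `study`, `comparisons`, `aggregates`,
#'   `ratings`, `provenance`.
#' @export
run_pipeline <- function(model, baselines, effects = effect_config(),
                         seed = 1L, out_dir = NULL,
                         scale = default_rating_scale(), dt = 0.05,
                         write_bundles = FALSE) {
  stage <- "design"
  result <- tryCatch({
    plans <- enumerate_design(model$model_id, baselines)
    stage <- "synth"
    study <- simulate_study(plans, model, effects, seed = seed, dt = dt)
    stage <- "analyze"
    comparisons <- compare_study(study)
    stage <- "aggregate"
    aggregates <- aggregate_study(comparisons)
    stage <- "rate"
    ratings <- rate_study(aggregates, scale)
    list(plans = plans, study = study, comparisons = comparisons,
         aggregates = aggregates, ratings = ratings)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  config_json <- jsonlite::toJSON(
    list(model = unclass(model), effects = unclass(effects),
         baselines = baselines, seed = as.integer(seed), dt = dt),
    auto_unbox = TRUE, digits = NA)
  result$provenance <- list(
    package = "kneesense",
    package_version = as.character(utils::packageVersion("kneesense")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    config_hash = fnv1a_hash(as.character(config_json)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$plans, file.path(out_dir, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(result$comparisons,
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(result$aggregates,
                     file.path(out_dir, "aggregates.csv"),
                     row.names = FALSE)
    utils::write.csv(result$ratings, file.path(out_dir, "ratings.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE,
                                pretty = TRUE),
               file.path(out_dir, "provenance.json"))
    if (write_bundles) {
      write_study(result$study, file.path(out_dir, "bundles"))
    }
  }
  result
}
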