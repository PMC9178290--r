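# Qualitative 0-3 influence rating of aggregated comparison metrics, and
# varus/valgus combination.

METRIC_KINDS <- c("convergence_pct", "valgus_rmse", "pressure_pct",
                  "location_mm")

# maps aggregate column names to metric kinds
METRIC_COLUMNS <- c(convergence_pct_diff = "convergence_pct",
                    valgus_rmse = "valgus_rmse",
                    pressure_pct_diff = "pressure_pct",
                    location_distance = "location_mm")

.rating_cache <- new.env(parent = emptyenv())

#' Load an influence rating scale
#'
#' Reads a rating-scale definition from a YAML file. The shipped default
#' (in `inst/extdata/rating_scale.yaml`) defines, per metric kind, the
#' inclusive upper bounds of the score bins 0.5 (Negligible) through 2.5
#' (Medium-Large); values above the last bound score 3 (Large) and an
#' exact zero scores 0 (None). Users may supply their own file with the
#' same structure to re-bin a study.
#'
#' @param path YAML file; `NULL` for the shipped default.
#' @return An object of class `rating_scale`.
#' @export
load_rating_scale <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rating_scale.yaml",
                                package = "kneesense", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$uppers), !is.null(cfg$scores))
  scores <- as.numeric(cfg$scores)
  uppers <- lapply(cfg$uppers, as.numeric)
  missing <- setdiff(METRIC_KINDS, names(uppers))
  if (length(missing)) {
    stop(sprintf("rating scale file lacks metric kind(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (k in METRIC_KINDS) {
    if (length(uppers[[k]]) != length(scores) ||
        any(diff(uppers[[k]]) <= 0) || any(uppers[[k]] <= 0)) {
      stop(sprintf("rating scale: bounds for '%s' must be %d strictly increasing positive values",
                   k, length(scores)), call. = FALSE)
    }
  }
  structure(
    list(scores = c(scores, as.numeric(cfg$top_score %||% 3)),
         uppers = uppers,
         zero_tolerance = as.numeric(cfg$zero_tolerance %||% 1e-12),
         version = cfg$version %||% 1),
    class = "rating_scale")
}

#' Default rating scale (cached)
#'
#' @return The shipped [load_rating_scale()] result.
#' @export
default_rating_scale <- function() {
  if (is.null(.rating_cache$scale)) {
    .rating_cache$scale <- load_rating_scale()
  }
  .rating_cache$scale
}

#' Score an aggregated metric on the 0-3 influence scale
#'
#' An exact zero (to within the scale's zero tolerance, which absorbs
#' floating-point noise) scores 0; otherwise the value falls in exactly
#' one bin, with bounds inclusive on the upper end: a metric exactly on a
#' printed boundary takes the lower score (e.g. a location distance of
#' 1.25 mm scores 1.5, not 2).
#'
#' @param metric_kind One of `"convergence_pct"`, `"valgus_rmse"`,
#'   `"pressure_pct"`, `"location_mm"`.
#' @param value Non-negative finite metric value(s); `NA` passes through.
#' @param scale A [load_rating_scale()] object.
#' @return Score(s) in `{0, 0.5, 1, 1.5, 2, 2.5, 3}` (or `NA`).
#' @examples
#' score_metric("valgus_rmse", 0.3)   # 1
#' score_metric("pressure_pct", 2454) # 3
#' @export
score_metric <- function(metric_kind, value, scale = default_rating_scale()) {
  metric_kind <- match.arg(metric_kind, METRIC_KINDS)
  uppers <- c(scale$uppers[[metric_kind]], Inf)
  one <- function(v) {
    if (is.na(v)) return(NA_real_)
    if (!is.finite(v) || v < 0) {
      stop(sprintf("metric value must be finite and non-negative, got %s",
                   format(v)), call. = FALSE)
    }
    if (abs(v) < scale$zero_tolerance) return(0)
    scale$scores[which(v <= uppers)[1]]
  }
  vapply(value, one, numeric(1))
}

#' Combine varus and valgus direction scores
#'
#' The varus and valgus aggregates are scored separately, then averaged,
#' which is why quarter-point combined scores (0.25, 0.75, ...) occur.
#' If only one direction could be rated (e.g. the other never converged),
#' the single-direction score is reported and flagged as partial rather
#' than imputing the missing direction.
#'
#' @param varus_score,valgus_score Scores from [score_metric()] (or `NA`).
#' @return List with `score` (combined, `NA` if both inputs are `NA`) and
#'   `partial` (logical).
#' @examples
#' combine_directions(0.5, 1)$score  # 0.75
#' @export
combine_directions <- function(varus_score, valgus_score) {
  if (is.na(varus_score) && is.na(valgus_score)) {
    return(list(score = NA_real_, partial = NA))
  }
  if (is.na(varus_score) || is.na(valgus_score)) {
    return(list(score = if (is.na(varus_score)) valgus_score else varus_score,
                partial = TRUE))
  }
  list(score = (varus_score + valgus_score) / 2, partial = FALSE)
}

#' Rate a study's aggregated metrics
#'
#' Maps per-parameter, per-direction aggregated metrics (from
#' [aggregate_study()]) onto the 0-3 influence scale: each direction is
#' scored separately for each of the four metric kinds, then the two
#' direction scores are averaged. Models are rated separately.
#'
#' @param aggregates Data.frame with columns `model_id`, `parameter`,
#'   `direction` and the four metric columns of [aggregate_parameter()].
#' @param scale A [load_rating_scale()] object.
#' @return Long-format data.frame: `model_id`, `parameter`, `category`,
#'   `metric_kind`, `varus_score`, `valgus_score`, `combined_score`,
#'   `partial`.
#' @export
rate_study <- function(aggregates, scale = default_rating_scale()) {
  stopifnot(all(c("model_id", "parameter", "direction") %in%
                  names(aggregates)))
  keys <- unique(aggregates[, c("model_id", "parameter",
                                intersect("category", names(aggregates))),
                            drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- aggregates[aggregates$model_id == keys$model_id[i] &
                        aggregates$parameter == keys$parameter[i], ,
                      drop = FALSE]
    per_kind <- lapply(names(METRIC_COLUMNS), function(col) {
      kind <- METRIC_COLUMNS[[col]]
      dir_score <- function(dir) {
        v <- sub[[col]][sub$direction == dir]
        if (!length(v)) NA_real_ else score_metric(kind, v, scale)
      }
      vs <- dir_score("varus")
      gs <- dir_score("valgus")
      comb <- combine_directions(vs, gs)
      data.frame(
        model_id = keys$model_id[i], parameter = keys$parameter[i],
        category = if ("category" %in% names(keys)) keys$category[i]
                   else NA_character_,
        metric_kind = kind, varus_score = vs, valgus_score = gs,
        combined_score = comb$score, partial = isTRUE(comb$partial),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, per_kind)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
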