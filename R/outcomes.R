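# Outcome parameter extraction and perturbed-vs-baseline comparison metrics:
# convergence, valgus kinematics RMSE, peak contact pressure and its
# location on the tibial articulating surfaces.

#' Convergence threshold for inclusion in the analysis
#'
#' A run must converge past time step 2.25 (10,000 Nmm applied varus or
#' valgus moment) to enter the kinematics/pressure/location analysis;
#' otherwise it is excluded and contributes to the convergence outcome only.
#' @export
ANALYSIS_TIME_THRESHOLD <- 2.25

#' Peak contact pressure of one contact frame
#'
#' Faces with a contact pressure strictly greater than 0 are selected and
#' ordered by pressure; the peak contact pressure is the unweighted mean
#' pressure over the top 10% of these faces (count `ceiling(0.1 * n)`, so
#' at least one face whenever any face is in contact), and its location is
#' the unweighted mean centroid of the same faces. Averaging over a face
#' set rather than taking the single maximum avoids spuriously high
#' stresses from single deformed elements. Ties at the top-set cutoff are
#' resolved by ascending face id, truncated to the ceiling count, so the
#' result is deterministic and permutation-invariant.
#'
#' @param frame Data.frame with columns `face_id`, `cx`, `cy`, `cz`,
#'   `pressure` (one compartment at one time step), e.g. from
#'   [contact_frame()].
#' @param side Optional side label carried through to the summary.
#' @return An object of class `peak_pressure_summary`: fields `side`,
#'   `peak_pressure` (N/mm^2, `NA` if no face is in contact), `location`
#'   (xyz mm, `NA` if no contact), `n_contact_faces`, `n_top_faces`.
#' @examples
#' f <- data.frame(face_id = 1:10, cx = 0, cy = 0, cz = 0, pressure = 1:10)
#' peak_contact_pressure(f)$peak_pressure  # 10
#' @export
peak_contact_pressure <- function(frame, side = NA_character_) {
  stopifnot(all(c("face_id", "cx", "cy", "cz", "pressure") %in% names(frame)))
  if (any(frame$pressure < 0)) {
    stop("negative contact pressure in frame", call. = FALSE)
  }
  contact <- frame[frame$pressure > 0, , drop = FALSE]
  n <- nrow(contact)
  if (n == 0) {
    return(structure(
      list(side = side, peak_pressure = NA_real_,
           location = c(NA_real_, NA_real_, NA_real_),
           n_contact_faces = 0L, n_top_faces = 0L),
      class = "peak_pressure_summary"))
  }
  n_top <- as.integer(ceiling(0.1 * n))
  ord <- order(-contact$pressure, contact$face_id)
  top <- contact[ord[seq_len(n_top)], , drop = FALSE]
  structure(
    list(side = side,
         peak_pressure = mean(top$pressure),
         location = c(mean(top$cx), mean(top$cy), mean(top$cz)),
         n_contact_faces = n,
         n_top_faces = n_top),
    class = "peak_pressure_summary")
}

#' @export
print.peak_pressure_summary <- function(x, ...) {
  if (x$n_contact_faces == 0) {
    cat("<peak_pressure_summary> no contact\n")
  } else {
    cat(sprintf(
      "<peak_pressure_summary> %s: %.4g N/mm^2 over top %d of %d faces at (%.2f, %.2f, %.2f) mm\n",
      x$side %||% "?", x$peak_pressure, x$n_top_faces, x$n_contact_faces,
      x$location[1], x$location[2], x$location[3]))
  }
  invisible(x)
}

# internal: both-side summaries of a result at one time
side_summaries <- function(result, time) {
  list(medial = peak_contact_pressure(
         contact_frame(result, time, "medial"), side = "medial"),
       lateral = peak_contact_pressure(
         contact_frame(result, time, "lateral"), side = "lateral"))
}

#' Select the common analysis time of a parameter group
#'
#' The pressure and location outcomes of a parameter of interest are
#' evaluated at a single time step to which all its simulations (and the
#' baseline) converged, and which is larger than 2.25 (10,000 Nmm of
#' applied moment). Runs that did not converge past 2.25 are first marked
#' excluded; the analysis time is then the largest time step present in
#' every remaining series and in the baseline. Using the latest common
#' time maximizes the applied moment and hence the discriminative power of
#' the comparison.
#'
#' @param runs List of [simulation_result()] objects of one parameter of
#'   interest (one direction).
#' @param baseline The baseline `simulation_result` of the same direction.
#' @param threshold Convergence threshold (default
#'   [ANALYSIS_TIME_THRESHOLD]).
#' @return List with `analysis_time` (`NA` if every run is excluded),
#'   logical vector `excluded`, and character vector `reason`.
#' @export
select_analysis_time <- function(runs, baseline,
                                 threshold = ANALYSIS_TIME_THRESHOLD) {
  stopifnot(length(runs) >= 1)
  blct <- baseline$convergence$last_converged_time
  if (blct <= threshold) {
    stop(sprintf(
      "baseline simulation converged only to %g (threshold %g); group cannot be analyzed",
      blct, threshold), call. = FALSE)
  }
  lct <- vapply(runs, function(r) r$convergence$last_converged_time,
                numeric(1))
  excluded <- lct <= threshold
  reason <- ifelse(
    excluded,
    sprintf("last converged time %.4g <= %.4g", lct, threshold),
    NA_character_)
  if (all(excluded)) {
    return(list(analysis_time = NA_real_, excluded = excluded,
                reason = reason))
  }
  members <- c(list(baseline), runs[!excluded])
  common <- Reduce(intersect,
                   lapply(members, function(r) round_time(r$kinematics$time)))
  common <- common[common > threshold]
  if (!length(common)) {
    stop("no common converged time step above the threshold in this group",
         call. = FALSE)
  }
  list(analysis_time = max(common), excluded = excluded, reason = reason)
}

#' Convergence percentage difference
#'
#' Percentage difference between the last converged time step of the
#' simulation of interest and that of the original simulation,
#' `100 * |t_interest - t_original| / t_original`. Reported as a magnitude;
#' set `signed = TRUE` for the signed diagnostic value.
#'
#' @param t_interest,t_original Last converged time steps.
#' @param signed Return the signed value instead of the magnitude.
#' @return Percentage.
#' @examples
#' convergence_pct_diff(2.25, 3)  # 25
#' @export
convergence_pct_diff <- function(t_interest, t_original, signed = FALSE) {
  if (any(t_original <= 0)) {
    stop("original last converged time must be positive", call. = FALSE)
  }
  d <- 100 * (t_interest - t_original) / t_original
  if (signed) d else abs(d)
}

#' Valgus kinematics RMSE between two runs
#'
#' Root mean square error of the valgus rotation, evaluated on the
#' converged time steps of the simulation of interest restricted to the
#' moment phase (t >= `t_start`) and clipped to the time span covered by
#' the original run (no extrapolation). Because the two runs may converge
#' at different time steps, the original's valgus rotation is linearly
#' interpolated between its converged time steps onto the evaluation grid.
#'
#' @param original,interest Kinematics data.frames (see
#'   [kinematics_series()]).
#' @param t_start Start of the comparison window (default 2.0, the moment
#'   ramp onset; earlier settling phases are shared across group members).
#' @return RMSE in degrees, or `NA` if the evaluation grid is empty (no
#'   overlap; the comparison should then be marked excluded).
#' @export
valgus_rmse <- function(original, interest, t_start = 2.0) {
  validate_kinematics(original, "original kinematics")
  validate_kinematics(interest, "interest kinematics")
  g <- interest$time[interest$time >= t_start - 1e-9]
  g <- g[g >= min(original$time) - 1e-9 & g <= max(original$time) + 1e-9]
  if (!length(g)) return(NA_real_)
  ov <- stats::approx(original$time, original$valgus_deg, xout = g,
                      ties = "ordered")$y
  iv <- interest$valgus_deg[match(round_time(g), round_time(interest$time))]
  sqrt(mean((iv - ov)^2))
}

#' Peak-pressure percentage difference, averaged over compartments
#'
#' Per compartment, `100 * |p_interest - p_original| / p_original`; the
#' medial and lateral values are then averaged. A compartment with no
#' contact in the original run is dropped (it has no reference pressure);
#' if the interest run has no contact on a compartment its peak is taken
#' as 0 (a 100% difference). If both compartments lack original contact
#' the metric is `NA`.
#'
#' @param interest,original Lists with elements `medial` and `lateral`,
#'   each a [peak_contact_pressure()] summary.
#' @return Percentage (scalar) with attribute `per_side`.
#' @export
pressure_pct_diff <- function(interest, original) {
  side_val <- function(sd) {
    o <- original[[sd]]
    i <- interest[[sd]]
    if (is.null(o) || o$n_contact_faces == 0L) return(NA_real_)
    pi_ <- if (i$n_contact_faces == 0L) 0 else i$peak_pressure
    100 * abs(pi_ - o$peak_pressure) / o$peak_pressure
  }
  v <- c(medial = side_val("medial"), lateral = side_val("lateral"))
  out <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(out, per_side = v)
}

#' Peak-pressure location distance, averaged over compartments
#'
#' Per compartment, the Euclidean distance (mm) between the peak-pressure
#' locations of the interest and original runs; the medial and lateral
#' distances are then averaged. Compartments without contact in either run
#' are dropped (no location is defined there).
#'
#' @inheritParams pressure_pct_diff
#' @return Distance in mm (scalar) with attribute `per_side`.
#' @export
location_distance <- function(interest, original) {
  side_val <- function(sd) {
    o <- original[[sd]]
    i <- interest[[sd]]
    if (is.null(o) || o$n_contact_faces == 0L ||
        is.null(i) || i$n_contact_faces == 0L) {
      return(NA_real_)
    }
    sqrt(sum((i$location - o$location)^2))
  }
  v <- c(medial = side_val("medial"), lateral = side_val("lateral"))
  out <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(out, per_side = v)
}

#' Compare one perturbed run against its baseline
#'
#' Computes the four outcome comparison metrics of one simulation of
#' interest: the convergence percentage difference (always available), and
#' - unless the run is excluded - the valgus kinematics RMSE and the
#' peak-pressure percentage difference and location distance at the
#' group's analysis time.
#'
#' @param interest,original [simulation_result()] objects of the same
#'   direction.
#' @param analysis_time Common analysis time from
#'   [select_analysis_time()] (`NA` if unavailable).
#' @param excluded Whether the interest run is excluded (converged at or
#'   before the threshold).
#' @param reason Exclusion reason (for the comparison table).
#' @return One-row data.frame: `plan_id`, `direction`, `analysis_time`,
#'   `convergence_pct_diff`, `valgus_rmse`, `pressure_pct_diff`,
#'   `location_distance`, `excluded`, `reason`.
#' @export
compare_run <- function(interest, original, analysis_time,
                        excluded = FALSE, reason = NA_character_) {
  stopifnot(identical(interest$direction, original$direction))
  conv <- convergence_pct_diff(interest$convergence$last_converged_time,
                               original$convergence$last_converged_time)
  if (isTRUE(excluded) || is.na(analysis_time)) {
    rmse <- pp <- ld <- NA_real_
    if (!isTRUE(excluded)) reason <- "no analysis time available for group"
  } else {
    rmse <- valgus_rmse(original$kinematics, interest$kinematics)
    si <- side_summaries(interest, analysis_time)
    so <- side_summaries(original, analysis_time)
    pp <- as.numeric(pressure_pct_diff(si, so))
    ld <- as.numeric(location_distance(si, so))
  }
  data.frame(
    plan_id = interest$plan_id, direction = interest$direction,
    analysis_time = analysis_time, convergence_pct_diff = conv,
    valgus_rmse = rmse, pressure_pct_diff = pp, location_distance = ld,
    excluded = isTRUE(excluded), reason = reason,
    stringsAsFactors = FALSE)
}

#' Analyze all runs of one parameter of interest (one direction)
#'
#' Marks exclusions, selects the common analysis time, and compares every
#' run against the baseline.
#'
#' @param runs List of [simulation_result()] objects.
#' @param baseline Baseline `simulation_result` of the same direction.
#' @param threshold Convergence threshold.
#' @return Comparison data.frame, one row per run (see [compare_run()]).
#' @export
analyze_parameter <- function(runs, baseline,
                              threshold = ANALYSIS_TIME_THRESHOLD) {
  sel <- select_analysis_time(runs, baseline, threshold)
  rows <- lapply(seq_along(runs), function(i) {
    compare_run(runs[[i]], baseline, sel$analysis_time,
                excluded = sel$excluded[i], reason = sel$reason[i])
  })
  do.call(rbind, rows)
}

#' Aggregate comparison metrics of one parameter of interest
#'
#' Arithmetic mean of each metric over the runs of one parameter, varus
#' and valgus kept separate. Excluded runs (no convergence past the
#' threshold) still contribute to the convergence metric but never to the
#' kinematics, pressure or location aggregates. If every run of a
#' direction is excluded those aggregates are `NA` (the parameter is then
#' rated on convergence only).
#'
#' @param comparisons Comparison data.frame from [analyze_parameter()]
#'   (may contain both directions).
#' @return Data.frame with one row per direction: `direction`, `n`,
#'   `n_excluded`, `convergence_pct_diff`, `valgus_rmse`,
#'   `pressure_pct_diff`, `location_distance`.
#' @export
aggregate_parameter <- function(comparisons) {
  stopifnot(nrow(comparisons) >= 1)
  out <- lapply(split(comparisons, comparisons$direction), function(d) {
    ok <- !d$excluded
    mean_ok <- function(x) {
      x <- x[ok & !is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }
    data.frame(
      direction = d$direction[1], n = nrow(d), n_excluded = sum(!ok),
      convergence_pct_diff = mean(d$convergence_pct_diff),
      valgus_rmse = mean_ok(d$valgus_rmse),
      pressure_pct_diff = mean_ok(d$pressure_pct_diff),
      location_distance = mean_ok(d$location_distance),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
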