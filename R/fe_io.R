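# Interchange data model and file formats for simulation result bundles.
#
# A bundle is a directory with three plain-text members:
#   kinematics.csv   time + six Grood & Suntay joint DOF
#   contact.csv      long-format per-face tibial contact pressure fields
#   convergence.json last converged time step + metadata + schema version
# The FE solver's native binary outputs are out of scope; an importer for
# them is a documented extension point.

FEIO_SCHEMA_VERSION <- "1.0"

KINEMATICS_COLS <- c("time", "flexion_deg", "valgus_deg", "intext_deg",
                     "ap_mm", "ml_mm", "si_mm")
CONTACT_COLS <- c("time", "side", "face_id", "cx", "cy", "cz", "pressure")

#' Construct a kinematics series
#'
#' Six joint-coordinate DOF (Grood & Suntay convention) at each converged
#' time step: flexion, valgus/varus rotation and internal-external rotation
#' in degrees, and anterior-posterior, medial-lateral and
#' superior-inferior translations in mm.
#'
#' @param time Strictly increasing numeric vector of converged time steps.
#' @param valgus_deg Valgus(+)/varus(-) rotation in degrees.
#' @param flexion_deg,intext_deg Remaining rotations in degrees.
#' @param ap_mm,ml_mm,si_mm Translations in mm.
#' @return A data.frame with the seven canonical columns.
#' @export
kinematics_series <- function(time, valgus_deg, flexion_deg = 0,
                              intext_deg = 0, ap_mm = 0, ml_mm = 0,
                              si_mm = 0) {
  kin <- data.frame(time = time, flexion_deg = flexion_deg,
                    valgus_deg = valgus_deg, intext_deg = intext_deg,
                    ap_mm = ap_mm, ml_mm = ml_mm, si_mm = si_mm)
  validate_kinematics(kin)
  kin
}

validate_kinematics <- function(kin, context = "kinematics") {
  missing <- setdiff(KINEMATICS_COLS, names(kin))
  if (length(missing)) {
    stop(sprintf("%s: missing columns %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(kin) == 0) stop(sprintf("%s: empty series", context), call. = FALSE)
  if (anyNA(kin[KINEMATICS_COLS])) {
    bad <- which(rowSums(is.na(kin[KINEMATICS_COLS])) > 0)[1]
    stop(sprintf("%s: missing DOF value at row %d (time %s)", context, bad,
                 kin$time[bad]), call. = FALSE)
  }
  if (any(diff(kin$time) <= 0)) {
    bad <- which(diff(kin$time) <= 0)[1] + 1L
    stop(sprintf("%s: time steps not strictly increasing at row %d (time %g)",
                 context, bad, kin$time[bad]), call. = FALSE)
  }
  invisible(kin)
}

validate_contact <- function(contact, context = "contact") {
  missing <- setdiff(CONTACT_COLS, names(contact))
  if (length(missing)) {
    stop(sprintf("%s: missing columns %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(contact) == 0) return(invisible(contact))
  bad_side <- which(!(contact$side %in% c("medial", "lateral")))
  if (length(bad_side)) {
    stop(sprintf("%s: row %d: unknown side token '%s'", context,
                 bad_side[1], contact$side[bad_side[1]]), call. = FALSE)
  }
  neg <- which(contact$pressure < 0)
  if (length(neg)) {
    stop(sprintf("%s: row %d (face %s): negative pressure %g", context,
                 neg[1], contact$face_id[neg[1]],
                 contact$pressure[neg[1]]), call. = FALSE)
  }
  cent <- as.matrix(contact[, c("cx", "cy", "cz")])
  if (anyNA(cent) || any(!is.finite(cent))) {
    bad <- which(rowSums(!is.finite(cent)) > 0)[1]
    stop(sprintf("%s: row %d (face %s): non-finite centroid", context,
                 bad, contact$face_id[bad]), call. = FALSE)
  }
  key <- paste(round_time(contact$time), contact$side, contact$face_id)
  if (anyDuplicated(key)) {
    dup <- key[anyDuplicated(key)]
    stop(sprintf("%s: duplicate face id within a frame (%s)", context, dup),
         call. = FALSE)
  }
  invisible(contact)
}

#' Construct and validate a simulation result
#'
#' One varus or valgus run of one perturbation plan (or the baseline):
#' its kinematics series, its per-time-step contact fields on the tibial
#' articulating surfaces, and its convergence record.
#'
#' @param plan_id Plan identifier, or `"original"` for the baseline run.
#' @param model_id Model identifier.
#' @param direction `"varus"` or `"valgus"`.
#' @param kinematics Data.frame from [kinematics_series()].
#' @param contact Data.frame with columns `time`, `side`, `face_id`, `cx`,
#'   `cy`, `cz`, `pressure` (pressure in N/mm^2, coordinates in mm).
#' @param last_converged_time Last converged time step in `[0, 3]`.
#' @param terminated_early Logical; defaults to `last_converged_time < 3`.
#' @return An object of class `simulation_result`.
#' @export
simulation_result <- function(plan_id, model_id, direction, kinematics,
                              contact, last_converged_time,
                              terminated_early = last_converged_time < 3 - 1e-9) {
  direction <- match.arg(direction, c("varus", "valgus"))
  res <- structure(
    list(plan_id = plan_id, model_id = model_id, direction = direction,
         kinematics = kinematics, contact = contact,
         convergence = list(last_converged_time = last_converged_time,
                            terminated_early = isTRUE(terminated_early))),
    class = "simulation_result"
  )
  validate_simulation_result(res)
}

#' @rdname simulation_result
#' @param res A `simulation_result` to validate.
#' @export
validate_simulation_result <- function(res) {
  stopifnot(inherits(res, "simulation_result"))
  lct <- res$convergence$last_converged_time
  if (!is.numeric(lct) || length(lct) != 1L || lct < 0 || lct > 3) {
    stop("last_converged_time must lie in [0, 3]", call. = FALSE)
  }
  validate_kinematics(res$kinematics)
  validate_contact(res$contact)
  if (max(res$kinematics$time) > lct + 1e-9) {
    stop(sprintf(
      "kinematics time %g exceeds last converged time %g",
      max(res$kinematics$time), lct), call. = FALSE)
  }
  if (nrow(res$contact) > 0) {
    ct <- unique(round_time(res$contact$time))
    kt <- round_time(res$kinematics$time)
    orphan <- setdiff(ct, kt)
    if (length(orphan)) {
      stop(sprintf(
        "contact frame at time %g has no converged kinematics step",
        orphan[1]), call. = FALSE)
    }
  }
  invisible(res)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> plan %s, model %s, %s\n  %d kinematics steps (t in [%g, %g]), %d contact rows, last converged t = %g%s\n",
    x$plan_id, x$model_id, x$direction, nrow(x$kinematics),
    min(x$kinematics$time), max(x$kinematics$time), nrow(x$contact),
    x$convergence$last_converged_time,
    if (x$convergence$terminated_early) " (terminated early)" else ""))
  invisible(x)
}

# internal: byte-stable CSV writer (fixed column order, %.10g floats)
write_stable_csv <- function(df, num_cols, path) {
  cols <- names(df)
  body <- df
  for (cl in intersect(cols, num_cols)) body[[cl]] <- fmt_num(df[[cl]])
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(unname(as.list(body)), sep = ",")))
  if (nrow(df) == 0) lines <- lines[1]
  writeLines(lines, path)
}

#' Write a simulation result bundle
#'
#' Serializes a [simulation_result()] to a directory containing
#' `kinematics.csv`, `contact.csv` and `convergence.json`. Output is
#' deterministic: fixed column order and float formatting, so two writes of
#' the same result are byte-identical and read-back agrees to better than
#' 1e-9 relative error.
#'
#' @param result A `simulation_result`.
#' @param path Bundle directory (created if needed).
#' @return Invisibly, the paths of the three files written.
#' @export
write_result_bundle <- function(result, path) {
  validate_simulation_result(result)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  kin_path <- file.path(path, "kinematics.csv")
  con_path <- file.path(path, "contact.csv")
  cvg_path <- file.path(path, "convergence.json")
  write_stable_csv(result$kinematics[KINEMATICS_COLS],
                   KINEMATICS_COLS, kin_path)
  contact <- result$contact[CONTACT_COLS]
  contact <- contact[order(contact$time, contact$side, contact$face_id), ,
                     drop = FALSE]
  write_stable_csv(contact, setdiff(CONTACT_COLS, c("side")), con_path)
  meta <- list(schema_version = FEIO_SCHEMA_VERSION,
               plan_id = result$plan_id, model_id = result$model_id,
               direction = result$direction,
               last_converged_time = result$convergence$last_converged_time,
               terminated_early = result$convergence$terminated_early)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), cvg_path)
  invisible(c(kin_path, con_path, cvg_path))
}

#' Read a simulation result bundle
#'
#' Reads and validates a bundle written by [write_result_bundle()] (or an
#' external tool following the same schema). Invariant violations are
#' rejected with row-level diagnostics naming the offending file, row and
#' face. Bundles with an unknown major schema version are rejected.
#'
#' @param path Bundle directory.
#' @return A validated [simulation_result()].
#' @export
read_result_bundle <- function(path) {
  files <- file.path(path, c("kinematics.csv", "contact.csv",
                             "convergence.json"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop(sprintf("missing bundle file: %s", missing[1]), call. = FALSE)
  }
  meta <- jsonlite::fromJSON(files[3])
  ver <- as.character(meta$schema_version %||% "")
  major <- strsplit(ver, ".", fixed = TRUE)[[1]][1]
  if (!identical(major, strsplit(FEIO_SCHEMA_VERSION, ".",
                                 fixed = TRUE)[[1]][1])) {
    stop(sprintf("%s: unsupported schema version '%s'", files[3], ver),
         call. = FALSE)
  }
  kin <- utils::read.csv(files[1], colClasses = "numeric")
  contact <- utils::read.csv(
    files[2],
    colClasses = c(time = "numeric", side = "character",
                   face_id = "integer", cx = "numeric", cy = "numeric",
                   cz = "numeric", pressure = "numeric"))
  validate_kinematics(kin, context = files[1])
  validate_contact(contact, context = files[2])
  res <- structure(
    list(plan_id = meta$plan_id, model_id = meta$model_id,
         direction = meta$direction, kinematics = kin, contact = contact,
         convergence = list(
           last_converged_time = meta$last_converged_time,
           terminated_early = isTRUE(meta$terminated_early))),
    class = "simulation_result")
  validate_simulation_result(res)
}

#' Extract one contact frame
#'
#' The per-face pressure field of one tibial compartment at one time step.
#'
#' @param result A [simulation_result()].
#' @param time Time step (matched to 1e-9).
#' @param side `"medial"` or `"lateral"`.
#' @return Data.frame with columns `face_id`, `cx`, `cy`, `cz`, `pressure`
#'   (possibly zero rows if the compartment carries no field at that time).
#' @export
contact_frame <- function(result, time, side = c("medial", "lateral")) {
  side <- match.arg(side)
  sel <- round_time(result$contact$time) == round_time(time) &
    result$contact$side == side
  result$contact[sel, c("face_id", "cx", "cy", "cz", "pressure"),
                 drop = FALSE]
}
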