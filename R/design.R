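# One-at-a-time perturbation design: parameter axes, plan enumeration,
# loading schedule, and attachment node-set halving.

#' Ligaments included in the sensitivity design
#'
#' Anterior/posterior cruciate and medial/lateral collateral ligaments, in
#' the fixed enumeration order used throughout the package.
#' @export
LIGAMENTS <- c("ACL", "PCL", "MCL", "LCL")

# fixed axis enumeration order (defines deterministic plan ordering)
AXIS_ORDER <- c(
  "prestretch", "youngs_modulus", "attachment", "horn_stiffness",
  "augmented_lagrangian", "penalty_factor", "auto_penalty", "two_pass",
  "search_radius",
  "quasi_newton", "displacement_tolerance",
  "force_penalty", "moment_penalty", "gap_tolerance", "angular_tolerance"
)

AXIS_CATEGORY <- c(
  prestretch = "ligament_meniscus", youngs_modulus = "ligament_meniscus",
  attachment = "ligament_meniscus", horn_stiffness = "ligament_meniscus",
  augmented_lagrangian = "contact", penalty_factor = "contact",
  auto_penalty = "contact", two_pass = "contact", search_radius = "contact",
  quasi_newton = "control", displacement_tolerance = "control",
  force_penalty = "rcj", moment_penalty = "rcj", gap_tolerance = "rcj",
  angular_tolerance = "rcj"
)

#' Construct a perturbation axis
#'
#' A parameter of interest with its baseline value and the ordered list of
#' perturbed values investigated (the baseline itself is excluded: the
#' unperturbed run is the original simulation).
#'
#' @param name Axis identifier (e.g. `"prestretch"`).
#' @param category One of `"ligament_meniscus"`, `"contact"`, `"control"`,
#'   `"rcj"`.
#' @param baseline Baseline (original) value; numeric or character token.
#' @param values Non-empty vector of perturbed values, baseline excluded.
#' @param structure Optional ligament tag (`"ACL"`, `"PCL"`, `"MCL"`,
#'   `"LCL"`) for per-ligament axes.
#' @param detail Optional free-text note carried onto plans (e.g. the
#'   `max_ups = 10` setting that accompanies the quasi-Newton axis).
#' @return An object of class `parameter_axis`.
#' @export
parameter_axis <- function(name, category, baseline, values,
                           structure = NA_character_,
                           detail = NA_character_) {
  category <- match.arg(category,
                        c("ligament_meniscus", "contact", "control", "rcj"))
  if (length(values) == 0) {
    stop(sprintf("axis '%s' has an empty values list", name), call. = FALSE)
  }
  if (any(vapply(values, function(v) identical(v, baseline), logical(1)))) {
    stop(sprintf("axis '%s': baseline value present in perturbed values",
                 name), call. = FALSE)
  }
  structure(
    list(name = name, category = category, baseline = baseline,
         values = values, structure = structure, detail = detail),
    class = "parameter_axis"
  )
}

#' Prestretch perturbation values around a calibrated factor
#'
#' Calibrated value +/- 0.1 in steps of 0.025 (eight values, the calibrated
#' value itself excluded), ascending.
#'
#' @param calibrated Calibrated (baseline) prestretch factor, dimensionless,
#'   positive.
#' @return Numeric vector of length 8.
#' @examples
#' prestretch_values(1.0)
#' @export
prestretch_values <- function(calibrated) {
  stopifnot(is.numeric(calibrated), length(calibrated) == 1L,
            is.finite(calibrated))
  if (calibrated <= 0) {
    stop("calibrated prestretch factor must be positive", call. = FALSE)
  }
  k <- setdiff(-4:4, 0L)
  sort(calibrated + k * 0.025)
}

#' Young's modulus perturbation values around a calibrated modulus
#'
#' Calibrated value +/- 100 MPa in steps of 25 MPa (eight values, baseline
#' excluded), ascending. Perturbed values must stay positive: a ligament
#' with non-positive stiffness is not physically realizable, so this is a
#' hard error rather than a silent clamp (clamping would change the design).
#'
#' @param calibrated Calibrated Young's modulus in MPa.
#' @return Numeric vector of length 8 (MPa).
#' @examples
#' youngs_modulus_values(300)
#' @export
youngs_modulus_values <- function(calibrated) {
  stopifnot(is.numeric(calibrated), length(calibrated) == 1L,
            is.finite(calibrated))
  vals <- sort(calibrated + setdiff(-4:4, 0L) * 25)
  bad <- vals[vals <= 0]
  if (length(bad)) {
    stop(sprintf(
      "calibrated Young's modulus %g MPa yields non-positive perturbed values: %s",
      calibrated, paste(bad, collapse = ", ")), call. = FALSE)
  }
  vals
}

#' Attachment node-set combinations for one ligament
#'
#' The tied-contact node set of each ligament end is either the original
#' set (set1) or its halved version (set2). Three perturbed combinations
#' are run per ligament, in this fixed order: (set1, set2), (set2, set2),
#' (set2, set1) as (femur, tibia/fibula). The all-original pair
#' (set1, set1) is the baseline and never emitted.
#'
#' @param ligament One of `"ACL"`, `"PCL"`, `"MCL"`, `"LCL"`.
#' @return A data.frame with columns `ligament`, `femur_set`, `tibia_set`.
#' @export
attachment_combinations <- function(ligament) {
  if (!is.character(ligament) || length(ligament) != 1L ||
      !(ligament %in% LIGAMENTS)) {
    stop(sprintf("unknown ligament tag '%s' (expected one of %s)",
                 as.character(ligament)[1],
                 paste(LIGAMENTS, collapse = ", ")), call. = FALSE)
  }
  data.frame(
    ligament = ligament,
    femur_set = c("set1", "set2", "set2"),
    tibia_set = c("set2", "set2", "set1"),
    stringsAsFactors = FALSE
  )
}

#' Construct an attachment node set
#'
#' The nodes of one ligament end involved in the rigid tied contact with
#' bone, with their coordinates in the model's global frame (mm).
#'
#' @param ligament Ligament tag.
#' @param bone_end `"femur"` or `"tibia_fibula"`.
#' @param node_ids Integer vector of unique node ids.
#' @param node_coords Numeric matrix, one row per node, three columns (mm).
#' @param set_label `"set1"` (original) or `"set2"` (halved).
#' @return An object of class `attachment_node_set`.
#' @export
attachment_node_set <- function(ligament, bone_end, node_ids, node_coords,
                                set_label = "set1") {
  bone_end <- match.arg(bone_end, c("femur", "tibia_fibula"))
  set_label <- match.arg(set_label, c("set1", "set2"))
  node_coords <- as.matrix(node_coords)
  if (length(node_ids) != nrow(node_coords) || ncol(node_coords) != 3L) {
    stop("node_coords must be an n x 3 matrix matching node_ids",
         call. = FALSE)
  }
  if (anyDuplicated(node_ids)) stop("node ids must be unique", call. = FALSE)
  structure(
    list(ligament = ligament, bone_end = bone_end,
         node_ids = as.integer(node_ids), node_coords = node_coords,
         set_label = set_label),
    class = "attachment_node_set"
  )
}

#' Halve an attachment node set along the anatomical axis
#'
#' Builds set2 from set1 by keeping the half of the nodes extremal along
#' the proximal-pointing anatomical axis: the most proximal half for the
#' ligament-femur tied contact and the most distal half for the
#' ligament-tibia/fibula tied contact. For odd counts the target size is
#' round-half-up of n/2 (i.e. `ceiling(n / 2)`). Ties in projection are
#' broken by ascending node id for reproducibility.
#'
#' @param set1 An [attachment_node_set()] with at least two nodes.
#' @param axis_direction Length-3 vector pointing proximally (need not be
#'   unit length).
#' @return An `attachment_node_set` labelled `"set2"` whose node ids are a
#'   subset of `set1`'s.
#' @export
halve_node_set <- function(set1, axis_direction = c(0, 0, 1)) {
  stopifnot(inherits(set1, "attachment_node_set"))
  n <- length(set1$node_ids)
  if (n < 2L) stop("set1 must contain at least two nodes", call. = FALSE)
  coords <- set1$node_coords
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("nodes without finite coordinates", call. = FALSE)
  }
  axis_direction <- as.numeric(axis_direction)
  nrm <- sqrt(sum(axis_direction^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("axis_direction must be a non-zero vector", call. = FALSE)
  }
  proj <- as.numeric(coords %*% (axis_direction / nrm))
  n2 <- ceiling(n / 2)
  ord <- if (set1$bone_end == "femur") {
    order(-proj, set1$node_ids)   # proximal half (largest projection)
  } else {
    order(proj, set1$node_ids)    # distal half (smallest projection)
  }
  keep <- sort(ord[seq_len(n2)])
  attachment_node_set(set1$ligament, set1$bone_end,
                      set1$node_ids[keep], coords[keep, , drop = FALSE],
                      set_label = "set2")
}

# internal: full axis registry for one model given calibrated baselines
parameter_axes <- function(baselines) {
  for (field in c("prestretch", "youngs_modulus")) {
    vals <- baselines[[field]]
    for (lig in LIGAMENTS) {
      if (is.null(vals) || is.na(vals[lig] %||% NA)) {
        stop(sprintf("missing calibrated %s for ligament %s", field, lig),
             call. = FALSE)
      }
    }
  }
  axes <- list()
  for (lig in LIGAMENTS) {
    axes[[paste0("prestretch_", lig)]] <- parameter_axis(
      "prestretch", "ligament_meniscus",
      baseline = unname(baselines$prestretch[lig]),
      values = prestretch_values(unname(baselines$prestretch[lig])),
      structure = lig)
  }
  for (lig in LIGAMENTS) {
    axes[[paste0("youngs_modulus_", lig)]] <- parameter_axis(
      "youngs_modulus", "ligament_meniscus",
      baseline = unname(baselines$youngs_modulus[lig]),
      values = youngs_modulus_values(unname(baselines$youngs_modulus[lig])),
      structure = lig)
  }
  for (lig in LIGAMENTS) {
    combos <- attachment_combinations(lig)
    axes[[paste0("attachment_", lig)]] <- parameter_axis(
      "attachment", "ligament_meniscus",
      baseline = "fem_set1.tib_set1",
      values = paste0("fem_", combos$femur_set, ".tib_", combos$tibia_set),
      structure = lig)
  }
  # 18 springs per horn attachment, per-spring stiffness in N/mm
  axes$horn_stiffness <- parameter_axis(
    "horn_stiffness", "ligament_meniscus", baseline = 1,
    values = c(5, 10, 20))
  axes$augmented_lagrangian <- parameter_axis(
    "augmented_lagrangian", "contact", baseline = 0, values = 1)
  axes$penalty_factor <- parameter_axis(
    "penalty_factor", "contact", baseline = 1, values = c(0.5, 2, 5, 10))
  axes$auto_penalty <- parameter_axis(
    "auto_penalty", "contact", baseline = 0, values = 1,
    detail = "penalty_factor=1")
  axes$two_pass <- parameter_axis(
    "two_pass", "contact", baseline = 1, values = 0)
  axes$search_radius <- parameter_axis(
    "search_radius", "contact", baseline = 0.005, values = 1)
  axes$quasi_newton <- parameter_axis(
    "quasi_newton", "control", baseline = "full_newton",
    values = c("BFGS", "Broyden"), detail = "max_ups=10")
  axes$displacement_tolerance <- parameter_axis(
    "displacement_tolerance", "control", baseline = 0.01, values = 0.001)
  axes$force_penalty <- parameter_axis(
    "force_penalty", "rcj", baseline = 10000, values = c(5000, 20000))
  axes$moment_penalty <- parameter_axis(
    "moment_penalty", "rcj", baseline = 3e6,
    values = c(5000, 10000, 20000))
  axes$gap_tolerance <- parameter_axis(
    "gap_tolerance", "rcj", baseline = 0.01, values = c(1e-4, 1e-3, 0.1))
  axes$angular_tolerance <- parameter_axis(
    "angular_tolerance", "rcj", baseline = 1e-4,
    values = c(0.001, 0.01, 0.1))
  axes
}

# internal: stable character label for a perturbed value
value_label <- function(v) {
  if (is.numeric(v)) {
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  } else {
    as.character(v)
  }
}

#' Enumerate the one-at-a-time perturbation design for one model
#'
#' Builds the full design table: 101 plans per model, each differing from
#' the baseline configuration in exactly one parameter axis. Numeric axis
#' values are enumerated ascending; rows are ordered by category, axis,
#' ligament and value, so the table is deterministic.
#'
#' @param model_id Model identifier (e.g. `"du02"`, `"oks001"`, or a
#'   synthetic id).
#' @param baselines List with named numeric vectors `prestretch` and
#'   `youngs_modulus`, one calibrated value per ligament (names
#'   `ACL`, `PCL`, `MCL`, `LCL`).
#' @return A data.frame with columns `plan_id`, `model_id`, `category`,
#'   `axis`, `structure`, `value` (character), `value_num` (numeric, `NA`
#'   for categorical values), `baseline` (character), `detail`.
#' @examples
#' bl <- list(prestretch = c(ACL = 1, PCL = 1.02, MCL = 0.98, LCL = 1.05),
#'            youngs_modulus = c(ACL = 250, PCL = 300, MCL = 320, LCL = 280))
#' plans <- enumerate_design("du02", bl)
#' nrow(plans)  # 101
#' @export
enumerate_design <- function(model_id, baselines) {
  axes <- parameter_axes(baselines)
  rows <- lapply(axes, function(ax) {
    vals <- ax$values
    labels <- vapply(vals, value_label, character(1))
    data.frame(
      model_id = model_id,
      category = ax$category,
      axis = ax$name,
      structure = ax$structure,
      value = labels,
      value_num = if (is.numeric(vals)) as.numeric(vals) else NA_real_,
      value_idx = seq_along(vals),
      baseline = value_label(ax$baseline),
      detail = ax$detail,
      stringsAsFactors = FALSE
    )
  })
  plans <- do.call(rbind, rows)
  # deterministic order: category (Table order), axis, ligament, value asc
  # numeric axes ascend by value; categorical axes keep their fixed
  # enumeration order (e.g. the three printed attachment combinations)
  ord <- order(
    match(plans$axis, AXIS_ORDER),
    match(plans$structure, LIGAMENTS),
    plans$value_num,
    plans$value_idx,
    method = "radix"
  )
  plans <- plans[ord, , drop = FALSE]
  plans$plan_id <- sprintf(
    "%s-%s-%s-%s", plans$model_id, plans$axis,
    ifelse(is.na(plans$structure), "all", plans$structure),
    gsub("[^A-Za-z0-9.\\-]", "", plans$value))
  if (anyDuplicated(plans$plan_id)) {
    stop("internal error: duplicate plan ids in design", call. = FALSE)
  }
  rownames(plans) <- NULL
  plans[, c("plan_id", "model_id", "category", "axis", "structure",
            "value", "value_num", "baseline", "detail")]
}

#' Total meniscal horn stiffness for a per-spring value
#'
#' Each horn attachment is modelled as 18 parallel springs; the total horn
#' stiffness is therefore 18 times the per-spring stiffness. Over the
#' design's per-spring range of 1-20 N/mm this spans 18-360 N/mm.
#'
#' @param per_spring Per-spring stiffness in N/mm.
#' @param n_springs Number of springs per horn attachment (default 18).
#' @return Total stiffness in N/mm.
#' @export
horn_stiffness_total <- function(per_spring, n_springs = 18L) {
  stopifnot(per_spring > 0, n_springs > 0)
  n_springs * per_spring
}

#' Half-body-weight axial load
#'
#' The axial compressive load applied during the loading phase is half the
#' specimen's body weight, `0.5 * mass * 9.81` N, rounded to 0.01 N.
#'
#' @param mass_kg Specimen mass in kg.
#' @return Load in N.
#' @export
bodyweight_axial_load <- function(mass_kg) {
  stopifnot(is.numeric(mass_kg), mass_kg > 0)
  round(0.5 * mass_kg * 9.81, 2)
}

#' Loading schedule of a varus/valgus simulation
#'
#' The staged loading protocol: prestretch application, rotation to the
#' robot-data flexion angle (with a -20 N axial settling load for the oks
#' family), rotation back to 0 degrees of flexion, application of the
#' half-body-weight axial load, then a linear varus or valgus moment ramp
#' to +/- 40,000 Nmm over time steps 2.0-3.0. The du02 and oks model
#' families differ only in the early settling phases.
#'
#' @param direction `"valgus"` (positive moment) or `"varus"` (negative).
#' @param model_family `"oks"` or `"du02"`.
#' @param mass_kg Optional specimen mass; fills in the axial-load phase
#'   target via [bodyweight_axial_load()].
#' @return An object of class `loading_schedule` with fields `phases`
#'   (data.frame `label`, `t_start`, `t_end`, `target`, `units`),
#'   `moment_magnitude` (40000 Nmm), `direction`, `model_family`,
#'   `axial_load_N`.
#' @export
loading_schedule <- function(direction = c("valgus", "varus"),
                             model_family = c("oks", "du02"),
                             mass_kg = NULL) {
  direction <- match.arg(direction)
  model_family <- match.arg(model_family)
  axial <- if (is.null(mass_kg)) NA_real_ else bodyweight_axial_load(mass_kg)
  moment <- if (direction == "valgus") 40000 else -40000
  phases <- if (model_family == "oks") {
    data.frame(
      label = c("prestretch", "rotate_to_robot_flexion", "axial_settle",
                "rotate_to_zero_flexion", "axial_bodyweight", "moment_ramp"),
      t_start = c(0, 0.1, 0.5, 1.0, 1.5, 2.0),
      t_end   = c(0.1, 0.5, 1.0, 1.5, 2.0, 3.0),
      target  = c(NA, NA, -20, 0, axial, moment),
      units   = c("", "deg", "N", "deg", "N", "Nmm"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      label = c("prestretch", "rotate_to_robot_flexion",
                "rotate_to_zero_flexion", "axial_bodyweight", "moment_ramp"),
      t_start = c(0, 0.1, 1.0, 1.5, 2.0),
      t_end   = c(0.1, 1.0, 1.5, 2.0, 3.0),
      target  = c(NA, NA, 0, axial, moment),
      units   = c("", "deg", "deg", "N", "Nmm"),
      stringsAsFactors = FALSE
    )
  }
  # invariants: contiguous, non-overlapping cover of [0, 3]; moment phase
  # spans [2, 3]
  stopifnot(phases$t_start[1] == 0,
            phases$t_end[nrow(phases)] == 3,
            all(abs(phases$t_end[-nrow(phases)] - phases$t_start[-1]) < 1e-12),
            phases$t_start[nrow(phases)] == 2)
  structure(
    list(phases = phases, moment_magnitude = 40000, direction = direction,
         model_family = model_family, axial_load_N = axial),
    class = "loading_schedule"
  )
}

#' Applied varus/valgus moment at a time step
#'
#' Zero until the moment phase starts at t = 2.0, then a linear ramp to
#' +/- 40,000 Nmm at t = 3.0 (positive for valgus, negative for varus).
#' At t = 2.25 the applied magnitude is 10,000 Nmm, the convergence
#' threshold used by the analysis stage.
#'
#' @param t Time step(s) in `[0, 3]`.
#' @param schedule A [loading_schedule()].
#' @return Moment in Nmm, same length as `t`.
#' @examples
#' applied_moment_at(2.25, loading_schedule("valgus"))  # 10000
#' @export
applied_moment_at <- function(t, schedule) {
  stopifnot(inherits(schedule, "loading_schedule"))
  if (any(!is.finite(t)) || any(t < 0 | t > 3)) {
    stop("time step outside the simulation window [0, 3]", call. = FALSE)
  }
  sgn <- if (schedule$direction == "valgus") 1 else -1
  ifelse(t <= 2, 0, sgn * schedule$moment_magnitude * (t - 2))
}

#' Write the design manifest
#'
#' One row per (plan x direction), as CSV and JSON.
#'
#' @param plans Design table from [enumerate_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the expanded manifest data.frame.
#' @export
write_design_manifest <- function(plans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- merge(
    plans, data.frame(direction = c("varus", "valgus")), by = NULL)
  manifest <- manifest[order(match(manifest$plan_id, plans$plan_id),
                             manifest$direction), ]
  rownames(manifest) <- NULL
  cols <- c("plan_id", "model_id", "category", "axis", "structure",
            "value", "direction")
  utils::write.csv(manifest[, cols], file.path(dir, "design_manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest[, cols],
                       file.path(dir, "design_manifest.json"),
                       dataframe = "rows", na = "null", auto_unbox = FALSE)
  invisible(manifest)
}
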