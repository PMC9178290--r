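# Synthetic generator of FE-like simulation result bundles with known
# injected effects, so every pipeline stage is testable without running a
# finite-element solver.

#' Configure a synthetic knee model
#'
#' Defines the stand-in for one calibrated FE model: the specimen mass
#' (drives the half-body-weight axial load), the linear valgus compliance
#' of the joint under the applied moment, and the two elliptical contact
#' patches on the medial and lateral tibial plateaus.
#'
#' @param model_id Identifier for the synthetic model.
#' @param mass_kg Specimen mass in kg.
#' @param model_family `"oks"` or `"du02"` (selects the loading schedule
#'   preset).
#' @param compliance_deg_per_Nmm Valgus rotation per unit applied moment
#'   (degrees/Nmm). The default 1e-4 gives 4 degrees of valgus at the full
#'   40,000 Nmm moment, a physiologically plausible frontal-plane laxity.
#' @param amplitude_MPa Baseline peak pressure amplitude of the contact
#'   bump (N/mm^2). The default 3 MPa is typical of tibiofemoral cartilage
#'   contact under load.
#' @param medial_center,lateral_center Patch centers (mm, model frame).
#' @param patch_radii_mm Ellipse semi-axes (medial-lateral,
#'   anterior-posterior) in mm, shared by both patches.
#' @param n_faces_per_side Number of surface faces per compartment
#'   (minimum 10).
#' @param contact_cutoff Fraction of the unscaled bump amplitude below
#'   which a face is out of contact (pressure 0). The default 0.35 puts
#'   roughly a fifth of each patch in contact, so the top-10% face subset
#'   is meaningful.
#' @param seed Integer seed for the model's stochastic components.
#' @return An object of class `synthetic_model_config`.
#' @export
synthetic_model_config <- function(model_id = "synth01", mass_kg = 70,
                                   model_family = c("oks", "du02"),
                                   compliance_deg_per_Nmm = 1e-4,
                                   amplitude_MPa = 3,
                                   medial_center = c(-22, 0, 0),
                                   lateral_center = c(22, 0, 0),
                                   patch_radii_mm = c(12, 18),
                                   n_faces_per_side = 200L,
                                   contact_cutoff = 0.35,
                                   seed = 1L) {
  model_family <- match.arg(model_family)
  stopifnot(n_faces_per_side >= 10L, compliance_deg_per_Nmm > 0,
            amplitude_MPa > 0, all(patch_radii_mm > 0),
            contact_cutoff > 0, contact_cutoff < 1)
  structure(
    list(model_id = model_id, mass_kg = mass_kg,
         model_family = model_family,
         compliance = compliance_deg_per_Nmm,
         amplitude = amplitude_MPa,
         medial_center = medial_center, lateral_center = lateral_center,
         patch_radii = patch_radii_mm,
         n_faces_per_side = as.integer(n_faces_per_side),
         contact_cutoff = contact_cutoff,
         seed = as.integer(seed)),
    class = "synthetic_model_config")
}

#' Generate the tibial articulating surface of a synthetic model
#'
#' Two disjoint elliptical patches of face centroids, labelled medial and
#' lateral. Centroids are laid out on a sunflower (Vogel) spiral, which is
#' deterministic, approximately uniform over the ellipse, and free of the
#' grid artifacts a lattice layout would give.
#'
#' @param config A [synthetic_model_config()].
#' @return Data.frame with columns `face_id`, `side`, `cx`, `cy`, `cz`
#'   (mm); face ids unique across sides.
#' @export
make_surface <- function(config) {
  stopifnot(inherits(config, "synthetic_model_config"))
  n <- config$n_faces_per_side
  a <- config$patch_radii[1]
  b <- config$patch_radii[2]
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  r <- sqrt((i - 0.5) / n)
  th <- i * golden
  patch <- function(center, side, id0) {
    data.frame(face_id = id0 + i, side = side,
               cx = center[1] + a * r * cos(th),
               cy = center[2] + b * r * sin(th),
               cz = center[3],
               stringsAsFactors = FALSE)
  }
  rbind(patch(config$medial_center, "medial", 0L),
        patch(config$lateral_center, "lateral", n))
}

#' Define injected effects for synthetic runs
#'
#' Maps perturbation axes (optionally down to a single ligament or value)
#' to ground-truth effects: a pressure scale factor `s`, a peak-location
#' shift `d` (mm), a valgus compliance multiplier `c`, and a convergence
#' truncation time `T`. Axes without a matching row get the null effect
#' (s = 1, d = 0, c = 1, T = 3: identical to baseline up to noise).
#'
#' @param table `NULL` (no effects) or a data.frame with columns `axis`,
#'   `structure`, `value` (character or `NA` = match any), and any of
#'   `pressure_scale`, `shift_x`, `shift_y`, `shift_z`,
#'   `compliance_mult`, `truncate_time`. The first matching row wins.
#' @param kinematics_sigma_deg Gaussian noise s.d. on the valgus rotation
#'   during the moment phase (degrees). Zero (the default) reproduces the
#'   deterministic character of FE output; positive values exist to
#'   exercise the pipeline's tolerance handling.
#' @param pressure_sigma_MPa Gaussian noise s.d. on contacting faces'
#'   pressures (truncated at zero).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(table = NULL, kinematics_sigma_deg = 0,
                          pressure_sigma_MPa = 0) {
  defaults <- data.frame(axis = character(), structure = character(),
                         value = character(), pressure_scale = numeric(),
                         shift_x = numeric(), shift_y = numeric(),
                         shift_z = numeric(), compliance_mult = numeric(),
                         truncate_time = numeric(), stringsAsFactors = FALSE)
  if (!is.null(table)) {
    stopifnot("axis" %in% names(table))
    for (col in names(defaults)) {
      if (!col %in% names(table)) {
        table[[col]] <- if (col %in% c("structure", "value")) {
          NA_character_
        } else if (col == "pressure_scale" || col == "compliance_mult") {
          1
        } else if (col == "truncate_time") 3 else 0
      }
    }
    table <- table[, names(defaults)]
    stopifnot(all(table$pressure_scale > 0),
              all(table$truncate_time > 0 & table$truncate_time <= 3))
  } else {
    table <- defaults
  }
  stopifnot(kinematics_sigma_deg >= 0, pressure_sigma_MPa >= 0)
  structure(
    list(table = table, kinematics_sigma = kinematics_sigma_deg,
         pressure_sigma = pressure_sigma_MPa),
    class = "effect_config")
}

# internal: ground-truth effect for one plan row (NULL plan = baseline)
effect_for_plan <- function(effects, plan) {
  null_eff <- list(s = 1, d = c(0, 0, 0), c = 1, T = 3)
  if (is.null(plan)) return(null_eff)
  tb <- effects$table
  if (nrow(tb) == 0) return(null_eff)
  match_str <- function(pat, x) {
    is.na(pat) | (!is.na(x) & pat == x)
  }
  hit <- which(tb$axis == plan$axis &
                 match_str(tb$structure, plan$structure) &
                 match_str(tb$value, plan$value))
  if (!length(hit)) return(null_eff)
  r <- tb[hit[1], ]
  list(s = r$pressure_scale,
       d = c(r$shift_x, r$shift_y, r$shift_z),
       c = r$compliance_mult, T = r$truncate_time)
}

#' Simulate one FE-like run
#'
#' Emulates the staged varus/valgus loading protocol on a synthetic model.
#' The valgus rotation follows `theta(t) = c * k * M(t)` during the moment
#' ramp (with `k` the model compliance and `M(t)` from
#' [applied_moment_at()]), plus optional Gaussian noise. Contact fields are
#' Gaussian pressure bumps on each tibial patch,
#' `p = s * A * exp(-|x - (center + d)| ^ 2 / (2 rho^2))` with
#' `rho = 0.4 * min(patch radii)`, zeroed outside the contact cutoff
#' (applied to the unscaled field, so the set of contacting faces - and
#' hence the top-10% subset - does not depend on the injected scale `s`).
#' The time grid is a uniform 0.05 step over [0, 3], truncated at the
#' injected convergence time `T`.
#'
#' With zero noise the induced comparison metrics have closed forms: the
#' pressure percentage difference is exactly `100 |s - 1|`, the location
#' distance recovers `|d|` up to the patch discretization, and the valgus
#' RMSE equals `|c - 1| * k * sqrt(mean(M(t)^2))` over the evaluation grid.
#'
#' @param model A [synthetic_model_config()].
#' @param direction `"varus"` or `"valgus"`.
#' @param plan One-row data.frame from [enumerate_design()], or `NULL` for
#'   the baseline run.
#' @param effects An [effect_config()].
#' @param surface Precomputed [make_surface()] table (recomputed if
#'   `NULL`).
#' @param seed Optional integer seed (only consulted when noise is
#'   non-zero).
#' @param dt Time-grid step (default 0.05).
#' @param contact_times Optional vector of times at which to emit contact
#'   frames; default is every converged step of the moment phase
#'   (t >= 2.0).
#' @return A [simulation_result()].
#' @export
simulate_run <- function(model, direction, plan = NULL,
                         effects = effect_config(), surface = NULL,
                         seed = NULL, dt = 0.05, contact_times = NULL) {
  stopifnot(inherits(model, "synthetic_model_config"),
            inherits(effects, "effect_config"))
  direction <- match.arg(direction, c("varus", "valgus"))
  eff <- effect_for_plan(effects, plan)
  sched <- loading_schedule(direction, model$model_family, model$mass_kg)
  times <- round_time(seq(0, 3, by = dt))
  times <- times[times <= eff$T + 1e-9]
  lct <- max(times)
  noisy <- effects$kinematics_sigma > 0 || effects$pressure_sigma > 0
  if (noisy && !is.null(seed)) set.seed(as.integer(seed))

  M <- applied_moment_at(times, sched)
  valgus <- eff$c * model$compliance * M
  if (effects$kinematics_sigma > 0) {
    ramp <- times > 2
    valgus[ramp] <- valgus[ramp] +
      stats::rnorm(sum(ramp), 0, effects$kinematics_sigma)
  }
  # simple deterministic profiles for the remaining DOF (plumbing only):
  # flexion rises to the robot angle during settling and returns to zero
  flex_nodes_t <- c(0, 0.1, 1.0, 1.5, 3.0)
  flex_nodes_y <- c(0, 0, 20, 0, 0)
  flexion <- stats::approx(flex_nodes_t, flex_nodes_y, xout = times)$y
  si <- ifelse(times >= 1.5, -0.2, 0)  # axial-load compression, mm
  kin <- kinematics_series(times, valgus_deg = valgus,
                           flexion_deg = flexion, si_mm = si)

  if (is.null(surface)) surface <- make_surface(model)
  ct <- times[times >= 2.0 - 1e-9]
  if (!is.null(contact_times)) {
    ct <- intersect(ct, round_time(contact_times))
  }
  rho <- 0.4 * min(model$patch_radii)
  centers <- list(medial = model$medial_center + eff$d,
                  lateral = model$lateral_center + eff$d)
  empty_contact <- data.frame(time = numeric(), side = character(),
                              face_id = integer(), cx = numeric(),
                              cy = numeric(), cz = numeric(),
                              pressure = numeric(), stringsAsFactors = FALSE)
  frames <- lapply(c("medial", "lateral"), function(sd) {
    if (!length(ct)) return(empty_contact)  # stalled before the moment phase
    patch <- surface[surface$side == sd, , drop = FALSE]
    ctr <- centers[[sd]]
    d2 <- (patch$cx - ctr[1])^2 + (patch$cy - ctr[2])^2 +
      (patch$cz - ctr[3])^2
    raw <- model$amplitude * exp(-d2 / (2 * rho^2))
    in_contact <- raw > model$contact_cutoff * model$amplitude
    base <- eff$s * raw * in_contact
    nt <- length(ct)
    p <- rep(base, times = nt)
    if (effects$pressure_sigma > 0 && any(in_contact)) {
      idx <- which(rep(in_contact, times = nt))
      p[idx] <- pmax(0, p[idx] +
                       stats::rnorm(length(idx), 0, effects$pressure_sigma))
    }
    data.frame(time = rep(ct, each = nrow(patch)),
               side = sd,
               face_id = rep(patch$face_id, times = nt),
               cx = rep(patch$cx, times = nt),
               cy = rep(patch$cy, times = nt),
               cz = rep(patch$cz, times = nt),
               pressure = p,
               stringsAsFactors = FALSE)
  })
  # all faces are reported, zero-pressure ones included: contact selection
  # (p > 0) is the analysis stage's job, as with real solver output
  contact <- do.call(rbind, frames)
  simulation_result(
    plan_id = if (is.null(plan)) "original" else plan$plan_id,
    model_id = model$model_id, direction = direction,
    kinematics = kin, contact = contact, last_converged_time = lct)
}

#' Simulate a full synthetic study
#'
#' One varus and one valgus run per perturbation plan plus the two baseline
#' runs (for a full 101-plan design: 204 bundles), with a ground-truth
#' manifest recording the injected effects of every plan for recovery
#' tests. Per-run seeds are derived deterministically from `seed`, so
#' identical seeds give identical studies.
#'
#' @param plans Design table from [enumerate_design()].
#' @param model A [synthetic_model_config()].
#' @param effects An [effect_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory: when given, every run is also
#'   written as a result bundle via [write_result_bundle()] (subdirectory
#'   `<plan_id>__<direction>`) together with `ground_truth.json`.
#' @param dt Time-grid step passed to [simulate_run()].
#' @return An object of class `synthetic_study`: list with `model`,
#'   `plans`, `results` (named list, key `<plan_id>::<direction>`),
#'   `baselines` (list `varus`/`valgus`), `manifest` (ground truth),
#'   `seed`.
#' @export
simulate_study <- function(plans, model, effects = effect_config(),
                           seed = 1L, out_dir = NULL, dt = 0.05) {
  surface <- make_surface(model)
  run_key <- function(plan_id, direction) paste(plan_id, direction,
                                                sep = "::")
  results <- list()
  baselines <- list()
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (as.integer(seed) + 7919L * counter) %% 2147483647L
  }
  for (dir in c("varus", "valgus")) {
    baselines[[dir]] <- simulate_run(model, dir, plan = NULL,
                                     effects = effects, surface = surface,
                                     seed = next_seed(), dt = dt)
  }
  manifest <- vector("list", nrow(plans))
  for (i in seq_len(nrow(plans))) {
    plan <- plans[i, , drop = FALSE]
    eff <- effect_for_plan(effects, plan)
    for (dir in c("varus", "valgus")) {
      results[[run_key(plan$plan_id, dir)]] <-
        simulate_run(model, dir, plan = plan, effects = effects,
                     surface = surface, seed = next_seed(), dt = dt)
    }
    manifest[[i]] <- data.frame(
      plan_id = plan$plan_id, axis = plan$axis,
      structure = plan$structure, value = plan$value,
      pressure_scale = eff$s, shift_x = eff$d[1], shift_y = eff$d[2],
      shift_z = eff$d[3], compliance_mult = eff$c,
      truncate_time = eff$T, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  study <- structure(
    list(model = model, plans = plans, results = results,
         baselines = baselines, manifest = manifest,
         seed = as.integer(seed)),
    class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write every bundle of a synthetic study to disk
#'
#' @param study A [simulate_study()] result.
#' @param out_dir Target directory.
#' @return Invisibly, the bundle directories written.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (dir in names(study$baselines)) {
    p <- file.path(out_dir, paste("original", dir, sep = "__"))
    write_result_bundle(study$baselines[[dir]], p)
    paths <- c(paths, p)
  }
  for (key in names(study$results)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    p <- file.path(out_dir, paste(parts[1], parts[2], sep = "__"))
    write_result_bundle(study$results[[key]], p)
    paths <- c(paths, p)
  }
  writeLines(jsonlite::toJSON(study$manifest, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             file.path(out_dir, "ground_truth.json"))
  invisible(paths)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> model %s: %d plans, %d perturbed runs + %d baselines (seed %d)\n",
    x$model$model_id, nrow(x$plans), length(x$results),
    length(x$baselines), x$seed))
  invisible(x)
}
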