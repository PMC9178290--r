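# shared fixtures, all built in code

tiny_baselines <- function() {
  list(prestretch = c(ACL = 1.00, PCL = 1.02, MCL = 0.98, LCL = 1.05),
       youngs_modulus = c(ACL = 250, PCL = 300, MCL = 320, LCL = 280))
}

small_model <- function(n_faces = 60L, seed = 1L) {
  synthetic_model_config(model_id = "synthTest", mass_kg = 70,
                         n_faces_per_side = n_faces, seed = seed)
}

# a valid hand-built simulation result on a coarse grid
toy_result <- function(plan_id = "original", direction = "valgus",
                       lct = 3, valgus_offset = 0, pressures = c(1, 2, 3),
                       loc_shift = c(0, 0, 0)) {
  times <- seq(0, lct, by = 0.5)
  kin <- kinematics_series(times, valgus_deg = times * 2 + valgus_offset)
  ct <- times[times >= 2]
  frame <- function(side, x0) {
    do.call(rbind, lapply(ct, function(t) {
      data.frame(time = t, side = side,
                 face_id = seq_along(pressures) +
                   if (side == "lateral") 100L else 0L,
                 cx = x0 + seq_along(pressures) + loc_shift[1],
                 cy = loc_shift[2], cz = loc_shift[3],
                 pressure = pressures)
    }))
  }
  simulation_result(plan_id, "toy", direction, kin,
                    rbind(frame("medial", -20), frame("lateral", 20)),
                    last_converged_time = lct)
}

# per-side peak summaries of a result at one time
side_sums <- function(result, time) {
  list(medial = peak_contact_pressure(
         contact_frame(result, time, "medial"), side = "medial"),
       lateral = peak_contact_pressure(
         contact_frame(result, time, "lateral"), side = "lateral"))
}

# brute-force oracle for the top-10% peak extraction: repeatedly pull the
# maximum rather than sorting, so it shares no code path with the package
oracle_peak <- function(frame) {
  contact <- frame[frame$pressure > 0, , drop = FALSE]
  n <- nrow(contact)
  if (n == 0) return(list(peak = NA_real_, loc = rep(NA_real_, 3)))
  k <- ceiling(0.1 * n)
  picked <- integer(0)
  pool <- contact
  for (i in seq_len(k)) {
    best <- which(pool$pressure == max(pool$pressure))
    best <- best[which.min(pool$face_id[best])]
    picked <- c(picked, pool$face_id[best])
    pool <- pool[-best, , drop = FALSE]
  }
  sel <- contact[contact$face_id %in% picked, , drop = FALSE]
  list(peak = sum(sel$pressure) / k,
       loc = c(sum(sel$cx), sum(sel$cy), sum(sel$cz)) / k)
}
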