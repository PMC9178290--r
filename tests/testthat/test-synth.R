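test_that("the synthetic surface is deterministic with disjoint labelled patches", {
  cfg <- small_model()
  surf <- make_surface(cfg)
  expect_equal(nrow(surf), 2 * cfg$n_faces_per_side)
  expect_false(anyDuplicated(surf$face_id) > 0)
  expect_equal(as.vector(table(surf$side)),
               rep(cfg$n_faces_per_side, 2))
  expect_identical(surf, make_surface(small_model()))
  # centroids stay inside their ellipse
  for (sd in c("medial", "lateral")) {
    p <- surf[surf$side == sd, ]
    ctr <- if (sd == "medial") cfg$medial_center else cfg$lateral_center
    u <- ((p$cx - ctr[1]) / cfg$patch_radii[1])^2 +
      ((p$cy - ctr[2]) / cfg$patch_radii[2])^2
    expect_true(all(u <= 1 + 1e-9))
  }
  expect_error(synthetic_model_config(n_faces_per_side = 5))
})

test_that("null effects and zero noise reproduce the baseline exactly", {
  cfg <- small_model()
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "penalty_factor", ][1, ]
  base <- simulate_run(cfg, "valgus")
  run <- simulate_run(cfg, "valgus", plan = plan)
  comp <- compare_run(run, base, analysis_time = 3)
  expect_equal(comp$convergence_pct_diff, 0)
  expect_equal(comp$valgus_rmse, 0)
  expect_equal(comp$pressure_pct_diff, 0)
  expect_equal(comp$location_distance, 0)
})

test_that("an injected pressure scale is recovered as 100|s - 1| exactly", {
  cfg <- small_model()
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "augmented_lagrangian", ][1, ]
  for (s in c(0.7, 1.3, 2.5)) {
    eff <- effect_config(data.frame(axis = "augmented_lagrangian",
                                    pressure_scale = s))
    run <- simulate_run(cfg, "valgus", plan = plan, effects = eff)
    base <- simulate_run(cfg, "valgus")
    pp <- pressure_pct_diff(side_sums(run, 3), side_sums(base, 3))
    expect_equal(as.numeric(pp), 100 * abs(s - 1), tolerance = 1e-12)
    expect_equal(unname(attr(pp, "per_side")),
                 rep(100 * abs(s - 1), 2), tolerance = 1e-12)
  }
})

test_that("an injected location shift is recovered to the patch resolution", {
  cfg <- small_model(n_faces = 300L)
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "search_radius", ][1, ]
  d <- c(1.5, -1.0, 0)
  eff <- effect_config(data.frame(axis = "search_radius",
                                  shift_x = d[1], shift_y = d[2],
                                  shift_z = d[3]))
  run <- simulate_run(cfg, "valgus", plan = plan, effects = eff)
  base <- simulate_run(cfg, "valgus")
  ld <- as.numeric(location_distance(side_sums(run, 3), side_sums(base, 3)))
  # tolerance: one centroid spacing ~ sqrt(patch area / n)
  spacing <- sqrt(pi * prod(cfg$patch_radii) / cfg$n_faces_per_side)
  expect_lt(abs(ld - sqrt(sum(d^2))), spacing)
})

test_that("a compliance multiplier yields its closed-form valgus RMSE", {
  cfg <- small_model()
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "two_pass", ][1, ]
  cmult <- 1.4
  eff <- effect_config(data.frame(axis = "two_pass",
                                  compliance_mult = cmult))
  run <- simulate_run(cfg, "valgus", plan = plan, effects = eff)
  base <- simulate_run(cfg, "valgus")
  got <- valgus_rmse(base$kinematics, run$kinematics)
  grid <- run$kinematics$time[run$kinematics$time >= 2]
  M <- applied_moment_at(grid, loading_schedule("valgus"))
  want <- abs(cmult - 1) * cfg$compliance * sqrt(mean(M^2))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("injected early truncation always triggers the exclusion rule", {
  cfg <- small_model()
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "moment_penalty", ][1, ]
  eff <- effect_config(data.frame(axis = "moment_penalty",
                                  truncate_time = 2.1))
  run <- simulate_run(cfg, "valgus", plan = plan, effects = eff)
  base <- simulate_run(cfg, "valgus")
  expect_lte(run$convergence$last_converged_time, 2.1)
  expect_true(run$convergence$terminated_early)
  sel <- select_analysis_time(list(run), base)
  expect_true(sel$excluded)
  # truncation just past the threshold is kept
  eff2 <- effect_config(data.frame(axis = "moment_penalty",
                                   truncate_time = 2.6))
  run2 <- simulate_run(cfg, "valgus", plan = plan, effects = eff2)
  sel2 <- select_analysis_time(list(run2), base)
  expect_false(sel2$excluded)
  expect_equal(sel2$analysis_time, 2.6)
})

test_that("a full study yields 204 bundles and a faithful ground-truth manifest", {
  cfg <- small_model(n_faces = 20L)
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  eff <- effect_config(data.frame(axis = "penalty_factor",
                                  pressure_scale = 1.25))
  study <- simulate_study(plans, cfg, eff, seed = 3, dt = 0.25)
  expect_equal(length(study$results), 202)
  expect_equal(length(study$baselines), 2)
  expect_equal(nrow(study$manifest), 101)
  expect_equal(sum(study$manifest$pressure_scale == 1.25), 4)
  expect_equal(study$manifest$pressure_scale[
    study$manifest$axis != "penalty_factor"],
    rep(1, 97))
})

test_that("identical seeds give identical studies, on disk too", {
  cfg <- small_model(n_faces = 12L)
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plans <- plans[plans$axis %in% c("two_pass", "force_penalty"), ]
  eff <- effect_config(kinematics_sigma_deg = 0.05,
                       pressure_sigma_MPa = 0.02)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(plans, cfg, eff, seed = 11, out_dir = d1, dt = 0.25)
  simulate_study(plans, cfg, eff, seed = 11, out_dir = d2, dt = 0.25)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed perturbs the noisy fields
  d3 <- withr::local_tempdir()
  simulate_study(plans, cfg, eff, seed = 12, out_dir = d3, dt = 0.25)
  same <- vapply(f1, function(f) {
    identical(readLines(file.path(d1, f)), readLines(file.path(d3, f)))
  }, logical(1))
  expect_false(all(same))
})

test_that("noisy pressure-scale estimates are unbiased over many seeds", {
  cfg <- small_model(n_faces = 80L)
  plans <- enumerate_design(cfg$model_id, tiny_baselines())
  plan <- plans[plans$axis == "augmented_lagrangian", ][1, ]
  s <- 1.2
  eff <- effect_config(data.frame(axis = "augmented_lagrangian",
                                  pressure_scale = s),
                       pressure_sigma_MPa = 0.05)
  est <- vapply(1:100, function(i) {
    base <- simulate_run(cfg, "valgus", effects = eff, seed = 2000 + 2 * i,
                         contact_times = 3)
    run <- simulate_run(cfg, "valgus", plan = plan, effects = eff,
                        seed = 2001 + 2 * i, contact_times = 3)
    as.numeric(pressure_pct_diff(side_sums(run, 3), side_sums(base, 3)))
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 100 * (s - 1)), 2 * mc_se + 1e-12)
})
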