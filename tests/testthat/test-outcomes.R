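mk_frame <- function(pressures, face_id = seq_along(pressures),
                     cx = seq_along(pressures), cy = 0, cz = 0) {
  data.frame(face_id = face_id, cx = cx, cy = cy, cz = cz,
             pressure = pressures)
}

test_that("peak contact pressure averages the top 10% of contacting faces", {
  # 10 faces, pressures 1..10: top set is the single highest face
  s <- peak_contact_pressure(mk_frame(1:10))
  expect_equal(s$peak_pressure, 10)
  expect_equal(s$n_contact_faces, 10L)
  expect_equal(s$n_top_faces, 1L)

  # 15 contacting faces: ceil(1.5) = 2, mean of the two largest
  s15 <- peak_contact_pressure(mk_frame(1:15))
  expect_equal(s15$n_top_faces, 2L)
  expect_equal(s15$peak_pressure, mean(c(14, 15)))

  # constant field: peak equals the constant, any count
  for (n in c(3, 12, 47)) {
    expect_equal(peak_contact_pressure(mk_frame(rep(2.5, n)))$peak_pressure,
                 2.5)
  }

  # faces at exactly zero pressure are not in contact
  s0 <- peak_contact_pressure(mk_frame(c(0, 0, 5)))
  expect_equal(s0$n_contact_faces, 1L)
  expect_equal(s0$peak_pressure, 5)

  # no contact at all: explicit empty summary, not an error
  none <- peak_contact_pressure(mk_frame(c(0, 0, 0)))
  expect_equal(none$n_contact_faces, 0L)
  expect_true(is.na(none$peak_pressure))
  expect_error(peak_contact_pressure(mk_frame(c(1, -2))), "negative")
})

test_that("peak extraction matches a brute-force oracle on small frames", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    fr <- mk_frame(round(stats::runif(n, 0, 5), 2),
                   face_id = sample.int(500, n),
                   cx = stats::rnorm(n), cy = stats::rnorm(n),
                   cz = stats::rnorm(n))
    got <- peak_contact_pressure(fr)
    want <- oracle_peak(fr)
    if (is.na(want$peak)) {
      expect_true(is.na(got$peak_pressure))
    } else {
      expect_equal(got$peak_pressure, want$peak)
      expect_equal(got$location, want$loc)
    }
  }
})

test_that("peak extraction is invariant to face ordering", {
  set.seed(11)
  fr <- mk_frame(stats::runif(18), face_id = sample.int(99, 18),
                 cx = stats::rnorm(18))
  perm <- fr[sample.int(18), ]
  expect_equal(peak_contact_pressure(perm)$peak_pressure,
               peak_contact_pressure(fr)$peak_pressure)
  expect_equal(peak_contact_pressure(perm)$location,
               peak_contact_pressure(fr)$location)
})

test_that("analysis time is the latest common step past the moment threshold", {
  r <- function(lct) toy_result("p", "valgus", lct = lct)
  base <- r(3)
  # all members at 3.0
  sel <- select_analysis_time(list(r(3), r(3)), base)
  expect_equal(sel$analysis_time, 3)
  expect_false(any(sel$excluded))
  # min over included members
  sel <- select_analysis_time(list(r(3), r(3), r(2.5)), base)
  expect_equal(sel$analysis_time, 2.5)
  # a member stalled at 2.0 is excluded, analysis time from the rest
  sel <- select_analysis_time(list(r(2.0), r(3)), base)
  expect_equal(sel$excluded, c(TRUE, FALSE))
  expect_match(sel$reason[1], "last converged time 2")
  expect_equal(sel$analysis_time, 3)
  # exactly at the threshold counts as excluded
  sel <- select_analysis_time(list(toy_result("p", "valgus", lct = 2.25)),
                              base)
  expect_true(sel$excluded)
  expect_true(is.na(sel$analysis_time))
  # a baseline that stalls dooms the whole group
  expect_error(select_analysis_time(list(r(3)), r(2.1)), "baseline")
})

test_that("convergence percentage difference is the absolute relative change", {
  expect_equal(convergence_pct_diff(3, 3), 0)
  expect_equal(convergence_pct_diff(2.25, 3), 25)
  expect_equal(convergence_pct_diff(1.5, 3), 50)
  expect_equal(convergence_pct_diff(1.5, 3, signed = TRUE), -50)
  expect_error(convergence_pct_diff(1, 0), "positive")
})

test_that("valgus RMSE interpolates the original onto the interest grid", {
  kin <- function(t, v) kinematics_series(t, valgus_deg = v)
  # identical series
  a <- kin(seq(2, 3, 0.25), seq(2, 3, 0.25))
  expect_equal(valgus_rmse(a, a), 0)
  # constant offset on a shared grid
  b <- kin(seq(2, 3, 0.25), seq(2, 3, 0.25) + 0.7)
  expect_equal(valgus_rmse(a, b), 0.7)
  # hand-checked interpolation: original linear on {2, 3}, interest on
  # {2, 2.5, 3} offset by 0.5
  orig <- kin(c(2, 3), c(2, 3))
  intr <- kin(c(2, 2.5, 3), c(2, 2.5, 3) + 0.5)
  expect_equal(valgus_rmse(orig, intr), 0.5)
  # invariant to adding the same constant to both series
  expect_equal(valgus_rmse(kin(c(2, 3), c(2, 3) + 5),
                           kin(c(2, 2.5, 3), c(2, 2.5, 3) + 5.5)), 0.5)
  # settling phases before t = 2 are not compared
  o2 <- kin(seq(0, 3, 0.5), c(9, 9, 9, 9, 0, 0, 0))
  i2 <- kin(seq(0, 3, 0.5), c(-9, 0, 9, 0, 0, 0, 0))
  expect_equal(valgus_rmse(o2, i2), 0)
  # grid clipped to the original's span; no extrapolation
  o3 <- kin(seq(2, 2.5, 0.25), rep(1, 3))
  i3 <- kin(seq(2, 3, 0.25), rep(2, 5))
  expect_equal(valgus_rmse(o3, i3), 1)
  # empty overlap yields NA, to be flagged as excluded upstream
  o4 <- kin(c(0, 1), c(0, 0))
  expect_true(is.na(valgus_rmse(o4, i3)))
})

test_that("pressure percentage difference averages the two compartments", {
  mk <- function(med, lat) {
    list(medial = peak_contact_pressure(mk_frame(med), side = "medial"),
         lateral = peak_contact_pressure(mk_frame(lat), side = "lateral"))
  }
  orig <- mk(10, 10)
  expect_equal(as.numeric(pressure_pct_diff(mk(14, 11), orig)), 25)
  expect_equal(as.numeric(pressure_pct_diff(orig, orig)), 0)
  # uniform scaling by 1.5: 50% on both sides
  fr <- mk_frame(c(1, 3, 2, 5))
  orig2 <- list(medial = peak_contact_pressure(fr),
                lateral = peak_contact_pressure(fr))
  scaled <- list(
    medial = peak_contact_pressure(transform(fr, pressure = pressure * 1.5)),
    lateral = peak_contact_pressure(transform(fr, pressure = pressure * 1.5)))
  expect_equal(as.numeric(pressure_pct_diff(scaled, orig2)), 50)
  # original side without contact is dropped from the average
  part <- pressure_pct_diff(mk(14, 11), mk(10, 0))
  expect_equal(as.numeric(part), 40)
  expect_true(is.na(attr(part, "per_side")["lateral"]))
  # both sides without original contact: metric absent
  expect_true(is.na(as.numeric(pressure_pct_diff(mk(1, 1), mk(0, 0)))))
  # interest losing contact reads as a 100% drop
  expect_equal(as.numeric(pressure_pct_diff(mk(0, 10), mk(10, 10))), 50)
})

test_that("location distance averages per-side Euclidean distances", {
  at <- function(x, y, z) {
    peak_contact_pressure(mk_frame(5, cx = x, cy = y, cz = z))
  }
  orig <- list(medial = at(0, 0, 0), lateral = at(10, 0, 0))
  expect_equal(as.numeric(location_distance(orig, orig)), 0)
  # medial offset (3, 4, 0) -> 5 mm; lateral unchanged -> mean 2.5
  moved <- list(medial = at(3, 4, 0), lateral = at(10, 0, 0))
  expect_equal(as.numeric(location_distance(moved, orig)), 2.5)
  # common rigid translation of both runs changes nothing
  shift <- function(s, d) {
    s$location <- s$location + d
    s
  }
  d <- c(1.5, -2, 0.5)
  orig_t <- lapply(orig, shift, d = d)
  moved_t <- lapply(moved, shift, d = d)
  expect_equal(as.numeric(location_distance(moved_t, orig_t)), 2.5)
  # translating only the interest run by d induces |d| on both sides
  only_i <- lapply(orig, shift, d = c(0, 3, 4))
  expect_equal(as.numeric(location_distance(only_i, orig)), 5)
})

test_that("aggregation keeps directions separate and honours exclusions", {
  comp <- rbind(
    compare_run(toy_result("a", "valgus", pressures = c(1, 2, 3) * 1.1),
                toy_result(), analysis_time = 3),
    compare_run(toy_result("b", "valgus", pressures = c(1, 2, 3) * 1.3),
                toy_result(), analysis_time = 3))
  agg <- aggregate_parameter(comp)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$pressure_pct_diff, 20)  # mean of 10% and 30%
  expect_equal(agg$n_excluded, 0)

  # single comparison: aggregate equals it
  one <- aggregate_parameter(comp[1, ])
  expect_equal(one$pressure_pct_diff, comp$pressure_pct_diff[1])

  # an excluded run still counts for convergence but nothing else
  base <- toy_result()
  runs <- list(toy_result("a", "valgus", lct = 2.0),
               toy_result("b", "valgus"),
               toy_result("c", "valgus", pressures = c(1, 2, 3) * 1.2))
  comp2 <- analyze_parameter(runs, base)
  expect_equal(comp2$excluded, c(TRUE, FALSE, FALSE))
  expect_true(is.na(comp2$pressure_pct_diff[1]))
  agg2 <- aggregate_parameter(comp2)
  expect_equal(agg2$n_excluded, 1)
  expect_equal(agg2$convergence_pct_diff,
               mean(c(100 * (3 - 2) / 3, 0, 0)))
  expect_equal(agg2$pressure_pct_diff, mean(c(0, 20)))

  # all runs excluded: quantitative aggregates unavailable
  agg3 <- aggregate_parameter(
    analyze_parameter(list(toy_result("a", "valgus", lct = 2.1)), base))
  expect_true(is.na(agg3$pressure_pct_diff))
  expect_false(is.na(agg3$convergence_pct_diff))
})
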