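make_ts <- function(apical, basolateral, times = c(7.5, 20, 24, 29),
                    design = "UniL", c0a = 1, c0b = 0, draws = c(40, 80)) {
  chamber_timeseries("cpd", design, times, apical, basolateral,
                     c0_apical = c0a, c0_basolateral = c0b,
                     apical_draw_ul = draws[1], basolateral_draw_ul = draws[2])
}

test_that("Kp,brain is the final basolateral-to-apical concentration ratio", {
  expect_equal(compute_kp_brain(make_ts(c(0.8, 0.6, 0.5, 0.5),
                                        c(0.1, 0.3, 0.5, 0.5))), 1)
  expect_equal(compute_kp_brain(make_ts(c(0.9, 0.6, 0.5, 0.5),
                                        c(0.5, 1.5, 1.9, 2.0))), 4)
  expect_error(compute_kp_brain(make_ts(c(0.5, 0.5, 0.5, 0),
                                        c(0.1, 0.1, 0.1, 0.1))), "zero")
  expect_error(compute_kp_brain(make_ts(c(0.5, 0.5, 0.5, NA),
                                        c(0.1, 0.1, 0.1, 0.1))), "quantified")
})

test_that("a binding-asymmetric passive simulation equilibrates at fu_A/fu_B", {
  p <- transwell_params(p_passive = 50, fu_apical = 0.5, fu_basolateral = 0.25)
  ts <- simulate_equilibrium_experiment(p, design = "UniL")
  expect_true(assess_equilibrium(ts))
  # unbound concentrations equalize, so the total ratio is fu_A/fu_B = 2
  expect_equal(compute_kp_brain(ts), 2, tolerance = 0.02)
  expect_equal(compute_kp_uu(compute_kp_brain(ts), 0.25, 0.5), 1,
               tolerance = 0.02)
})

test_that("Kp,uu scales Kp,brain by the unbound-fraction ratio", {
  expect_equal(compute_kp_uu(2, 0.25, 0.5), 1)
  expect_equal(compute_kp_uu(1.5, 0.3, 0.3), 1.5)
  # a strong plasma-to-brain binding difference masks restricted penetration
  expect_equal(round(compute_kp_uu(1, 0.131, 0.892), 3), 0.147)
  expect_error(compute_kp_uu(1, 0, 0.5), "unbound")
  expect_error(compute_kp_uu(-1, 0.5, 0.5), "kp_brain")
})

test_that("equilibrium assessment compares the final two sampling times", {
  expect_true(assess_equilibrium(make_ts(c(0.8, 0.6, 0.5, 0.5),
                                         c(0.1, 0.3, 0.45, 0.5))))
  # basolateral still rising 50% between 24 and 29 h
  expect_false(assess_equilibrium(make_ts(c(0.9, 0.8, 0.7, 0.65),
                                          c(0.05, 0.15, 0.2, 0.3))))
  # tolerance is a knob
  expect_true(assess_equilibrium(make_ts(c(1, 1, 1, 1),
                                         c(0.5, 0.5, 0.5, 0.6)),
                                 rel_tol = 0.25))
  expect_error(assess_equilibrium(
    chamber_timeseries("x", "UniL", 29, 0.5, 0.5, c0_apical = 1)),
    "two time points")
})

test_that("distribution recovery is exact on conservative simulations", {
  for (design in c("UniL", "BiL")) {
    p <- transwell_params(p_passive = 8, fu_apical = 0.6, fu_basolateral = 0.2)
    ts <- simulate_equilibrium_experiment(p, design = design)
    rec <- compute_distribution_recovery(ts)
    expect_equal(rec$recovery_pct, 100, tolerance = 1e-3)
    expect_true(rec$acceptable)
    expect_false(rec$partial)
  }
})

test_that("a strong monolayer depot produces the low-recovery phenotype", {
  p <- transwell_params(p_passive = 20, depot_kon = 0.3, depot_koff = 0.1)
  ts <- simulate_equilibrium_experiment(p, design = "UniL")
  rec <- compute_distribution_recovery(ts)
  expect_lt(rec$recovery_pct, 50)
  expect_gt(rec$recovery_pct, 10)
  expect_false(rec$acceptable)
})

test_that("no transport and no sampling gives exactly 100% recovery", {
  ts <- chamber_timeseries("inert", "UniL", c(24, 29), c(1, 1), c(0, 0),
                           c0_apical = 1, apical_draw_ul = 0,
                           basolateral_draw_ul = 0)
  expect_equal(compute_distribution_recovery(ts)$recovery_pct, 100)
})

test_that("censored interim samples flag the recovery as partial", {
  ts <- make_ts(c(NA, 0.6, 0.5, 0.5), c(0.1, 0.3, 0.45, 0.5))
  rec <- compute_distribution_recovery(ts)
  expect_true(rec$partial)
  expect_true(rec$recovery_pct > 0)
})

test_that("penetration classification is scale-invariant in the chamber units", {
  expect_equal(classify_brain_penetration(c(0.147, 0.3, 0.5, 0.7, 1.0)),
               c("restricted", "partial", "partial", "partial",
                 "unrestricted"))
  expect_error(classify_brain_penetration(0), "positive")
  # common rescaling of both chambers leaves class unchanged
  base <- make_ts(c(0.8, 0.6, 0.5, 0.5), c(0.1, 0.3, 0.45, 0.5))
  for (s in c(1e-3, 0.1, 7, 1e4)) {
    scaled <- make_ts(s * c(0.8, 0.6, 0.5, 0.5), s * c(0.1, 0.3, 0.45, 0.5))
    expect_equal(
      classify_brain_penetration(compute_kp_uu(compute_kp_brain(scaled),
                                               0.2, 0.6)),
      classify_brain_penetration(compute_kp_uu(compute_kp_brain(base),
                                               0.2, 0.6)))
  }
})

test_that("kp_table joins fu variants and carries QC flags", {
  ts1 <- simulate_equilibrium_experiment(
    transwell_params(p_passive = 30, fu_apical = 0.5, fu_basolateral = 0.25),
    design = "UniL", compound_id = "fast")
  ts2 <- simulate_equilibrium_experiment(
    transwell_params(p_passive = 0.3), design = "UniL", compound_id = "slow")
  fu <- data.frame(
    compound_id = c("fast", "fast", "fast", "fast", "slow"),
    matrix = c("BSA", "brain_homogenate", "BSA", "brain_homogenate", "BSA"),
    fu = c(0.5, 0.25, 0.5, 0.26, 0.9),
    source = c("measured", "measured", "predicted", "predicted", "measured"),
    stringsAsFactors = FALSE)
  out <- kp_table(list(ts1, ts2), fu)
  fast <- out[out$compound_id == "fast", ]
  expect_equal(fast$kp_uu_measured_fu, fast$kp_brain * 0.25 / 0.5)
  expect_equal(fast$kp_uu_predicted_fu, fast$kp_brain * 0.26 / 0.5)
  expect_true(fast$equilibrium_reached)
  slow <- out[out$compound_id == "slow", ]
  # missing brain fu -> Kp reported, Kp,uu absent
  expect_true(is.na(slow$kp_uu_measured_fu))
  expect_false(slow$equilibrium_reached)
  expect_false(slow$qc_pass)
})
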