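mass_error <- function(ts) {
  ml <- attr(ts, "ground_truth")$mass_ledger
  abs(ml$loaded - (ml$apical_final + ml$basolateral_final +
                     ml$depot_final + ml$sampled)) / ml$loaded
}

test_that("mass is conserved to 0.1% across a 100-point parameter grid", {
  grid <- expand.grid(p = c(0.2, 1, 5, 20, 50),
                      E = c(1, 2, 10),
                      fu_a = c(0.05, 1),
                      fu_b = c(0.2, 1),
                      depot = c(0, 0.3))
  grid <- grid[seq_len(min(100, nrow(grid))), ]
  expect_gte(nrow(grid), 100)
  for (i in seq_len(nrow(grid))) {
    p <- transwell_params(p_passive = grid$p[i], efflux_factor = grid$E[i],
                          fu_apical = grid$fu_a[i], fu_basolateral = grid$fu_b[i],
                          depot_kon = grid$depot[i], depot_koff = 0.1)
    ts <- simulate_equilibrium_experiment(
      p, design = if (i %% 2 == 0) "UniL" else "BiL")
    expect_lt(mass_error(ts), 0.001)
  }
})

test_that("the no-depot steady-state unbound ratio is 1/E over a grid", {
  long <- sampling_schedule(times_h = c(100, 200, 240, 290),
                            apical_draw_ul = 0, basolateral_draw_ul = 0)
  for (E in c(1, 2, 4, 10)) {
    for (fu in list(c(1, 1), c(0.5, 0.25), c(0.1, 0.8))) {
      for (vols in list(c(500, 1000), c(300, 300))) {
        p <- transwell_params(p_passive = 30, efflux_factor = E,
                              fu_apical = fu[1], fu_basolateral = fu[2],
                              apical_volume = vols[1],
                              basolateral_volume = vols[2])
        ts <- simulate_equilibrium_experiment(p, schedule = long,
                                              design = "BiL")
        gt <- attr(ts, "ground_truth")
        n <- length(ts$times_h)
        unbound_ratio <- (fu[2] * gt$basolateral_true[n]) /
          (fu[1] * gt$apical_true[n])
        expect_equal(unbound_ratio, 1 / E, tolerance = 1e-6)
      }
    }
  }
})

test_that("a fully symmetric system converges to the mass-weighted common level", {
  p <- transwell_params(p_passive = 50)
  ts <- simulate_equilibrium_experiment(p, design = "BiL", c0 = 1)
  expect_equal(compute_kp_brain(ts), 1, tolerance = 1e-6)
  # Uni-L: all mass redistributes over both chambers
  tsu <- simulate_equilibrium_experiment(p, design = "UniL", c0 = 1)
  expect_equal(compute_kp_brain(tsu), 1, tolerance = 0.01)
})

test_that("the pipeline recovers Kp,uu = 1 (passive) and 1/E (efflux) at equilibrium", {
  # passive, binding-asymmetric
  p0 <- transwell_params(p_passive = 50, fu_apical = 0.5,
                         fu_basolateral = 0.25)
  ts0 <- simulate_equilibrium_experiment(p0, design = "UniL")
  expect_true(assess_equilibrium(ts0))
  kpuu0 <- compute_kp_uu(compute_kp_brain(ts0), 0.25, 0.5)
  expect_equal(kpuu0, 1, tolerance = 0.02)

  for (E in c(2, 4, 10)) {
    pE <- transwell_params(p_passive = 50, efflux_factor = E)
    tsE <- simulate_equilibrium_experiment(pE, design = "BiL")
    kpuu <- compute_kp_uu(compute_kp_brain(tsE), 1, 1)
    expect_equal(kpuu, 1 / E, tolerance = 0.05)
  }
})

test_that("zero permeability transports nothing", {
  m <- simulate_transport_experiment(transport_params(p_passive = 0), "AtoB")
  expect_equal(m$c_receiver_final, 0)
  expect_equal(m$c_donor_final, 1)
})

test_that("the Papp estimator recovers the true permeability under sink conditions", {
  for (p in c(0.5, 2, 5)) {
    for (dir in c("AtoB", "BtoA")) {
      m <- simulate_transport_experiment(transport_params(p_passive = p), dir)
      # sink condition: receiver below 10% of donor
      expect_lt(m$c_receiver_final, 0.1 * m$c0_donor)
      est <- compute_papp(m)$papp
      expect_equal(est, attr(m, "ground_truth")$p_effective, tolerance = 0.05)
    }
  }
})

test_that("paired simulated legs recover the efflux factor", {
  for (E in c(1, 4)) {
    tp <- transport_params(p_passive = 3, efflux_factor = E)
    ab <- compute_papp(simulate_transport_experiment(tp, "AtoB"))
    ba <- compute_papp(simulate_transport_experiment(tp, "BtoA"))
    er <- compute_efflux_ratio(ab, ba)
    expect_equal(er$er, E, tolerance = 0.05)
  }
})

test_that("dialysis noise is mean-one multiplicative with characterized bias", {
  set.seed(99)
  fus <- replicate(1000, {
    measured_fu(simulate_dialysis(0.3, noise_cv = 0.1))$fu_raw
  })
  # ratio of two mean-one lognormals has mean exp(sdlog^2) = 1 + cv^2
  expect_equal(mean(fus), 0.3 * (1 + 0.1^2), tolerance = 0.02)
})

test_that("equilibration slows monotonically as permeability falls", {
  final_gap <- function(p_passive) {
    p <- transwell_params(p_passive = p_passive)
    ts <- simulate_equilibrium_experiment(p, design = "UniL")
    gt <- attr(ts, "ground_truth")
    n <- length(ts$times_h)
    abs(gt$basolateral_true[n] - gt$basolateral_true[n - 1]) /
      gt$basolateral_true[n - 1]
  }
  gaps <- vapply(c(0.2, 0.5, 1, 2, 5, 10), final_gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("low-permeability settings fail the 29-h equilibrium criterion, fast ones pass", {
  for (p in c(0.2, 0.5)) {
    ts <- simulate_equilibrium_experiment(transwell_params(p_passive = p),
                                          design = "UniL")
    expect_false(assess_equilibrium(ts))
  }
  for (p in c(5, 20)) {
    ts <- simulate_equilibrium_experiment(transwell_params(p_passive = p),
                                          design = "UniL")
    expect_true(assess_equilibrium(ts))
  }
})

test_that("volume replacement barely shifts Kp when draws are small", {
  p <- transwell_params(p_passive = 50, fu_apical = 0.5, fu_basolateral = 0.25)
  kp <- vapply(c(TRUE, FALSE), function(repl) {
    sched <- sampling_schedule(replace_volume = repl)
    compute_kp_brain(simulate_equilibrium_experiment(p, schedule = sched,
                                                     design = "UniL"))
  }, numeric(1))
  expect_equal(kp[1], kp[2], tolerance = 0.01)
})

test_that("sampling draws larger than the chamber are rejected", {
  sched <- sampling_schedule(times_h = c(1, 2), apical_draw_ul = 400,
                             basolateral_draw_ul = 80)
  expect_error(simulate_equilibrium_experiment(
    transwell_params(p_passive = 5), schedule = sched, design = "UniL",
    c0 = 1), "exceeds")
})

test_that("cohort generation is deterministic and schema-complete", {
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  generate_cohort(n_compounds = 4, seed = 7, dir = d1)
  generate_cohort(n_compounds = 4, seed = 7, dir = d2)
  for (f in c("transport.csv", "dialysis.csv", "fu_reference.csv",
              "timeseries.csv", "ivive.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "cohortC")
  generate_cohort(n_compounds = 4, seed = 8, dir = d3)
  expect_false(identical(readLines(file.path(d1, "transport.csv")),
                         readLines(file.path(d3, "transport.csv"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("an empty cohort yields empty but schema-valid tables", {
  d <- file.path(tempdir(), "cohort0")
  b <- generate_cohort(n_compounds = 0, seed = 1, dir = d)
  expect_equal(nrow(b$transport), 0)
  expect_equal(nrow(read_transport_csv(file.path(d, "transport.csv"))), 0)
  expect_equal(length(read_timeseries_csv(file.path(d, "timeseries.csv"))), 0)
  unlink(d, recursive = TRUE)
})
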