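test_that("apparent permeability matches the closed-form hand calculation", {
  # (0.01 uM / 3600 s) * 0.25 cm3 / (0.0804 cm2 * 1 uM) = 8.64e-6 cm/s
  m <- make_leg("AtoB", c_receiver = 0.01, c0 = 1)
  res <- compute_papp(m)
  expect_equal(res$papp, (0.01 / 3600) * 0.25 / 0.0804 * 1e6, tolerance = 1e-12)
  expect_equal(round(res$papp, 2), 8.64)
  expect_equal(res$permeability_class, "moderate")

  # no flux
  expect_equal(compute_papp(make_leg("AtoB", 0))$papp, 0)
})

test_that("papp scales linearly in receiver conc and inversely in c0, area, time", {
  base <- compute_papp(make_leg("AtoB", 0.01, c0 = 1))$papp
  for (s in c(0.5, 2, 7)) {
    expect_equal(compute_papp(make_leg("AtoB", 0.01 * s))$papp, base * s)
    expect_equal(compute_papp(make_leg("AtoB", 0.01, c0 = s))$papp, base / s)
    expect_equal(compute_papp(make_leg("AtoB", 0.01, duration_s = 3600 * s))$papp,
                 base / s)
    m <- make_leg("AtoB", 0.01)
    m$geometry$area_cm2 <- 0.0804 * s
    expect_equal(compute_papp(m)$papp, base / s)
  }
})

test_that("below-LLOQ receiver concentrations propagate as censored, never zero", {
  m <- make_leg("AtoB", c_receiver = 0.0005, lloq = 0.001)
  res <- compute_papp(m)
  expect_true(res$censored)
  expect_true(is.na(res$papp))
  expect_equal(res$permeability_class, "censored")
  # explicit NA (not quantifiable at all)
  res2 <- compute_papp(make_leg("AtoB", NA_real_, lloq = 0.001))
  expect_true(res2$censored)
})

test_that("invalid geometry and concentrations are rejected", {
  expect_error(transport_geometry(0, 250, 0.0804, 3600), "positive")
  expect_error(transport_geometry(50, 250, -1, 3600), "positive")
  expect_error(transport_measurement("x", "AtoB", c0_donor = 0,
                                     c_donor_final = 1, c_receiver_final = 0),
               "positive")
  expect_error(transport_measurement("x", "AtoB", c0_donor = 1,
                                     c_donor_final = -0.1,
                                     c_receiver_final = 0),
               "non-negative")
})

test_that("efflux ratio is BtoA over AtoB and reciprocal-symmetric", {
  ab <- papp_result("cpd", "AtoB", 8.5)
  ba <- papp_result("cpd", "BtoA", 37)
  er <- compute_efflux_ratio(ab, ba)
  expect_equal(er$er, 37 / 8.5)
  expect_equal(round_half_up(er$er), 4.4)
  expect_equal(er$pgp_class, "likely")

  # symmetry: equal permeabilities give ER 1
  expect_equal(compute_efflux_ratio(papp_result("z", "AtoB", 5),
                                    papp_result("z", "BtoA", 5))$er, 1)

  # reciprocal property over random quantified pairs
  set.seed(42)
  for (i in 1:20) {
    p1 <- runif(1, 0.1, 50)
    p2 <- runif(1, 0.1, 50)
    e1 <- compute_efflux_ratio(papp_result("a", "AtoB", p1),
                               papp_result("a", "BtoA", p2))$er
    e2 <- compute_efflux_ratio(papp_result("a", "AtoB", p2),
                               papp_result("a", "BtoA", p1))$er
    expect_equal(e1 * e2, 1, tolerance = 1e-12)
  }
})

test_that("censored legs follow the cimetidine rule", {
  cens <- papp_result("cim", "AtoB", NA)
  quant <- papp_result("cim", "BtoA", 2.5)
  er <- compute_efflux_ratio(cens, quant)
  expect_true(is.na(er$er))
  expect_equal(er$pgp_class, "possible")

  both <- compute_efflux_ratio(papp_result("aten", "AtoB", NA),
                               papp_result("aten", "BtoA", NA))
  expect_equal(both$pgp_class, "not_available")

  expect_error(compute_efflux_ratio(papp_result("a", "AtoB", 1),
                                    papp_result("b", "BtoA", 1)),
               "same compound")
})

test_that("reference efflux ratios round-trip from their tabulated permeability pairs", {
  tab <- reference_papp()
  # compounds whose reported ER was evidently computed from unrounded
  # replicate data do not round-trip from the tabulated means and are
  # checked elsewhere: buspirone (0.95 -> printed 0.9), gabapentin
  # (0.55 -> 0.5), citalopram (1.64 -> 1.7)
  skip_ids <- c("buspirone", "gabapentin", "citalopram")
  tab <- tab[!is.na(tab$papp_atob_1e6_cm_s) & !is.na(tab$papp_btoa_1e6_cm_s) &
               !tab$compound_id %in% skip_ids, ]
  for (i in seq_len(nrow(tab))) {
    er <- compute_efflux_ratio(
      papp_result(tab$compound_id[i], "AtoB", tab$papp_atob_1e6_cm_s[i]),
      papp_result(tab$compound_id[i], "BtoA", tab$papp_btoa_1e6_cm_s[i]))
    expect_equal(round_half_up(er$er, 1), tab$er_reported[i],
                 info = tab$compound_id[i])
    expect_equal(er$pgp_class, tab$pgp_class_reported[i],
                 info = tab$compound_id[i])
  }
})

test_that("mass-balance recovery is the recovered fraction of the donor load", {
  # nothing moved
  m <- make_leg("AtoB", c_receiver = 0, c_donor = 1, c0 = 1)
  expect_equal(compute_transport_recovery(m), 100)
  # arithmetic oracle: 100 * (250*0.1 + 50*0.5) / (50*1) = 100
  m2 <- make_leg("AtoB", c_receiver = 0.1, c_donor = 0.5, c0 = 1)
  expect_equal(compute_transport_recovery(m2), 100)
  # everything lost
  m3 <- make_leg("AtoB", c_receiver = 0, c_donor = 0, c0 = 1)
  expect_equal(compute_transport_recovery(m3), 0)
  # cell term only increases recovery
  m4 <- make_leg("AtoB", c_receiver = 0.05, c_donor = 0.4, c0 = 1)
  m4$c_cell_lysate <- 0.3
  expect_gte(compute_transport_recovery(m4, include_cell = TRUE),
             compute_transport_recovery(m4, include_cell = FALSE))
  # requesting the cell term without a lysate measurement errors
  expect_error(compute_transport_recovery(m2, include_cell = TRUE), "lysate")
})

test_that("permeability and P-gp classification boundaries are half-closed", {
  expect_equal(classify_permeability(c(0.4, 1.0, 9.9, 10, 39)),
               c("low", "moderate", "moderate", "moderate", "high"))
  expect_error(classify_permeability(-1), "non-negative")
  expect_equal(classify_pgp(c(1.0, 1.5, 1.6, 2.0, 2.1, 4.4)),
               c("unlikely", "possible", "possible", "possible",
                 "likely", "likely"))
  expect_error(classify_pgp(0), "positive")
  tab <- reference_papp()
  ok <- !is.na(tab$papp_atob_1e6_cm_s)
  expect_equal(classify_permeability(tab$papp_atob_1e6_cm_s[ok]),
               tab$permeability_class_reported[ok])
})

test_that("papp_table computes the full per-compound summary from long data", {
  df <- data.frame(
    compound_id = rep(c("fast", "pumped", "blocked"), each = 2),
    direction = rep(c("AtoB", "BtoA"), 3),
    c0_donor_uM = 1,
    c_donor_final_uM = c(0.9, 0.9, 0.95, 0.7, 0.99, 0.9),
    c_receiver_final_uM = c(0.02, 0.004, 0.005, 0.08, NA, 0.003),
    c_cell_lysate_uM = NA_real_,
    lloq_uM = 0.001,
    donor_volume_uL = rep(c(50, 250), 3),
    receiver_volume_uL = rep(c(250, 50), 3),
    area_cm2 = 0.0804, duration_s = 3600,
    stringsAsFactors = FALSE)
  out <- papp_table(df)
  expect_equal(nrow(out), 3)
  blocked <- out[out$compound_id == "blocked", ]
  expect_true(blocked$censored_AtoB)
  expect_equal(blocked$pgp_class, "possible")
  pumped <- out[out$compound_id == "pumped", ]
  # receiver-volume conversion: BtoA receiver is the 50 uL apical side
  expect_equal(pumped$er, (0.08 * 50) / (0.005 * 250), tolerance = 1e-10)
  expect_equal(pumped$pgp_class, "likely")
})
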