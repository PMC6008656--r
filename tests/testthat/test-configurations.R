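test_that("the configuration space has 21 members with the right structure", {
  cfg <- ba_configurations()
  expect_equal(nrow(cfg), 21L)
  expect_equal(sum(!cfg$sulfated), 18L)
  expect_true(all(cfg$species[cfg$sulfated] == "LCA"))
  expect_equal(
    nrow(dplyr::distinct(cfg, species, conjugation, sulfated)), 21L
  )
  expect_error(
    bilecirc:::validate_configuration("CA", "u", TRUE),
    "sulfated"
  )
  expect_error(hepatic_extraction(ba_params(), "DCA", "g", TRUE), "sulfated")
})

test_that("there are 18 compartments with plasma outside the EHC loop", {
  comp <- ba_compartments()
  expect_equal(nrow(comp), 18L)
  expect_equal(comp$region[comp$id == "si_1"], "duodenum")
  expect_equal(sum(comp$region == "jejunum"), 4L)
  expect_equal(sum(comp$region == "ileum"), 5L)
  expect_equal(sum(comp$region == "colon"), 5L)
  # plasma receives only hepatic spillover: with full extraction and no
  # plasma return, plasma stays empty over a simulated day
  p <- ba_params(
    psi_tri = 1, psi_di = 1, psi_mono = 1, psi_u = 1, psi_sulf = 1,
    k_pl = 0
  )
  x0 <- empty_state()
  x0[state_index("CA", "t", FALSE, "si_3")] <- 500
  x0[state_index("CDCA", "u", FALSE, "li")] <- 200
  traj <- ba_simulate(p, x0, days = 1, dt_h = 1)
  pl <- dplyr::filter(traj, compartment == "pl")
  expect_equal(max(abs(pl$amount_umol)), 0)
})

test_that("hepatic extraction follows the psi product rule", {
  p <- ba_params(psi_tri = 0.95, psi_u = 0.625, psi_sulf = 0.5)
  expect_identical(hepatic_extraction(p, "CA", "t"), 0.95)
  expect_identical(hepatic_extraction(p, "CA", "g"), 0.95)
  expect_equal(hepatic_extraction(p, "CA", "u"), 0.59375, tolerance = 1e-15)
  p0 <- ba_params(psi_tri = 0, psi_di = 0, psi_mono = 0)
  cfg <- ba_configurations()
  expect_equal(
    hepatic_extraction(p0, cfg$species, cfg$conjugation, cfg$sulfated),
    rep(0, 21)
  )
})

test_that("conjugated extraction is at least unconjugated, in bounds", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_params()
    tab <- extraction_table(p)
    expect_true(all(tab$psi >= 0 & tab$psi <= 1))
    for (sp in unique(tab$species)) {
      conj <- tab$psi[tab$species == sp & tab$conjugation != "u" &
        !tab$sulfated]
      unconj <- tab$psi[tab$species == sp & tab$conjugation == "u" &
        !tab$sulfated]
      expect_true(all(conj >= unconj - 1e-12))
    }
  }
})

test_that("the colonic transformation map has exactly the four edges", {
  map <- transformation_map()
  expect_setequal(
    paste(map$substrate, map$product),
    c("CA DCA", "CDCA LCA", "CDCA UDCA", "UDCA LCA")
  )
  expect_false("DCA" %in% map$substrate)
  expect_equal(sum(map$substrate == "CDCA"), 2L)
  expect_false("O" %in% c(map$substrate, map$product))
})

test_that("transformation acts only on unconjugated species in the colon", {
  # a conjugated CA bolus in the colon with deconjugation disabled is
  # never transformed: no DCA appears anywhere
  p <- ba_params(k_dec_si = 0, k_dec_co = 0, k_u = 0)
  x0 <- empty_state()
  x0[state_index("CA", "g", FALSE, "co_2")] <- 100
  traj <- ba_simulate(p, x0, days = 1, dt_h = 2)
  dca <- dplyr::filter(traj, species == "DCA")
  expect_equal(max(dca$amount_umol), 0)
  # the unconjugated bolus is transformed
  x0 <- empty_state()
  x0[state_index("CA", "u", FALSE, "co_2")] <- 100
  traj <- ba_simulate(p, x0, days = 1, dt_h = 2)
  dca <- dplyr::filter(traj, species == "DCA", time_h == 24)
  expect_gt(sum(dca$amount_umol), 1)
})
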