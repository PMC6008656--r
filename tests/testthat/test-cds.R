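test_that("the packaged calibration dataset has the documented structure", {
  cds <- cds_fixture()
  expect_equal(nrow(cds), 76L)
  expect_equal(dplyr::n_distinct(cds$category), 7L)
  expect_setequal(
    unique(cds$category),
    c(
      "composition", "conjugation", "sulfation", "pools", "fluxes",
      "postprandial", "transit"
    )
  )
  expect_true(all(is.finite(cds$value) & cds$value > 0))
  grp <- dplyr::filter(cds, category %in% c("composition", "conjugation"))
  sums <- tapply(grp$value, grp$group_id, sum)
  expect_true(all(abs(sums - 1) <= 0.01))
  # printed-value-linked entries are flagged
  expect_false(any(cds$reconstructed[cds$id %in%
    c("pp_total_foldpeak", "pp_total_tpeak")]))
})

test_that("CDS validation rejects malformed datasets", {
  cds <- cds_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cds(cds[-3, ], path)
  expect_error(read_cds(path), "76")
  bad <- cds
  bad$value[bad$id == "pool_total"] <- -1
  write_cds(bad, path)
  expect_error(read_cds(path), "positive")
  bad <- cds
  bad$value[bad$group_id == "comp_plasma"] <- 0.5
  write_cds(bad, path)
  expect_error(read_cds(path), "summing")
})

test_that("zero-noise synthetic data equals the model observables", {
  obs <- default_obs()
  cds <- generate_synthetic_cds(ba_params(), 0, observables = obs)
  expect_equal(
    cds$value[match(obs$id, cds$id)],
    pmax(obs$value, 1e-9),
    tolerance = 1e-12
  )
})

test_that("synthetic data is deterministic in the seed and mean-one", {
  obs <- default_obs()
  a <- generate_synthetic_cds(ba_params(), 0.2, seed = 5, observables = obs)
  b <- generate_synthetic_cds(ba_params(), 0.2, seed = 5, observables = obs)
  c <- generate_synthetic_cds(ba_params(), 0.2, seed = 6, observables = obs)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
  expect_true(all(a$value > 0))
  # lognormal factors are mean-one: across many seeds the average of a
  # non-renormalized entry stays within 3 standard errors of truth
  n <- 400
  cv <- 0.1
  vals <- vapply(seq_len(n), function(s) {
    g <- generate_synthetic_cds(ba_params(), cv, seed = s, observables = obs)
    g$value[g$id == "pool_total"]
  }, 0)
  truth <- obs$value[obs$id == "pool_total"]
  se <- stats::sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - truth), 3 * se + 1e-12)
})

test_that("the objective at truth grows with the noise level", {
  obs <- default_obs()
  med_nsse <- vapply(c(0, 0.05, 0.1, 0.2), function(cv) {
    stats::median(vapply(1:7, function(s) {
      cds <- generate_synthetic_cds(ba_params(), cv,
        seed = s,
        observables = obs
      )
      ba_nsse(cds, observables = obs)
    }, 0))
  }, 0)
  expect_true(all(diff(med_nsse) > 0))
})
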