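test_that("the objective is zero at a perfect fit", {
  cds <- cds_fixture()
  expect_identical(ba_nsse(cds, observables = obs_from_cds(cds)), 0)
})

test_that("hand-computed objective values are reproduced exactly", {
  # single unit-weight entry, d = 2, y = 3 -> ((3-2)/2)^2 = 0.25
  toy <- tibble::tibble(
    id = "pool_x", category = "pools", group_id = "pool_x", value = 2
  )
  obs <- tibble::tibble(id = "pool_x", value = 3)
  expect_equal(ba_nsse(toy, observables = obs, validate = FALSE), 0.25,
    tolerance = 1e-15
  )
  # five-species composition, every component at relative error 0.5 with
  # weight 1/5 -> 5 * (0.5/5)^2 = 0.05
  toy5 <- tibble::tibble(
    id = paste0("c", 1:5), category = "composition", group_id = "g",
    value = rep(0.2, 5)
  )
  obs5 <- tibble::tibble(id = paste0("c", 1:5), value = rep(0.3, 5))
  expect_equal(ba_nsse(toy5, observables = obs5, validate = FALSE), 0.05,
    tolerance = 1e-15
  )
})

test_that("the objective is invariant to entry order and monotone in entries", {
  cds <- cds_fixture()
  obs <- default_obs()
  base <- ba_nsse(cds, observables = obs)
  shuffled <- cds[sample.int(nrow(cds)), ]
  expect_equal(ba_nsse(shuffled, observables = obs), base, tolerance = 1e-12)
  # removing any entry never increases the objective at fixed parameters
  set.seed(3)
  for (i in sample.int(nrow(cds), 6)) {
    expect_lte(
      ba_nsse(cds[-i, ], observables = obs, validate = FALSE),
      base + 1e-12
    )
  }
})

test_that("weights down-weight grouped categories only", {
  cds <- cds_fixture()
  w <- bilecirc:::cds_weights(cds)
  expect_true(all(w[cds$category %in%
    c("pools", "fluxes", "postprandial", "transit")] == 1))
  expect_equal(w[cds$group_id == "comp_plasma"], rep(1 / 6, 6))
  expect_equal(w[cds$group_id == "comp_synthesis"], rep(1 / 3, 3))
  expect_equal(w[cds$group_id == "conj_bile"], rep(1 / 3, 3))
})

test_that("fitting is reproducible and a fixed point at the optimum", {
  obs <- default_obs()
  cds <- generate_synthetic_cds(ba_params(), 0, observables = obs)
  # truth is the starting point: a short refit must stay put
  fit1 <- ba_fit(cds, ba_params(),
    n_starts = 1, free = c("k_u", "k_si_beta"),
    maxiter = 5, ss_tol = 1e-6
  )
  expect_lt(fit1$nsse, 1e-8)
  expect_equal(
    p_values(fit1$params)[["k_u"]], p_values(ba_params())[["k_u"]],
    tolerance = 1e-4
  )
  # bit-for-bit reproducibility for a given seed
  p0 <- p_set(ba_params(), k_u = 35)
  fit_a <- ba_fit(cds, p0,
    n_starts = 2, seed = 9, free = "k_u",
    maxiter = 4, ss_tol = 1e-5
  )
  fit_b <- ba_fit(cds, p0,
    n_starts = 2, seed = 9, free = "k_u",
    maxiter = 4, ss_tol = 1e-5
  )
  expect_identical(p_values(fit_a$params), p_values(fit_b$params))
  expect_identical(fit_a$nsse, fit_b$nsse)
  expect_identical(fit_a$start_results$nsse, fit_b$start_results$nsse)
})

test_that("tidy and glance summarize fits in broom style", {
  obs <- default_obs()
  cds <- generate_synthetic_cds(ba_params(), 0, observables = obs)
  fit <- ba_fit(cds, ba_params(),
    n_starts = 1, free = "k_u", maxiter = 2,
    ss_tol = 1e-5
  )
  td <- tidy(fit)
  expect_equal(td$term, "k_u")
  expect_true(all(c("estimate", "lower", "upper", "at_bound") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 76L)
  expect_equal(gl$n_free, 1L)
})
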