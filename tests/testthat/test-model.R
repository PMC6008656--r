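# parameter set with every exchange between compartments disabled except
# intestinal transit (used by conservation and cascade-oracle tests)
transit_only_params <- function(...) {
  ba_params(
    k_u = 0, k_up = 0, k_up_co = 0, Vmax = 0, k_dec_si = 0, k_dec_co = 0,
    k_sulf = 0, k_CA_DCA = 0, k_CDCA_LCA = 0, k_CDCA_UDCA = 0,
    k_UDCA_LCA = 0, delta_SI = 0, k_conj = 0, k_xl = 0,
    ...
  )
}

test_that("the transit multiplier follows the meal forcing", {
  p <- ba_params(delta_SI = 0.5, beta_SI = log(2))
  # exactly at a meal
  expect_equal(transit_multiplier(p, 0), 1.5)
  # one hour after: 1 + 0.5 * 2^-1
  expect_equal(transit_multiplier(p, 1), 1.25, tolerance = 1e-12)
  # before any meal (fasted start, first meal at 6 h)
  p2 <- ba_params(delta_SI = 0.5, meal_times_h = c(6, 12, 18))
  expect_equal(transit_multiplier(p2, 3), 1)
  expect_gt(transit_multiplier(p2, 6), 1.49)
  expect_error(transit_multiplier(p, -1), "non-negative")
})

test_that("an empty system only receives synthesis in the liver", {
  p <- ba_params()
  d <- ba_rhs(p, empty_state(), 0)
  v <- p_values(p)
  expect_equal(
    d[state_index("CA", "u", FALSE, "li")], v[["k_u"]] * v[["f_CA"]]
  )
  expect_equal(
    d[state_index("CDCA", "u", FALSE, "li")], v[["k_u"]] * v[["f_CDCA"]]
  )
  expect_equal(
    d[state_index("O", "u", FALSE, "li")],
    v[["k_u"]] * (1 - v[["f_CA"]] - v[["f_CDCA"]])
  )
  core <- seq_len(21 * 18)
  expect_equal(sum(d[core] != 0), 3L)
})

test_that("total mass changes only by synthesis minus fecal loss", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    x <- empty_state()
    x[1:378] <- stats::runif(378, 0, 100)
    t <- stats::runif(1, 0, 24)
    d <- ba_rhs(p, x, t)
    fecal_rate <- sum(d[379:399])
    expect_equal(
      sum(d[1:378]), p_values(p)[["k_u"]] - fecal_rate,
      tolerance = 1e-10
    )
  }
})

test_that("a bolus is fully recovered in feces when uptake is disabled", {
  p <- transit_only_params()
  x0 <- empty_state()
  x0[state_index("CA", "t", FALSE, "si_1")] <- 100
  end <- bilecirc:::simulate_span(p, x0, 0, 2000, out_times = 2000)[1, ]
  expect_equal(sum(end[379:399]), 100, tolerance = 1e-6)
  expect_equal(
    end[379 + state_index("CA", "t", FALSE, "li") - 1], 100,
    tolerance = 1e-6
  )
  expect_lt(sum(end[1:378]), 1e-4)
})

test_that("simulation matches the analytic linear-cascade solution", {
  # transit-only single species: si_1 and si_2 follow the two-compartment
  # cascade A1 = A0 exp(-kt), A2 = A0 k t exp(-kt)
  k <- 2.2
  p <- transit_only_params(k_si_alpha = k)
  a0 <- 100
  x0 <- empty_state()
  i1 <- state_index("CDCA", "g", FALSE, "si_1")
  i2 <- state_index("CDCA", "g", FALSE, "si_2")
  x0[i1] <- a0
  times <- c(0.1, 0.25, 0.5, 1, 2)
  mat <- bilecirc:::simulate_span(p, x0, 0, max(times), out_times = times)
  a1 <- a0 * exp(-k * times)
  a2 <- a0 * k * times * exp(-k * times)
  expect_equal(mat[, i1], a1, tolerance = 1e-6)
  expect_equal(mat[, i2], a2, tolerance = 1e-6)
})

test_that("trajectories stay non-negative and tidy output is consistent", {
  ss <- default_steady()
  traj <- ba_simulate(ba_params(), ss$state, days = 1, dt_h = 0.25)
  expect_true(all(traj$amount_umol >= 0))
  expect_equal(nrow(traj), 378L * length(unique(traj$time_h)))
  # tidy long format agrees with the raw state matrix
  mat <- bilecirc:::trajectory_matrix(traj)
  row5 <- dplyr::filter(traj, time_h == 1)
  i <- state_index(
    row5$species, row5$conjugation, row5$sulfated, row5$compartment
  )
  expect_equal(row5$amount_umol, mat[5, i])
})

test_that("non-finite states are rejected with a located error", {
  x <- empty_state()
  x[state_index("DCA", "u", FALSE, "co_2")] <- NaN
  expect_error(ba_rhs(ba_params(), x, 0), "compartment")
})

test_that("trajectory CSV export round-trips", {
  x0 <- empty_state()
  x0[state_index("CA", "g", FALSE, "gb")] <- 50
  traj <- ba_simulate(ba_params(), x0, days = 1, dt_h = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$amount_umol, traj$amount_umol)
})
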