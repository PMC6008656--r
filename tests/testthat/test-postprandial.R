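test_that("peak extraction recovers an exact quadratic peak off-grid", {
  # parabola peaking at 90 min with height 3, sampled on a 30-min grid:
  # the quadratic refinement must recover the vertex exactly
  tg <- seq(0, 300, by = 30)
  rel <- 3 - ((tg - 90) / 120)^2
  curve <- tibble::new_tibble(
    tibble::tibble(time_min = tg, class = "total", conc_uM = rel, rel = rel),
    class = "ba_postprandial"
  )
  ch <- pp_characteristics(curve)
  expect_equal(ch$fold_peak, 3, tolerance = 1e-12)
  expect_equal(ch$t_peak_min, 90, tolerance = 1e-12)
  expect_equal(ch$fold_30min, rel[tg == 30])
  # a vertex between grid points is found too
  rel2 <- 2 - ((tg - 105) / 120)^2
  curve2 <- tibble::new_tibble(
    tibble::tibble(
      time_min = tg, class = "total", conc_uM = rel2, rel = rel2
    ),
    class = "ba_postprandial"
  )
  ch2 <- pp_characteristics(curve2)
  expect_equal(ch2$t_peak_min, 105, tolerance = 1e-12)
  expect_equal(ch2$fold_peak, 2, tolerance = 1e-12)
})

test_that("without propulsion, gallbladder content or secretion there is no rise", {
  p <- p_set(ba_params(), delta_SI = 0, k_xl = 0)
  x0 <- default_steady()$state
  # empty the gallbladder
  gb_cols <- (match("gb", ba_compartments()$id) - 1L) * 21L + 1:21
  x0[gb_cols] <- 0
  resp <- postprandial_response(p, x0, hours = 4)
  ch <- pp_characteristics(resp)
  # zeroing the gallbladder takes the state off its periodic orbit, so a
  # small fasting drift remains; the meal-driven rise (about 3-fold in
  # the intact model) must be gone
  expect_lte(max(ch$fold_peak), 1.05)
})

test_that("the calibrated model shows a strong early postprandial rise", {
  resp <- postprandial_response(ba_params(), default_steady()$state)
  ch <- pp_characteristics(resp)
  tot <- ch[ch$class == "total", ]
  expect_gt(tot$fold_peak, 2)
  expect_gt(tot$fold_30min, 1)
  expect_lt(tot$t_peak_min, 180)
  # conjugated bile acids respond more strongly than unconjugated
  expect_gt(
    ch$fold_peak[ch$class == "conjugated"],
    ch$fold_peak[ch$class == "unconjugated"]
  )
})

test_that("cholecystectomy empties the gallbladder at steady state", {
  ss <- periodic_steady_state(
    cholecystectomy(ba_params()),
    tol = 1e-5, x0 = default_steady()$state
  )
  gb_cols <- (match("gb", ba_compartments()$id) - 1L) * 21L + 1:21
  expect_equal(max(ss$state[gb_cols]), 0)
})

test_that("decomposition components sum to the total exactly", {
  set.seed(11)
  for (i in 1:3) {
    p <- random_params(scale = 0.2)
    ss <- periodic_steady_state(p, tol = 1e-4, max_days = 150)
    dec <- decompose_postprandial(p, ss$state, hours = 3, dt_min = 5)
    expect_equal(
      dec$total, dec$propulsion + dec$recycling + dec$gallbladder,
      tolerance = 1e-12
    )
    expect_equal(dec$total[1], 0)
  }
})

test_that("a model without propulsion has a zero propulsion component", {
  p <- p_set(ba_params(), delta_SI = 0)
  ss <- periodic_steady_state(p, tol = 1e-5, x0 = default_steady()$state)
  dec <- decompose_postprandial(p, ss$state, hours = 3, dt_min = 10)
  expect_equal(max(abs(dec$propulsion)), 0, tolerance = 1e-9)
})
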