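test_that("the elasticity formula reproduces hand-computed values", {
  p <- ba_params(k_u = 1)
  # output independent of the parameter
  s0 <- local_sensitivity(p,
    output = function(q) c(a = 5), parameters = "k_u",
    delta = 0.01
  )
  expect_identical(s0$S, 0)
  # linear output: elasticity 1 for any delta and any coefficient
  f_lin <- function(q) c(a = 3.7 * p_values(q)[["k_u"]])
  for (d in c(0.01, 0.05, 0.2)) {
    s1 <- local_sensitivity(p, output = f_lin, parameters = "k_u", delta = d)
    expect_equal(s1$S, 1, tolerance = 1e-12)
  }
  # quadratic output at p = 1, delta = 0.01: (0.0201 + 0.0199) / 0.02 = 2
  f_sq <- function(q) c(a = p_values(q)[["k_u"]]^2)
  s2 <- local_sensitivity(p, output = f_sq, parameters = "k_u", delta = 0.01)
  expect_equal(s2$S, 2, tolerance = 1e-12)
})

test_that("sensitivity is invariant to relabeling output components", {
  p <- ba_params()
  f1 <- function(q) {
    v <- p_values(q)
    c(a = v[["k_u"]], b = v[["k_u"]]^2, c = 2)
  }
  f2 <- function(q) rev(f1(q))
  s1 <- local_sensitivity(p, f1, parameters = "k_u", delta = 0.02)
  s2 <- local_sensitivity(p, f2, parameters = "k_u", delta = 0.02)
  expect_equal(s1$S, s2$S, tolerance = 1e-14)
})

test_that("zero output components are rejected by name", {
  p <- ba_params()
  expect_error(
    local_sensitivity(p, function(q) c(bad = 0), parameters = "k_u"),
    "bad"
  )
})

test_that("model-output sensitivities are step-robust", {
  p <- ba_params()
  s1 <- local_sensitivity(p,
    output = "fasting_plasma", parameters = "k_u",
    delta = 0.01, ss_tol = 1e-7
  )
  s2 <- local_sensitivity(p,
    output = "fasting_plasma", parameters = "k_u",
    delta = 0.005, ss_tol = 1e-7
  )
  expect_gt(s1$S, 0)
  expect_lt(abs(s1$S - s2$S) / s1$S, 0.1)
})

test_that("colonic transit controls the deoxycholate pool with the right sign", {
  p <- ba_params()
  x0 <- default_steady()$state
  dca_pool <- function(q) {
    ss <- periodic_steady_state(q, tol = 1e-6, x0 = x0)
    cfg <- ba_configurations()
    m <- matrix(ss$state[1:378], nrow = 21)
    sum(m[cfg$species == "DCA", ])
  }
  base <- dca_pool(p)
  # faster colonic transit (shorter colonic residence) shrinks the pool
  faster <- dca_pool(p_set(p, k_co = p_values(p)[["k_co"]] * 1.2))
  expect_lt(faster, base)
})
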