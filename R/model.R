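# State vector layout: 378 core amounts (21 configurations x 18
# compartments, compartment-major) followed by 29 cumulative-flux
# bookkeeping states integrated alongside the kinetics.
N_CONFIG <- 21L
N_COMP <- 18L
N_CORE <- N_CONFIG * N_COMP
N_STATE <- 407L
AUX_FECAL <- N_CORE + 1:21 # cumulative fecal output per configuration
AUX_SECR <- 400L # cumulative duodenal secretion (liver + gallbladder)
AUX_COIN <- 401L # cumulative si_10 -> co_1 flux
AUX_UPSI <- 402L # cumulative small-intestinal uptake
AUX_UPCO <- 403L # cumulative colonic uptake
AUX_TRANS <- 404:407 # cumulative CA->DCA, CDCA->LCA, CDCA->UDCA, UDCA->LCA

#' Index into the model state vector
#'
#' @param species,conjugation,sulfated Configuration (see
#'   [ba_configurations()]).
#' @param compartment Compartment id, e.g. `"li"` or `"si_3"`.
#' @return Integer position(s) in the 407-element state vector.
#' @export
#' @examples
#' state_index("CA", "t", FALSE, "si_1")
state_index <- function(species, conjugation = "u", sulfated = FALSE,
                        compartment = "li") {
  cfg <- ba_configurations()
  comp <- ba_compartments()
  n <- max(
    length(species), length(conjugation), length(sulfated),
    length(compartment)
  )
  species <- rep_len(species, n)
  conjugation <- rep_len(conjugation, n)
  sulfated <- rep_len(sulfated, n)
  compartment <- rep_len(compartment, n)
  ci <- match(
    paste(species, conjugation, sulfated),
    paste(cfg$species, cfg$conjugation, cfg$sulfated)
  )
  ki <- match(compartment, comp$id)
  if (anyNA(ci)) stop("invalid configuration", call. = FALSE)
  if (anyNA(ki)) stop("invalid compartment", call. = FALSE)
  (ki - 1L) * N_CONFIG + ci
}

#' Empty model state
#'
#' @return A zero state vector (407 entries: 378 amounts plus cumulative
#'   flux bookkeeping), in micromoles.
#' @export
empty_state <- function() {
  numeric(N_STATE)
}

state_names <- function() {
  cfg <- ba_configurations()
  comp <- ba_compartments()
  cfg_lab <- ifelse(cfg$sulfated, paste0(cfg$conjugation, "LCA_s"),
    paste0(cfg$conjugation, cfg$species)
  )
  core <- as.vector(outer(cfg_lab, comp$id, function(c, k) paste0(k, ".", c)))
  c(
    core, paste0("fecal.", cfg_lab),
    "cum_secretion", "cum_colon_inflow", "cum_uptake_si", "cum_uptake_co",
    "cum_CA_DCA", "cum_CDCA_LCA", "cum_CDCA_UDCA", "cum_UDCA_LCA"
  )
}

# the 35-element parameter vector handed to the compiled rhs
parms_vector <- function(params, t_last_meal = 0, forcing_on = 1) {
  c(unname(p_values(params)), t_last_meal, forcing_on)
}

# time of the most recent meal at or before absolute time t (hours).
# Meals recur daily at `meal_times(params)`. With periodic = FALSE, no
# meal precedes day 0's first meal (overnight-fasted start); with
# periodic = TRUE the daily schedule extends into the past.
last_meal_time <- function(t, params, periodic = TRUE) {
  meals <- meal_times(params)
  vapply(t, function(ti) {
    day <- floor(ti / 24)
    cand <- c((day - 1) * 24 + meals, day * 24 + meals)
    cand <- cand[cand <= ti + 1e-12]
    if (!periodic) cand <- cand[cand >= min(meals)]
    if (!length(cand)) -Inf else max(cand)
  }, 0)
}

#' Postprandial intestinal propulsion multiplier
#'
#' In response to a meal, small-intestinal transit is transiently
#' accelerated: both `k_si_alpha` and `k_si_beta` are multiplied by
#' `1 + delta_SI * exp(-beta_SI * (t - t_last_meal))`. Colonic transit is
#' not meal-modulated. Before any meal the multiplier is 1.
#'
#' @param params A [ba_params()] object.
#' @param t Time(s) in hours, non-negative.
#' @param periodic If `TRUE`, the daily meal schedule extends into the
#'   past (periodic day); if `FALSE` (default) the subject is fasted
#'   before day 0's first meal.
#' @return Dimensionless multiplier(s) `>= 1`.
#' @export
#' @examples
#' p <- ba_params(delta_SI = 0.5, beta_SI = log(2))
#' transit_multiplier(p, 1) # one hour after the t = 0 meal: 1.25
transit_multiplier <- function(params, t, periodic = FALSE) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  v <- p_values(params)
  tlm <- last_meal_time(t, params, periodic = periodic)
  ifelse(is.finite(tlm),
    1 + v[["delta_SI"]] * exp(-v[["beta_SI"]] * (t - tlm)),
    1
  )
}

# gallbladder postprandial emptying signal s_GB(t) in [0, 1]
gb_signal <- function(params, t, periodic = FALSE) {
  v <- p_values(params)
  tlm <- last_meal_time(t, params, periodic = periodic)
  ifelse(is.finite(tlm),
    v[["delta_GB"]] * exp(-v[["beta_GB"]] * (t - tlm)),
    0
  )
}

#' Evaluate the model right-hand side
#'
#' Direct evaluation of the time derivative of the state vector (compiled
#' core), mainly useful for structural checks such as mass-balance
#' identities.
#'
#' @param params A [ba_params()] object.
#' @param state Numeric state vector (407 entries, micromoles).
#' @param t Time in hours.
#' @param periodic Meal-history convention, see [transit_multiplier()].
#' @return The derivative vector, micromoles per hour.
#' @export
ba_rhs <- function(params, state, t = 0, periodic = TRUE) {
  stopifnot(length(state) == N_STATE)
  tlm <- last_meal_time(t, params, periodic = periodic)
  pv <- parms_vector(params,
    t_last_meal = if (is.finite(tlm)) tlm else 0,
    forcing_on = as.numeric(is.finite(tlm))
  )
  .Call("bilecirc_rhs_eval", as.numeric(t), as.numeric(state), pv,
    PACKAGE = "bilecirc"
  )
}

# Integrate from t0 to t1 (absolute hours), restarting at each meal so the
# exponential forcing is evaluated piecewise-smoothly. Returns the matrix
# of states at `out_times` (rows), which must lie within [t0, t1].
simulate_span <- function(params, state, t0, t1, out_times = t1,
                          periodic = TRUE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(t1 > t0, all(out_times >= t0 - 1e-9), all(out_times <= t1 + 1e-9))
  meals <- meal_times(params)
  occur <- sort(unique(as.vector(outer(
    (floor(t0 / 24) - 1):(ceiling(t1 / 24) + 1) * 24, meals, "+"
  ))))
  breaks <- sort(unique(c(t0, occur[occur > t0 + 1e-12 & occur < t1 - 1e-12], t1)))
  out <- matrix(NA_real_, length(out_times), N_STATE)
  done <- rep(FALSE, length(out_times))
  hit0 <- abs(out_times - t0) < 1e-9
  if (any(hit0)) {
    out[hit0, ] <- matrix(state, sum(hit0), N_STATE, byrow = TRUE)
    done[hit0] <- TRUE
  }
  y <- as.numeric(state)
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]
    b <- breaks[s + 1]
    tlm <- last_meal_time(a, params, periodic = periodic)
    pv <- parms_vector(params,
      t_last_meal = if (is.finite(tlm)) tlm else 0,
      forcing_on = as.numeric(is.finite(tlm))
    )
    sel <- !done & out_times > a + 1e-12 & out_times <= b + 1e-9
    tt <- sort(unique(c(a, out_times[sel], b)))
    sol <- deSolve::lsoda(
      y = y, times = tt, func = "bilecirc_derivs", parms = pv,
      dllname = "bilecirc", initfunc = "bilecirc_initmod",
      rtol = rtol, atol = atol, maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed on [", a, ", ", b, "] h", call. = FALSE)
    }
    states <- sol[, -1, drop = FALSE]
    neg <- min(states)
    if (neg < -1e-6) {
      stop("negative amount beyond tolerance (", signif(neg, 3),
        " umol) during integration",
        call. = FALSE
      )
    }
    states[states < 0] <- 0
    if (any(sel)) {
      idx <- match(round(out_times[sel], 9), round(tt, 9))
      out[sel, ] <- states[idx, , drop = FALSE]
      done[sel] <- TRUE
    }
    y <- states[nrow(states), ]
  }
  out
}

#' Simulate the model through the daily meal protocol
#'
#' Integrates the full 378-state kinetic system from a starting state over
#' one or more 24-h days, with meals at the schedule carried by `params`.
#' The stiff-capable solver restarts at each meal so the postprandial
#' forcing is handled cleanly.
#'
#' @param params A [ba_params()] object.
#' @param x0 Starting state (default: the periodic steady state is *not*
#'   sought here; a zero state is used). See [periodic_steady_state()].
#' @param days Number of days to simulate.
#' @param dt_h Output grid spacing in hours.
#' @param periodic Meal-history convention for times before the first
#'   meal, see [transit_multiplier()].
#' @param rtol,atol Solver tolerances (relative; absolute in micromoles).
#' @return A `ba_trajectory`: a tibble with columns `time_h`,
#'   `compartment`, `species`, `conjugation`, `sulfated`, `amount_umol`,
#'   carrying the raw state matrix as attribute `"state_matrix"` (rows =
#'   attribute `"times"`).
#' @export
ba_simulate <- function(params, x0 = NULL, days = 1, dt_h = 0.1,
                        periodic = TRUE, rtol = 1e-8, atol = 1e-10) {
  x0 <- x0 %||% empty_state()
  times <- seq(0, days * 24, by = dt_h)
  mat <- simulate_span(params, x0, 0, days * 24,
    out_times = times,
    periodic = periodic, rtol = rtol, atol = atol
  )
  as_ba_trajectory(mat, times)
}

as_ba_trajectory <- function(mat, times) {
  cfg <- ba_configurations()
  comp <- ba_compartments()
  grid <- tidyr::expand_grid(
    compartment = comp$id,
    cfg[, c("species", "conjugation", "sulfated")]
  )
  core <- mat[, seq_len(N_CORE), drop = FALSE]
  out <- tibble::tibble(
    time_h = rep(times, each = N_CORE),
    compartment = rep(grid$compartment, length(times)),
    species = rep(grid$species, length(times)),
    conjugation = rep(grid$conjugation, length(times)),
    sulfated = rep(grid$sulfated, length(times)),
    amount_umol = as.vector(t(core))
  )
  tibble::new_tibble(out,
    class = "ba_trajectory",
    state_matrix = mat, times = times
  )
}

trajectory_matrix <- function(trajectory) {
  attr(trajectory, "state_matrix")
}

trajectory_times <- function(trajectory) {
  attr(trajectory, "times")
}

#' Write a trajectory to CSV
#'
#' @param trajectory A [ba_simulate()] result.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(
    as.data.frame(trajectory[, c(
      "time_h", "compartment", "species",
      "conjugation", "sulfated", "amount_umol"
    )]),
    path,
    row.names = FALSE
  )
  invisible(path)
}

# total amounts per compartment group, from a state matrix
comp_total <- function(mat, compartment) {
  ki <- match(compartment, ba_compartments()$id)
  cols <- as.vector(outer(1:N_CONFIG, (ki - 1L) * N_CONFIG, "+"))
  rowSums(mat[, cols, drop = FALSE])
}
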