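#' 24-hour systemic flux summary
#'
#' Integrates the main whole-body fluxes over one periodic day and
#' expresses them relative to the 24-h duodenal secretion, defined as the
#' total amount of bile acids entering the duodenum from the liver
#' directly and from the gallbladder. Also reports the daily pool
#' turnover (secretion / total pool).
#'
#' @param params A [ba_params()] object.
#' @param x0 Periodic day-start state; computed if `NULL`.
#' @param ... Passed to [periodic_steady_state()] when `x0` is `NULL`.
#' @return A tibble of class `ba_fluxes` with columns `flux`,
#'   `umol_per_day` and `pct_secretion`, plus attribute
#'   `"turnover_per_day"`.
#' @export
flux_summary <- function(params, x0 = NULL, ...) {
  if (is.null(x0)) x0 <- periodic_steady_state(params, ...)$state
  end <- simulate_span(params, x0, 0, 24, out_times = 24, periodic = TRUE)[1, ]
  secretion <- end[AUX_SECR]
  if (secretion <= 0) stop("duodenal secretion is zero", call. = FALSE)
  v <- p_values(params)
  vals <- c(
    duodenal_secretion = secretion,
    si_to_colon = end[AUX_COIN],
    fecal_loss = sum(end[AUX_FECAL]),
    synthesis = v[["k_u"]] * 24,
    recycled_si = end[AUX_UPSI],
    recycled_colon = end[AUX_UPCO],
    recycled_total = end[AUX_UPSI] + end[AUX_UPCO]
  )
  pool <- sum(x0[seq_len(N_CORE)])
  tibble::new_tibble(
    tibble::tibble(
      flux = names(vals),
      umol_per_day = unname(vals),
      pct_secretion = 100 * unname(vals) / secretion
    ),
    class = "ba_fluxes",
    turnover_per_day = secretion / pool
  )
}

#' Instantaneous transit flux across an intestinal boundary
#'
#' Returns the first-order transit flux (amount in the upstream segment
#' times its meal-modulated transit rate) across a named boundary, over
#' the time span of a simulated trajectory.
#'
#' @param trajectory A [ba_simulate()] result.
#' @param params The parameter set used to produce the trajectory.
#' @param boundary One of `"si_2-si_3"`, `"si_5-si_6"`, `"si_8-si_9"`,
#'   `"si_10-co_1"`.
#' @param periodic Meal-history convention, see [transit_multiplier()].
#' @return A tibble with columns `time_h` and `flux_umol_h`.
#' @export
intestinal_flux_series <- function(trajectory, params,
                                   boundary = c(
                                     "si_2-si_3", "si_5-si_6",
                                     "si_8-si_9", "si_10-co_1"
                                   ),
                                   periodic = TRUE) {
  boundary <- match.arg(boundary)
  from <- sub("-.*", "", boundary)
  seg <- as.integer(sub("si_", "", from))
  rate_name <- if (seg <= 5) "k_si_alpha" else "k_si_beta"
  mat <- trajectory_matrix(trajectory)
  times <- trajectory_times(trajectory)
  amt <- comp_total(mat, from)
  m <- transit_multiplier(params, times, periodic = periodic)
  tibble::tibble(
    time_h = times,
    flux_umol_h = p_values(params)[[rate_name]] * m * amt
  )
}
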