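# Canonical observable ids, categories and weight groups. The calibration
# dataset uses exactly these ids; group_id drives the 1/group-size weights
# of the composition, conjugation and sulfation categories.
SPECIES6 <- c("CA", "CDCA", "DCA", "UDCA", "LCA", "O")
CONJ3 <- c("u", "g", "t")

observable_index <- function() {
  comp_pools <- c("plasma", "portal", "liver", "gallbladder", "feces")
  rows <- list()
  for (pool in comp_pools) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = paste0("composition_", pool, "_", SPECIES6),
      category = "composition", group_id = paste0("comp_", pool)
    )
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = paste0("composition_synthesis_", c("CA", "CDCA", "O")),
    category = "composition", group_id = "comp_synthesis"
  )
  for (pool in c("plasma", "bile", "liver", "feces")) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = paste0("conjugation_", pool, "_", CONJ3),
      category = "conjugation", group_id = paste0("conj_", pool)
    )
  }
  sulf <- c(
    "sulfation_LCA_plasma", "sulfation_LCA_bile", "sulfation_LCA_feces",
    "sulfation_total_plasma", "sulfation_total_bile", "sulfation_total_feces"
  )
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = sulf, category = "sulfation", group_id = sulf
  )
  pools <- paste0("pool_", c(
    "total", "CA", "CDCA", "DCA", "plasma", "portal", "liver", "gallbladder"
  ))
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = pools, category = "pools", group_id = pools
  )
  fluxes <- c(
    "flux_synthesis", "flux_biliary_output", "fcr_CA", "fcr_CDCA", "fcr_DCA"
  )
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = fluxes, category = "fluxes", group_id = fluxes
  )
  pp <- as.vector(outer(
    c("fold30", "foldpeak", "tpeak"), c("total", "conj", "unconj"),
    function(q, cl) paste0("pp_", cl, "_", q)
  ))
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = pp, category = "postprandial", group_id = pp
  )
  tr <- c("transit_si_fasting", "transit_si_postprandial", "transit_colon")
  rows[[length(rows) + 1]] <- tibble::tibble(
    id = tr, category = "transit", group_id = tr
  )
  dplyr::bind_rows(rows)
}

# per-configuration absorbed flux (umol/h) at a given state: passive
# uptake of unconjugated forms everywhere plus shared-carrier active
# uptake in si_9/si_10. Used for portal-blood observables (the model has
# no explicit portal compartment; the instantaneous absorbed-flux
# composition stands in for portal blood).
absorbed_flux <- function(params, state) {
  v <- p_values(params)
  cfg <- ba_configurations()
  comp <- ba_compartments()
  m <- matrix(state[seq_len(N_CORE)], nrow = N_CONFIG) # config x compartment
  si_cols <- match(paste0("si_", 1:10), comp$id)
  co_cols <- match(paste0("co_", 1:5), comp$id)
  fac <- ifelse(cfg$conjugation == "u", ifelse(cfg$sulfated, 0.5, 1), 0)
  flux <- fac * (
    v[["k_up"]] * rowSums(m[, si_cols, drop = FALSE]) +
      v[["k_up_co"]] * rowSums(m[, co_cols, drop = FALSE])
  )
  for (j in match(paste0("si_", 9:10), comp$id)) {
    tot <- sum(m[, j])
    if (tot > 0) flux <- flux + v[["Vmax"]] * m[, j] / (v[["Km"]] + tot)
  }
  flux
}

species_of <- function(cfg = ba_configurations()) cfg$species
conj_of <- function(cfg = ba_configurations()) cfg$conjugation

frac_by <- function(amounts, groups, levels) {
  tot <- sum(amounts)
  vapply(levels, function(l) {
    if (tot > 0) sum(amounts[groups == l]) / tot else 0
  }, 0)
}

#' Model observables aligned to the calibration dataset
#'
#' Computes, at the 24-h periodic steady state, the 76 observables the
#' calibration dataset targets: pool sizes; composition, conjugation and
#' sulfation fractions of the plasma, portal, liver, gallbladder (bile)
#' and fecal pools and of the synthesis flux; daily fluxes and fractional
#' catabolic rates; postprandial characteristics of the total, conjugated
#' and unconjugated plasma response; and intestinal transit times.
#' Species fractions count sulfated LCA as LCA; fractional catabolic
#' rates are daily irreversible losses (fecal plus colonic
#' transformation) divided by the species pool; small-intestinal transit
#' time is the sum of mean residence times over the ten segments, at the
#' fasting (multiplier 1) or maximally meal-stimulated (multiplier
#' `1 + delta_SI`) transit rate.
#'
#' @param params A [ba_params()] object.
#' @param x0 Periodic day-start state (warm start for the steady-state
#'   search is taken from here too); computed if `NULL`.
#' @param ss_tol,max_days Periodic steady-state settings.
#' @param pp_dt_min Postprandial grid resolution, minutes.
#' @return A tibble with columns `id`, `category`, `group_id`, `value`,
#'   carrying the steady state as attribute `"x0"`.
#' @export
ba_observables <- function(params, x0 = NULL, ss_tol = 1e-6,
                           max_days = 200, pp_dt_min = 1) {
  ss <- periodic_steady_state(params,
    tol = ss_tol, max_days = max_days,
    x0 = x0
  )
  x0 <- ss$state
  v <- p_values(params)
  cfg <- ba_configurations()
  comp <- ba_compartments()
  end <- simulate_span(params, x0, 0, 24, out_times = 24, periodic = TRUE)[1, ]
  m0 <- matrix(x0[seq_len(N_CORE)], nrow = N_CONFIG) # config x compartment
  fecal <- end[AUX_FECAL]
  trans <- end[AUX_TRANS]
  portal_flux <- absorbed_flux(params, x0)

  pool_amt <- list(
    plasma = m0[, match("pl", comp$id)],
    portal = portal_flux,
    liver = m0[, match("li", comp$id)],
    gallbladder = m0[, match("gb", comp$id)],
    bile = m0[, match("gb", comp$id)],
    feces = fecal
  )
  val <- c()
  for (pool in c("plasma", "portal", "liver", "gallbladder", "feces")) {
    val[paste0("composition_", pool, "_", SPECIES6)] <-
      frac_by(pool_amt[[pool]], cfg$species, SPECIES6)
  }
  f_o <- max(0, 1 - v[["f_CA"]] - v[["f_CDCA"]])
  val[paste0("composition_synthesis_", c("CA", "CDCA", "O"))] <-
    c(v[["f_CA"]], v[["f_CDCA"]], f_o)
  for (pool in c("plasma", "bile", "liver", "feces")) {
    val[paste0("conjugation_", pool, "_", CONJ3)] <-
      frac_by(pool_amt[[pool]], cfg$conjugation, CONJ3)
  }
  lca_sulf <- function(amt) {
    lca <- sum(amt[cfg$species == "LCA"])
    if (lca > 0) sum(amt[cfg$sulfated]) / lca else 0
  }
  tot_sulf <- function(amt) {
    tot <- sum(amt)
    if (tot > 0) sum(amt[cfg$sulfated]) / tot else 0
  }
  val["sulfation_LCA_plasma"] <- lca_sulf(pool_amt$plasma)
  val["sulfation_LCA_bile"] <- lca_sulf(pool_amt$bile)
  val["sulfation_LCA_feces"] <- lca_sulf(pool_amt$feces)
  val["sulfation_total_plasma"] <- tot_sulf(pool_amt$plasma)
  val["sulfation_total_bile"] <- tot_sulf(pool_amt$bile)
  val["sulfation_total_feces"] <- tot_sulf(pool_amt$feces)

  sp_pool <- function(sp) sum(m0[cfg$species == sp, ])
  val["pool_total"] <- sum(m0)
  val["pool_CA"] <- sp_pool("CA")
  val["pool_CDCA"] <- sp_pool("CDCA")
  val["pool_DCA"] <- sp_pool("DCA")
  val["pool_plasma"] <- sum(pool_amt$plasma)
  val["pool_portal"] <- attr(params, "tau_portal") * sum(portal_flux)
  val["pool_liver"] <- sum(pool_amt$liver)
  val["pool_gallbladder"] <- sum(pool_amt$gallbladder)

  val["flux_synthesis"] <- v[["k_u"]] * 24
  val["flux_biliary_output"] <- end[AUX_SECR]
  fecal_sp <- function(sp) sum(fecal[cfg$species == sp])
  val["fcr_CA"] <- (fecal_sp("CA") + trans[1]) / max(sp_pool("CA"), 1e-12)
  val["fcr_CDCA"] <-
    (fecal_sp("CDCA") + trans[2] + trans[3]) / max(sp_pool("CDCA"), 1e-12)
  val["fcr_DCA"] <- fecal_sp("DCA") / max(sp_pool("DCA"), 1e-12)

  pp <- pp_characteristics(
    postprandial_response(params, x0, dt_min = pp_dt_min)
  )
  cls <- c(total = "total", conj = "conjugated", unconj = "unconjugated")
  for (short in names(cls)) {
    row <- pp[pp$class == cls[[short]], ]
    val[paste0("pp_", short, "_fold30")] <- row$fold_30min
    val[paste0("pp_", short, "_foldpeak")] <- row$fold_peak
    val[paste0("pp_", short, "_tpeak")] <- row$t_peak_min
  }

  # Small-intestinal transit time: sum of segment mean residence times.
  # The postprandial value uses the propulsion multiplier averaged over a
  # 6-h inter-meal window (transit measurements integrate over the whole
  # postprandial period, not the instant of the meal).
  si_time <- 5 / v[["k_si_alpha"]] + 5 / v[["k_si_beta"]]
  t_win <- 6
  m_bar <- 1 + v[["delta_SI"]] *
    (1 - exp(-v[["beta_SI"]] * t_win)) / (v[["beta_SI"]] * t_win)
  val["transit_si_fasting"] <- si_time
  val["transit_si_postprandial"] <- si_time / m_bar
  val["transit_colon"] <- 5 / v[["k_co"]]

  idx <- observable_index()
  out <- idx
  out$value <- unname(val[idx$id])
  if (any(!is.finite(out$value))) {
    stop("non-finite observable(s): ",
      paste(out$id[!is.finite(out$value)], collapse = ", "),
      call. = FALSE
    )
  }
  attr(out, "x0") <- x0
  out
}
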