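# Canonical free-parameter table: name, default value, physiological bounds,
# unit. Defaults are the package's calibrated estimates on the packaged
# calibration dataset; bounds are the physiological ranges used by the
# bounded optimizer. psi_u's lower bound of 0.625 is literature-derived.
param_table <- function() {
  m <- matrix(c(
    "k_si_alpha", 3.90715, 0.5, 10, "1/h",
    "k_si_beta", 1.67483, 0.05, 5, "1/h",
    "k_co", 0.182152, 0.02, 1, "1/h",
    "delta_SI", 1.26154, 0, 10, "-",
    "beta_SI", 0.488253, 0.1, 10, "1/h",
    "delta_GB", 1, 0, 1, "-",
    "beta_GB", 0.536873, 0.1, 10, "1/h",
    "gamma_GB", 0.662868, 0, 1, "-",
    "k_xg", 10.7469, 0.05, 20, "1/h",
    "eps_GB", 0.0088303, 0, 0.5, "-",
    "k_xl", 5.09211, 0.5, 50, "1/h",
    "k_pl", 8.11791, 0.1, 100, "1/h",
    "k_u", 27.0727, 5, 100, "umol/h",
    "f_CA", 0.599372, 0.1, 0.8, "-",
    "f_CDCA", 0.344591, 0.1, 0.8, "-",
    "f_gly", 0.73552, 0.3, 0.95, "-",
    "k_conj", 17.9443, 0.5, 100, "1/h",
    "k_sulf", 0.0852745, 0, 5, "1/h",
    "psi_tri", 0.910722, 0.5, 0.999, "-",
    "psi_di", 0.866923, 0.4, 0.999, "-",
    "psi_mono", 0.955456, 0.2, 0.999, "-",
    "psi_u", 0.66258, 0.625, 1, "-",
    "psi_sulf", 0.678471, 0.05, 1, "-",
    "Vmax", 5547.52, 100, 20000, "umol/h",
    "Km", 657.286, 10, 5000, "umol",
    "k_up", 0.0010004, 0.001, 1, "1/h",
    "k_up_co", 0.0256537, 0.001, 0.5, "1/h",
    "k_dec_si", 0.0100004, 0.01, 5, "1/h",
    "k_dec_co", 0.180424, 0.05, 20, "1/h",
    "k_CA_DCA", 0.133826, 0.01, 5, "1/h",
    "k_CDCA_LCA", 0.01, 0.01, 5, "1/h",
    "k_CDCA_UDCA", 0.0295237, 0.001, 2, "1/h",
    "k_UDCA_LCA", 0.01, 0.01, 5, "1/h"
  ), ncol = 5, byrow = TRUE)
  tibble::tibble(
    name = m[, 1],
    value = as.numeric(m[, 2]),
    lower = as.numeric(m[, 3]),
    upper = as.numeric(m[, 4]),
    unit = m[, 5]
  )
}

# parameters that are fractions (linear profile grids; others log-spaced)
fraction_params <- function() {
  c(
    "delta_GB", "gamma_GB", "eps_GB", "f_CA", "f_CDCA", "f_gly",
    "psi_tri", "psi_di", "psi_mono", "psi_u", "psi_sulf"
  )
}

#' Model parameter set
#'
#' Constructs the set of 33 free kinetic parameters (with physiological
#' bounds and units) plus fixed constants. Defaults are the package's
#' calibrated estimates; any parameter can be overridden by name. Fixed
#' constants are the plasma distribution volume `V_pl` (L, used only to
#' report concentrations), the portal transit time `tau_portal` (h, used
#' only to report a portal pool from the instantaneous absorbed flux) and
#' the daily meal times (h; meals at 0, 6 and 12 h give the 6, 6 and 12 h
#' inter-meal intervals of the simulated day).
#'
#' @param ... Named parameter overrides, e.g. `ba_params(k_u = 30)`.
#' @param values Optional named numeric vector of overrides (applied
#'   before `...`).
#' @param meal_times_h Meal times within the 24-h day, hours.
#' @param V_pl Plasma volume in litres.
#' @return A tibble of class `ba_params` with columns `name`, `value`,
#'   `lower`, `upper`, `unit`, carrying the constants as attributes.
#' @export
#' @examples
#' p <- ba_params(delta_SI = 2)
#' p_values(p)[["delta_SI"]]
ba_params <- function(..., values = NULL, meal_times_h = c(0, 6, 12),
                      V_pl = 3.5) {
  tab <- param_table()
  over <- c(values, unlist(list(...)))
  if (length(over)) {
    bad <- setdiff(names(over), tab$name)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    tab$value[match(names(over), tab$name)] <- as.numeric(over)
  }
  new_ba_params(tab,
    meal_times_h = sort(meal_times_h), V_pl = V_pl,
    tau_portal = 0.012
  )
}

new_ba_params <- function(tab, meal_times_h, V_pl, tau_portal = 0.012) {
  out <- tibble::new_tibble(tab,
    class = "ba_params",
    meal_times_h = meal_times_h, V_pl = V_pl, tau_portal = tau_portal
  )
  validate_ba_params(out)
  out
}

# Structural validity: non-negative rates, fractions in [0, 1], synthesis
# fractions summing to at most 1. Physiological *bounds* are data carried
# alongside (used by the optimizer and by in_bounds()); deliberately
# out-of-bounds counterfactuals such as k_xl = 0 remain simulable.
validate_ba_params <- function(params) {
  stopifnot(nrow(params) == 33L)
  vals <- stats::setNames(params$value, params$name)
  if (any(vals < 0)) {
    stop("negative parameter value(s): ",
      paste(names(vals)[vals < 0], collapse = ", "),
      call. = FALSE
    )
  }
  fr <- vals[fraction_params()]
  if (any(fr > 1 + 1e-12)) {
    stop("fraction parameter(s) above 1: ",
      paste(names(fr)[fr > 1 + 1e-12], collapse = ", "),
      call. = FALSE
    )
  }
  if (vals[["f_CA"]] + vals[["f_CDCA"]] > 1 + 1e-9) {
    stop("f_CA + f_CDCA must not exceed 1", call. = FALSE)
  }
  invisible(params)
}

#' Are all parameters within their physiological bounds?
#'
#' @param params A [ba_params()] object.
#' @return Logical scalar.
#' @export
in_bounds <- function(params) {
  all(params$value >= params$lower - 1e-12 &
    params$value <= params$upper + 1e-12)
}

#' @export
print.ba_params <- function(x, ...) {
  cat("<ba_params> 33 free parameters; meals at ",
    paste(attr(x, "meal_times_h"), collapse = ", "), " h; V_pl = ",
    attr(x, "V_pl"), " L\n",
    sep = ""
  )
  NextMethod()
}

#' Accessors for parameter sets
#'
#' `p_values()` returns the named numeric vector of free-parameter values;
#' `p_set()` returns a modified copy; `p_bounds()` the lower/upper bounds;
#' `meal_times()` the daily meal schedule.
#'
#' @param params A [ba_params()] object.
#' @param ... Named replacements for `p_set()`.
#' @export
p_values <- function(params) {
  stats::setNames(params$value, params$name)
}

#' @rdname p_values
#' @export
p_set <- function(params, ...) {
  over <- unlist(list(...))
  bad <- setdiff(names(over), params$name)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params$value[match(names(over), params$name)] <- as.numeric(over)
  validate_ba_params(params)
  params
}

#' @rdname p_values
#' @export
p_bounds <- function(params) {
  list(
    lower = stats::setNames(params$lower, params$name),
    upper = stats::setNames(params$upper, params$name)
  )
}

#' @rdname p_values
#' @export
meal_times <- function(params) attr(params, "meal_times_h")

# replace the full value vector (names must match), without bounds clamping
# (used by the optimizer, which guarantees in-bounds proposals)
p_replace <- function(params, values) {
  stopifnot(all(names(values) %in% params$name))
  params$value[match(names(values), params$name)] <- as.numeric(values)
  params
}

#' In silico cholecystectomy
#'
#' Removes gallbladder storage from the model by setting the fraction of
#' hepatic biliary output diverted to the gallbladder (`gamma_GB`) to zero;
#' all other parameters are untouched. No post-surgical adaptation is
#' modelled.
#'
#' @param params A [ba_params()] object.
#' @return The modified parameter set.
#' @export
#' @examples
#' p_values(cholecystectomy(ba_params()))[["gamma_GB"]]
cholecystectomy <- function(params) {
  p_set(params, gamma_GB = 0)
}

#' Read and write parameter files
#'
#' Parameter files are YAML with blocks `free_parameters` (list of
#' name/value/lower/upper/unit), `constants` (`V_pl_L`, `tau_portal_h`)
#' and `meal_times_h`.
#'
#' @param path File path.
#' @param params A [ba_params()] object.
#' @return `read_params()` returns a [ba_params()] object;
#'   `write_params()` invisibly returns `path`.
#' @export
read_params <- function(path) {
  doc <- yaml::read_yaml(path)
  fp <- doc$free_parameters
  tab <- tibble::tibble(
    name = vapply(fp, `[[`, "", "name"),
    value = vapply(fp, function(x) as.numeric(x$value), 0),
    lower = vapply(fp, function(x) as.numeric(x$lower), 0),
    upper = vapply(fp, function(x) as.numeric(x$upper), 0),
    unit = vapply(fp, `[[`, "", "unit")
  )
  canon <- param_table()$name
  if (!setequal(tab$name, canon)) {
    stop("parameter file must define exactly the 33 canonical parameters",
      call. = FALSE
    )
  }
  tab <- tab[match(canon, tab$name), ]
  new_ba_params(tab,
    meal_times_h = sort(as.numeric(doc$meal_times_h %||% c(0, 6, 12))),
    V_pl = as.numeric(doc$constants$V_pl_L %||% 3.5),
    tau_portal = as.numeric(doc$constants$tau_portal_h %||% 0.012)
  )
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  doc <- list(
    free_parameters = purrr::pmap(
      params[, c("name", "value", "lower", "upper", "unit")], list
    ),
    constants = list(
      V_pl_L = attr(params, "V_pl"),
      tau_portal_h = attr(params, "tau_portal")
    ),
    meal_times_h = as.list(meal_times(params))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
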