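# local sensitivity (finite-difference elasticity) and profile likelihood

# Built-in model output vectors for sensitivity analysis. Each returns a
# function(params) -> named numeric vector; steady-state searches warm
# start from a shared cache so the +/- perturbed evaluations are cheap.
sensitivity_output <- function(output, cds = NULL, ss_tol = 1e-6,
                               max_days = 250) {
  cache <- new.env(parent = emptyenv())
  cache$x0 <- NULL
  with_ss <- function(fn) {
    function(params) {
      ss <- periodic_steady_state(params,
        tol = ss_tol, max_days = max_days, x0 = cache$x0
      )
      cache$x0 <- ss$state
      fn(params, ss$state)
    }
  }
  cfg <- ba_configurations()
  pl_cols <- (match("pl", ba_compartments()$id) - 1L) * N_CONFIG +
    seq_len(N_CONFIG)
  switch(output,
    fasting_plasma = with_ss(function(params, x0) {
      c(fasting_plasma_uM = sum(x0[pl_cols]) / attr(params, "V_pl"))
    }),
    plasma_composition = with_ss(function(params, x0) {
      amt <- x0[pl_cols]
      f <- frac_by(amt, cfg$species, setdiff(SPECIES6, "O"))
      stats::setNames(f, paste0("plasma_frac_", setdiff(SPECIES6, "O")))
    }),
    plasma_conjugation = with_ss(function(params, x0) {
      amt <- x0[pl_cols]
      stats::setNames(
        frac_by(amt, cfg$conjugation, CONJ3),
        paste0("plasma_conj_", CONJ3)
      )
    }),
    postprandial = with_ss(function(params, x0) {
      r <- postprandial_response(params, x0, hours = 6, dt_min = 5)
      r <- r[r$class == "total", ]
      stats::setNames(r$rel, paste0("rel_t", r$time_min))
    }),
    dca_pool = with_ss(function(params, x0) {
      m0 <- matrix(x0[seq_len(N_CORE)], nrow = N_CONFIG)
      c(dca_pool_umol = sum(m0[cfg$species == "DCA", ]))
    }),
    nsse = {
      if (is.null(cds)) stop("output \"nsse\" requires a cds", call. = FALSE)
      function(params) {
        obs <- ba_observables(params,
          x0 = cache$x0, ss_tol = ss_tol,
          max_days = max_days
        )
        cache$x0 <- attr(obs, "x0")
        by_cat <- ba_nsse_by_category(cds, observables = obs)
        stats::setNames(by_cat$nsse, paste0("nsse_", by_cat$category))
      }
    },
    stop("unknown sensitivity output: ", output, call. = FALSE)
  )
}

#' Local parameter sensitivity (finite-difference elasticity)
#'
#' For each parameter, the model output vector `f` is evaluated at the
#' unperturbed parameters and with the parameter scaled by `1 + delta`
#' and `1 - delta`; the sensitivity is the mean, over output components,
#' of the two absolute relative changes divided by `2 * delta`:
#' `S = sum_j (|f_j(p) - f_j(p+)| + |f_j(p) - f_j(p-)|) / f_j(p) /
#' (2 * delta * N_f)`. A linear dependence `f = c * p_k` therefore gives
#' `S = 1` for any `delta`.
#'
#' @param params A [ba_params()] object (evaluation point).
#' @param output Either a function `params -> named numeric vector`, or
#'   the name of a built-in output: `"fasting_plasma"`,
#'   `"plasma_composition"`, `"plasma_conjugation"`, `"postprandial"`
#'   (relative total-plasma curve, 5-min grid over 0-6 h), `"dca_pool"`,
#'   or `"nsse"` (per-category objective; requires `cds`).
#' @param parameters Parameter names to perturb (default: all 33).
#' @param delta Relative perturbation (default 0.01).
#' @param cds Calibration dataset, for `output = "nsse"`.
#' @param ss_tol,max_days Steady-state settings for built-in outputs.
#' @return A tibble of class `ba_sensitivity` with columns `parameter`,
#'   `output`, `S`, `delta`.
#' @export
local_sensitivity <- function(params, output = "fasting_plasma",
                              parameters = NULL, delta = 0.01, cds = NULL,
                              ss_tol = 1e-6, max_days = 250) {
  stopifnot(delta > 0)
  out_name <- if (is.character(output)) output else "custom"
  f <- if (is.character(output)) {
    sensitivity_output(output, cds = cds, ss_tol = ss_tol,
      max_days = max_days
    )
  } else {
    output
  }
  parameters <- parameters %||% params$name
  f0 <- f(params)
  if (any(f0 == 0)) {
    stop("zero output component(s) (division by f_j): ",
      paste(names(f0)[f0 == 0], collapse = ", "),
      call. = FALSE
    )
  }
  n_f <- length(f0)
  v <- p_values(params)
  fracs <- fraction_params()
  S <- vapply(parameters, function(pk) {
    # perturbed values are clipped to the structural domain (fractions
    # cannot exceed 1), and the normalization uses the relative step
    # actually applied, so the index stays well defined for parameters
    # sitting exactly on a structural boundary (interior parameters
    # reduce to the plain two-sided formula)
    up_v <- v[[pk]] * (1 + delta)
    dn_v <- v[[pk]] * (1 - delta)
    if (pk %in% fracs) up_v <- min(up_v, 1)
    up <- f(p_replace(params, stats::setNames(up_v, pk)))
    dn <- f(p_replace(params, stats::setNames(dn_v, pk)))
    step <- if (v[[pk]] > 0) (up_v - dn_v) / v[[pk]] else 2 * delta
    sum((abs(f0 - up) + abs(f0 - dn)) / abs(f0)) / (step * n_f)
  }, 0)
  tibble::new_tibble(
    tibble::tibble(
      parameter = parameters, output = out_name, S = unname(S),
      delta = delta
    ),
    class = "ba_sensitivity"
  )
}

#' Determinants of the deoxycholate pool
#'
#' Ranks all 33 parameters by the local sensitivity of the total DCA pool
#' size at the periodic steady state; the distal intestinal transit
#' parameters are expected near the top.
#'
#' @inheritParams local_sensitivity
#' @return A `ba_sensitivity` tibble sorted by decreasing `S`, with an
#'   added `rank` column.
#' @export
dca_pool_determinants <- function(params, delta = 0.01, ss_tol = 1e-6,
                                  max_days = 250) {
  res <- local_sensitivity(params,
    output = "dca_pool", delta = delta,
    ss_tol = ss_tol, max_days = max_days
  )
  res <- dplyr::arrange(res, dplyr::desc(.data$S))
  res$rank <- seq_len(nrow(res))
  res
}

#' Profile likelihood of a parameter
#'
#' Identifiability diagnostic: the parameter is fixed at each grid value
#' in turn and all remaining free parameters are reoptimized, giving the
#' minimum achievable objective as a function of the fixed value. Grids
#' are walked outward from the optimum with warm starts from the
#' neighbouring solution. A steep profile marks an identifiable
#' parameter; a flat region marks practical non-identifiability.
#'
#' @param cds A CDS tibble.
#' @param params Optimized [ba_params()] (the profile anchor).
#' @param parameter Name of the profiled parameter.
#' @param grid Fixed values to profile at. Default: `n_side` points per
#'   side of the optimum spanning the bounds (log-spaced for rates,
#'   linear for fractions), plus the optimum itself.
#' @param n_side Grid points per side when `grid` is `NULL`.
#' @param maxiter,n_starts,ss_tol Passed to the inner [ba_fit()] refits.
#' @return A tibble of class `ba_profile` with columns `parameter`,
#'   `value`, `nsse`, `ok`.
#' @export
profile_likelihood <- function(cds, params, parameter, grid = NULL,
                               n_side = 11, maxiter = 10, n_starts = 1,
                               ss_tol = 1e-5) {
  stopifnot(parameter %in% params$name)
  v_opt <- p_values(params)[[parameter]]
  row <- params[params$name == parameter, ]
  if (is.null(grid)) {
    linear <- parameter %in% fraction_params() || row$lower <= 0
    span <- function(a, b, n) {
      if (n < 1 || abs(b - a) < 1e-12) {
        return(numeric(0))
      }
      if (linear) {
        seq(a, b, length.out = n + 1)[-1]
      } else {
        exp(seq(log(a), log(b), length.out = n + 1))[-1]
      }
    }
    grid <- c(rev(span(v_opt, row$lower + (row$lower <= 0) * 1e-6, n_side)),
      v_opt, span(v_opt, row$upper, n_side)
    )
  }
  grid <- sort(unique(grid))
  i_opt <- which.min(abs(grid - v_opt))
  free <- setdiff(params$name, parameter)
  run_side <- function(idx) {
    p_warm <- params
    out <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      gv <- grid[idx[k]]
      p_try <- p_replace(p_warm, stats::setNames(gv, parameter))
      fit <- tryCatch(
        ba_fit(cds, p_try,
          n_starts = n_starts, free = free,
          maxiter = maxiter, ss_tol = ss_tol
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        out[[k]] <- tibble::tibble(value = gv, nsse = NA_real_, ok = FALSE)
      } else {
        out[[k]] <- tibble::tibble(value = gv, nsse = fit$nsse, ok = TRUE)
        p_warm <- fit$params
      }
    }
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(
    run_side(i_opt:1),
    if (i_opt < length(grid)) run_side((i_opt + 1):length(grid))
  )
  res <- dplyr::arrange(dplyr::distinct(res, .data$value, .keep_all = TRUE),
    .data$value
  )
  tibble::new_tibble(
    tibble::tibble(parameter = parameter, res),
    class = "ba_profile"
  )
}
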