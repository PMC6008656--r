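# calibration: weighted normalized least squares against the CDS

# weight per CDS entry: 1 for pools/fluxes/postprandial/transit, 1/group
# size for composition, conjugation and sulfation, so a composition
# vector carries the same total weight as a single scalar target.
# group_size is data carried with each entry (so weights are unchanged
# when a subset of entries is evaluated); it is recomputed from the
# group layout only when the column is absent.
cds_weights <- function(cds) {
  gs <- cds[["group_size"]]
  if (is.null(gs)) {
    grp_sizes <- table(cds$group_id)
    gs <- as.numeric(grp_sizes[cds$group_id])
  }
  ifelse(
    cds$category %in% c("composition", "conjugation", "sulfation"),
    1 / gs,
    1
  )
}

# weighted relative residuals w_i * (y_i - d_i) / d_i aligned by id
cds_residuals <- function(cds, observables) {
  y <- observables$value[match(cds$id, observables$id)]
  if (anyNA(y)) {
    stop("observables missing CDS entries: ",
      paste(cds$id[is.na(y)], collapse = ", "),
      call. = FALSE
    )
  }
  cds_weights(cds) * (y - cds$value) / cds$value
}

#' Normalized sum of squared errors against a calibration dataset
#'
#' The calibration objective: the sum over CDS entries of the squared
#' weighted relative deviation of the model observable from its target,
#' with weight 1 for pool, flux, postprandial and transit entries and
#' 1/(group size) for composition, conjugation and sulfation entries so
#' that fraction vectors are not over-weighted.
#'
#' @param cds A CDS tibble (see [read_cds()]).
#' @param params A [ba_params()] object; ignored when `observables` is
#'   supplied.
#' @param observables Optionally, a precomputed [ba_observables()] table.
#' @param validate Validate `cds` first (disable for toy datasets when
#'   exercising the objective arithmetic alone).
#' @param ... Passed to [ba_observables()].
#' @return The scalar objective value (dimensionless, `>= 0`).
#' @export
ba_nsse <- function(cds, params = NULL, observables = NULL,
                    validate = TRUE, ...) {
  if (validate) validate_cds(cds)
  if (is.null(observables)) {
    observables <- ba_observables(params, ...)
  }
  sum(cds_residuals(cds, observables)^2)
}

#' Per-category decomposition of the calibration objective
#'
#' @inheritParams ba_nsse
#' @return A tibble with columns `category` and `nsse`.
#' @export
ba_nsse_by_category <- function(cds, params = NULL, observables = NULL,
                                validate = TRUE, ...) {
  if (validate) validate_cds(cds)
  if (is.null(observables)) {
    observables <- ba_observables(params, ...)
  }
  r <- cds_residuals(cds, observables)
  tibble::tibble(
    category = names(split(r, cds$category)),
    nsse = vapply(split(r, cds$category), function(x) sum(x^2), 0)
  )
}

# Latin-hypercube parameter starts within bounds; rate-like parameters
# are sampled log-uniformly, fractions and zero-bounded amplitudes
# uniformly. f_CA + f_CDCA is rescaled to at most 0.95 where violated.
lhs_starts <- function(params, n, seed) {
  free <- params$name
  lower <- params$lower
  upper <- params$upper
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )
  set.seed(seed)
  u <- lhs::randomLHS(n, length(free))
  log_scale <- lower > 0 & !free %in% fraction_params()
  starts <- matrix(NA_real_, n, length(free), dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    starts[, j] <- if (log_scale[j]) {
      exp(log(lower[j]) + u[, j] * (log(upper[j]) - log(lower[j])))
    } else {
      lower[j] + u[, j] * (upper[j] - lower[j])
    }
  }
  if (all(c("f_CA", "f_CDCA") %in% free)) {
    s <- starts[, "f_CA"] + starts[, "f_CDCA"]
    fix <- s > 0.95
    starts[fix, "f_CA"] <- starts[fix, "f_CA"] * 0.95 / s[fix]
    starts[fix, "f_CDCA"] <- starts[fix, "f_CDCA"] * 0.95 / s[fix]
  }
  starts
}

#' Calibrate model parameters to a dataset
#'
#' Bounded multistart nonlinear least squares on the weighted relative
#' residuals of [ba_nsse()]: the current parameter values plus
#' `n_starts - 1` Latin-hypercube samples within bounds are each refined
#' by bounded Levenberg-Marquardt, and the best solution is returned.
#' Periodic steady states are warm-started along the optimization path,
#' which keeps the repeated model evaluations cheap. Reproducible for a
#' given seed.
#'
#' @param cds A CDS tibble.
#' @param params Starting [ba_params()] object (also the first start).
#' @param n_starts Number of starts (`>= 1`).
#' @param seed Integer seed for the Latin hypercube.
#' @param free Names of parameters to optimize; the rest stay fixed at
#'   their values in `params` (used for restricted refits and profile
#'   likelihood). Default: all 33.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param epsfcn Finite-difference step scale for the Jacobian; the
#'   default gives relative steps of about 1e-3, well above the
#'   steady-state solver noise in the observables.
#' @param ss_tol,max_days Periodic steady-state settings for model
#'   evaluations.
#' @param verbose Print per-start progress.
#' @return An object of class `ba_fit`: a list with elements `params`
#'   (best-fit parameter set), `nsse`, `start_results` (tibble of all
#'   starts), `free`, `cds`.
#' @export
ba_fit <- function(cds, params = ba_params(), n_starts = 20, seed = 1,
                   free = NULL, maxiter = 30, epsfcn = 1e-6,
                   ss_tol = 1e-6, max_days = 250, verbose = FALSE) {
  validate_cds(cds)
  stopifnot(n_starts >= 1)
  free <- free %||% params$name
  stopifnot(all(free %in% params$name))
  bounds <- p_bounds(params)
  n_res <- nrow(cds) + 1L # +1: synthesis-fraction feasibility penalty

  cache <- new.env(parent = emptyenv())
  cache$x0 <- NULL
  resid_fn <- function(theta) {
    p <- p_replace(params, stats::setNames(theta, free))
    v <- p_values(p)
    pen <- 1e3 * max(0, v[["f_CA"]] + v[["f_CDCA"]] - 1)
    if (pen > 0) {
      p <- p_replace(p, c(
        f_CA = v[["f_CA"]] / (v[["f_CA"]] + v[["f_CDCA"]]),
        f_CDCA = v[["f_CDCA"]] / (v[["f_CA"]] + v[["f_CDCA"]])
      ))
    }
    obs <- tryCatch(
      ba_observables(p,
        x0 = cache$x0, ss_tol = ss_tol,
        max_days = max_days
      ),
      error = function(e) NULL
    )
    if (is.null(obs)) {
      return(rep(1e3, n_res))
    }
    cache$x0 <- attr(obs, "x0")
    c(cds_residuals(cds, obs), pen)
  }

  starts <- lhs_starts(params[params$name %in% free, ], n_starts, seed)
  starts[1, ] <- p_values(params)[free]
  results <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    cache$x0 <- NULL
    # iteration-cap warnings are expected for deliberately short refits;
    # convergence status is recorded in start_results instead
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = starts[i, ], lower = bounds$lower[free],
        upper = bounds$upper[free], fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = maxiter, epsfcn = epsfcn, nprint = 0
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      results[[i]] <- tibble::tibble(
        start = i, nsse = NA_real_, converged = FALSE, message = "failed"
      )
      next
    }
    nsse_i <- sum(resid_fn(fit$par)^2)
    results[[i]] <- tibble::tibble(
      start = i, nsse = nsse_i, converged = fit$info %in% 1:4,
      message = fit$message
    )
    if (verbose) {
      message(sprintf("start %d/%d: nSSE = %.4g", i, n_starts, nsse_i))
    }
    if (is.null(best) || (is.finite(nsse_i) && nsse_i < best$nsse)) {
      best <- list(par = fit$par, nsse = nsse_i)
    }
  }
  if (is.null(best)) {
    stop("all optimization starts failed to evaluate", call. = FALSE)
  }
  p_opt <- p_replace(params, stats::setNames(best$par, free))
  structure(
    list(
      params = p_opt, nsse = best$nsse,
      start_results = dplyr::bind_rows(results),
      free = free, cds = cds
    ),
    class = "ba_fit"
  )
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(
    "<ba_fit> nSSE =", signif(x$nsse, 5), "over", nrow(x$cds),
    "targets;", length(x$free), "free parameter(s),",
    nrow(x$start_results), "start(s)\n"
  )
  invisible(x)
}

#' Tidy a fitted calibration
#'
#' @param x A [ba_fit()] object.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `lower`,
#'   `upper`, `unit`, `at_bound`.
#' @export
tidy.ba_fit <- function(x, ...) {
  p <- x$params[x$params$name %in% x$free, ]
  tibble::tibble(
    term = p$name, estimate = p$value, lower = p$lower, upper = p$upper,
    unit = p$unit,
    at_bound = dplyr::case_when(
      abs(p$value - p$lower) < 1e-8 * pmax(abs(p$lower), 1) ~ "lower",
      abs(p$value - p$upper) < 1e-8 * pmax(abs(p$upper), 1) ~ "upper",
      TRUE ~ "no"
    )
  )
}

#' @rdname tidy.ba_fit
#' @return `glance()`: a one-row tibble with `nsse`, `n_obs`, `n_free`,
#'   `n_starts`, `n_converged`.
#' @export
glance.ba_fit <- function(x, ...) {
  tibble::tibble(
    nsse = x$nsse, n_obs = nrow(x$cds), n_free = length(x$free),
    n_starts = nrow(x$start_results),
    n_converged = sum(x$start_results$converged, na.rm = TRUE)
  )
}
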