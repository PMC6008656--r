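#' Postprandial plasma bile acid response
#'
#' Simulates from the first meal of the day (taken from the fasting state
#' `x0`) and returns the plasma total bile acid concentration relative to
#' its fasting value, on a dense grid, for the total pool and for the
#' conjugated and unconjugated fractions.
#'
#' @param params A [ba_params()] object.
#' @param x0 Fasting day-start state, normally
#'   `periodic_steady_state(params)$state`. If `NULL` it is computed.
#' @param hours Duration of the simulated response window.
#' @param dt_min Output grid spacing in minutes (peak detection
#'   resolution).
#' @param ... Passed to [periodic_steady_state()] when `x0` is `NULL`.
#' @return A tibble of class `ba_postprandial` with columns `time_min`,
#'   `class` (`"total"`, `"conjugated"`, `"unconjugated"`), `conc_uM` and
#'   `rel` (concentration / fasting concentration).
#' @export
postprandial_response <- function(params, x0 = NULL, hours = 6,
                                  dt_min = 1, ...) {
  if (is.null(x0)) x0 <- periodic_steady_state(params, ...)$state
  t_meal <- min(meal_times(params))
  times <- t_meal + seq(0, hours, by = dt_min / 60)
  mat <- simulate_span(params, x0, t_meal, t_meal + hours,
    out_times = times, periodic = TRUE
  )
  plasma_curves(mat, times - t_meal, attr(params, "V_pl"))
}

plasma_curves <- function(mat, rel_times, V_pl) {
  cfg <- ba_configurations()
  pl0 <- (match("pl", ba_compartments()$id) - 1L) * N_CONFIG
  cols <- pl0 + seq_len(N_CONFIG)
  pl <- mat[, cols, drop = FALSE]
  tot <- rowSums(pl)
  unconj <- rowSums(pl[, cfg$conjugation == "u", drop = FALSE])
  conj <- tot - unconj
  curves <- list(total = tot, conjugated = conj, unconjugated = unconj)
  out <- purrr::imap_dfr(curves, function(amt, cl) {
    if (!all(is.finite(amt))) {
      stop("non-finite plasma curve for class ", cl, call. = FALSE)
    }
    base <- amt[1]
    tibble::tibble(
      time_min = rel_times * 60,
      class = cl,
      conc_uM = amt / V_pl,
      rel = if (base > 0) amt / base else rep(NA_real_, length(amt))
    )
  })
  tibble::new_tibble(out, class = "ba_postprandial")
}

#' Postprandial characteristics of a response curve
#'
#' Extracts, per class, the relative concentration 30 min after the meal,
#' the relative height of the postprandial peak, and the time of the peak
#' in minutes. The peak is located on the sampling grid (earliest time on
#' ties; the fasting time point itself is excluded) and refined by
#' quadratic interpolation through the three points around the maximum,
#' which gives sub-grid resolution and keeps the peak characteristics
#' smooth in the parameters.
#'
#' @param response A [postprandial_response()] result.
#' @return A tibble with columns `class`, `fold_30min`, `fold_peak`,
#'   `t_peak_min`.
#' @export
pp_characteristics <- function(response) {
  response |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      fold_30min = .data$rel[which.min(abs(.data$time_min - 30))],
      fold_peak = refine_peak(.data$time_min, .data$rel)[["height"]],
      t_peak_min = refine_peak(.data$time_min, .data$rel)[["time"]],
      .groups = "drop"
    )
}

# quadratic refinement of a gridded maximum (interior peaks only)
refine_peak <- function(time_min, rel) {
  if (all(is.na(rel))) {
    return(c(height = NA_real_, time = NA_real_))
  }
  post <- which(time_min > 0)
  i <- post[which.max(rel[post])]
  if (i <= 1L || i >= length(rel)) {
    return(c(height = rel[i], time = time_min[i]))
  }
  y0 <- rel[i - 1]
  y1 <- rel[i]
  y2 <- rel[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || denom >= -1e-300) {
    return(c(height = y1, time = time_min[i]))
  }
  s <- 0.5 * (y0 - y2) / denom # vertex offset in grid units, in (-1, 1)
  h <- time_min[i] - time_min[i - 1]
  c(
    height = y1 - 0.25 * (y0 - y2) * s,
    time = time_min[i] + s * h
  )
}

#' Decompose the postprandial response into its driving processes
#'
#' Runs the model from the intact fasting state three times: normally,
#' with the postprandial propulsion amplitude `delta_SI` set to 0, and
#' with liver-to-bile secretion `k_xl` set to 0 (no hepatic recycling).
#' The gastrointestinal-propulsion component is the difference between
#' the normal and no-propulsion curves, the recycling component the
#' difference between the normal and no-recycling curves, and the
#' gallbladder component the remainder, so the three components sum to
#' the total change from fasting exactly, by construction. All three runs
#' start from the same intact-model fasting state (counterfactual
#' design); components may be negative.
#'
#' @inheritParams postprandial_response
#' @return A tibble of class `ba_decomposition` with columns `time_min`,
#'   `total`, `propulsion`, `recycling`, `gallbladder` (plasma total
#'   concentration change from fasting, micromolar).
#' @export
decompose_postprandial <- function(params, x0 = NULL, hours = 6,
                                   dt_min = 1, ...) {
  if (is.null(x0)) x0 <- periodic_steady_state(params, ...)$state
  total_curve <- function(p) {
    r <- postprandial_response(p, x0, hours = hours, dt_min = dt_min)
    dplyr::filter(r, .data$class == "total")
  }
  normal <- total_curve(params)
  no_prop <- total_curve(p_set(params, delta_SI = 0))
  no_rec <- total_curve(p_set(params, k_xl = 0))
  if (!all(is.finite(no_prop$conc_uM)) || !all(is.finite(no_rec$conc_uM))) {
    stop("non-finite counterfactual response curve", call. = FALSE)
  }
  total <- normal$conc_uM - normal$conc_uM[1]
  propulsion <- normal$conc_uM - no_prop$conc_uM
  recycling <- normal$conc_uM - no_rec$conc_uM
  tibble::new_tibble(
    tibble::tibble(
      time_min = normal$time_min,
      total = total,
      propulsion = propulsion,
      recycling = recycling,
      gallbladder = total - propulsion - recycling
    ),
    class = "ba_decomposition"
  )
}

#' Peak times of the decomposition components
#'
#' @param decomposition A [decompose_postprandial()] result.
#' @return A tibble with columns `component` and `t_peak_min`.
#' @export
decomposition_peaks <- function(decomposition) {
  comp <- c("total", "propulsion", "recycling", "gallbladder")
  post <- decomposition$time_min > 0
  tibble::tibble(
    component = comp,
    t_peak_min = vapply(comp, function(cl) {
      y <- decomposition[[cl]][post]
      decomposition$time_min[post][which.max(y)]
    }, 0)
  )
}
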