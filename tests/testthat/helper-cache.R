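# Shared fixtures, computed once per test run. The calibrated default
# parameter set's periodic steady state and observables are reused by
# several files; random in-bounds parameter sets are drawn around the
# defaults so that steady states stay cheap to find.
.fixtures <- new.env(parent = emptyenv())

default_steady <- function() {
  if (is.null(.fixtures$ss)) {
    .fixtures$ss <- periodic_steady_state(ba_params(), tol = 1e-6)
  }
  .fixtures$ss
}

default_obs <- function() {
  if (is.null(.fixtures$obs)) {
    .fixtures$obs <- ba_observables(ba_params(), x0 = default_steady()$state)
  }
  .fixtures$obs
}

# random parameter set within bounds: defaults perturbed log-normally and
# clamped to the physiological ranges
random_params <- function(scale = 0.3) {
  tab <- ba_params()
  v <- tab$value * exp(stats::rnorm(nrow(tab), 0, scale))
  v <- pmin(pmax(v, tab$lower), tab$upper)
  names(v) <- tab$name
  s <- v[["f_CA"]] + v[["f_CDCA"]]
  if (s > 0.95) {
    v[["f_CA"]] <- v[["f_CA"]] * 0.95 / s
    v[["f_CDCA"]] <- v[["f_CDCA"]] * 0.95 / s
  }
  ba_params(values = v)
}

# observables tibble whose values equal the CDS targets (perfect fit)
obs_from_cds <- function(cds) {
  tibble::tibble(id = cds$id, value = cds$value)
}
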