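#' Bile acid configurations tracked by the model
#'
#' The model follows 21 molecular configurations: six bile acid species
#' (cholic acid CA, chenodeoxycholic acid CDCA, deoxycholic acid DCA,
#' ursodeoxycholic acid UDCA, lithocholic acid LCA, and a generic "other"
#' class O), each in unconjugated, glycine- and taurine-conjugated form,
#' plus the three conjugation states of sulfated LCA. Sulfation is modelled
#' for LCA only, where it is quantitatively important in humans.
#'
#' @return A tibble with one row per configuration and columns `config`
#'   (1-based index in state-vector order), `species`, `conjugation`
#'   (`"u"`, `"g"` or `"t"`) and `sulfated`.
#' @export
#' @examples
#' ba_configurations()
ba_configurations <- function() {
  species <- c("CA", "CDCA", "DCA", "UDCA", "LCA", "O")
  conj <- c("u", "g", "t")
  tibble::tibble(
    config = 1:21,
    species = c(rep(species, each = 3), rep("LCA", 3)),
    conjugation = c(rep(conj, 6), conj),
    sulfated = c(rep(FALSE, 18), rep(TRUE, 3))
  )
}

#' Model compartments
#'
#' Eighteen compartments: liver (`li`), gallbladder (`gb`), systemic plasma
#' (`pl`), ten small-intestinal segments (`si_1` duodenum, `si_2`–`si_5`
#' jejunum, `si_6`–`si_10` ileum) and five colonic segments
#' (`co_1`–`co_5`). Plasma sits outside the enterohepatic loop: its only
#' inflow is hepatic spillover of absorbed bile acids and its only outflow
#' returns toward the liver.
#'
#' @return A tibble with columns `comp` (1-based index), `id` and `region`.
#' @export
ba_compartments <- function() {
  tibble::tibble(
    comp = 1:18,
    id = c("li", "gb", "pl", paste0("si_", 1:10), paste0("co_", 1:5)),
    region = c(
      "liver", "gallbladder", "plasma",
      "duodenum", rep("jejunum", 4), rep("ileum", 5),
      rep("colon", 5)
    )
  )
}

#' Colonic biotransformation map
#'
#' Microbial 7-alpha-dehydroxylation and epimerization act on the
#' unconjugated pool in the colon only: CA -> DCA, CDCA -> LCA,
#' CDCA -> UDCA and UDCA -> LCA. The generic "other" class and the
#' terminal secondary species DCA have no outgoing edges.
#'
#' @return A tibble with columns `substrate` and `product` (species codes).
#' @export
#' @examples
#' transformation_map()
transformation_map <- function() {
  tibble::tibble(
    substrate = c("CA", "CDCA", "CDCA", "UDCA"),
    product = c("DCA", "LCA", "UDCA", "LCA")
  )
}

validate_configuration <- function(species, conjugation, sulfated) {
  species <- match.arg(species, c("CA", "CDCA", "DCA", "UDCA", "LCA", "O"))
  conjugation <- match.arg(conjugation, c("u", "g", "t"))
  if (sulfated && species != "LCA") {
    stop("sulfated configurations exist only for LCA", call. = FALSE)
  }
  list(species = species, conjugation = conjugation, sulfated = sulfated)
}

#' Hepatic first-pass extraction of a bile acid configuration
#'
#' Extraction from portal blood depends on hydroxylation state
#' (`psi_tri` for CA; `psi_di` for CDCA, DCA, UDCA and the
#' di-hydroxyl-dominated "other" class; `psi_mono` for LCA), is reduced
#' for unconjugated forms (multiplier `psi_u`) and for sulfated forms
#' (multiplier `psi_sulf`). The product is clamped to `[0, 1]`; the
#' non-extracted remainder of any absorbed flux spills into systemic
#' plasma.
#'
#' @param params A [ba_params()] parameter set.
#' @param species,conjugation,sulfated Configuration; vectors are recycled.
#' @return Numeric vector of extraction fractions in `[0, 1]`.
#' @export
#' @examples
#' p <- ba_params()
#' hepatic_extraction(p, "CA", "t")        # conjugated CA: psi_tri
#' hepatic_extraction(p, "CA", "u")        # unconjugated: psi_tri * psi_u
hepatic_extraction <- function(params, species, conjugation = "u",
                               sulfated = FALSE) {
  n <- max(length(species), length(conjugation), length(sulfated))
  species <- rep_len(species, n)
  conjugation <- rep_len(conjugation, n)
  sulfated <- rep_len(sulfated, n)
  mapply(validate_configuration, species, conjugation, sulfated,
    SIMPLIFY = FALSE
  )
  v <- p_values(params)
  base <- ifelse(species == "CA", v[["psi_tri"]],
    ifelse(species == "LCA", v[["psi_mono"]], v[["psi_di"]])
  )
  psi <- base *
    ifelse(conjugation == "u", v[["psi_u"]], 1) *
    ifelse(sulfated, v[["psi_sulf"]], 1)
  pmin(pmax(psi, 0), 1)
}

#' @rdname hepatic_extraction
#' @return `extraction_table()`: extraction fractions for all 21
#'   configurations as a tibble.
#' @export
extraction_table <- function(params) {
  cfg <- ba_configurations()
  cfg$psi <- hepatic_extraction(
    params, cfg$species, cfg$conjugation, cfg$sulfated
  )
  cfg
}
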