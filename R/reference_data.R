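# Published reference quantities shipped as plain-text tables: the 13
# dose-response-confirmed Parkin fragment hits (heavy-atom count, KD,
# printed ligand efficiency, NMR confirmation) and the protein-ligand /
# reducing-agent reference interactions used to validate surface activity.

#' Confirmed Parkin fragment hits
#'
#' The thirteen fragment hits confirmed in dose response on full-length
#' FLAG-Parkin, with heavy-atom count, KD determined by SPR, the published
#' ligand efficiency, and the orthogonal NMR confirmation boolean.
#'
#' @return A data frame with columns `fragment`, `heavy_atoms`, `kd_uM`,
#'   `le_published`, `nmr_confirmed`.
#' @export
parkin_confirmed_hits <- function() {
  path <- system.file("extdata", "parkin_confirmed_hits.tsv",
                      package = "sprscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference interactions of the Parkin surface
#'
#' Protein ligands (ubiquitin-like domain UblD, the E2 conjugating enzyme
#' UbcH7, ubiquitin) and the reducing agent DTT, with the affinity measured
#' on full-length FLAG-Parkin at room temperature, the approximate
#' dissociation half-life where reported, and the injected concentration
#' series (uM, comma-separated, high to low).
#'
#' @return A data frame with columns `ligand`, `kd_uM`,
#'   `dissociation_half_life_s` (NA where only steady-state data exist) and
#'   `concentrations_uM`.
#' @export
parkin_reference_ligands <- function() {
  path <- system.file("extdata", "parkin_reference_ligands.tsv",
                      package = "sprscreen", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out
}

#' Parse the concentration series column of [parkin_reference_ligands()]
#'
#' @param x A comma-separated series in uM.
#' @return Numeric concentrations in molar units, decreasing.
#' @export
parse_concentration_series <- function(x) {
  as.numeric(strsplit(x, ",")[[1]]) * 1e-6
}
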