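#' The bundled EGFR demonstration model
#'
#' A six-rule model of early EGFR signaling: (R1) EGF binds the receptor's
#' extracellular domain, requiring the transmembrane site unbound; (R2,
#' R3) dephosphorylation of the two receptor tyrosines in any receptor
#' context; (R4) dimerization through the transmembrane sites, requiring
#' both extracellular domains ligand-bound (`!+`); (R5, R6)
#' transphosphorylation of each tyrosine conditional on the dimer bond.
#' Seed species are free EGF and the four unbound receptor
#' phosphoform variants, the set over which R1 expands into four distinct
#' concrete reactions.
#'
#' This exact formulation — per-site (de)phosphorylation rules, `!+`
#' ligand wildcards in dimerization, explicit `!1` dimer bonds in the
#' modification rules — is what yields a process diagram with six process
#' nodes and four molecular-complex nodes (EGF, EGFR, EGF·EGFR,
#' EGFR·EGFR); reformulating rules changes the diagram without changing
#' the model.
#'
#' @return a validated `bngl_model` with 2 molecule types and 6 rules.
#' @seealso [egfr_bngl_path()] for the on-disk BNGL source.
#' @export
egfr_model <- function() {
  parse_model(file = egfr_bngl_path())
}

#' Path to the bundled EGFR model file
#'
#' @return path of `egfr_mpd.bngl` inside the installed package.
#' @export
egfr_bngl_path <- function() {
  system.file("extdata", "egfr_mpd.bngl", package = "mpdiagram",
              mustWork = TRUE)
}
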