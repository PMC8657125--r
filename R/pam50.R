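#' @keywords internal
"_PACKAGE"

#' Intrinsic subtype labels, in fixed canonical order
#'
#' The five intrinsic breast cancer subtypes in the order used throughout the
#' package: basal-like, HER2-enriched, luminal A, luminal B, normal-like.
#' This order also defines the deterministic tie-break for subtype calls.
#'
#' @return Character vector of length 5.
#' @export
pam50_subtypes <- function() {
  c("Basal", "Her2", "LumA", "LumB", "Normal")
}

#' The PAM50 gene panel (canonical HGNC symbols)
#'
#' The 50-gene panel used for intrinsic subtyping, under current HGNC
#' symbols (legacy names such as ORC6L, KNTC2 and CDCA1 are resolved via
#' [resolve_gene_aliases()]).
#'
#' @return Character vector of 50 gene symbols in canonical (alphabetical)
#'   panel order.
#' @export
pam50_genes <- function() {
  c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
    "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
    "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
    "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
    "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
    "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B", "TYMS",
    "UBE2C", "UBE2T")
}

#' Genes dropped from the reduced 46-gene classification panel
#'
#' Four genes are excluded from both the subtype-call correlations and the
#' four correlation inputs of the ROR formula; only 46 of the 50 panel genes
#' are used for classification.
#'
#' @return Character vector of 4 gene symbols.
#' @export
reduced_panel_excluded <- function() {
  c("BIRC5", "CCNB1", "GRB7", "MYBL2")
}

#' The 18-gene proliferation signature (canonical symbols)
#'
#' Genes whose arithmetic mean (on centered log2 expression) is the
#' proliferation score entering the ROR formula. Legacy symbols ORC6L,
#' KNTC2 and CDCA1 correspond to ORC6, NDC80 and NUF2.
#'
#' @return Character vector of 18 gene symbols.
#' @export
proliferation_genes <- function() {
  c("ANLN", "CEP55", "ORC6", "CCNE1", "EXO1", "PTTG1", "CDC20", "KIF2C",
    "RRM2", "CDC6", "NDC80", "TYMS", "NUF2", "MELK", "UBE2C", "CENPF",
    "MKI67", "UBE2T")
}

#' Legacy-to-canonical gene symbol map
#'
#' Covers the legacy symbols that appear in historical PAM50 gene lists and
#' centroid files, plus the ERS1 misspelling of ESR1 seen in some sources.
#' Symbols already canonical map to themselves under
#' [resolve_gene_aliases()].
#'
#' @return Named character vector: names are legacy symbols, values are
#'   canonical HGNC symbols.
#' @export
gene_alias_map <- function() {
  c(ORC6L = "ORC6", KNTC2 = "NDC80", CDCA1 = "NUF2", ERS1 = "ESR1")
}

#' Resolve gene symbols to canonical HGNC names
#'
#' Applies [gene_alias_map()]; unknown symbols pass through unchanged, so
#' resolution is idempotent.
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector of the same length, canonical symbols.
#' @export
resolve_gene_aliases <- function(genes) {
  stopifnot(is.character(genes))
  map <- gene_alias_map()
  hit <- genes %in% names(map)
  genes[hit] <- unname(map[genes[hit]])
  genes
}

#' ROR formula coefficients
#'
#' The published constants of the linear risk-of-recurrence score
#' \deqn{ROR = 54.7690 (-0.0067 Basal + 0.4317 HER2 - 0.3172 LumA
#'   + 0.4894 LumB + 0.1981 prolif + 0.1133 T + 0.8826)}
#' where Basal, HER2, LumA and LumB are Pearson correlations to the
#' respective centroids, prolif is the 18-gene proliferation score, and
#' T indicates tumor size > 2 cm.
#'
#' @return Named list of the seven coefficients and the scale factor.
#' @export
ror_coefficients <- function() {
  list(scale = 54.7690,
       basal = -0.0067,
       her2 = 0.4317,
       luma = -0.3172,
       lumb = 0.4894,
       prolif = 0.1981,
       size = 0.1133,
       intercept = 0.8826)
}

#' Node-status-dependent risk category thresholds
#'
#' Cutoffs on the continuous ROR score: node-negative (pN0) tumors use
#' 40/60, tumors with 1-3 positive nodes use 15/40, and tumors with 4 or
#' more positive nodes are always high risk. The interval convention is
#' low <= lower cutoff < intermediate <= upper cutoff < high.
#'
#' @return Named list with elements `pN0`, `pN1_3` (each `c(lower, upper)`)
#'   and `pN4plus` (`NULL`, always high).
#' @export
risk_thresholds <- function() {
  list(pN0 = c(40, 60), pN1_3 = c(15, 40), pN4plus = NULL)
}

#' Risk category and node class level sets
#' @keywords internal
risk_levels <- function() c("low", "intermediate", "high")

#' @keywords internal
node_levels <- function() c("pN0", "pN1_3", "pN4plus")
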