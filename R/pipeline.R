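#' Run the full subtyping and ROR pipeline on one expression matrix
#'
#' Chains the whole research-based procedure: ER status from the bimodal
#' ESR1 distribution (or supplied labels), 60/40 ER-weighted per-gene
#' centering, Pearson correlation to the five centroids on the 46-gene
#' reduced panel, argmax subtype call, 18-gene proliferation score, the
#' linear ROR score, and node-dependent risk categorization.
#'
#' @param expr An `expr_matrix` of log2 expression covering the panel.
#' @param clinical Clinical table with `sample_id`, `size_gt_2cm`,
#'   `node_class` (see [load_clinical()]).
#' @param centroids A `centroid_set` (default: packaged synthetic set).
#' @param er `"auto"` to fit the ESR1 mixture, or an `er_call` (e.g. from
#'   [er_call_from_status()]).
#' @param w Weight on the ER-positive class mean (default 0.6).
#' @param seed Seed for the ER mixture fit.
#' @param allow_missing Allow classification on a reduced-panel subset.
#' @return List with `ror` (a categorized `ror_result`), `subtypes`,
#'   `er`, `centered`, and `reference`.
#' @export
ror_pipeline <- function(expr, clinical, centroids = load_centroids(),
                         er = "auto", w = 0.6, seed = 1L,
                         allow_missing = FALSE) {
  if (identical(er, "auto")) er <- call_er_status(expr, seed = seed)
  stopifnot(inherits(er, "er_call"))
  cls <- classify_subtypes(expr, er, centroids, w = w,
                           allow_missing = allow_missing)
  prolif <- proliferation_score(cls$centered)
  ror <- ror_score(cls$subtypes, prolif, clinical)
  list(ror = ror, subtypes = cls$subtypes, er = er,
       centered = cls$centered, reference = cls$reference)
}

#' Published discordant-case table (printed scores and categories)
#'
#' The 13 node-negative cases reported as risk-group discordant between
#' the macrodissected-FFPE and fresh-frozen-bulk ROR scores, with their
#' printed continuous scores and categories for both preparations. Used to
#' check the agreement statistics and the category boundary convention
#' against the published values.
#'
#' @return Data.frame with `sample_id`, `subtype`, `prosigna_ror`,
#'   `prosigna_cat`, `ror_macro`, `macro_cat`, `ror_bulk`, `bulk_cat`.
#' @export
reported_discordant_cases <- function() {
  path <- system.file("extdata", "reported_discordant_cases.tsv",
                      package = "ror50")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
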