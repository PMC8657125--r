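#' 18-gene proliferation score
#'
#' Arithmetic mean, per sample, of the centered log2 expression of the 18
#' proliferation signature genes ([proliferation_genes()]). All 18 genes
#' must be present after alias resolution; there is no silent fallback to a
#' smaller mean.
#'
#' @param centered A centered `expr_matrix`.
#' @return Named numeric vector, one score per sample.
#' @export
proliferation_score <- function(centered) {
  pg <- proliferation_genes()
  miss <- setdiff(pg, rownames(centered))
  if (length(miss))
    stop("proliferation gene(s) missing from the matrix: ",
         paste(miss, collapse = ", "))
  colMeans(unclass(centered)[pg, , drop = FALSE])
}

#' Continuous risk-of-recurrence score
#'
#' Evaluates the linear ROR formula
#' `scale * (c_b*Basal + c_h*HER2 + c_a*LumA + c_l*LumB + c_p*prolif +
#' c_T*T + intercept)` per sample, using the Pearson correlations to the
#' four tumor subtypes (the normal-like correlation never enters), the
#' proliferation score, and the tumor-size indicator. The calibrated range
#' is 0-100; raw values are reported unclipped, with a flag when they fall
#' outside that range.
#'
#' @param subtypes A filled `subtype_result`.
#' @param prolif Named numeric vector of proliferation scores (names =
#'   sample IDs), as from [proliferation_score()].
#' @param clinical Data.frame with `sample_id`, `size_gt_2cm` and (for
#'   categorization) `node_class`; see [load_clinical()].
#' @param coeffs Coefficients, default the published [ror_coefficients()].
#' @param thresholds Risk cutoffs, default [risk_thresholds()].
#' @param categorize Also assign the node-dependent risk category
#'   (default `TRUE`; requires `node_class`).
#' @param clip Clip reported scores into \[0, 100\] (default `FALSE`; the
#'   flag `clipped` marks out-of-range raw scores either way).
#' @return A `ror_result` data.frame with per-sample correlations, prolif,
#'   `T`, `ror`, `node_class`, `category`, `tie` and `clipped` columns.
#' @export
ror_score <- function(subtypes, prolif, clinical,
                      coeffs = ror_coefficients(),
                      thresholds = risk_thresholds(),
                      categorize = TRUE, clip = FALSE) {
  stopifnot(inherits(subtypes, "subtype_result"))
  ids <- subtypes$sample_id
  p <- prolif[match(ids, names(prolif))]
  if (anyNA(p))
    stop("proliferation score missing for sample(s): ",
         paste(ids[is.na(p)], collapse = ", "))
  ci <- match(ids, clinical$sample_id)
  if (anyNA(ci))
    stop("clinical annotation missing for sample(s): ",
         paste(ids[is.na(ci)], collapse = ", "))
  size <- clinical$size_gt_2cm[ci]
  if (anyNA(size)) stop("size_gt_2cm (T indicator) missing for scored sample(s)")
  Tind <- as.numeric(size)
  raw <- coeffs$scale * (coeffs$basal * subtypes$corr_Basal +
                           coeffs$her2 * subtypes$corr_Her2 +
                           coeffs$luma * subtypes$corr_LumA +
                           coeffs$lumb * subtypes$corr_LumB +
                           coeffs$prolif * p +
                           coeffs$size * Tind +
                           coeffs$intercept)
  clipped <- raw < 0 | raw > 100
  ror <- if (clip) pmin(100, pmax(0, raw)) else raw
  out <- data.frame(sample_id = ids,
                    basal = subtypes$corr_Basal, her2 = subtypes$corr_Her2,
                    luma = subtypes$corr_LumA, lumb = subtypes$corr_LumB,
                    prolif = unname(p), T = Tind, ror = ror,
                    clipped = clipped, stringsAsFactors = FALSE)
  if (!is.null(subtypes$call)) {
    out$call <- subtypes$call
    out$tie <- subtypes$tie
  }
  if (categorize) {
    if (!"node_class" %in% colnames(clinical))
      stop("node_class required in `clinical` to categorize risk")
    nc <- clinical$node_class[ci]
    if (anyNA(nc)) stop("node_class missing for scored sample(s)")
    out$node_class <- nc
    out$category <- categorize_risk(ror, nc, thresholds)
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ror_result", "data.frame")
  out
}

#' Node-status-dependent risk categorization
#'
#' Maps a continuous ROR score to low / intermediate / high risk using the
#' cutoffs for the sample's node class: 40/60 for node-negative, 15/40 for
#' 1-3 positive nodes, and automatic high risk for 4 or more nodes.
#' Boundary convention: low <= lower cutoff < intermediate <= upper cutoff
#' < high.
#'
#' @param ror Numeric vector of continuous ROR scores.
#' @param node_class Factor/character vector over pN0/pN1_3/pN4plus
#'   (recycled if length 1).
#' @param thresholds Cutoff table, default [risk_thresholds()].
#' @return Factor over low/intermediate/high.
#' @export
categorize_risk <- function(ror, node_class, thresholds = risk_thresholds()) {
  if (any(!is.finite(ror))) stop("ROR scores must be finite")
  node_class <- as.character(node_class)
  if (length(node_class) == 1) node_class <- rep(node_class, length(ror))
  stopifnot(length(node_class) == length(ror),
            all(node_class %in% node_levels()))
  out <- character(length(ror))
  for (cls in unique(node_class)) {
    i <- node_class == cls
    if (cls == "pN4plus") {
      out[i] <- "high"
    } else {
      cut <- thresholds[[cls]]
      stopifnot(length(cut) == 2, cut[1] < cut[2])
      out[i] <- ifelse(ror[i] <= cut[1], "low",
                       ifelse(ror[i] <= cut[2], "intermediate", "high"))
    }
  }
  factor(out, levels = risk_levels(), ordered = TRUE)
}
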