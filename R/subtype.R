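#' Correlate centered profiles to the five subtype centroids
#'
#' Computes, for every sample, the Pearson correlation between its centered
#' 46-gene expression vector and each of the five subtype centroids
#' (normal-like included). The four genes outside the reduced panel are
#' never used, either for the subtype call or for the four correlations
#' entering the ROR formula.
#'
#' @param centered A centered `expr_matrix` (output of
#'   [weighted_center()]).
#' @param centroids A `centroid_set`.
#' @param allow_missing If `TRUE`, compute on the intersection of available
#'   reduced-panel genes instead of erroring when some are absent; the gene
#'   count used is recorded per sample in `n_genes_used`.
#' @return A `subtype_result` data.frame with `sample_id`, one correlation
#'   column per subtype (`corr_Basal` ... `corr_Normal`) and `n_genes_used`;
#'   call fields are filled by [assign_subtypes()].
#' @export
centroid_correlations <- function(centered, centroids, allow_missing = FALSE) {
  stopifnot(inherits(centroids, "centroid_set"))
  reduced <- centroids$genes[centroids$reduced_mask]
  have <- intersect(reduced, rownames(centered))
  if (length(have) < length(reduced) && !allow_missing)
    stop("centered matrix lacks reduced-panel gene(s): ",
         paste(setdiff(reduced, have), collapse = ", "),
         " (use allow_missing = TRUE to correlate on the intersection)")
  if (length(have) < 3)
    stop("fewer than 3 reduced-panel genes available; correlations unusable")
  X <- unclass(centered)[have, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance across the reduced panel for sample(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         "; Pearson correlation undefined")
  C <- centroids$values[have, , drop = FALSE]
  corr <- t(stats::cor(X, C, method = "pearson"))  # subtypes x samples
  out <- data.frame(sample_id = colnames(centered),
                    t(corr), stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", paste0("corr_", centroids$subtypes))
  out$n_genes_used <- length(have)
  rownames(out) <- NULL
  class(out) <- c("subtype_result", "data.frame")
  out
}

#' Build a subtype result from given correlations
#'
#' Wraps a samples x 5 matrix of centroid correlations (columns in the
#' fixed subtype order) as a `subtype_result`, e.g. for evaluating the ROR
#' formula on externally supplied correlations.
#'
#' @param corr Numeric matrix, samples in rows (rownames = sample IDs, or
#'   auto-numbered), five columns in [pam50_subtypes()] order.
#' @param n_genes_used Gene count to record (default `NA`).
#' @return A `subtype_result` with correlation columns only.
#' @export
subtype_result_from_correlations <- function(corr, n_genes_used = NA_integer_) {
  corr <- as.matrix(corr)
  if (ncol(corr) != 5) stop("corr must have 5 columns (one per subtype)")
  ids <- rownames(corr)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(nrow(corr)))
  out <- data.frame(sample_id = ids, corr, stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", paste0("corr_", pam50_subtypes()))
  out$n_genes_used <- n_genes_used
  rownames(out) <- NULL
  class(out) <- c("subtype_result", "data.frame")
  out
}

#' Assign subtype calls from centroid correlations
#'
#' Argmax assignment over the five correlations, with runner-up and margin
#' (top minus second correlation). Exact ties are broken by the fixed
#' subtype order Basal, Her2, LumA, LumB, Normal and flagged.
#'
#' @param result A `subtype_result` from [centroid_correlations()].
#' @return The same object with `call`, `runner_up`, `margin` and `tie`
#'   columns filled.
#' @export
assign_subtypes <- function(result) {
  stopifnot(inherits(result, "subtype_result"))
  sub <- pam50_subtypes()
  M <- as.matrix(result[, paste0("corr_", sub)])
  top <- apply(M, 1, which.max)                     # first max = fixed order
  second <- vapply(seq_len(nrow(M)), function(i) {
    v <- M[i, ]
    v[top[i]] <- -Inf
    which.max(v)
  }, integer(1))
  tie <- vapply(seq_len(nrow(M)), function(i)
    sum(M[i, ] == max(M[i, ])) > 1, logical(1))
  result$call <- factor(sub[top], levels = sub)
  result$runner_up <- factor(sub[second], levels = sub)
  result$margin <- M[cbind(seq_len(nrow(M)), top)] -
    M[cbind(seq_len(nrow(M)), second)]
  result$tie <- tie
  result
}

#' Center, correlate and call subtypes in one step
#'
#' Convenience wrapper: ER-weighted centering followed by
#' [centroid_correlations()] and [assign_subtypes()].
#'
#' @inheritParams weighted_center
#' @inheritParams centroid_correlations
#' @return List with `subtypes` (a filled `subtype_result`), `centered`,
#'   and `reference`.
#' @export
classify_subtypes <- function(expr, er, centroids, w = 0.6,
                              allow_missing = FALSE) {
  ctr <- weighted_center(expr, er, w = w)
  res <- assign_subtypes(
    centroid_correlations(ctr$centered, centroids,
                          allow_missing = allow_missing))
  list(subtypes = res, centered = ctr$centered, reference = ctr$reference)
}
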