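#' Call ER status from the bimodal ESR1 distribution
#'
#' Fits a two-component one-dimensional Gaussian mixture (unequal
#' variances) to the log2 expression of ESR1 across the cohort. The
#' component with the larger mean is taken as ER-positive; each sample is
#' labelled by its posterior probability, and the decision threshold is the
#' expression value at which the two posteriors are equal.
#'
#' The fit errors out as "unimodal" when the mixture is degenerate — a
#' component carrying less than 5% of the samples, or component means less
#' than 0.5 log2 units apart — in which case ER status should be supplied
#' externally (e.g. from IHC) instead.
#'
#' @param expr An `expr_matrix` containing the ER gene.
#' @param gene Gene whose bimodality defines ER status (default `"ESR1"`).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An `er_call`: data.frame with `sample_id`, `status`
#'   (`ER_pos`/`ER_neg`) and `posterior_prob_pos`, with attributes
#'   `threshold`, `mean_pos`, `mean_neg`.
#' @importFrom mclust Mclust mclustBIC
#' @export
call_er_status <- function(expr, gene = "ESR1", seed = 1L) {
  if (!gene %in% rownames(expr))
    stop("gene '", gene, "' not present in the expression matrix")
  x <- as.numeric(expr[gene, ])
  if (length(x) < 6) stop("need at least 6 samples to fit the ER mixture")
  # EM on (near-)constant data cannot separate two modes; fail fast
  if (stats::sd(x) < 1e-8 || length(unique(x)) < 3)
    stop("unimodal ", gene, " distribution (no spread in expression); ",
         "supply ER status externally (e.g. IHC)")
  set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
  if (is.null(fit))
    stop("unimodal ", gene, " distribution: two-component mixture fit failed; ",
         "supply ER status externally (e.g. IHC)")
  mu <- fit$parameters$mean
  pro <- fit$parameters$pro
  if (min(pro) < 0.05 || abs(diff(mu)) < 0.5)
    stop("unimodal ", gene, " distribution (component weight ",
         sprintf("%.3f", min(pro)), ", mean separation ",
         sprintf("%.3f", abs(diff(mu))),
         " log2 units); supply ER status externally (e.g. IHC)")
  pos_comp <- which.max(mu)
  post_pos <- fit$z[, pos_comp]
  status <- ifelse(post_pos >= 0.5, "ER_pos", "ER_neg")
  # threshold: equal-posterior point between the two component means
  s2 <- fit$parameters$variance$sigmasq
  if (length(s2) == 1) s2 <- rep(s2, 2)
  f <- function(v) pro[1] * stats::dnorm(v, mu[1], sqrt(s2[1])) -
    pro[2] * stats::dnorm(v, mu[2], sqrt(s2[2]))
  thr <- tryCatch(stats::uniroot(f, lower = min(mu), upper = max(mu))$root,
                  error = function(e) mean(mu))
  out <- data.frame(sample_id = colnames(expr),
                    status = status,
                    posterior_prob_pos = post_pos,
                    stringsAsFactors = FALSE)
  structure(out, threshold = thr,
            mean_pos = max(mu), mean_neg = min(mu),
            class = c("er_call", "data.frame"))
}

#' Build an ER call object from known statuses
#'
#' Wraps externally determined ER labels (IHC, or simulation ground truth)
#' in the same container [call_er_status()] returns, so downstream
#' centering code takes either source.
#'
#' @param sample_id Character vector of sample IDs.
#' @param status Character or logical vector; `TRUE`/`"ER_pos"` marks
#'   ER-positive samples.
#' @return An `er_call`.
#' @export
er_call_from_status <- function(sample_id, status) {
  if (is.logical(status)) status <- ifelse(status, "ER_pos", "ER_neg")
  if (!all(status %in% c("ER_pos", "ER_neg")))
    stop("status must be ER_pos/ER_neg (or logical)")
  out <- data.frame(sample_id = sample_id, status = status,
                    posterior_prob_pos = as.numeric(status == "ER_pos"),
                    stringsAsFactors = FALSE)
  structure(out, threshold = NA_real_, mean_pos = NA_real_,
            mean_neg = NA_real_, class = c("er_call", "data.frame"))
}

#' ER-balanced per-gene centering
#'
#' Centers each gene across tumors against a weighted average of its
#' ER-positive and ER-negative class means, with weight `w` (default 0.6)
#' on the ER-positive mean. The weighting compensates for a cohort whose
#' ER-positive fraction differs from the ~60% of the original subtype
#' training series, so that a cohort with, say, 80% ER-positive tumors is
#' not centered toward its ER-positive bulk.
#'
#' @param expr An `expr_matrix` (log2 values).
#' @param er An `er_call` covering the samples of `expr`.
#' @param w Weight on the ER-positive class mean, in (0,1); default 0.6.
#' @param fallback_plain If one ER class is empty, set `TRUE` to center on
#'   the plain per-gene mean instead of erroring (explicit opt-in).
#' @return List with `centered` (an `expr_matrix`) and `reference`
#'   (a `centering_reference` data.frame with per-gene `mean_pos`,
#'   `mean_neg`, `reference`) reusable on new samples via
#'   [apply_centering()].
#' @export
weighted_center <- function(expr, er, w = 0.6, fallback_plain = FALSE) {
  stopifnot(w > 0, w < 1)
  st <- er$status[match(colnames(expr), er$sample_id)]
  if (anyNA(st))
    stop("ER call missing for sample(s): ",
         paste(colnames(expr)[is.na(st)], collapse = ", "))
  pos <- st == "ER_pos"
  if (!any(pos) || all(pos)) {
    if (!fallback_plain)
      stop("one ER class is empty; ER-weighted centering undefined. ",
           "Pass fallback_plain = TRUE to center on the plain per-gene mean ",
           "(w is then ignored).")
    ref <- rowMeans(expr)
    reference <- data.frame(gene = rownames(expr), mean_pos = ref,
                            mean_neg = ref, reference = ref,
                            stringsAsFactors = FALSE)
  } else {
    mean_pos <- rowMeans(expr[, pos, drop = FALSE])
    mean_neg <- rowMeans(expr[, !pos, drop = FALSE])
    reference <- data.frame(gene = rownames(expr),
                            mean_pos = mean_pos, mean_neg = mean_neg,
                            reference = w * mean_pos + (1 - w) * mean_neg,
                            stringsAsFactors = FALSE)
  }
  rownames(reference) <- NULL
  attr(reference, "w") <- w
  class(reference) <- c("centering_reference", "data.frame")
  centered <- expression_matrix(unclass(expr) - reference$reference,
                                platform = attr(expr, "platform"),
                                resolve_aliases = FALSE)
  list(centered = centered, reference = reference)
}

#' Center new samples against a stored reference
#'
#' Subtracts the per-gene reference learned by [weighted_center()] from a
#' (possibly new) expression matrix covering the same genes.
#'
#' @param expr An `expr_matrix`.
#' @param reference A `centering_reference`.
#' @return A centered `expr_matrix`.
#' @export
apply_centering <- function(expr, reference) {
  idx <- match(rownames(expr), reference$gene)
  if (anyNA(idx))
    stop("reference lacks gene(s): ",
         paste(rownames(expr)[is.na(idx)], collapse = ", "))
  expression_matrix(unclass(expr) - reference$reference[idx],
                    platform = attr(expr, "platform"),
                    resolve_aliases = FALSE)
}
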