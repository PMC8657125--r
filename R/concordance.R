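#' Agreement statistics between two score sets
#'
#' Compares two continuous score vectors (e.g. ROR from two preparations of
#' the same tumors) on their shared samples: squared Pearson correlation,
#' mean absolute difference, and the signed difference range. Differences
#' follow the fixed convention A - B, A being the first argument.
#'
#' @param score_a,score_b Named numeric vectors (names = sample IDs), or
#'   `ror_result` objects (their `ror` column is used).
#' @return A `score_agreement` list: `r_squared`, `mean_abs_diff`,
#'   `signed_diff_min`, `signed_diff_max`, `n`.
#' @export
score_agreement <- function(score_a, score_b) {
  a <- as_score_vector(score_a)
  b <- as_score_vector(score_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("need at least 3 shared samples (got ", length(shared), ")")
  a <- a[shared]; b <- b[shared]
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("scores must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one score set; correlation undefined")
  d <- a - b
  structure(list(r_squared = stats::cor(a, b)^2,
                 mean_abs_diff = mean(abs(d)),
                 signed_diff_min = min(d),
                 signed_diff_max = max(d),
                 n = length(shared)),
            class = "score_agreement")
}

#' @keywords internal
as_score_vector <- function(x) {
  if (inherits(x, "ror_result")) return(stats::setNames(x$ror, x$sample_id))
  if (is.data.frame(x) && all(c("sample_id", "ror") %in% colnames(x)))
    return(stats::setNames(x$ror, x$sample_id))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("scores must be a named numeric vector or a ror_result")
}

#' @export
print.score_agreement <- function(x, ...) {
  cat(sprintf("score_agreement over %d samples: r^2 = %.3f, mean |diff| = %.2f, signed diff in [%.2f, %.2f]\n",
              x$n, x$r_squared, x$mean_abs_diff,
              x$signed_diff_min, x$signed_diff_max))
  invisible(x)
}

#' Subtype confusion matrix between two call sets
#'
#' Cross-tabulates subtype calls on the shared samples; rows are the calls
#' of the first set, columns of the second, in fixed subtype order. The
#' concordance fraction is trace / total.
#'
#' @param calls_a,calls_b Named factors/character vectors of subtype calls
#'   (names = sample IDs), or `subtype_result` objects.
#' @return A `subtype_confusion`: 5 x 5 integer matrix with attributes
#'   `n` and `concordance`.
#' @export
subtype_confusion <- function(calls_a, calls_b) {
  a <- as_call_vector(calls_a)
  b <- as_call_vector(calls_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 1) stop("no shared samples between the two call sets")
  sub <- pam50_subtypes()
  tab <- table(factor(a[shared], levels = sub),
               factor(b[shared], levels = sub))
  m <- matrix(as.integer(tab), 5, 5, dimnames = list(A = sub, B = sub))
  structure(m, n = length(shared),
            concordance = sum(diag(m)) / length(shared),
            class = c("subtype_confusion", "matrix"))
}

#' @keywords internal
as_call_vector <- function(x) {
  if (inherits(x, "subtype_result") ||
      (is.data.frame(x) && all(c("sample_id", "call") %in% colnames(x))))
    return(stats::setNames(as.character(x$call), x$sample_id))
  if (!is.null(names(x))) return(stats::setNames(as.character(x), names(x)))
  stop("calls must be a named vector or a subtype_result with calls assigned")
}

#' @export
print.subtype_confusion <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("n = %d, concordance = %.3f\n",
              attr(x, "n"), attr(x, "concordance")))
  invisible(x)
}

#' Risk-group discordant cases between two categorized score sets
#'
#' Lists the samples whose risk category differs between two `ror_result`
#' sets categorized under the same threshold table, sorted by signed score
#' difference (A - B) in decreasing order. An optional subset restricts the
#' comparison, e.g. to the patients eligible for clinical testing
#' (`"er_pos_her2_neg_pn0"`: ER-positive, HER2-negative, node-negative).
#'
#' @param ror_a,ror_b Categorized `ror_result` objects.
#' @param clinical Clinical table with `sample_id` plus `er_status` and
#'   `her2_status` columns when a subset preset needs them.
#' @param subset `NULL` (all shared samples) or the preset
#'   `"er_pos_her2_neg_pn0"`.
#' @return Data.frame of `DiscordanceRecord`s: `sample_id`, `category_a`,
#'   `category_b`, `ror_a`, `ror_b`, `signed_diff`, `subtype_a`,
#'   `subtype_b`; attribute `n_compared` gives the subset size.
#' @export
risk_group_discordance <- function(ror_a, ror_b, clinical = NULL,
                                   subset = NULL) {
  stopifnot(inherits(ror_a, "ror_result"), inherits(ror_b, "ror_result"))
  if (!"category" %in% colnames(ror_a) || !"category" %in% colnames(ror_b))
    stop("both ror_result sets must be categorized")
  if (!identical(attr(ror_a, "thresholds"), attr(ror_b, "thresholds")))
    stop("the two result sets were categorized under different threshold tables")
  shared <- intersect(ror_a$sample_id, ror_b$sample_id)
  if (!is.null(subset)) {
    subset <- match.arg(subset, "er_pos_her2_neg_pn0")
    if (is.null(clinical) ||
        !all(c("er_status", "her2_status", "node_class") %in% colnames(clinical)))
      stop("subset '", subset,
           "' needs a clinical table with er_status, her2_status, node_class")
    keep <- clinical$sample_id[clinical$er_status == "ER_pos" &
                                 clinical$her2_status == "negative" &
                                 as.character(clinical$node_class) == "pN0"]
    shared <- intersect(shared, keep)
  }
  ia <- match(shared, ror_a$sample_id)
  ib <- match(shared, ror_b$sample_id)
  rec <- data.frame(sample_id = shared,
                    category_a = as.character(ror_a$category[ia]),
                    category_b = as.character(ror_b$category[ib]),
                    ror_a = ror_a$ror[ia], ror_b = ror_b$ror[ib],
                    signed_diff = ror_a$ror[ia] - ror_b$ror[ib],
                    subtype_a = if (!is.null(ror_a$call))
                      as.character(ror_a$call[ia]) else NA_character_,
                    subtype_b = if (!is.null(ror_b$call))
                      as.character(ror_b$call[ib]) else NA_character_,
                    stringsAsFactors = FALSE)
  rec <- rec[rec$category_a != rec$category_b, , drop = FALSE]
  rec <- rec[order(rec$signed_diff, decreasing = TRUE), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_compared") <- length(shared)
  rec
}

#' Per-gene correlation between two platforms
#'
#' Pearson correlation, gene by gene across shared samples, between two
#' expression matrices of the same cohort (e.g. macrodissected FFPE counts
#' vs fresh-frozen bulk RNA-seq). Genes with zero variance on either
#' platform get `NA` and a flag rather than an error. Proliferation
#' signature genes are marked.
#'
#' @param expr_a,expr_b `expr_matrix` objects sharing samples and genes.
#' @param threshold Flag genes at or below this correlation (default 0.75).
#' @return Data.frame with `gene`, `r`, `below_threshold`,
#'   `is_proliferation`, `n_samples`.
#' @export
per_gene_cross_correlation <- function(expr_a, expr_b, threshold = 0.75) {
  shared_s <- intersect(colnames(expr_a), colnames(expr_b))
  if (length(shared_s) < 3) stop("need at least 3 shared samples")
  shared_g <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(shared_g) < 1) stop("no shared genes")
  A <- unclass(expr_a)[shared_g, shared_s, drop = FALSE]
  B <- unclass(expr_b)[shared_g, shared_s, drop = FALSE]
  r <- vapply(seq_along(shared_g), function(i) {
    if (stats::sd(A[i, ]) == 0 || stats::sd(B[i, ]) == 0) return(NA_real_)
    stats::cor(A[i, ], B[i, ])
  }, numeric(1))
  data.frame(gene = shared_g, r = r,
             below_threshold = is.na(r) | r <= threshold,
             is_proliferation = shared_g %in% proliferation_genes(),
             n_samples = length(shared_s),
             stringsAsFactors = FALSE)
}
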