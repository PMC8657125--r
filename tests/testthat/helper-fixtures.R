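# Fixtures built in code: tiny matrices and toy centroid sets.

# genes x samples expr_matrix with auto names
toy_expr <- function(values, genes = NULL, samples = NULL,
                     platform = "simulated") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(genes))
    genes <- if (!is.null(rownames(values))) rownames(values)
             else sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(values))) colnames(values)
               else sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, platform = platform, resolve_aliases = FALSE)
}

# toy centroid_set over arbitrary genes; full reduced mask by default
toy_centroids <- function(values, genes = NULL, mask = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  dimnames(values) <- list(genes, pam50_subtypes())
  if (is.null(mask)) mask <- rep(TRUE, length(genes))
  structure(list(genes = genes, subtypes = pam50_subtypes(),
                 values = values, reduced_mask = mask),
            class = "centroid_set")
}

# clinical table for simulated/toy samples
toy_clinical <- function(ids, nodes = "pN0", size = FALSE) {
  data.frame(sample_id = ids,
             size_gt_2cm = rep_len(size, length(ids)),
             node_class = factor(rep_len(nodes, length(ids)),
                                 levels = c("pN0", "pN1_3", "pN4plus")),
             stringsAsFactors = FALSE)
}

# textbook Pearson correlation, written independently of stats::cor
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
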