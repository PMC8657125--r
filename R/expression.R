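#' Construct an expression matrix object
#'
#' A thin validated wrapper around a numeric genes x samples matrix of log2
#' expression values, tagged with the platform it came from.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs). Values are log2 units.
#' @param platform One of `"nCounter_FFPE"`, `"RNAseq_FF"`, `"simulated"`.
#' @param resolve_aliases Resolve legacy gene symbols to canonical names
#'   (default `TRUE`).
#' @return An `expr_matrix`: the matrix with a `platform` attribute.
#' @export
expression_matrix <- function(values,
                              platform = c("simulated", "nCounter_FFPE", "RNAseq_FF"),
                              resolve_aliases = TRUE) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (resolve_aliases) {
    rn <- resolve_gene_aliases(rownames(values))
    dup <- rn[duplicated(rn)]
    if (length(dup))
      stop("duplicate gene symbol(s) after alias resolution: ",
           paste(unique(dup), collapse = ", "))
    rownames(values) <- rn
  } else if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (nrow(values) < 2) stop("need at least 2 genes")
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  # canonical panel order when the full panel is present
  panel <- pam50_genes()
  if (all(panel %in% rownames(values)) && nrow(values) == length(panel))
    values <- values[panel, , drop = FALSE]
  structure(values, platform = platform, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "platform")))
  invisible(x)
}

#' Keep matrix semantics (and attributes) under subsetting
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, platform = attr(x, "platform"),
                     class = c("expr_matrix", class(out)[!class(out) %in% "expr_matrix"]))
  out
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose first column (`gene`) holds gene
#' symbols and whose remaining columns are samples. Legacy symbols are
#' resolved to canonical names; if all 50 panel genes are present the rows
#' are reordered to canonical panel order.
#'
#' @param path Path to the TSV file.
#' @param platform Platform tag, see [expression_matrix()].
#' @return An `expr_matrix`.
#' @export
load_expression_matrix <- function(path,
                                   platform = c("simulated", "nCounter_FFPE", "RNAseq_FF")) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- df[[1]]
  num <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = list(genes, colnames(num))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s' in %s",
                 genes[bad[1]], colnames(num)[bad[2]], path))
  }
  expression_matrix(vals, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_matrix()]; values are written with six
#' decimals, so a round trip agrees to 1e-6.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   format(unclass(expr), digits = NULL, nsmall = 6,
                          trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a PAM50 centroid set
#'
#' Reads a TSV with columns `gene, Basal, Her2, LumA, LumB, Normal`,
#' resolves legacy gene symbols, orders genes to the canonical panel and
#' attaches the reduced 46-gene mask used for classification.
#'
#' The file packaged with this repository
#' (`inst/extdata/pam50_centroids_synthetic.tsv`) is a synthetic stand-in
#' for the published centroids: it reproduces their qualitative module
#' structure (proliferation, ER/luminal, HER2 amplicon, basal/keratin
#' blocks) but not their numeric values.
#'
#' @param path Path to a centroid TSV; default is the packaged synthetic set.
#' @return A `centroid_set`: list with `genes` (50 symbols), `subtypes`,
#'   `values` (50 x 5 matrix) and `reduced_mask` (logical, 46 `TRUE`).
#' @export
load_centroids <- function(path = system.file("extdata",
                                              "pam50_centroids_synthetic.tsv",
                                              package = "ror50")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", pam50_subtypes())
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("centroid file missing column(s): ", paste(miss, collapse = ", "))
  genes <- resolve_gene_aliases(df$gene)
  if (anyDuplicated(genes))
    stop("duplicate centroid gene(s) after alias resolution: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  panel <- pam50_genes()
  if (!setequal(genes, panel))
    stop(sprintf("centroid gene set must be the 50-gene panel after alias resolution (got %d genes; missing: %s)",
                 length(genes),
                 paste(setdiff(panel, genes), collapse = ", ")))
  vals <- as.matrix(df[, pam50_subtypes()])
  rownames(vals) <- genes
  vals <- vals[panel, , drop = FALSE]
  if (!all(is.finite(vals))) stop("centroid values must be finite")
  mask <- !(panel %in% reduced_panel_excluded())
  structure(list(genes = panel, subtypes = pam50_subtypes(),
                 values = vals, reduced_mask = mask),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d genes x %d subtypes (%d in reduced panel)\n",
              length(x$genes), length(x$subtypes), sum(x$reduced_mask)))
  invisible(x)
}

#' Load a clinical annotation table
#'
#' Reads a TSV with columns `sample_id, nodes, size_gt_2cm` and optional
#' `er_status, her2_status, prosigna_subtype, prosigna_ror`. `nodes` may be
#' given as class labels (`pN0`, `pN1_3`, `pN4plus`), as ranges
#' (`0`, `1-3`, `4+`) or as integer node counts, which are binned.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `node_class` as a factor over
#'   pN0/pN1_3/pN4plus and `size_gt_2cm` logical.
#' @export
load_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "nodes", "size_gt_2cm")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  df$node_class <- parse_node_class(df$nodes)
  df$size_gt_2cm <- parse_logical(df$size_gt_2cm)
  if ("prosigna_ror" %in% colnames(df)) {
    pr <- df$prosigna_ror
    if (any(!is.na(pr) & (pr < 0 | pr > 100)))
      stop("prosigna_ror outside [0, 100]")
  }
  df
}

#' @keywords internal
parse_node_class <- function(x) {
  x <- trimws(as.character(x))
  lab <- rep(NA_character_, length(x))
  lab[x %in% c("pN0", "0", "N0")] <- "pN0"
  lab[x %in% c("pN1_3", "1-3", "1_3", "pN1")] <- "pN1_3"
  lab[x %in% c("pN4plus", "4+", ">=4", "pN2", "pN3")] <- "pN4plus"
  n <- suppressWarnings(as.integer(x))
  num <- is.na(lab) & !is.na(n)
  lab[num & n == 0] <- "pN0"
  lab[num & n >= 1 & n <= 3] <- "pN1_3"
  lab[num & n >= 4] <- "pN4plus"
  if (anyNA(lab))
    stop("unparseable node status value(s): ",
         paste(unique(x[is.na(lab)]), collapse = ", "))
  factor(lab, levels = node_levels())
}

#' @keywords internal
parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("unparseable logical value(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Write a result table or report
#'
#' TSV output writes one row per record. JSON output wraps the results with
#' provenance metadata: package version, a content hash of the
#' configuration, and the seed, so a report identifies the run that made it.
#'
#' @param results A data.frame (tsv or json) or list (json) of results;
#'   must be non-empty.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param config Optional list describing the run configuration (hashed
#'   into the JSON metadata).
#' @param seed Optional integer seed recorded in JSON metadata.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         config = NULL, seed = NULL) {
  format <- match.arg(format)
  n <- if (is.data.frame(results)) nrow(results) else length(results)
  if (is.null(results) || n == 0)
    stop("refusing to write an empty report")
  if (format == "tsv") {
    if (!is.data.frame(results))
      stop("tsv reports require a data.frame")
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(
      meta = list(package = "ror50",
                  version = as.character(utils::packageVersion("ror50")),
                  config_hash = config_hash(config),
                  seed = seed),
      results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  invisible(path)
}

#' Content hash of a configuration list
#' @keywords internal
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
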