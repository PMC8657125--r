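test_that("expression TSV round-trips with alias resolution and panel ordering", {
  set.seed(11)
  # write the full panel under shuffled legacy names
  genes <- pam50_genes()
  legacy <- genes
  map <- gene_alias_map()
  for (i in seq_along(map)) legacy[legacy == map[i]] <- names(map)[i]
  ord <- sample(seq_along(genes))
  vals <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(legacy[ord], paste0("S", 1:4)))
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)

  m <- load_expression_matrix(f, platform = "nCounter_FFPE")
  expect_s3_class(m, "expr_matrix")
  expect_identical(rownames(m), genes)          # canonical order restored
  expect_identical(attr(m, "platform"), "nCounter_FFPE")
  expect_false(any(c("ORC6L", "KNTC2", "CDCA1") %in% rownames(m)))
  expect_equal(as.numeric(m["ORC6", "S1"]),
               as.numeric(vals[legacy[ord] == "ORC6L", "S1"]))

  # write-then-read identity within the 6-decimal formatting tolerance
  f2 <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, f2)
  m2 <- load_expression_matrix(f2, platform = "nCounter_FFPE")
  expect_identical(dimnames(m2), dimnames(m))
  expect_lt(max(abs(m2 - m)), 1e-6)
})

test_that("malformed expression files raise located errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "ESR1\t1.2\t2.2", "ERS1\t0.1\t0.2",
               "PGR\t1\t2"), f)
  expect_error(load_expression_matrix(f), "ESR1")   # ERS1 resolves onto ESR1

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "ESR1\t1.2\tabc", "PGR\t1\t2"), f2)
  expect_error(load_expression_matrix(f2), "ESR1.*S2")
})

test_that("alias resolution is idempotent and functional", {
  g <- c("ORC6L", "KNTC2", "CDCA1", "ERS1", "ESR1", "ANLN", "NOTAGENE")
  once <- resolve_gene_aliases(g)
  expect_identical(once, c("ORC6", "NDC80", "NUF2", "ESR1", "ESR1",
                           "ANLN", "NOTAGENE"))
  expect_identical(resolve_gene_aliases(once), once)
})

test_that("packaged centroid set has the reduced-mask structure and loads deterministically", {
  cen <- load_centroids()
  expect_identical(dim(cen$values), c(50L, 5L))
  expect_identical(cen$subtypes, c("Basal", "Her2", "LumA", "LumB", "Normal"))
  expect_identical(sum(cen$reduced_mask), 46L)
  expect_setequal(cen$genes[!cen$reduced_mask],
                  c("BIRC5", "CCNB1", "GRB7", "MYBL2"))
  expect_identical(cen, load_centroids())
})

test_that("centroid loading validates columns and gene set", {
  cen <- load_centroids()
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = cen$genes, cen$values, check.names = FALSE)
  write.table(df[, -2], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_centroids(f), "Basal")
  write.table(df[-1, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_centroids(f), "50-gene panel")
})

test_that("clinical tables parse node classes from counts, ranges and labels", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tnodes\tsize_gt_2cm",
               "A\t0\tTRUE", "B\t1-3\tFALSE", "C\t4+\t1",
               "D\t2\t0", "E\tpN0\tyes"), f)
  cl <- load_clinical(f)
  expect_identical(as.character(cl$node_class),
                   c("pN0", "pN1_3", "pN4plus", "pN1_3", "pN0"))
  expect_identical(cl$size_gt_2cm, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  writeLines(c("sample_id\tnodes\tsize_gt_2cm", "A\tmany\tTRUE"), f)
  expect_error(load_clinical(f), "node status")
})

test_that("reports round-trip and refuse empty inputs", {
  res <- data.frame(sample_id = c("A", "B"), ror = c(12.5, 61.25))
  f <- tempfile(fileext = ".tsv")
  write_report(res, f, "tsv")
  back <- read.delim(f)
  expect_equal(back$ror, res$ror)

  j <- tempfile(fileext = ".json")
  write_report(res, j, "json", config = list(w = 0.6), seed = 42L)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$results$ror, res$ror)
  expect_identical(parsed$meta$seed, 42L)
  expect_match(parsed$meta$config_hash, "^[0-9a-f]{32}$")

  expect_error(write_report(res[0, ], tempfile(), "tsv"), "empty")
})
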