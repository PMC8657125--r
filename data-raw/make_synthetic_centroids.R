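# Builds inst/extdata/pam50_centroids_synthetic.tsv: a SYNTHETIC stand-in
# for the published PAM50 subtype centroids. Values are designed once from
# the qualitative module structure of the published centroids —
# proliferation genes high in basal-like/luminal B and lowest in
# normal-like; the ER/luminal module high in luminal tumors; the HER2
# amplicon high in HER2-enriched; basal keratins shared by basal-like and
# normal epithelium — plus a small fixed jitter so no two genes are
# collinear. Units mimic gene-centered log2 ratios (roughly -2..2).
# The file uses legacy gene symbols (ORC6L, KNTC2, CDCA1) on purpose, as
# historical centroid files do, to exercise alias resolution.

order5 <- c("Basal", "Her2", "LumA", "LumB", "Normal")
prof <- list()
add <- function(genes, v) for (g in genes) prof[[g]] <<- v

prolif <- c("ANLN", "CEP55", "ORC6L", "CCNE1", "EXO1", "PTTG1", "CDC20",
            "KIF2C", "RRM2", "CDC6", "KNTC2", "TYMS", "CDCA1", "MELK",
            "UBE2C", "CENPF", "MKI67", "UBE2T", "BIRC5", "CCNB1", "MYBL2")
add(prolif, c(1.10, 0.45, -0.85, 0.75, -1.35))

luminal <- c("NAT1", "MAPT", "SLC39A6", "BCL2", "BLVRA", "CXXC5", "GPR160",
             "MLPH", "BAG1", "MDM2", "TMEM45B")
add(luminal, c(-1.30, -0.65, 0.95, 0.60, 0.25))
add("ESR1",  c(-1.80, -0.90, 1.30, 1.00, 0.30))
add("PGR",   c(-1.20, -0.90, 1.10, 0.30, 0.40))
add("FOXA1", c(-1.60, 0.20, 1.00, 0.90, 0.30))

add(c("ERBB2", "GRB7"), c(-0.40, 1.90, -0.30, 0.10, -0.30))
add("FGFR4",            c(-0.30, 1.10, -0.10, 0.20, -0.20))

basal <- c("MIA", "FOXC1", "CDH3", "EGFR", "PHGDH", "ACTR3B", "MYC")
add(basal, c(1.30, -0.20, -0.90, -0.70, 0.35))
# basal keratins and SFRP1: also expressed by normal breast epithelium
add(c("KRT5", "KRT14", "KRT17", "SFRP1"), c(1.40, -0.50, -1.00, -1.10, 0.90))

add("MMP11", c(-0.20, 0.60, 0.40, 0.60, -1.20))

genes <- names(prof)
stopifnot(length(genes) == 50)
M <- t(vapply(genes, function(g) prof[[g]], numeric(5)))
colnames(M) <- order5

set.seed(20211204)  # fixed once; publication date of the source study
M <- M + matrix(rnorm(50 * 5, 0, 0.15), 50, 5)

df <- data.frame(gene = genes, round(M, 4), check.names = FALSE)
dir.create(file.path("inst", "extdata"), recursive = TRUE, showWarnings = FALSE)
write.table(df, file.path("inst", "extdata", "pam50_centroids_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(df), "genes\n")
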