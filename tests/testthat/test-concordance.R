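test_that("score agreement statistics behave on identical and swapped inputs", {
  a <- setNames(c(10, 25, 60, 42), paste0("S", 1:4))
  expect_error(score_agreement(a[1:2], a[1:2]), "3 shared")
  self <- score_agreement(a, a)
  expect_equal(self$r_squared, 1.0)
  expect_equal(self$mean_abs_diff, 0)

  set.seed(5)
  b <- a + rnorm(4)
  ab <- score_agreement(a, b)
  ba <- score_agreement(b, a)
  expect_equal(ab$r_squared, ba$r_squared)
  expect_equal(ab$signed_diff_max, -ba$signed_diff_min)
  expect_equal(ab$signed_diff_min, -ba$signed_diff_max)
  expect_lte(ab$mean_abs_diff,
             max(abs(ab$signed_diff_min), abs(ab$signed_diff_max)))
  expect_error(score_agreement(a, setNames(rep(1, 4), names(a))),
               "zero variance")
})

test_that("subtype confusion counts match a hand tally", {
  a <- setNames(c("LumA", "LumA", "Basal"), c("s1", "s2", "s3"))
  b <- setNames(c("LumA", "LumB", "Basal"), c("s1", "s2", "s3"))
  m <- subtype_confusion(a, b)
  expect_identical(m["LumA", "LumA"], 1L)
  expect_identical(m["LumA", "LumB"], 1L)
  expect_identical(m["Basal", "Basal"], 1L)
  expect_identical(sum(m), 3L)
  expect_equal(attr(m, "concordance"), 2 / 3)

  ident <- subtype_confusion(a, a)
  expect_identical(sum(ident) - sum(diag(ident)), 0L)
  expect_equal(attr(ident, "concordance"), 1.0)
  expect_error(subtype_confusion(a, setNames("LumA", "zz")), "shared")
})

test_that("risk-group discordance applies thresholds, ordering and subsets", {
  mk <- function(ids, scores, nodes = "pN0") {
    res <- subtype_result_from_correlations(
      matrix(0, length(ids), 5, dimnames = list(ids, NULL)))
    ror_score(res, setNames(rep(0, length(ids)), ids),
              toy_clinical(ids, nodes = nodes)) -> r
    r$ror <- scores
    r$category <- categorize_risk(scores, as.character(r$node_class))
    r
  }
  ids <- c("a", "b")
  A <- mk(ids, c(39, 50))
  B <- mk(ids, c(45, 50))
  rec <- risk_group_discordance(A, B)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$sample_id, "a")
  expect_identical(rec$category_a, "low")
  expect_identical(rec$category_b, "intermediate")
  expect_equal(rec$signed_diff, -6)
  expect_identical(attr(rec, "n_compared"), 2L)

  none <- risk_group_discordance(A, A)
  expect_identical(nrow(none), 0L)

  # records come back sorted by decreasing signed difference
  ids3 <- c("a", "b", "c")
  A3 <- mk(ids3, c(39, 70, 41))
  B3 <- mk(ids3, c(45, 50, 39))
  rec3 <- risk_group_discordance(A3, B3)
  expect_identical(rec3$sample_id, c("b", "c", "a"))
  expect_true(all(diff(rec3$signed_diff) <= 0))

  # mismatched threshold tables refuse to compare
  B_alt <- mk(ids, c(45, 50))
  attr(B_alt, "thresholds") <- list(pN0 = c(30, 70), pN1_3 = c(15, 40),
                                    pN4plus = NULL)
  expect_error(risk_group_discordance(A, B_alt), "threshold")

  # eligibility subset keeps ER+/HER2-/pN0 samples only
  clin <- data.frame(sample_id = ids,
                     er_status = c("ER_pos", "ER_neg"),
                     her2_status = c("negative", "negative"),
                     node_class = factor(c("pN0", "pN0"),
                                         levels = c("pN0", "pN1_3", "pN4plus")))
  sub <- risk_group_discordance(A, B, clin, subset = "er_pos_her2_neg_pn0")
  expect_identical(attr(sub, "n_compared"), 1L)
  expect_identical(sub$sample_id, "a")
})

test_that("per-gene cross-platform correlation is affine-invariant and flags nulls", {
  set.seed(6)
  X <- matrix(rnorm(10 * 94), 10, 94)
  ea <- toy_expr(X)
  eb <- toy_expr(2 * X + 1)
  r <- per_gene_cross_correlation(ea, eb)
  expect_equal(r$r, rep(1, 10), tolerance = 1e-12)
  expect_false(any(r$below_threshold))

  # an independent gene shows |r| < 0.3 at n = 94
  Y <- X
  Y[1, ] <- rnorm(94)
  rn <- per_gene_cross_correlation(ea, toy_expr(Y))
  expect_lt(abs(rn$r[1]), 0.3)
  expect_true(rn$below_threshold[1])

  # zero-variance gene flagged as undefined, not an error
  Z <- X
  Z[2, ] <- 0
  rz <- per_gene_cross_correlation(ea, toy_expr(Z))
  expect_true(is.na(rz$r[2]))
  expect_true(rz$below_threshold[2])

  # proliferation genes are marked
  pg <- proliferation_genes()
  em <- toy_expr(X, genes = c(pg[1:5], sprintf("G%02d", 6:10)))
  rm <- per_gene_cross_correlation(em, em)
  expect_identical(rm$is_proliferation, c(rep(TRUE, 5), rep(FALSE, 5)))
})
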