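ror_inputs <- function(corr, prolif, size = FALSE, nodes = "pN0") {
  res <- subtype_result_from_correlations(matrix(corr, 1))
  list(subtypes = res,
       prolif = setNames(prolif, res$sample_id),
       clinical = toy_clinical(res$sample_id, nodes = nodes, size = size))
}

test_that("the proliferation score is the plain 18-gene mean", {
  pg <- proliferation_genes()
  expect_length(pg, 18)
  m1 <- toy_expr(matrix(0.5, 18, 1), genes = pg)
  expect_equal(unname(proliferation_score(m1)), 0.5)
  m2 <- toy_expr(matrix(1:18, 18, 1), genes = pg)
  expect_equal(unname(proliferation_score(m2)), 9.5)
  set.seed(8)
  perm <- sample(18)
  m3 <- toy_expr(matrix(1:18, 18, 1)[perm, , drop = FALSE], genes = pg[perm])
  expect_equal(unname(proliferation_score(m3)), 9.5)
  expect_error(proliferation_score(toy_expr(matrix(0, 17, 1),
                                            genes = pg[-1])), pg[1])
})

test_that("the ROR formula reproduces its analytic anchors", {
  z <- ror_inputs(rep(0, 5), 0)
  r0 <- ror_score(z$subtypes, z$prolif, z$clinical)
  expect_equal(r0$ror, 54.7690 * 0.8826, tolerance = 1e-4)

  t1 <- ror_inputs(rep(0, 5), 0, size = TRUE)
  r1 <- ror_score(t1$subtypes, t1$prolif, t1$clinical)
  expect_equal(r1$ror - r0$ror, 54.7690 * 0.1133, tolerance = 1e-4)

  la <- ror_inputs(c(0, 0, 1, 0, 0), 0)
  rla <- ror_score(la$subtypes, la$prolif, la$clinical)
  expect_equal(rla$ror, 54.7690 * (-0.3172 + 0.8826), tolerance = 1e-4)

  # the normal-like correlation never enters the score
  nl <- ror_inputs(c(0, 0, 0, 0, 0.9), 0)
  rnl <- ror_score(nl$subtypes, nl$prolif, nl$clinical)
  expect_equal(rnl$ror, r0$ror)
})

test_that("ROR is monotone in each input with the printed coefficient signs", {
  set.seed(77)
  co <- ror_coefficients()
  signs <- c(basal = sign(co$basal), her2 = sign(co$her2),
             luma = sign(co$luma), lumb = sign(co$lumb),
             prolif = sign(co$prolif))
  for (i in 1:20) {
    corr <- runif(5, -1, 1)
    prolif <- runif(1, -2, 2)
    base <- ror_inputs(corr, prolif)
    r_base <- ror_score(base$subtypes, base$prolif, base$clinical)$ror
    for (term in names(signs)) {
      corr2 <- corr; prolif2 <- prolif
      if (term == "prolif") prolif2 <- prolif + 0.1
      else corr2[match(term, c("basal", "her2", "luma", "lumb"))] <-
          corr2[match(term, c("basal", "her2", "luma", "lumb"))] + 0.1
      up <- ror_inputs(corr2, prolif2)
      r_up <- ror_score(up$subtypes, up$prolif, up$clinical)$ror
      expect_true(sign(r_up - r_base) == signs[term])
    }
  }
})

test_that("risk categorization honors node-dependent cutoffs and boundaries", {
  # boundary convention pinned by published categorized scores
  expect_identical(as.character(categorize_risk(39.94, "pN0")), "low")
  expect_identical(as.character(categorize_risk(54.86, "pN0")), "intermediate")
  expect_identical(as.character(categorize_risk(60.06, "pN0")), "high")
  expect_identical(as.character(categorize_risk(c(40, 60), "pN0")),
                   c("low", "intermediate"))
  # 1-3 positive nodes shift the cutoffs to 15/40
  expect_identical(as.character(categorize_risk(c(15, 15.01, 40, 40.01),
                                                "pN1_3")),
                   c("low", "intermediate", "intermediate", "high"))
  # 4+ nodes are always high risk
  expect_identical(as.character(categorize_risk(c(0, 5, 99), "pN4plus")),
                   rep("high", 3))
  expect_error(categorize_risk(NaN, "pN0"), "finite")
})

test_that("categorization is monotone in the score within each node class", {
  set.seed(13)
  scores <- sort(runif(200, -10, 110))
  for (cls in c("pN0", "pN1_3", "pN4plus")) {
    cat_codes <- as.integer(categorize_risk(scores, cls))
    expect_true(all(diff(cat_codes) >= 0))
  }
})

test_that("ror_score validates its clinical inputs and flags out-of-range scores", {
  z <- ror_inputs(rep(0, 5), 0)
  expect_error(ror_score(z$subtypes, setNames(0, "nope"), z$clinical),
               "missing")
  noT <- z$clinical; noT$size_gt_2cm <- NA
  expect_error(ror_score(z$subtypes, z$prolif, noT), "T indicator")

  hot <- ror_inputs(c(0, 1, 0, 1, 0), 5)   # pushes the raw score above 100
  r <- ror_score(hot$subtypes, hot$prolif, hot$clinical)
  expect_true(r$clipped)
  expect_gt(r$ror, 100)                     # raw value reported unclipped
})
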