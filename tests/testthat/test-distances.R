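test_that("global alignment is optimal against exhaustive enumeration", {
  al <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(al$gap_columns, 0)
  expect_equal(al$score, 8)

  al2 <- global_align("ACGT", "AGT")
  expect_equal(al2$gap_columns, 1)
  expect_equal(al2$score, oracle_align_score("ACGT", "AGT"))

  set.seed(5)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:7, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:7, 1), replace = TRUE),
               collapse = "")
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("p-distance uses pairwise deletion and is symmetric", {
  expect_equal(p_distance("ACGT", "ACGT")$p, 0)
  expect_equal(p_distance("ACGT", "ACGA")$p, 0.25)
  # gap and N columns are excluded from numerator and denominator
  pd <- p_distance("AC-GTN", "ACTGAA")
  expect_equal(pd$compared, 4)   # columns 3 (gap) and 6 (N) are excluded
  expect_equal(pd$p, 0.25)       # only column 5 (T/A) differs
  expect_error(p_distance("---", "AAA"), "zero comparable")
  expect_error(p_distance("ACG", "AC"), "lengths differ")
  set.seed(6)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 40, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 40, replace = TRUE), collapse = "")
    expect_equal(p_distance(a, b)$p, p_distance(b, a)$p)
    # invariant under simultaneous reverse-complement of both rows
    a2 <- chartr("ACGT", "TGCA", paste(rev(strsplit(a, "")[[1]]), collapse = ""))
    b2 <- chartr("ACGT", "TGCA", paste(rev(strsplit(b, "")[[1]]), collapse = ""))
    expect_equal(p_distance(a2, b2)$p, p_distance(a, b)$p)
  }
})

test_that("NG86 handles the textbook single- and multi-hit codon cases", {
  r0 <- ng86("ATGAAA", "ATGAAA")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$omega))

  # Phe TTT -> TTC: one synonymous third-position difference
  r1 <- ng86("TTTAAA", "TTCAAA")
  expect_equal(r1$Nd, 0)
  expect_equal(r1$Sd, 1)
  o1 <- oracle_ng86("TTTAAA", "TTCAAA")
  expect_equal(r1$S_sites, o1$S)
  expect_equal(r1$N_sites, o1$N)
  expect_equal(r1$Ka, o1$Ka)
  expect_equal(r1$Ks, o1$Ks)

  # two-hit codon TTA vs CTG: pathway-averaged split equals enumeration
  r2 <- ng86("TTA", "CTG")
  o2 <- oracle_ng86("TTA", "CTG")
  expect_equal(r2$Sd, o2$Sd)
  expect_equal(r2$Nd, o2$Nd)
})

test_that("NG86 equals the exhaustive oracle on random short CDS pairs", {
  set.seed(99)
  for (i in 1:150) {
    k <- sample(1:5, 1)
    a <- random_cds(k)
    b <- random_cds(k)
    r <- ng86(a, b)
    o <- oracle_ng86(a, b)
    expect_equal(r$S_sites + r$N_sites, 3 * r$codons)
    expect_equal(r$S_sites, o$S, info = paste(a, b))
    expect_equal(r$Sd, o$Sd, info = paste(a, b))
    expect_equal(r$Nd, o$Nd, info = paste(a, b))
    expect_equal(r$pS, o$pS, info = paste(a, b))
    expect_equal(r$pN, o$pN, info = paste(a, b))
  }
})

test_that("Jukes-Cantor correction has the right fixed points and domain", {
  expect_equal(jc_correct(0), 0)
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
  expect_gt(jc_correct(0.1), 0.1)  # correction always inflates
})

test_that("gene-set distances: identity, missing genes, class means", {
  g <- shared_genome()
  d <- gene_set_distances(g, g)
  expect_true(all(d$per_gene$p == 0))
  expect_equal(d$mean_p, 0)
  expect_equal(nrow(d$per_gene), 15)

  crippled <- g
  crippled$features <- crippled$features[crippled$features$name != "rrnS", ]
  expect_warning(d2 <- gene_set_distances(g, crippled), "rrnS")
  expect_equal(nrow(d2$per_gene), 14)
})

test_that("synonymy verdicts follow the distance thresholds", {
  expect_identical(synonymy_assessment(0.0032)$verdict, "likely_conspecific")
  expect_identical(synonymy_assessment(0.0829)$verdict, "likely_distinct")
  expect_identical(synonymy_assessment(0.02)$verdict, "ambiguous")
  # boundary values are not strictly below/above -> ambiguous
  expect_identical(synonymy_assessment(0.01)$verdict, "ambiguous")
  expect_identical(synonymy_assessment(0.03)$verdict, "ambiguous")
  v <- synonymy_assessment(0.005, thresholds = c(0.002, 0.004))
  expect_identical(v$verdict, "likely_distinct")
  expect_error(synonymy_assessment(0.5, thresholds = c(0.05, 0.01)))
  expect_error(synonymy_assessment(1.5))
})
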