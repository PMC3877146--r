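test_that("gene-content audit flags missing, duplicated and extra genes", {
  g <- shared_genome()
  a <- audit_gene_content(g)
  expect_length(a$missing, 0)
  expect_length(a$duplicated, 0)
  expect_true(a$complete)

  drop <- g
  drop$features <- drop$features[drop$features$name != "trnW", ]
  expect_identical(audit_gene_content(drop)$missing, "trnW")

  dup <- g
  extra <- dup$features[dup$features$name == "trnM", ]
  dup$features <- rbind(dup$features, extra)
  suppressWarnings(d2 <- mitogenome(dup$identifier, dup$sequence, dup$features))
  expect_identical(audit_gene_content(d2)$duplicated, "trnM")

  empty <- mitogenome("e", "ACGTACGT",
                      data.frame(name = character(), kind = character(),
                                 strand = character(), start = integer(),
                                 end = integer()))
  expect_length(audit_gene_content(empty)$missing, 37)
})

test_that("start/stop classification follows length mod 3 and trailing bases", {
  r <- classify_start_stop("ATGAAATAA", "toy")
  expect_identical(r$start_class, "canonical_ATN")
  expect_identical(r$stop_class, "complete_TAA")
  expect_false(r$internal_stop)

  # 3k+1 ending in T -> incomplete_T
  expect_identical(classify_start_stop("ATGAAAT", "toy")$stop_class, "incomplete_T")
  # 3k+2 ending in TA -> incomplete_TA
  expect_identical(classify_start_stop("ATGAAATA", "toy")$stop_class, "incomplete_TA")
  expect_identical(classify_start_stop("TTGAAATAG", "toy")$start_class, "TTG")
  expect_identical(classify_start_stop("TTGAAATAG", "toy")$stop_class, "complete_TAG")
  expect_identical(classify_start_stop("CCGAAACCC", "toy")$start_class, "other")
  expect_identical(classify_start_stop("CCGAAACCC", "toy")$stop_class, "other")
  # premature stop in the annotated frame (TAA at codon 2), final codon excluded
  expect_true(classify_start_stop("ATGTAAAAATAA", "toy")$internal_stop)
  expect_error(classify_start_stop("ATGAA", "toy"), "degenerate")
})

test_that("generated PCGs reproduce the configured start and stop classes", {
  g <- shared_genome()
  cfg <- attr(g, "config")
  aud <- audit_genome(g)
  for (i in seq_len(nrow(aud$codons))) {
    gene <- aud$codons$gene[i]
    expect_identical(aud$codons$start_codon[i], unname(cfg$start_codons[[gene]]),
                     info = gene)
    expect_identical(aud$codons$stop_class[i], unname(cfg$stop_modes[[gene]]),
                     info = gene)
    expect_false(aud$codons$internal_stop[i], info = gene)
  }
})

test_that("junction accounting classifies abutting, overlap and spacer pairs", {
  tiny <- tiny_two_gene_genome()
  j <- junction_accounting(tiny)
  expect_equal(nrow(j$junctions), 2)  # one internal + the wrap-around
  expect_true(all(j$junctions$relation == "abutting"))
  expect_equal(j$total_overlap_bp, 0)
  expect_equal(j$total_spacer_bp, 0)

  # nested feature excluded with a warning
  nest <- mitogenome("n", paste(rep("ACGT", 10), collapse = ""),
                     data.frame(name = c("big", "inner", "after"),
                                kind = "rRNA", strand = "J",
                                start = c(0L, 5L, 20L), end = c(18L, 9L, 40L)))
  expect_warning(jn <- junction_accounting(nest), "nested")
  expect_identical(jn$nested, "inner")
  expect_equal(nrow(jn$junctions), 2)
})

test_that("planted overlaps are recovered with their conserved shared sequences", {
  g <- shared_genome()
  j <- junction_accounting(g)
  expect_equal(j$n_overlap_junctions, 11)
  expect_equal(j$total_overlap_bp, 35)
  expect_equal(j$longest_overlap, 8)
  expect_equal(j$n_spacer_junctions, 10)
  ov <- j$junctions[j$junctions$relation == "overlap", ]
  expect_true(all(j$junctions$size[j$junctions$relation == "spacer"] >= 1 &
                    j$junctions$size[j$junctions$relation == "spacer"] <= 29))

  # the atp8/atp6 junction shares the conserved heptamer in coding orientation
  f <- g$features
  atp6_start <- f$start[f$name == "atp6"]
  shared <- substring(g$sequence, atp6_start + 1, atp6_start + 7)
  expect_identical(shared, "ATGATAA")
  expect_identical(substring(extract_gene(g, "atp6"), 1, 7), "ATGATAA")
  # nad4l/nad4: shared heptamer on the minority strand, coding orientation
  expect_identical(substring(extract_gene(g, "nad4"), 1, 7), "ATGTTAA")
  cytb_head <- substring(extract_gene(g, "cytb"), 1, 8)
  expect_identical(cytb_head, "ATGATTAA")
})

test_that("junction conservation identity holds on seeded genomes incl. rotations", {
  for (s in 1:8) {
    g <- generate_mitogenome(synthetic_config(seed = 3000 + s))
    off <- sample.int(g$length, 1)
    for (gen in list(g, rotate_mitogenome(g, off))) {
      j <- junction_accounting(gen)
      expect_equal(sum(feature_lengths(gen)) - j$total_overlap_bp +
                     j$total_spacer_bp, gen$length)
    }
  }
})

test_that("gene-order comparison is rotation-invariant and symmetric", {
  g <- shared_genome()
  sig <- gene_order_signature(g)
  expect_identical(sig$genes[1], "trnI")
  self <- compare_gene_order(sig, sig)
  expect_equal(self$n_broken, 0)

  sig_rot <- gene_order_signature(rotate_mitogenome(g, 4321L))
  expect_equal(compare_gene_order(sig, sig_rot)$n_broken, 0)
})

test_that("ancestral vs derived order differs exactly at the trnC/trnW junctions", {
  cw <- generate_mitogenome(synthetic_config(seed = 11, gene_order = "neuroptera_cw"))
  anc <- generate_mitogenome(synthetic_config(seed = 11, gene_order = "dyakuba"))
  scw <- gene_order_signature(cw)
  sanc <- gene_order_signature(anc)
  cmp <- compare_gene_order(scw, sanc)
  broken <- c(cmp$broken_a, cmp$broken_b)
  expect_true(length(broken) > 0)
  expect_true(all(grepl("trnC|trnW", broken)))
  expect_true(cmp$flags$a$cw_swap)
  expect_false(cmp$flags$b$cw_swap)
  # symmetry of the broken-adjacency count
  rev_cmp <- compare_gene_order(sanc, scw)
  expect_equal(rev_cmp$n_broken, cmp$n_broken)
})

test_that("broken-adjacency count matches brute-force neighbour enumeration", {
  g <- shared_genome()
  sig <- gene_order_signature(g)
  # transpose one tRNA: move trnF next to trnV
  genes <- sig$genes; strands <- sig$strands
  i <- match("trnF", genes)
  genes2 <- append(genes[-i], "trnF", after = match("trnV", genes[-i]))
  strands2 <- append(strands[-i], sig$strands[i],
                     after = match("trnV", genes[-i]))
  sig2 <- structure(list(genes = genes2, strands = strands2, anchor = genes2[1]),
                    class = "gene_order_signature")
  cmp <- compare_gene_order(sig, sig2)
  o1 <- oracle_adjacencies(sig$genes, sig$strands)
  o2 <- oracle_adjacencies(sig2$genes, sig2$strands)
  expect_equal(cmp$n_broken, length(setdiff(o1, o2)) + length(setdiff(o2, o1)))
  expect_true(cmp$n_broken > 0)
})
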