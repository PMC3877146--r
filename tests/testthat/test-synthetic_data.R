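test_that("generation is deterministic: same seed, byte-identical output", {
  g1 <- generate_mitogenome(synthetic_config(seed = 123))
  g2 <- generate_mitogenome(synthetic_config(seed = 123))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  expect_identical(attr(g1, "trna_structures"), attr(g2, "trna_structures"))
  g3 <- generate_mitogenome(synthetic_config(seed = 124))
  expect_false(identical(g1$sequence, g3$sequence))

  p1 <- withr::local_tempfile(fileext = ".gb")
  p2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g1, p1)
  write_genbank(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(), "seed is mandatory")
  expect_error(synthetic_config(seed = 1, at_coding = 1.2))
  gl <- default_gene_lengths()
  gl["cox1"] <- 1536L  # 3k, incompatible with an incomplete_T stop
  expect_error(synthetic_config(seed = 1, gene_lengths = gl), "incompatible")
})

test_that("generated genome passes the full audit with the derived gene order", {
  g <- shared_genome()
  expect_true(audit_gene_content(g)$complete)
  expect_equal(nrow(g$features), 38)  # 37 genes + CR
  expect_true(has_cw_swap(gene_order_signature(g)))
  anc <- generate_mitogenome(synthetic_config(seed = 7, gene_order = "dyakuba"))
  expect_false(has_cw_swap(gene_order_signature(anc)))
  # 23 features on the majority strand, 14 on the minority (+ CR on J)
  expect_equal(sum(g$features$strand == "J" & g$features$name != "CR"), 23)
  expect_equal(sum(g$features$strand == "N"), 14)
})

test_that("zero rates give an identical child and an empty log", {
  g <- shared_genome()
  r <- mutate_genome(g, list(syn = 0, nonsyn = 0, rna = 0, cr_sub = 0,
                             cr_indel = 0), seed = 5)
  expect_identical(r$genome$sequence, g$sequence)
  expect_equal(nrow(r$log$events), 0)
  expect_equal(nrow(r$log$cr_indels), 0)
})

test_that("mutation is deterministic given a seed and rejects extreme rates", {
  g <- shared_genome()
  r1 <- mutate_genome(g, list(syn = 0.01, rna = 0.01), seed = 9)
  r2 <- mutate_genome(g, list(syn = 0.01, rna = 0.01), seed = 9)
  expect_identical(r1$genome$sequence, r2$genome$sequence)
  expect_identical(r1$log$events, r2$log$events)
  expect_error(mutate_genome(g, list(syn = 0.9), seed = 1))
})

test_that("a synonymous-only process leaves Ka at exactly zero", {
  g <- shared_genome()
  r <- mutate_genome(g, list(syn = 0.03, nonsyn = 0), seed = 17)
  expect_true(any(r$log$events$class == "synonymous"))
  expect_false(any(r$log$events$class == "nonsynonymous"))
  kk <- genome_kaks(g, r$genome)
  expect_true(all(kk$Ka == 0))
  expect_true(any(kk$Ks > 0))
})

test_that("planted starts, stops and overlap sequences are protected from mutation", {
  g <- shared_genome()
  r <- mutate_genome(g, list(syn = 0.2, nonsyn = 0.05, rna = 0.2), seed = 31)
  child <- r$genome
  cfg <- attr(g, "config")
  aud <- audit_genome(child)
  for (i in seq_len(nrow(aud$codons))) {
    gene <- aud$codons$gene[i]
    expect_identical(aud$codons$start_codon[i], unname(cfg$start_codons[[gene]]))
    expect_identical(aud$codons$stop_class[i], unname(cfg$stop_modes[[gene]]))
    expect_false(aud$codons$internal_stop[i])
  }
  expect_identical(substring(extract_gene(child, "atp6"), 1, 7), "ATGATAA")
  expect_identical(substring(extract_gene(child, "nad4"), 1, 7), "ATGTTAA")
  j <- junction_accounting(child)
  expect_equal(j$n_overlap_junctions, 11)
  expect_equal(j$total_overlap_bp, 35)
})

test_that("the mutation log replays to the child exactly", {
  pair <- shared_pair()
  rebuilt <- replay_mutations(pair$parent, pair$log)
  expect_identical(rebuilt$sequence, pair$child$sequence)
  expect_identical(rebuilt$features, pair$child$features)
  expect_true(nrow(pair$log$cr_indels) > 0)  # the CR indel process did run
})

test_that("control-region indels change CR length and shift only downstream coordinates", {
  g <- shared_genome()
  r <- mutate_genome(g, list(cr_indel = 0.01), seed = 41)
  del <- sum(r$log$cr_indels$len[r$log$cr_indels$type == "del"])
  expect_gt(del, 0)
  expect_equal(r$genome$length, g$length - del)
  fcr <- g$features[g$features$name == "CR", ]
  before <- g$features$start < fcr$start
  expect_equal(r$genome$features$start[before], g$features$start[before])
  al <- global_align(extract_gene(g, "CR"), extract_gene(r$genome, "CR"))
  expect_equal(al$gap_columns, del)
})

test_that("per-gene p-distance estimates are unbiased against the planted rate", {
  g <- shared_genome()
  d <- 0.01
  n_rep <- 30
  tot_diff <- 0; tot_sites <- 0; tot_len <- 0
  genes <- c(canonical_gene_set()[1:13])
  for (s in seq_len(n_rep)) {
    r <- mutate_genome(g, list(syn = d, nonsyn = d), seed = 7000 + s)
    el <- r$log$eligible
    for (gene in genes) {
      pa <- extract_gene(g, gene); pb <- extract_gene(r$genome, gene)
      pd <- p_distance(pa, pb, gene)
      tot_diff <- tot_diff + pd$differing
      tot_sites <- tot_sites + el$sites[el$gene == gene]
      tot_len <- tot_len + pd$compared
    }
  }
  expected <- d * tot_sites / tot_len
  p_hat <- tot_diff / tot_len
  se <- sqrt(expected * (1 - expected) / tot_len)
  expect_lt(abs(p_hat - expected), 3 * se)
})

test_that("fixture pairs realise their divergence profiles", {
  pair <- shared_pair()
  expect_identical(pair$report$verdict$verdict, "likely_conspecific")
  expect_lt(pair$report$mean_p_all, 0.01)
  kk <- pair$report$kaks
  with_sub <- !is.na(kk$omega)
  expect_true(all(kk$omega[with_sub] < 1))  # purifying regime: nonsyn << syn

  far <- make_fixture_pair("distinct_like", seed = 3)
  frag <- p_distance(extract_gene(far$parent, "rrnL"),
                     extract_gene(far$child, "rrnL"))
  expect_gt(frag$p, 0.03)
  expect_identical(synonymy_assessment(frag$p)$verdict, "likely_distinct")
})
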