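test_that("reverse complement is a strand involution over {A,C,G,T,N}", {
  expect_identical(reverse_complement("AATT"), "AATT")
  expect_identical(reverse_complement("ATGATAA"), "TTATCAT")
  expect_identical(reverse_complement("ANC"), "GNT")
  expect_error(reverse_complement("ACGU"), "alphabet")
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("mitogenome construction validates and normalizes coordinates", {
  expect_error(mitogenome("x", "ACGU", data.frame()), "outside")
  f <- data.frame(name = "g", kind = "rRNA", strand = "J", start = 2, end = 2)
  expect_error(mitogenome("x", "ACGTACGT", f), "end must exceed start")
  # start beyond length is reduced modulo length, preserving the span
  f2 <- data.frame(name = "g", kind = "rRNA", strand = "J", start = 9, end = 12)
  g <- mitogenome("x", "ACGTACGT", f2)
  expect_equal(g$features$start, 1)
  expect_equal(g$features$end, 4)
  expect_error(mitogenome("x", "ACGT",
                          data.frame(name = "g", kind = "rRNA", strand = "+",
                                     start = 0, end = 2)), "strand")
})

test_that("extract_gene honours strand and wraps across the origin", {
  seq <- "ATGCATGCATGCATGCATGC"  # 20 bp
  feats <- data.frame(name = c("fwd", "rev", "wrap"),
                      kind = "rRNA", strand = c("J", "N", "J"),
                      start = c(0L, 0L, 15L), end = c(4L, 4L, 25L))
  g <- mitogenome("t", seq, feats)
  expect_identical(extract_gene(g, "fwd"), "ATGC")
  expect_identical(extract_gene(g, "rev"), "GCAT")
  wrapped <- extract_gene(g, "wrap")
  expect_identical(wrapped, paste0(substring(seq, 16, 20), substring(seq, 1, 5)))
  expect_equal(nchar(wrapped), 10)  # == end - start despite wrapping
  expect_error(extract_gene(g, "nope"), "lookup")
})

test_that("extracted length equals end - start for every feature after rotation", {
  g <- shared_genome()
  for (off in c(1L, 5000L, g$length - 3L)) {
    r <- rotate_mitogenome(g, off)
    lens <- feature_lengths(r)
    for (nm in names(lens))
      expect_equal(nchar(extract_gene(r, nm)), unname(lens[[nm]]), info = nm)
  }
})

test_that("GenBank write -> read round trip preserves everything", {
  g0 <- shared_genome()
  f_nad2 <- g0$features[g0$features$name == "nad2", ]
  g <- rotate_mitogenome(g0, (f_nad2$start + f_nad2$end) %/% 2)
  # rotating into the middle of nad2 makes it span the origin
  expect_true(any(g$features$end > g$length))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_true(g2$is_circular)
  f1 <- g$features[order(g$features$name), c("name", "kind", "strand", "start", "end")]
  f2 <- g2$features[order(g2$features$name), c("name", "kind", "strand", "start", "end")]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2, f1)
})

test_that("GenBank dialect parsing: complement strand, origin join, name mapping", {
  seq <- paste(rep("acgtacgtac", 20), collapse = "")  # 200 bp
  gb <- c(
    "LOCUS       TEST00001                200 bp    DNA     circular INV 01-JAN-2020",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "     CDS             complement(5..100)",
    '                     /gene="ND1"',
    "     CDS             join(190..200,1..50)",
    '                     /product="cytochrome c oxidase subunit 1"',
    "     rRNA            101..160",
    '                     /product="16S ribosomal RNA"',
    "     D-loop          161..189",
    "ORIGIN",
    paste0("        1 ", paste(substring(seq, seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    paste0("       61 ", paste(substring(seq, seq(61, 111, 10), seq(70, 120, 10)),
                               collapse = " ")),
    paste0("      121 ", paste(substring(seq, seq(121, 171, 10), seq(130, 180, 10)),
                               collapse = " ")),
    paste0("      181 ", paste(substring(seq, seq(181, 191, 10), seq(190, 200, 10)),
                               collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- read_genbank(path)
  f <- g$features
  expect_setequal(f$name, c("nad1", "cox1", "rrnL", "CR"))
  expect_equal(f$strand[f$name == "nad1"], "N")
  cox1 <- f[f$name == "cox1", ]
  expect_equal(cox1$start, 189)
  expect_equal(cox1$end, 250)  # wrapped: 11 + 50 = 61 bp
  expect_equal(nchar(extract_gene(g, "cox1")), 61)
  expect_equal(f$kind[f$name == "CR"], "control_region")
})

test_that("feature table and FASTA side-car round trip", {
  g <- shared_genome()
  ft <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_feature_table(g, ft)
  write_fasta(g, fa)
  g2 <- read_fasta_genome(fa, feature_table = ft)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$features[, c("name", "strand", "start", "end")],
               g$features[, c("name", "strand", "start", "end")])
})

test_that("gene-name normalization covers the common GenBank dialects", {
  expect_identical(normalize_gene_name(c("COB", "CYTB", "cytochrome b")),
                   rep("cytb", 3))
  expect_identical(normalize_gene_name("NADH dehydrogenase subunit 4L"), "nad4l")
  expect_identical(normalize_gene_name(c("16S rRNA", "l-rRNA", "12S ribosomal RNA")),
                   c("rrnL", "rrnL", "rrnS"))
  expect_identical(normalize_gene_name(c("tRNA-Trp", "trnW", "tRNA-Leu(UUR)",
                                         "tRNA-Ser(AGN)")),
                   c("trnW", "trnW", "trnL2", "trnS1"))
  expect_identical(normalize_gene_name(c("D-loop", "control region")),
                   c("CR", "CR"))
  expect_true(is.na(normalize_gene_name("totally unknown")))
})
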