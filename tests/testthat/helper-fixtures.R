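# Shared fixtures, generated once per test run.

.fixture_env <- new.env()

shared_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- generate_mitogenome(synthetic_config(seed = 42))
  .fixture_env$genome
}

shared_pair <- function() {
  if (is.null(.fixture_env$pair))
    .fixture_env$pair <- make_fixture_pair("rapisma_like", seed = 42)
  .fixture_env$pair
}

# a tiny hand-made circular genome with fully known layout:
#   geneA [0,10) J, geneB [10,20) J on a 20 bp circle (both abutting)
tiny_two_gene_genome <- function() {
  mitogenome("tiny", paste(rep(c("A", "C", "G", "T"), 5), collapse = ""),
             data.frame(name = c("geneA", "geneB"),
                        kind = c("rRNA", "rRNA"), strand = c("J", "J"),
                        start = c(0L, 10L), end = c(10L, 20L)),
             is_circular = TRUE)
}
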