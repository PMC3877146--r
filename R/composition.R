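# Base composition, strand skews and codon usage / RSCU.
#
# Skews follow the usual strand-asymmetry definitions,
# AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), computed from raw
# counts (never from rounded percentages). N bases are excluded from all
# counts.

#' Base composition and strand skews of a sequence
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return List of class `composition_report`: `counts` (A/C/G/T, N
#'   excluded), `pct`, `at_content` (percent), `at_skew`, `gc_skew`
#'   (dimensionless, in `[-1, 1]`; `NA` when the denominator is zero).
#' @export
composition_report <- function(seq) {
  seq <- toupper(seq)
  if (!.valid_seq(seq)) stop("alphabet error")
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars != "N"]
  if (!length(chars)) stop("undefined composition: sequence empty after N removal")
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), numeric(1))
  tot <- sum(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts,
    pct = 100 * counts / tot,
    at_content = 100 * at / tot,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "composition_report")
}

#' Codon usage and RSCU over a set of coding sequences
#'
#' Each sequence is assumed to start in frame; trailing 1-2 nt (incomplete
#' stop codons) are dropped. Codons containing `N` (or alignment gaps) are
#' skipped. Complete stop codons are tallied separately and excluded from
#' the percentage and RSCU denominators. RSCU is a codon's count divided by
#' the mean count of its synonymous family (so an unbiased family has RSCU 1
#' for every member and family RSCU values sum to the family size).
#'
#' @param cds_set character vector (or list) of in-frame CDS sequences.
#' @param table a [codon_table()]; its `family_mode` fixes the family
#'   partition.
#' @return Object of class `codon_usage`: data frame `codons` (codon,
#'   amino_acid, family, count, pct, rscu), `stop_counts`, `n_codons`
#'   (sense codons counted), `family_mode`.
#' @export
codon_usage <- function(cds_set, table = codon_table()) {
  cds_set <- toupper(unlist(cds_set, use.names = FALSE))
  all_cods <- unlist(lapply(cds_set, function(s) {
    n <- nchar(s)
    k <- n %/% 3
    if (n %% 3 != 0 && n %% 3 != 1 && n %% 3 != 2) stop("unreachable")
    if (k == 0) return(character())
    substring(s, 3 * (seq_len(k) - 1) + 1, 3 * seq_len(k))
  }))
  clean <- all_cods[grepl("^[ACGT]{3}$", all_cods)]
  if (length(clean) < length(all_cods))
    warning(length(all_cods) - length(clean), " codon(s) with gaps/N skipped")
  sense <- names(table$aa)[table$aa != "*"]
  stop_counts <- vapply(table$stops, function(cd) sum(clean == cd), numeric(1))
  counts <- vapply(sense, function(cd) sum(clean == cd), numeric(1))
  tot <- sum(counts)
  fam <- table$family[sense]
  rscu <- numeric(length(sense))
  for (fm in unique(fam)) {
    idx <- which(fam == fm)
    fs <- sum(counts[idx])
    rscu[idx] <- if (fs > 0) counts[idx] * length(idx) / fs else 0
  }
  codons <- data.frame(codon = sense, amino_acid = unname(table$aa[sense]),
                       family = unname(fam), count = unname(counts),
                       pct = if (tot > 0) 100 * unname(counts) / tot else 0,
                       rscu = rscu, stringsAsFactors = FALSE)
  structure(list(codons = codons, stop_counts = stop_counts, n_codons = tot,
                 family_mode = table$family_mode), class = "codon_usage")
}

#' Most-used and unused codons
#'
#' Ranking is by percentage of counted sense codons, ties broken
#' lexicographically.
#'
#' @param table a [codon_usage()] result.
#' @param n number of codons to return (capped at the number of sense
#'   codons).
#' @return `top_codons`: data frame of the `n` top codons;
#'   `absent_codons`: character vector of sense codons with count zero.
#' @export
top_codons <- function(table, n = 6) {
  cod <- table$codons
  ord <- order(-cod$pct, cod$codon)
  utils::head(cod[ord, c("codon", "amino_acid", "count", "pct", "rscu")],
              min(n, nrow(cod)))
}

#' @rdname top_codons
#' @export
absent_codons <- function(table) {
  sort(table$codons$codon[table$codons$count == 0])
}

#' Codon usage of a genome's protein-coding genes
#'
#' Convenience wrapper: extracts every annotated PCG in coding orientation
#' and feeds the set to [codon_usage()].
#'
#' @param genome a `mitogenome`.
#' @param table a [codon_table()].
#' @export
genome_codon_usage <- function(genome, table = codon_table()) {
  pcgs <- intersect(genome$features$name, PCG_GENES)
  codon_usage(vapply(pcgs, function(g) extract_gene(genome, g), character(1)),
              table = table)
}

#' Export a codon-usage table as TSV
#'
#' @param usage a [codon_usage()] result.
#' @param path output TSV path.
#' @export
write_codon_usage <- function(usage, path) {
  utils::write.table(usage$codons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
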