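# Annotation auditing: gene content vs the canonical 37-gene set, start/stop
# codon classification, overlap/spacer accounting around the circle, and
# rotation-invariant gene-order comparison.

#' Audit gene content against the canonical 37-gene set
#'
#' @param genome a `mitogenome`.
#' @return List with `missing`, `duplicated` and `extra` gene-symbol vectors
#'   plus a `complete` flag (the control region is not part of the 37-gene
#'   inventory and is ignored here).
#' @export
audit_gene_content <- function(genome) {
  canon <- canonical_gene_set()
  present <- genome$features$name
  list(missing = setdiff(canon, present),
       duplicated = sort(unique(present[duplicated(present)])),
       extra = setdiff(present, c(canon, "CR")),
       complete = length(setdiff(canon, present)) == 0 &&
         !anyDuplicated(present))
}

#' Classify the start and stop codon of a protein-coding gene
#'
#' The start codon is the first 3 nt of the coding-strand sequence; the stop
#' class is derived from the extracted length modulo 3 and the trailing
#' nucleotides (a length of 3k+1 ending in `T` or 3k+2 ending in `TA` is an
#' incomplete stop, completed by post-transcriptional polyadenylation). The
#' reading frame is taken from the annotation, never re-inferred; internal
#' translation is scanned for premature stop codons (final codon excluded).
#'
#' @param genome a `mitogenome`.
#' @param gene PCG name.
#' @param table a [codon_table()].
#' @return List of class `codon_report`: `gene`, `start_codon`,
#'   `start_class` (`canonical_ATN`/`TTG`/`GTG`/`other`), `stop_class`
#'   (`complete_TAA`/`complete_TAG`/`incomplete_TA`/`incomplete_T`/`other`),
#'   `internal_stop` flag.
#' @export
classify_start_stop <- function(genome, gene, table = codon_table()) {
  seq <- if (inherits(genome, "mitogenome")) extract_gene(genome, gene) else genome
  n <- nchar(seq)
  if (n < 6) stop("degenerate gene: '", gene, "' has extracted length ", n, " < 6")
  start_codon <- substring(seq, 1, 3)
  start_class <-
    if (start_codon %in% c("ATA", "ATT", "ATC", "ATG")) "canonical_ATN"
    else if (start_codon == "TTG") "TTG"
    else if (start_codon == "GTG") "GTG"
    else "other"
  r <- n %% 3
  stop_class <- if (r == 0) {
    last3 <- substring(seq, n - 2, n)
    if (last3 == "TAA") "complete_TAA"
    else if (last3 == "TAG") "complete_TAG" else "other"
  } else if (r == 2) {
    if (substring(seq, n - 1, n) == "TA") "incomplete_TA" else "other"
  } else {
    if (substring(seq, n, n) == "T") "incomplete_T" else "other"
  }
  n_codons <- n %/% 3
  interior <- if (r == 0) seq_len(n_codons - 1) else seq_len(n_codons)
  cods <- substring(seq, (interior - 1) * 3 + 1, interior * 3)
  internal_stop <- any(cods %in% table$stops)
  structure(list(gene = gene, start_codon = start_codon,
                 start_class = start_class, stop_class = stop_class,
                 internal_stop = internal_stop), class = "codon_report")
}

#' Account for every junction on the gene circle
#'
#' Features are sorted by start; each adjacent pair (including the
#' wrap-around between the last and first feature on a circular genome)
#' yields one junction record classified as `overlap`, `spacer` or
#' `abutting`. A feature nested entirely within its predecessor is excluded
#' from the spacer arithmetic and reported separately with a warning.
#'
#' Conservation identity (no nesting): sum of feature lengths minus total
#' overlap plus total spacer equals the genome length.
#'
#' @param genome a `mitogenome`.
#' @return List with `junctions` (data frame: `upstream`, `downstream`,
#'   `relation`, `size`) and totals `n_overlap_junctions`,
#'   `total_overlap_bp`, `longest_overlap`, `total_spacer_bp`,
#'   `n_spacer_junctions`, `nested` (names of nested features).
#' @export
junction_accounting <- function(genome) {
  f <- genome$features[order(genome$features$start), ]
  n <- nrow(f)
  if (n < 2) stop("need at least two features for junction accounting")
  nested <- character()
  keep <- rep(TRUE, n)
  # nested = start and end both inside the running envelope of earlier features
  reach <- f$end[1]
  for (i in 2:n) {
    if (f$end[i] <= reach) {
      nested <- c(nested, f$name[i]); keep[i] <- FALSE
    } else {
      reach <- f$end[i]
    }
  }
  if (length(nested)) warning("nested feature(s) excluded: ", paste(nested, collapse = ", "))
  f <- f[keep, ]
  n <- nrow(f)
  up <- f$name
  down <- c(f$name[-1], f$name[1])
  gaps <- c(f$start[-1] - f$end[-n],
            if (genome$is_circular) (f$start[1] + genome$length) - f$end[n] else NA)
  if (!genome$is_circular) { up <- up[-n]; down <- down[-n]; gaps <- gaps[-n] }
  rel <- ifelse(gaps < 0, "overlap", ifelse(gaps > 0, "spacer", "abutting"))
  junctions <- data.frame(upstream = up, downstream = down, relation = rel,
                          size = abs(gaps), stringsAsFactors = FALSE)
  ov <- junctions$size[junctions$relation == "overlap"]
  list(junctions = junctions,
       n_overlap_junctions = sum(junctions$relation == "overlap"),
       total_overlap_bp = sum(ov),
       longest_overlap = if (length(ov)) max(ov) else 0L,
       total_spacer_bp = sum(junctions$size[junctions$relation == "spacer"]),
       n_spacer_junctions = sum(junctions$relation == "spacer"),
       nested = nested)
}

#' Circular gene-order signature
#'
#' The ordered list of (gene, strand) around the circle, rotated to begin at
#' a fixed anchor gene so comparisons are rotation-invariant.
#'
#' @param genome a `mitogenome`.
#' @param anchor anchor gene (default `trnI`, the conventional start of the
#'   insect mitogenome); if absent the lexicographically first gene is used.
#' @return Object of class `gene_order_signature` with `genes` and `strands`.
#' @export
gene_order_signature <- function(genome, anchor = "trnI") {
  f <- genome$features[order(genome$features$start), ]
  i <- match(anchor, f$name)
  if (is.na(i)) i <- which.min(f$name)
  ord <- c(i:nrow(f), seq_len(i - 1))
  structure(list(genes = f$name[ord], strands = f$strand[ord], anchor = f$name[i]),
            class = "gene_order_signature")
}

.adjacency_set <- function(sig) {
  n <- length(sig$genes)
  a <- sig$genes
  b <- c(sig$genes[-1], sig$genes[1])
  sa <- sig$strands
  sb <- c(sig$strands[-1], sig$strands[1])
  orient <- ifelse(sa == sb, "same", "opposite")
  vapply(seq_len(n), function(i) {
    pair <- sort(c(a[i], b[i]))
    paste(pair[1], pair[2], orient[i], sep = "|")
  }, character(1))
}

#' Compare two circular gene orders
#'
#' Adjacency = an unordered pair of neighbouring genes together with their
#' relative orientation. The comparison is invariant under rotation and is
#' symmetric in the broken-adjacency count. Named rearrangement flags are
#' evaluated on each signature; currently `cw_swap` = tRNA-Cys immediately
#' upstream of tRNA-Trp (the derived arrangement shared by Neuroptera,
#' against the ancestral insect order where tRNA-Cys follows tRNA-Trp).
#'
#' @param a,b `gene_order_signature` objects.
#' @return List with `shared`, `broken_a`, `broken_b` adjacency keys,
#'   `n_broken`, gene-set differences, and `flags` (per signature).
#' @export
compare_gene_order <- function(a, b) {
  only_a <- setdiff(a$genes, b$genes)
  only_b <- setdiff(b$genes, a$genes)
  sa <- .adjacency_set(a)
  sb <- .adjacency_set(b)
  list(shared = intersect(sa, sb),
       broken_a = setdiff(sa, sb),
       broken_b = setdiff(sb, sa),
       n_broken = length(setdiff(sa, sb)) + length(setdiff(sb, sa)),
       genes_only_a = only_a, genes_only_b = only_b,
       flags = list(a = list(cw_swap = has_cw_swap(a)),
                    b = list(cw_swap = has_cw_swap(b))))
}

#' @rdname compare_gene_order
#' @export
has_cw_swap <- function(sig) {
  i <- match("trnC", sig$genes)
  if (is.na(i)) return(FALSE)
  nxt <- sig$genes[if (i == length(sig$genes)) 1 else i + 1]
  identical(nxt, "trnW")
}

#' Full annotation audit of one genome
#'
#' Convenience wrapper combining [audit_gene_content()],
#' [classify_start_stop()] over all PCGs and [junction_accounting()].
#'
#' @param genome a `mitogenome`.
#' @param table a [codon_table()].
#' @return List with `content`, `codons` (data frame), `junctions`.
#' @export
audit_genome <- function(genome, table = codon_table()) {
  content <- audit_gene_content(genome)
  pcgs <- intersect(genome$features$name, PCG_GENES)
  codons <- do.call(rbind, lapply(pcgs, function(g) {
    r <- classify_start_stop(genome, g, table)
    data.frame(gene = g, start_codon = r$start_codon, start_class = r$start_class,
               stop_class = r$stop_class, internal_stop = r$internal_stop,
               stringsAsFactors = FALSE)
  }))
  list(content = content, codons = codons, junctions = junction_accounting(genome))
}
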