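# Classification of tRNA cloverleaf stem pairs and structural comparison of
# the tRNA complements of two genomes. Cloverleaf annotations are input (a
# TSV per genome), not inferred: structure prediction is an external step.

#' Read / write a tRNA cloverleaf structure table
#'
#' TSV columns: `trna`, `record` (`pair` or `span`), `element` (arm name
#' `AA`/`DHU`/`AC`/`T` for pairs; `DHU_loop`, `AC_loop`, `anticodon`,
#' `variable_loop`, `T_loop` for spans), `pos_i`, `pos_j` (0-based
#' tRNA-local positions; for spans, the inclusive range ends). Validated on
#' load: pairs must be non-crossing within an arm, the acceptor stem has at
#' most 7 pairs, and the anticodon span is exactly 3 nt.
#'
#' @param path TSV path.
#' @return Data frame with the columns above.
#' @export
read_trna_structures <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trna", "record", "element", "pos_i", "pos_j")
  if (!all(need %in% names(tab)))
    stop("structure table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  validate_trna_structure(tab)
  tab
}

#' @rdname read_trna_structures
#' @param structures structure data frame to write.
#' @export
write_trna_structures <- function(structures, path) {
  utils::write.table(structures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_trna_structures
#' @export
validate_trna_structure <- function(structures) {
  for (tr in unique(structures$trna)) {
    st <- structures[structures$trna == tr, ]
    pairs <- st[st$record == "pair", ]
    for (arm in unique(pairs$element)) {
      p <- pairs[pairs$element == arm, ]
      if (arm == "AA" && nrow(p) > 7)
        stop(tr, ": acceptor stem has ", nrow(p), " pairs (> 7)")
      ord <- order(p$pos_i)
      if (nrow(p) > 1 && any(diff(p$pos_j[ord]) >= 0))
        stop(tr, ": crossing pairs in ", arm, " stem")
    }
    anti <- st[st$record == "span" & st$element == "anticodon", ]
    if (nrow(anti) == 1 && anti$pos_j - anti$pos_i != 2)
      stop(tr, ": anticodon span is not 3 nt")
  }
  invisible(TRUE)
}

#' Classify the base pairs of one tRNA
#'
#' Each annotated pair is looked up in the sequence and classified:
#' `A:T`, `T:A`, `G:C`, `C:G` are Watson-Crick; `G:T` and `T:G` are G-U
#' wobble pairs; anything else is a mismatch. The classification is
#' independent of the (i, j) orientation convention.
#'
#' @param seq tRNA sequence (coding orientation).
#' @param structure structure rows for this tRNA (see
#'   [read_trna_structures()]).
#' @return List of class `pair_classification`: `pairs` data frame (arm,
#'   pos_i, pos_j, nt_i, nt_j, class), `tally` (overall), `by_arm`.
#' @export
classify_pairs <- function(seq, structure) {
  seq <- toupper(seq)
  n <- nchar(seq)
  p <- structure[structure$record == "pair", ]
  if (nrow(p) && (max(p$pos_i, p$pos_j) >= n || min(p$pos_i, p$pos_j) < 0))
    stop("structure error: pair index outside sequence of length ", n)
  nt_i <- substring(seq, p$pos_i + 1, p$pos_i + 1)
  nt_j <- substring(seq, p$pos_j + 1, p$pos_j + 1)
  key <- paste0(nt_i, nt_j)
  cls <- ifelse(key %in% c("AT", "TA", "GC", "CG"), "watson_crick",
                ifelse(key %in% c("GT", "TG"), "GU_wobble", "mismatch"))
  pairs <- data.frame(arm = p$element, pos_i = p$pos_i, pos_j = p$pos_j,
                      nt_i = nt_i, nt_j = nt_j, class = cls,
                      stringsAsFactors = FALSE)
  lv <- c("watson_crick", "GU_wobble", "mismatch")
  tally <- vapply(lv, function(l) sum(cls == l), numeric(1))
  by_arm <- do.call(rbind, lapply(split(pairs, pairs$arm), function(d)
    vapply(lv, function(l) sum(d$class == l), numeric(1))))
  structure(list(pairs = pairs, tally = tally, by_arm = by_arm),
            class = "pair_classification")
}

#' Stem and loop size profile of a cloverleaf annotation
#'
#' @param structure structure rows for one tRNA.
#' @return List with `stems` (named pair counts per arm) and `loops` (named
#'   span lengths).
#' @export
arm_profile <- function(structure) {
  p <- structure[structure$record == "pair", ]
  s <- structure[structure$record == "span", ]
  arms <- c("AA", "DHU", "AC", "T")
  stems <- vapply(arms, function(a) sum(p$element == a), numeric(1))
  loops <- stats::setNames(s$pos_j - s$pos_i + 1, s$element)
  list(stems = stems, loops = loops)
}

#' Positions at which homologous tRNAs of two genomes differ
#'
#' @param genome_a,genome_b `mitogenome` objects carrying the 22 tRNAs.
#' @return Named list over shared tRNAs; each element is an integer vector
#'   of differing 0-based tRNA-local positions (coding orientation), or the
#'   string `"length_mismatch"` when the homologs differ in length.
#' @export
diff_trnas <- function(genome_a, genome_b) {
  trnas <- intersect(intersect(genome_a$features$name, TRNA_GENES),
                     genome_b$features$name)
  out <- lapply(trnas, function(g) {
    sa <- strsplit(extract_gene(genome_a, g), "")[[1]]
    sb <- strsplit(extract_gene(genome_b, g), "")[[1]]
    if (length(sa) != length(sb)) return("length_mismatch")
    which(sa != sb) - 1L
  })
  stats::setNames(out, trnas)
}
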