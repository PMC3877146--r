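# Core domain object: an annotated, usually circular, mitochondrial genome.
#
# Coordinates are 0-based half-open internally and converted to/from GenBank
# 1-based inclusive at the I/O boundary. A feature that spans the origin of
# the circle is virtually linearized: its end exceeds the genome length and
# all arithmetic is modulo the length.

.valid_seq <- function(seq) {
  grepl("^[ACGTN]*$", seq)
}

#' Construct an annotated mitogenome
#'
#' @param identifier record identifier (accession or label).
#' @param sequence nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @param features data frame with columns `name`, `kind`
#'   (`PCG`/`tRNA`/`rRNA`/`control_region`), `strand` (`"J"` majority /
#'   `"N"` minority), `start` (0-based inclusive), `end` (0-based exclusive,
#'   may exceed the genome length for origin-spanning features) and
#'   optionally `anticodon`.
#' @param is_circular logical flag.
#' @return Object of class `mitogenome`.
#' @export
mitogenome <- function(identifier, sequence, features, is_circular = TRUE) {
  sequence <- toupper(sequence)
  if (!.valid_seq(sequence)) stop("sequence contains characters outside {A,C,G,T,N}")
  len <- nchar(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$anticodon))
    features$anticodon <- rep(NA_character_, nrow(features))
  stopifnot(all(c("name", "kind", "strand", "start", "end") %in% names(features)))
  if (nrow(features)) {
    if (any(features$end <= features$start)) stop("feature end must exceed start")
    if (any(features$end - features$start > len)) stop("feature longer than genome")
    # normalize: start in [0, len)
    shift <- features$start %/% len
    features$start <- features$start - shift * len
    features$end <- features$end - shift * len
    if (!is_circular && any(features$end > len))
      stop("origin-spanning feature on a linear genome")
    dup <- features$name[duplicated(features$name)]
    if (length(dup)) warning("duplicated gene name(s): ", paste(unique(dup), collapse = ", "))
    if (!all(features$strand %in% c("J", "N"))) stop("strand must be 'J' or 'N'")
  }
  rownames(features) <- NULL
  structure(list(identifier = identifier, sequence = sequence, length = len,
                 is_circular = is_circular, features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %d bp, %s, %d features\n", x$identifier,
              x$length, if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' @export
feature_lengths <- function(genome) {
  with(genome$features, stats::setNames(end - start, name))
}

#' Reverse complement of a DNA string
#'
#' Involution over the alphabet `{A,C,G,T,N}`; `N` maps to `N`.
#'
#' @param seq nucleotide string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (!.valid_seq(seq)) stop("alphabet error: sequence contains characters outside {A,C,G,T,N}")
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Circular substring: 0-based half-open [start, end), end may exceed length.
circular_substring <- function(sequence, start, end, len = nchar(sequence)) {
  stopifnot(end > start, end - start <= len)
  start <- start %% len
  end2 <- start + (end - start)
  if (end2 <= len) {
    substring(sequence, start + 1, end2)
  } else {
    paste0(substring(sequence, start + 1, len), substring(sequence, 1, end2 - len))
  }
}

#' Extract a gene's coding-strand sequence
#'
#' Wraps across the origin for origin-spanning features and
#' reverse-complements minority (N) strand features.
#'
#' @param genome a `mitogenome`.
#' @param name canonical gene symbol.
#' @return Nucleotide string in coding orientation.
#' @export
extract_gene <- function(genome, name) {
  i <- match(name, genome$features$name)
  if (is.na(i)) stop("lookup error: gene '", name, "' not annotated in ", genome$identifier)
  f <- genome$features[i, ]
  s <- circular_substring(genome$sequence, f$start, f$end, genome$length)
  if (f$strand == "N") s <- reverse_complement(s)
  s
}

#' Rotate a circular genome to a new origin
#'
#' @param genome a circular `mitogenome`.
#' @param offset new origin, 0-based position in the current coordinates.
#' @return Rotated `mitogenome`; features that now span the origin keep a
#'   single record with `end > length`.
#' @export
rotate_mitogenome <- function(genome, offset) {
  stopifnot(genome$is_circular)
  len <- genome$length
  offset <- offset %% len
  if (offset == 0) return(genome)
  seq2 <- paste0(substring(genome$sequence, offset + 1, len),
                 substring(genome$sequence, 1, offset))
  f <- genome$features
  gl <- f$end - f$start
  f$start <- (f$start - offset) %% len
  f$end <- f$start + gl
  mitogenome(genome$identifier, seq2, f, is_circular = TRUE)
}

# ---------------------------------------------------------------------------
# GenBank flat-file I/O (single record). Hand-written: no installed package
# parses GenBank feature tables.

.kind_to_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "misc_feature")

.parse_location <- function(loc, genome_len) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    strsplit(inner, ",")[[1]]
  } else loc
  m <- regmatches(spans, regexec("^(\\d+)\\.\\.(\\d+)$", trimws(spans)))
  if (any(vapply(m, length, 1L) != 3)) {
    m1 <- regmatches(spans, regexec("^(\\d+)$", trimws(spans)))  # single-base
    if (all(vapply(m1, length, 1L) == 2)) {
      m <- lapply(m1, function(x) c(x, x[2]))
    } else stop("cannot parse location: ", loc)
  }
  starts <- vapply(m, function(x) as.integer(x[2]), 1L)
  ends <- vapply(m, function(x) as.integer(x[3]), 1L)
  if (length(starts) == 1) {
    return(list(start = starts - 1L, end = ends, strand = strand))
  }
  # origin-spanning join: last span ends at genome length, next starts at 1
  if (length(starts) == 2 && ends[1] == genome_len && starts[2] == 1) {
    return(list(start = starts[1] - 1L, end = genome_len + ends[2], strand = strand))
  }
  warning("multi-span location merged to its extremes: ", loc)
  list(start = min(starts) - 1L, end = max(ends), strand = strand)
}

#' Read a single-record GenBank flat file
#'
#' Every `CDS`, `tRNA`, `rRNA`, `D-loop` and control-region `misc_feature`
#' becomes a feature with a normalized canonical name (e.g. `ND1` ->
#' `nad1`, `16S rRNA` -> `rrnL`); `join` locations that span the origin
#' become one wrapped feature. Gene names with no known mapping are retained
#' verbatim with a warning.
#'
#' @param path file path.
#' @return A `mitogenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("parse error: no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  identifier <- toks[2]
  len <- as.integer(toks[3])
  is_circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("parse error: missing sequence (no ORIGIN) in ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1):(endrec - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("parse error: missing sequence in ", path)
  if (!is.na(len) && nchar(sequence) != len)
    warning("LOCUS length ", len, " != sequence length ", nchar(sequence))
  len <- nchar(sequence)

  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1):(ori[1] - 1)]
    # a new feature starts at column 6 with a non-blank key
    is_key <- grepl("^ {1,10}\\S", block) & !grepl("^ {12,}", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      key <- trimws(substring(block[from], 1, 21))
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")) next
      loc <- trimws(substring(block[from], 22))
      body <- block[seq(from, to)]
      # continuation lines of the location (no "/" qualifier yet)
      j <- 2
      while (j <= length(body) && !grepl("^\\s*/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1
      }
      quals <- body[grepl("^\\s*/", body)]
      getq <- function(q) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^[^=]*=|"', "", hit[1])
      }
      gene_raw <- getq("gene")
      if (is.na(gene_raw)) gene_raw <- getq("product")
      if (is.na(gene_raw)) gene_raw <- getq("note")
      if (key == "D-loop" && is.na(gene_raw)) gene_raw <- "D-loop"
      pl <- .parse_location(loc, len)
      canon <- normalize_gene_name(gene_raw)
      if (is.na(canon)) {
        if (key == "D-loop") canon <- "CR"
        else {
          warning("unmappable gene name '", gene_raw, "'; retained as-is")
          canon <- if (is.na(gene_raw)) paste0("unnamed_", k) else gene_raw
        }
      }
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     misc_feature = "control_region", `D-loop` = "control_region")
      if (canon == "CR") kind <- "control_region"
      feats[[length(feats) + 1]] <- data.frame(
        name = canon, kind = kind, strand = pl$strand,
        start = pl$start, end = pl$end, anticodon = getq("anticodon_seq"),
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(name = character(), kind = character(), strand = character(),
               start = integer(), end = integer(), anticodon = character())
  mitogenome(identifier, sequence, features, is_circular = is_circular)
}

.format_location <- function(start, end, strand, len) {
  loc <- if (end <= len) {
    sprintf("%d..%d", start + 1, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1, len, end - len)
  }
  if (strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Inverse of [read_genbank()]: a read -> write -> read round trip preserves
#' the sequence and all feature coordinates and strands exactly.
#'
#' @param genome a `mitogenome`.
#' @param path output file path.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     %s INV %s",
                     genome$identifier, genome$length, topo,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     genome$identifier), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", genome$length), con)
  writeLines(sprintf('                     /organism="%s"', genome$identifier), con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- .kind_to_key[[f$kind[i]]]
    loc <- .format_location(f$start[i], f$end[i], f$strand[i], genome$length)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
    writeLines(sprintf('                     /product="%s"',
                       display_gene_name(f$name[i])), con)
    if (f$kind[i] == "control_region")
      writeLines('                     /note="putative control region"', con)
    if (!is.na(f$anticodon[i]))
      writeLines(sprintf('                     /anticodon_seq="%s"', f$anticodon[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  for (p in seq(1, nchar(s), by = 60)) {
    chunk <- substring(s, p, min(p + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA and feature-table side-car

#' @rdname write_genbank
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$identifier
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA genome with an optional annotation side-car
#'
#' @param path FASTA path (first record used).
#' @param feature_table optional TSV path, see [read_feature_table()].
#' @param is_circular topology flag.
#' @return A `mitogenome`.
#' @export
read_fasta_genome <- function(path, feature_table = NULL, is_circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("parse error: empty FASTA ", path)
  feats <- if (is.null(feature_table)) {
    data.frame(name = character(), kind = character(), strand = character(),
               start = integer(), end = integer(), anticodon = character())
  } else read_feature_table(feature_table)
  mitogenome(sub("\\s.*", "", names(x)[1]), as.character(x[[1]]), feats,
             is_circular = is_circular)
}

#' Read/write the TSV feature table side-car
#'
#' Columns: `name`, `kind`, `strand`, `start_1based`, `end_1based`,
#' `anticodon`. 1-based inclusive coordinates at the file boundary;
#' origin-spanning features carry `end_1based > genome length`.
#'
#' @param path TSV path.
#' @return Internal feature data frame (0-based half-open).
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "kind", "strand", "start_1based", "end_1based")
  if (!all(need %in% names(tab))) stop("feature table missing columns: ",
                                       paste(setdiff(need, names(tab)), collapse = ", "))
  if (is.null(tab$anticodon)) tab$anticodon <- NA_character_
  data.frame(name = tab$name, kind = tab$kind, strand = tab$strand,
             start = tab$start_1based - 1L, end = tab$end_1based,
             anticodon = as.character(tab$anticodon), stringsAsFactors = FALSE)
}

#' @rdname read_feature_table
#' @param genome a `mitogenome` whose features are written.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  out <- data.frame(name = f$name, kind = f$kind, strand = f$strand,
                    start_1based = f$start + 1L, end_1based = f$end,
                    anticodon = f$anticodon)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
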