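# Seeded generator of realistic annotated mitogenomes and diverged sister
# genomes with ground-truth mutation logs.
#
# The generator emulates the organisation of an insect mitogenome: a
# circular ~16 kb molecule carrying 13 PCGs + 22 tRNAs + 2 rRNAs + a control
# region in a template gene order (ancestral insect order, or the derived
# arrangement with tRNA-Cys upstream of tRNA-Trp), strong A+T bias (~80% in
# coding regions, ~95% in the control region), conserved overlap heptamers
# at the atp8/atp6 and nad4l/nad4 junctions, canonical ATN/TTG start codons
# and complete or incomplete (single T) stop codons. Randomness uses R's
# default Mersenne-Twister generator; the seed is mandatory and recorded.

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

default_gene_lengths <- function() {
  path <- system.file("extdata", "gene_lengths.tsv", package = "mitocompare")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$length), tab$gene)
}

default_start_codons <- function() {
  c(atp6 = "ATG", cox2 = "ATG", cox3 = "ATG", cytb = "ATG", nad4 = "ATG",
    atp8 = "ATT", cox1 = "ATT", nad2 = "ATT", nad3 = "ATT",
    nad4l = "ATA", nad5 = "ATA", nad6 = "ATA", nad1 = "TTG")
}

default_stop_modes <- function() {
  m <- stats::setNames(rep("complete_TAA", length(PCG_GENES)), PCG_GENES)
  m["nad1"] <- "complete_TAG"
  m[c("cox1", "cox2", "nad4", "nad5")] <- "incomplete_T"
  m
}

# Planted overlaps, keyed by genome-order junction "left|right". Character
# values are conserved shared sequences in coding orientation (the classic
# ATGATAA/ATGTTAA heptamers plus an 8 bp nad6/cytb overlap); integer values
# are sizes only. Defaults realise 11 overlap junctions / 35 bp total /
# longest 8 bp.
default_overlaps <- function() {
  list("atp8|atp6" = "ATGATAA", "nad4|nad4l" = "ATGTTAA",
       "nad6|cytb" = "ATGATTAA",
       "trnQ|trnM" = 1L, "trnK|trnD" = 1L, "cox3|trnG" = 1L,
       "trnA|trnR" = 2L, "trnR|trnN" = 2L, "trnN|trnS1" = 2L,
       "trnS1|trnE" = 2L, "trnT|trnP" = 2L)
}

# Ten small intergenic spacers, 1-29 bp.
default_spacers <- function() {
  c("trnI|trnQ" = 3L, "trnM|nad2" = 1L, "trnY|cox1" = 2L, "trnD|atp8" = 2L,
    "nad3|trnA" = 4L, "trnE|trnF" = 6L, "trnH|nad4" = 1L, "nad4l|trnT" = 9L,
    "trnP|nad6" = 16L, "cytb|trnS2" = 29L)
}

#' Configuration for the synthetic-mitogenome generator
#'
#' @param seed mandatory integer seed.
#' @param gene_order `"neuroptera_cw"` (default; tRNA-Cys upstream of
#'   tRNA-Trp), `"dyakuba"` (ancestral insect order) or `"custom"` with
#'   `custom_order` a data frame (`name`, `kind`, `strand`).
#' @param at_coding A+T proportion of coding/RNA regions (default 0.80).
#' @param at_cr A+T proportion of the control region (default 0.95).
#' @param at_skew,gc_skew genome(J)-strand skews of the generated sequence
#'   (defaults -0.0675 / -0.185, typical of a strongly AT-biased insect
#'   mitogenome).
#' @param cr_length control-region length in bp (default 1167).
#' @param gene_lengths named integer vector of PCG/rRNA lengths.
#' @param start_codons,stop_modes named vectors over the 13 PCGs.
#' @param overlaps planted overlap map (see `default_overlaps`).
#' @param spacers planted spacer map.
#' @param wobble_prob per-stem-pair probability of a planted G-U wobble pair
#'   in tRNAs (default 0.035, ~15 G-U pairs expected over 22 tRNAs).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             gene_order = c("neuroptera_cw", "dyakuba", "custom"),
                             custom_order = NULL,
                             at_coding = 0.80, at_cr = 0.95,
                             at_skew = -0.0675, gc_skew = -0.185,
                             cr_length = 1167L,
                             gene_lengths = default_gene_lengths(),
                             start_codons = default_start_codons(),
                             stop_modes = default_stop_modes(),
                             overlaps = default_overlaps(),
                             spacers = default_spacers(),
                             wobble_prob = 0.035) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  gene_order <- match.arg(gene_order)
  stopifnot(at_coding > 0, at_coding < 1, at_cr > 0, at_cr < 1,
            cr_length >= 100)
  # length/stop-mode consistency: incomplete_T needs length = 3k+1,
  # incomplete_TA needs 3k+2, complete stops need 3k
  for (g in PCG_GENES) {
    want <- switch(stop_modes[[g]], incomplete_T = 1L, incomplete_TA = 2L, 0L)
    if (gene_lengths[[g]] %% 3L != want)
      stop("gene length of ", g, " (", gene_lengths[[g]],
           ") incompatible with stop mode ", stop_modes[[g]])
  }
  structure(list(seed = as.integer(seed), gene_order = gene_order,
                 custom_order = custom_order, at_coding = at_coding,
                 at_cr = at_cr, at_skew = at_skew, gc_skew = gc_skew,
                 cr_length = as.integer(cr_length), gene_lengths = gene_lengths,
                 start_codons = start_codons, stop_modes = stop_modes,
                 overlaps = overlaps, spacers = spacers,
                 wobble_prob = wobble_prob),
            class = "synthetic_config")
}

# nucleotide probabilities from an AT proportion and the two skews
.nt_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

.swap_probs <- function(p) c(A = unname(p["T"]), C = unname(p["G"]),
                             G = unname(p["C"]), T = unname(p["A"]))

.sample_nt <- function(n, probs) {
  if (n <= 0) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# k sense codons, iid nucleotides with stop codons rejected
.sample_codons <- function(k, probs, stops) {
  if (k <= 0) return(character())
  cods <- paste0(.sample_nt(k, probs), .sample_nt(k, probs), .sample_nt(k, probs))
  bad <- which(cods %in% stops)
  while (length(bad)) {
    cods[bad] <- paste0(.sample_nt(length(bad), probs),
                        .sample_nt(length(bad), probs),
                        .sample_nt(length(bad), probs))
    bad <- bad[cods[bad] %in% stops]
  }
  cods
}

# Build one PCG in coding orientation, then overwrite planted head/tail
# characters and resample any interior codon the planting turned into a stop.
.gen_pcg <- function(gene, len, start_codon, stop_mode, probs, table,
                     head = NULL, tail = NULL) {
  r <- len %% 3L
  stop_str <- switch(stop_mode, complete_TAA = "TAA", complete_TAG = "TAG",
                     incomplete_T = "T", incomplete_TA = "TA")
  k_body <- (len - 3L - nchar(stop_str)) %/% 3L
  if (stop_mode %in% c("incomplete_T", "incomplete_TA")) {
    # body fills full codons between start and the trailing partial stop
    k_body <- (len - 3L - r) %/% 3L
    stop_str <- if (stop_mode == "incomplete_T") "T" else "TA"
  }
  body <- .sample_codons(k_body, probs, table$stops)
  seq <- paste0(start_codon, paste(body, collapse = ""), stop_str)
  stopifnot(nchar(seq) == len)
  cv <- strsplit(seq, "")[[1]]
  locked <- logical(len)
  locked[1:3] <- TRUE
  locked[(len - nchar(stop_str) + 1):len] <- TRUE
  if (!is.null(head)) {
    h <- strsplit(head, "")[[1]]
    cv[seq_along(h)] <- h
    locked[seq_along(h)] <- TRUE
  }
  if (!is.null(tail)) {
    t_ <- strsplit(tail, "")[[1]]
    idx <- (len - length(t_) + 1):len
    cv[idx] <- t_
    locked[idx] <- TRUE
  }
  # fix any interior codon that planting turned into a stop
  n_cod <- len %/% 3L
  interior <- if (r == 0) seq_len(n_cod - 1) else seq_len(n_cod)
  interior <- setdiff(interior, 1L)  # start codon is codon 1
  for (ci in interior) {
    idx <- (3 * (ci - 1) + 1):(3 * ci)
    for (tries in 1:100) {
      if (!(paste(cv[idx], collapse = "") %in% table$stops)) break
      free <- idx[!locked[idx]]
      if (!length(free)) stop("planted constraint forces an interior stop in ", gene)
      cv[free] <- .sample_nt(length(free), probs)
    }
  }
  paste(cv, collapse = "")
}

# ---------------------------------------------------------------------------
# tRNA generation: a cloverleaf with acceptor (7 bp), DHU (0/3-4 bp),
# anticodon (4-5 bp) and T (4-5 bp) stems. tRNA-Ser(AGN) has no DHU stem
# (its DHU arm forms a simple loop); tRNA-Lys/Met/Ser(AGN)/Thr carry a 4 bp
# anticodon stem; the tRNA-Thr anticodon loop has 9 nt, all others 7.

.gen_stem <- function(n, probs, wobble_slots) {
  five <- character(n); three <- character(n)
  for (i in seq_len(n)) {
    if (i %in% wobble_slots) {
      if (stats::runif(1) < 0.5) { five[i] <- "G"; three[i] <- "T" }
      else { five[i] <- "T"; three[i] <- "G" }
    } else {
      five[i] <- .sample_nt(1, probs)
      three[i] <- .complement_map[[five[i]]]
    }
  }
  list(five = five, three = rev(three))
}

#' Generate one synthetic tRNA with its cloverleaf annotation
#'
#' @param name canonical tRNA symbol.
#' @param probs nucleotide sampling probabilities (named A/C/G/T).
#' @param wobble_prob per-pair probability of planting a G-U wobble pair.
#' @param wobble_n optionally plant exactly this many wobble pairs
#'   (overrides `wobble_prob`).
#' @param anticodon 3-mer anticodon (DNA alphabet, coding orientation).
#' @return List with `seq` and `structure` (data frame: `trna`, `record`
#'   (`pair`/`span`), `element`, `pos_i`, `pos_j`; 0-based tRNA-local
#'   positions).
#' @export
gen_trna <- function(name, probs = .nt_probs(0.8, -0.0675, -0.185),
                     wobble_prob = 0.035, wobble_n = NULL,
                     anticodon = STANDARD_ANTICODONS[[name]]) {
  n_acc <- 7L
  n_d <- if (name == "trnS1") 0L else sample(3:4, 1)
  n_ac <- if (name %in% c("trnK", "trnM", "trnS1", "trnT")) 4L else 5L
  l_acl <- if (name == "trnT") 9L else 7L
  n_t <- sample(4:5, 1)
  for (try in 1:50) {
    l_d <- if (n_d == 0L) sample(5:8, 1) else sample(4:9, 1)
    l_v <- sample(4:5, 1)
    l_t <- sample(4:9, 1)
    total <- 2 * n_acc + 2L + 2 * n_d + l_d + 1L + 2 * n_ac + l_acl + l_v +
      2 * n_t + l_t + 1L
    if (total >= 63 && total <= 71) break
  }
  n_pairs <- n_acc + n_d + n_ac + n_t
  wob <- if (!is.null(wobble_n)) {
    sort(sample(n_pairs, wobble_n))
  } else {
    which(stats::runif(n_pairs) < wobble_prob)
  }
  off <- 0L
  in_arm <- function(k, size) wob[wob > off & wob <= off + size] - off
  acc <- .gen_stem(n_acc, probs, in_arm(0, n_acc)); off <- off + n_acc
  dst <- .gen_stem(n_d, probs, in_arm(0, n_d)); off <- off + n_d
  acs <- .gen_stem(n_ac, probs, in_arm(0, n_ac)); off <- off + n_ac
  tst <- .gen_stem(n_t, probs, in_arm(0, n_t))

  dloop <- .sample_nt(l_d, probs)
  acloop <- .sample_nt(l_acl, probs)
  ac_at <- (l_acl - 3L) %/% 2L  # anticodon centred in the loop
  acloop[(ac_at + 1):(ac_at + 3)] <- strsplit(anticodon, "")[[1]]
  vloop <- .sample_nt(l_v, probs)
  tloop <- .sample_nt(l_t, probs)
  link1 <- .sample_nt(2, probs)
  link2 <- .sample_nt(1, probs)
  disc <- .sample_nt(1, probs)

  parts <- list(acc5 = acc$five, link1 = link1, d5 = dst$five, dloop = dloop,
                d3 = dst$three, link2 = link2, ac5 = acs$five,
                acloop = acloop, ac3 = acs$three, vloop = vloop,
                t5 = tst$five, tloop = tloop, t3 = tst$three,
                acc3 = acc$three, disc = disc)
  lens <- vapply(parts, length, 1L)
  starts <- cumsum(c(0L, lens))[seq_along(lens)]
  names(starts) <- names(parts)
  seq <- paste(unlist(parts), collapse = "")

  pair_rows <- function(arm, p5, p3, n) {
    if (n == 0L) return(NULL)
    data.frame(trna = name, record = "pair", element = arm,
               pos_i = starts[[p5]] + 0:(n - 1),
               pos_j = starts[[p3]] + (n - 1):0, stringsAsFactors = FALSE)
  }
  span_row <- function(el, part) {
    data.frame(trna = name, record = "span", element = el,
               pos_i = starts[[part]],
               pos_j = starts[[part]] + lens[[part]] - 1L,
               stringsAsFactors = FALSE)
  }
  structure_df <- rbind(
    pair_rows("AA", "acc5", "acc3", n_acc),
    pair_rows("DHU", "d5", "d3", n_d),
    pair_rows("AC", "ac5", "ac3", n_ac),
    pair_rows("T", "t5", "t3", n_t),
    span_row("DHU_loop", "dloop"),
    span_row("AC_loop", "acloop"),
    data.frame(trna = name, record = "span", element = "anticodon",
               pos_i = starts[["acloop"]] + ac_at,
               pos_j = starts[["acloop"]] + ac_at + 2L, stringsAsFactors = FALSE),
    span_row("variable_loop", "vloop"),
    span_row("T_loop", "tloop"))
  list(seq = seq, structure = structure_df, n_wobble = length(wob))
}

# ---------------------------------------------------------------------------

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic for a given config (identical seed, identical output). The
#' result passes [audit_gene_content()] with nothing missing, every PCG
#' carries its configured start and stop class, [junction_accounting()]
#' reproduces the planted overlaps and spacers, and regional composition
#' matches the configured AT bias within binomial noise.
#'
#' @param config a [synthetic_config()].
#' @param identifier record identifier.
#' @return A `mitogenome` with attributes `trna_structures` (data frame, see
#'   [gen_trna()]) and `config`.
#' @export
generate_mitogenome <- function(config, identifier = sprintf("SYN%06d", config$seed)) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  table <- codon_table()
  order_df <- switch(config$gene_order,
    custom = config$custom_order,
    {
      path <- system.file("extdata", "gene_orders",
                          paste0(config$gene_order, ".tsv"),
                          package = "mitocompare")
      utils::read.delim(path, stringsAsFactors = FALSE)
    })
  probs_j <- .nt_probs(config$at_coding, config$at_skew, config$gc_skew)
  probs_cr <- .nt_probs(config$at_cr, config$at_skew, config$gc_skew)

  # planted head/tail constraints in coding orientation, from the overlap map
  heads <- list(); tails <- list()
  for (key in names(config$overlaps)) {
    v <- config$overlaps[[key]]
    if (!is.character(v)) next
    lr <- strsplit(key, "|", fixed = TRUE)[[1]]
    strands <- order_df$strand[match(lr, order_df$name)]
    if (all(strands == "J")) {
      tails[[lr[1]]] <- v; heads[[lr[2]]] <- v
    } else if (all(strands == "N")) {
      # genome-left gene is coding-downstream: shared sequence is its coding
      # head and the genome-right gene's coding tail
      heads[[lr[1]]] <- v; tails[[lr[2]]] <- v
    } else stop("sequence-planted overlap across strands unsupported: ", key)
  }

  seqs <- list()       # coding orientation
  trna_structs <- list()
  for (i in seq_len(nrow(order_df))) {
    g <- order_df$name[i]; kind <- order_df$kind[i]; strand <- order_df$strand[i]
    p <- if (strand == "J") probs_j else .swap_probs(probs_j)
    seqs[[g]] <- switch(kind,
      PCG = .gen_pcg(g, config$gene_lengths[[g]], config$start_codons[[g]],
                     config$stop_modes[[g]], p, table,
                     head = heads[[g]], tail = tails[[g]]),
      rRNA = paste(.sample_nt(config$gene_lengths[[g]], p), collapse = ""),
      tRNA = {
        tr <- gen_trna(g, probs = p, wobble_prob = config$wobble_prob)
        trna_structs[[g]] <- tr$structure
        tr$seq
      },
      control_region = paste(.sample_nt(config$cr_length,
                                        if (strand == "J") probs_cr else .swap_probs(probs_cr)),
                             collapse = ""))
  }

  # assemble the circle in genome (J) orientation
  genome <- ""
  feats <- vector("list", nrow(order_df))
  prev <- NULL
  for (i in seq_len(nrow(order_df))) {
    g <- order_df$name[i]
    gseq <- if (order_df$strand[i] == "N") reverse_complement(seqs[[g]]) else seqs[[g]]
    glen <- nchar(gseq)
    o <- 0L; sp <- 0L
    if (!is.null(prev)) {
      key <- paste0(prev, "|", g)
      ov <- config$overlaps[[key]]
      if (!is.null(ov)) o <- if (is.character(ov)) nchar(ov) else as.integer(ov)
      if (key %in% names(config$spacers)) sp <- as.integer(config$spacers[[key]])
    }
    if (o > 0L) {
      left_tail <- substring(genome, nchar(genome) - o + 1, nchar(genome))
      if (substring(gseq, 1, o) != left_tail) {
        if (is.character(config$overlaps[[paste0(prev, "|", g)]]))
          stop("internal inconsistency planting overlap ", prev, "|", g)
        gseq <- paste0(left_tail, substring(gseq, o + 1))  # size-only overlap
      }
      start <- nchar(genome) - o
      genome <- paste0(genome, substring(gseq, o + 1))
    } else {
      if (sp > 0L) genome <- paste0(genome, paste(.sample_nt(sp, probs_j), collapse = ""))
      start <- nchar(genome)
      genome <- paste0(genome, gseq)
    }
    feats[[i]] <- data.frame(
      name = g, kind = order_df$kind[i], strand = order_df$strand[i],
      start = start, end = start + glen,
      anticodon = if (order_df$kind[i] == "tRNA") STANDARD_ANTICODONS[[g]] else NA_character_,
      stringsAsFactors = FALSE)
    prev <- g
  }
  gen <- mitogenome(identifier, genome, do.call(rbind, feats), is_circular = TRUE)
  attr(gen, "trna_structures") <- do.call(rbind, trna_structs)
  attr(gen, "config") <- config
  gen
}

# ---------------------------------------------------------------------------
# Divergence process

# coding-position -> genome-position map for a feature row
.coding_to_genome <- function(f, len) {
  gl <- f$end - f$start
  if (f$strand == "J") (f$start + 0:(gl - 1)) %% len
  else (f$end - 1 - 0:(gl - 1)) %% len
}

# synonymous / nonsynonymous single-change alternatives at one codon position
.pos_alternatives <- function(codon, pos, table) {
  muts <- .codon_pos_alts(codon, pos, table)
  aam <- table$aa[muts]
  keep <- aam != "*"
  muts <- muts[keep]; aam <- aam[keep]
  list(syn = muts[aam == table$aa[[codon]]],
       nonsyn = muts[aam != table$aa[[codon]]])
}

# Precomputed per-codon mutation table: for each sense codon and position,
# the synonymous/nonsynonymous target codons (stops excluded) and the NG86
# synonymous site fraction. Built once per genetic code and cached.
.codon_alt_table <- function(table) {
  key <- paste0("alt_table:", table$code_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  sense <- names(table$aa)[table$aa != "*"]
  out <- lapply(sense, function(cod) {
    per_pos <- lapply(1:3, function(k) .pos_alternatives(cod, k, table))
    fS <- vapply(per_pos, function(a) {
      n <- length(a$syn) + length(a$nonsyn)
      if (n == 0) NA_real_ else length(a$syn) / n
    }, numeric(1))
    list(fS = fS, syn = lapply(per_pos, `[[`, "syn"),
         nonsyn = lapply(per_pos, `[[`, "nonsyn"))
  })
  names(out) <- sense
  .ng_cache[[key]] <- out
  out
}

#' Mutate a mitogenome under per-class substitution and indel rates
#'
#' Substitutions in PCGs are placed per the NG86 site classification: a
#' synonymous event never changes the amino acid, a nonsynonymous event
#' always does, and neither creates a stop codon. Planted start/stop codons
#' and all overlap positions are protected from mutation. RNA genes and the
#' control region receive uniform per-site substitutions; the control region
#' additionally undergoes an indel process. The returned log replays to the
#' child exactly (see [replay_mutations()]).
#'
#' @param parent a `mitogenome` (control region must not span the origin).
#' @param rates list with elements `syn` (synonymous substitutions per
#'   synonymous site), `nonsyn`, `rna` (per site), `cr_sub` (per site),
#'   `cr_indel` (per-site event rate), optional `cr_indel_len_mean`
#'   (default 5.6) and `cr_indel_del_prob` (default 1: deletions only).
#' @param seed integer seed.
#' @return List with `genome` (the child) and `log` (class `mutation_log`):
#'   `events` data frame (gene, pos, from, to, class; coding-orientation
#'   0-based positions), `cr_indels` data frame (pos, type, len, seq),
#'   `eligible` per-gene data frame (gene, sites, syn_sites, nonsyn_sites),
#'   `rates`, `seed`.
#' @export
mutate_genome <- function(parent, rates, seed) {
  stopifnot(inherits(parent, "mitogenome"))
  rates <- utils::modifyList(list(syn = 0, nonsyn = 0, rna = 0, cr_sub = 0,
                                  cr_indel = 0, cr_indel_len_mean = 5.6,
                                  cr_indel_del_prob = 1), rates)
  stopifnot(all(unlist(rates[c("syn", "nonsyn", "rna", "cr_sub", "cr_indel")]) <= 0.5))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  table <- codon_table()
  len <- parent$length
  chars <- strsplit(parent$sequence, "")[[1]]

  # protected genome positions: all overlaps + PCG start/stop codons
  prot <- logical(len)
  ja <- junction_accounting(parent)
  f_sorted <- parent$features[order(parent$features$start), ]
  for (i in seq_len(nrow(ja$junctions))) {
    if (ja$junctions$relation[i] != "overlap") next
    dn <- ja$junctions$downstream[i]
    o <- ja$junctions$size[i]
    st <- parent$features$start[match(dn, parent$features$name)]
    prot[(st + 0:(o - 1)) %% len + 1] <- TRUE
  }
  for (i in which(parent$features$kind == "PCG")) {
    f <- parent$features[i, ]
    map <- .coding_to_genome(f, len)
    gl <- f$end - f$start
    r <- gl %% 3L
    stop_len <- if (r == 0) 3L else r
    prot[map[c(1:3, (gl - stop_len + 1):gl)] + 1] <- TRUE
  }

  events <- list()
  eligible <- list()
  for (i in seq_len(nrow(parent$features))) {
    f <- parent$features[i, ]
    g <- f$name
    map <- .coding_to_genome(f, len)
    cv <- strsplit(extract_gene(parent, g), "")[[1]]
    gl <- length(cv)
    if (f$kind == "PCG") {
      alt_tab <- .codon_alt_table(table)
      n_cod <- gl %/% 3L
      open <- !prot[map + 1]                 # mutable positions
      us <- stats::runif(gl)                 # one uniform draw per position
      rmax <- max(rates$syn, rates$nonsyn)
      elig <- 0L; s_sites <- 0; n_sites <- 0
      for (ci in seq_len(n_cod)) {
        idx <- (3 * (ci - 1) + 1):(3 * ci)
        codon <- paste(cv[idx], collapse = "")
        info <- alt_tab[[codon]]
        if (is.null(info)) next               # stop codon (protected anyway)
        ks <- which(open[idx] & !is.na(info$fS))
        if (!length(ks)) next
        elig <- elig + length(ks)
        s_sites <- s_sites + sum(info$fS[ks])
        n_sites <- n_sites + sum(1 - info$fS[ks])
        if (all(us[idx[ks]] >= rmax)) next    # fast path: no event possible
        for (k in ks) {
          cp <- idx[k]
          # refresh context if an earlier position of this codon mutated
          codon_now <- paste(cv[idx], collapse = "")
          info_now <- alt_tab[[codon_now]]
          fS <- info_now$fS[k]
          if (is.na(fS)) next
          p_syn <- rates$syn * fS
          p_non <- rates$nonsyn * (1 - fS)
          target <- NULL; cls <- NULL
          if (us[cp] < p_syn && length(info_now$syn[[k]])) {
            target <- sample(info_now$syn[[k]], 1); cls <- "synonymous"
          } else if (us[cp] < p_syn + p_non && length(info_now$nonsyn[[k]])) {
            target <- sample(info_now$nonsyn[[k]], 1); cls <- "nonsynonymous"
          }
          if (!is.null(target)) {
            newnt <- substring(target, k, k)
            events[[length(events) + 1]] <- data.frame(
              gene = g, pos = cp - 1L, from = cv[cp], to = newnt, class = cls,
              stringsAsFactors = FALSE)
            cv[cp] <- newnt
            chars[map[cp] + 1] <- if (f$strand == "J") newnt else .complement_map[[newnt]]
          }
        }
      }
      eligible[[g]] <- data.frame(gene = g, sites = elig, syn_sites = s_sites,
                                  nonsyn_sites = n_sites, stringsAsFactors = FALSE)
    } else {
      rate <- if (f$kind == "control_region") rates$cr_sub else rates$rna
      hit <- which(stats::runif(gl) < rate & !prot[map + 1])
      for (cp in hit) {
        newnt <- sample(setdiff(c("A", "C", "G", "T"), cv[cp]), 1)
        events[[length(events) + 1]] <- data.frame(
          gene = g, pos = cp - 1L, from = cv[cp], to = newnt,
          class = if (f$kind == "control_region") "cr" else "rna",
          stringsAsFactors = FALSE)
        cv[cp] <- newnt
        chars[map[cp] + 1] <- if (f$strand == "J") newnt else .complement_map[[newnt]]
      }
      eligible[[g]] <- data.frame(gene = g, sites = sum(!prot[map + 1]),
                                  syn_sites = NA_real_, nonsyn_sites = NA_real_,
                                  stringsAsFactors = FALSE)
    }
  }

  # control-region indels
  cr_events <- data.frame(pos = integer(), type = character(), len = integer(),
                          seq = character(), stringsAsFactors = FALSE)
  icr <- match("CR", parent$features$name)
  if (!is.na(icr) && rates$cr_indel > 0) {
    fcr <- parent$features[icr, ]
    if (fcr$end > len) stop("control region spans the origin; rotate first")
    crlen <- fcr$end - fcr$start
    hit <- which(stats::runif(crlen) < rates$cr_indel)
    probs_cr <- .nt_probs(0.95, -0.0675, -0.185)
    for (p in hit) {
      type <- if (stats::runif(1) < rates$cr_indel_del_prob) "del" else "ins"
      l <- 1L + stats::rpois(1, rates$cr_indel_len_mean - 1)
      if (type == "del") l <- min(l, crlen - p + 1L)
      cr_events <- rbind(cr_events, data.frame(
        pos = p - 1L, type = type, len = l,
        seq = if (type == "ins") paste(.sample_nt(l, probs_cr), collapse = "") else "",
        stringsAsFactors = FALSE))
    }
  }

  log <- structure(list(
    events = if (length(events)) do.call(rbind, events) else
      data.frame(gene = character(), pos = integer(), from = character(),
                 to = character(), class = character()),
    cr_indels = cr_events,
    eligible = do.call(rbind, eligible),
    rates = rates, seed = as.integer(seed)), class = "mutation_log")

  child <- .apply_cr_indels(parent, chars, cr_events)
  child$identifier <- paste0(parent$identifier, "_child")
  list(genome = child, log = log)
}

# apply CR indels to a substituted character vector and rebuild the genome
.apply_cr_indels <- function(parent, chars, cr_events) {
  len <- parent$length
  icr <- match("CR", parent$features$name)
  if (is.na(icr) || nrow(cr_events) == 0) {
    return(mitogenome(parent$identifier, paste(chars, collapse = ""),
                      parent$features, parent$is_circular))
  }
  fcr <- parent$features[icr, ]
  cr <- chars[(fcr$start + 1):fcr$end]
  ev <- cr_events[order(-cr_events$pos), ]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i] + 1L
    if (ev$type[i] == "del") {
      drop <- p:min(p + ev$len[i] - 1L, length(cr))
      cr <- cr[-drop]
    } else {
      ins <- strsplit(ev$seq[i], "")[[1]]
      cr <- append(cr, ins, after = p - 1L)
    }
  }
  delta <- length(cr) - (fcr$end - fcr$start)
  newchars <- c(chars[seq_len(fcr$start)], cr,
                if (fcr$end < len) chars[(fcr$end + 1):len])
  f <- parent$features
  shift <- f$start >= fcr$end
  f$start[shift] <- f$start[shift] + delta
  f$end[shift | f$name == "CR"] <- f$end[shift | f$name == "CR"] + delta
  mitogenome(parent$identifier, paste(newchars, collapse = ""), f,
             parent$is_circular)
}

#' Replay a mutation log against the parent genome
#'
#' Deterministic reconstruction of the child from `(parent, log)`; used to
#' verify that the log is a complete ground-truth record.
#'
#' @param parent the parent `mitogenome`.
#' @param log a `mutation_log`.
#' @return The reconstructed child `mitogenome`.
#' @export
replay_mutations <- function(parent, log) {
  len <- parent$length
  chars <- strsplit(parent$sequence, "")[[1]]
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    f <- parent$features[match(ev$gene[i], parent$features$name), ]
    map <- .coding_to_genome(f, len)
    gp <- map[ev$pos[i] + 1] + 1
    chars[gp] <- if (f$strand == "J") ev$to[i] else .complement_map[[ev$to[i]]]
  }
  child <- .apply_cr_indels(parent, chars, log$cr_indels)
  child$identifier <- paste0(parent$identifier, "_child")
  child
}

#' Deterministic fixture pair of closely related mitogenomes
#'
#' `rapisma_like` emulates a conspecific pair: per-gene divergence well
#' below 0.01 (synonymous-biased PCG substitutions, light rRNA divergence,
#' and a control-region deletion process removing ~26 bp in expectation).
#' `distinct_like` raises the RNA substitution rate to ~0.085 so that
#' rRNA-fragment distances exceed the 0.03 interspecific threshold.
#'
#' @param profile `"rapisma_like"` or `"distinct_like"`.
#' @param seed integer seed.
#' @return List with `parent`, `child`, `log`, `rates` and `report` (the
#'   [compare_genomes()] result for the pair).
#' @export
make_fixture_pair <- function(profile = c("rapisma_like", "distinct_like"),
                              seed = 1) {
  profile <- match.arg(profile)
  rates <- switch(profile,
    rapisma_like = list(syn = 0.0138, nonsyn = 0.00079, rna = 0.0021,
                        cr_sub = 0.005, cr_indel = 0.004),
    distinct_like = list(syn = 0.25, nonsyn = 0.04, rna = 0.085,
                         cr_sub = 0.1, cr_indel = 0.01))
  parent <- generate_mitogenome(synthetic_config(seed = seed))
  res <- mutate_genome(parent, rates, seed = seed + 1000L)
  report <- compare_genomes(parent, res$genome)
  list(parent = parent, child = res$genome, log = res$log, rates = rates,
       report = report)
}
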