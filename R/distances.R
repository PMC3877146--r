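# Pairwise gene alignment, uncorrected p-distance, Nei-Gojobori (1986)
# Ka/Ks, gene-set averaging and the distance-threshold conspecificity rule.

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under a simple match/mismatch score and a linear
#' gap penalty (gap opening cost 0). The dynamic programme is delegated to
#' `Biostrings::pairwiseAlignment`, which is deterministic.
#'
#' @param a,b nucleotide strings.
#' @param match match score (default 1).
#' @param mismatch mismatch score (default -1).
#' @param gap per-gap-character penalty (default -2, i.e. each gap column
#'   costs 2).
#' @return List with gapped strings `a`, `b`, the optimal `score`, and
#'   `gap_columns` (columns containing a gap in either row).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(a)),
                                      Biostrings::DNAString(toupper(b)),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = abs(gap))
  ga <- as.character(Biostrings::alignedPattern(al))
  gb <- as.character(Biostrings::alignedSubject(al))
  cols_a <- strsplit(ga, "")[[1]]
  cols_b <- strsplit(gb, "")[[1]]
  list(a = ga, b = gb, score = Biostrings::score(al),
       gap_columns = sum(cols_a == "-" | cols_b == "-"))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: columns containing a gap or `N` in either row are
#' excluded from both the numerator and the denominator.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @param gene optional gene label carried through to the result.
#' @return List of class `gene_distance`: `gene`, `compared`, `differing`,
#'   `p`.
#' @export
p_distance <- function(aligned_a, aligned_b, gene = NA_character_) {
  xa <- strsplit(toupper(aligned_a), "")[[1]]
  xb <- strsplit(toupper(aligned_b), "")[[1]]
  if (length(xa) != length(xb)) stop("aligned lengths differ")
  ok <- xa %in% c("A", "C", "G", "T") & xb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("undefined distance: zero comparable sites")
  compared <- sum(ok)
  differing <- sum(xa[ok] != xb[ok])
  structure(list(gene = gene, compared = compared, differing = differing,
                 p = differing / compared), class = "gene_distance")
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' `d = -(3/4) ln(1 - (4/3) p)`; undefined (`NA`) for `p >= 3/4`.
#'
#' @param p proportion of differing sites.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# ---------------------------------------------------------------------------
# NG86 machinery. Per-codon synonymous site fractions and pathway-averaged
# difference splits are precomputed against translation table 5 and cached.

.ng_cache <- new.env(parent = emptyenv())

.codon_pos_alts <- function(codon, pos, table) {
  nts <- c("A", "C", "G", "T")
  cur <- substring(codon, pos, pos)
  alts <- setdiff(nts, cur)
  muts <- vapply(alts, function(nt) {
    x <- strsplit(codon, "")[[1]]; x[pos] <- nt; paste(x, collapse = "")
  }, character(1))
  muts
}

# Per-codon site counts: position i contributes s_i = (# synonymous
# single-nucleotide changes) / (# changes not creating a stop codon); the
# nonsynonymous complement is 1 - s_i, so S + N = 3 for every codon.
ng86_codon_sites <- function(codon, table = codon_table()) {
  key <- paste0("sites:", codon, ":", table$code_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  aa0 <- table$aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    muts <- .codon_pos_alts(codon, pos, table)
    aam <- table$aa[muts]
    nonstop <- aam != "*"
    if (any(nonstop)) s <- s + sum(aam[nonstop] == aa0) / sum(nonstop)
  }
  res <- c(S = s, N = 3 - s)
  .ng_cache[[key]] <- res
  res
}

# Pathway-averaged synonymous/nonsynonymous difference split between two
# codons: all orderings of the differing positions are enumerated, pathways
# passing through a stop codon are excluded (unless every pathway does, in
# which case all are kept), and the per-step synonymous/nonsynonymous calls
# are averaged over the admissible pathways with equal weight.
ng86_codon_diffs <- function(ca, cb, table = codon_table()) {
  if (ca == cb) return(c(Sd = 0, Nd = 0))
  key <- paste0("diff:", ca, ":", cb, ":", table$code_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  xa <- strsplit(ca, "")[[1]]
  xb <- strsplit(cb, "")[[1]]
  pos <- which(xa != xb)
  perms <- switch(as.character(length(pos)),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
                  })
  walk <- function(order) {
    cur <- xa
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- xb[p]
      nxt <- paste(cur, collapse = "")
      if (table$aa[[nxt]] == "*" && nxt != cb) blocked <- TRUE
      if (table$aa[[prev]] == table$aa[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res_all <- vapply(perms, walk, numeric(3))
  ok <- res_all["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, length(perms))
  out <- c(Sd = mean(res_all["sd", ok]), Nd = mean(res_all["nd", ok]))
  .ng_cache[[key]] <- out
  out
}

#' Nei-Gojobori (1986) Ka and Ks for a pair of in-frame CDSs
#'
#' Synonymous and nonsynonymous site counts are computed per codon (averaged
#' over the two sequences); differences in multi-hit codons are averaged
#' over all minimal mutational pathways with equal weights, pathways through
#' stop codons excluded; the Jukes-Cantor correction is applied to pS and pN
#' separately. Trailing incomplete codons are dropped; codons containing
#' `N`, gaps, or a stop codon in either sequence are skipped.
#'
#' @param cds_a,cds_b in-frame coding sequences (equal-length comparison is
#'   over the first `min` full codons).
#' @param table a [codon_table()].
#' @param gene optional label.
#' @return List of class `evol_rates`: `codons`, `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega` (`NA` when `Ks` is 0 or a
#'   correction is undefined).
#' @export
ng86 <- function(cds_a, cds_b, table = codon_table(), gene = NA_character_) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  k <- min(nchar(cds_a), nchar(cds_b)) %/% 3
  if (k == 0) stop("no full codons to compare")
  idx <- seq_len(k)
  ca <- substring(cds_a, 3 * (idx - 1) + 1, 3 * idx)
  cb <- substring(cds_b, 3 * (idx - 1) + 1, 3 * idx)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok <- ok & !(ca %in% table$stops) & !(cb %in% table$stops)
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  sites_a <- vapply(ca, ng86_codon_sites, numeric(2), table = table)
  sites_b <- vapply(cb, ng86_codon_sites, numeric(2), table = table)
  S <- (sum(sites_a["S", ]) + sum(sites_b["S", ])) / 2
  N <- (sum(sites_a["N", ]) + sum(sites_b["N", ])) / 2
  diffs <- vapply(seq_along(ca), function(i) ng86_codon_diffs(ca[i], cb[i], table),
                  numeric(2))
  Sd <- sum(diffs["Sd", ]); Nd <- sum(diffs["Nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(gene = gene, codons = length(ca), S_sites = S, N_sites = N,
                 Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka,
                 omega = omega), class = "evol_rates")
}

#' Per-gene p-distances between two genomes and their mean
#'
#' Each named gene is extracted in coding orientation from both genomes,
#' globally aligned, and measured with [p_distance()] (pairwise deletion by
#' default; complete deletion of the whole alignment is available via
#' `gap_handling = "complete"`, which drops gapped columns before counting -
#' identical here since pairwise deletion already excludes them). The mean
#' over genes is unweighted. A Jukes-Cantor corrected variant is available
#' via `model = "jc"`; the default, consistent with distances reported as
#' exactly 0.0000 for identical genes, is the uncorrected p-distance.
#'
#' @param genome_a,genome_b `mitogenome` objects.
#' @param genes gene-name set (default: the 13 PCGs plus the 2 rRNAs).
#' @param model `"p"` (default) or `"jc"`.
#' @param ... scoring parameters passed to [global_align()].
#' @return List of class `gene_set_distances`: `per_gene` data frame (gene,
#'   compared, differing, p, d), `mean_p`, `mean_d`, `missing`.
#' @export
gene_set_distances <- function(genome_a, genome_b,
                               genes = c(PCG_GENES, RRNA_GENES),
                               model = c("p", "jc"), ...) {
  model <- match.arg(model)
  missing <- genes[!(genes %in% genome_a$features$name &
                       genes %in% genome_b$features$name)]
  if (length(missing))
    warning("gene(s) missing from one genome, excluded: ",
            paste(missing, collapse = ", "))
  genes <- setdiff(genes, missing)
  if (!length(genes)) stop("no shared genes to compare")
  rows <- lapply(genes, function(g) {
    al <- global_align(extract_gene(genome_a, g), extract_gene(genome_b, g), ...)
    pd <- p_distance(al$a, al$b, gene = g)
    data.frame(gene = g, compared = pd$compared, differing = pd$differing,
               p = pd$p, d = jc_correct(pd$p), stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  structure(list(per_gene = per_gene,
                 mean_p = mean(per_gene$p),
                 mean_d = mean(per_gene$d),
                 mean = if (model == "p") mean(per_gene$p) else mean(per_gene$d),
                 model = model, missing = missing),
            class = "gene_set_distances")
}

#' Distance-threshold conspecificity assessment
#'
#' Mean genetic distance below the lower threshold indicates likely
#' intraspecific divergence; above the upper threshold, likely distinct
#' species; in between, the verdict is ambiguous. Defaults (0.01 / 0.03)
#' follow the intraspecific/interspecific divergence bands reported for
#' insect mitochondrial markers.
#'
#' @param mean_p mean distance over the gene set (proportion).
#' @param thresholds numeric length-2: `c(conspecific_below, distinct_above)`.
#' @param per_gene optional per-gene distance data frame carried through.
#' @return List of class `synonymy_verdict`: `mean`, `verdict`
#'   (`likely_conspecific` / `ambiguous` / `likely_distinct`), `thresholds`,
#'   `per_gene`.
#' @export
synonymy_assessment <- function(mean_p,
                                thresholds = c(conspecific_below = 0.01,
                                               distinct_above = 0.03),
                                per_gene = NULL) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2],
            mean_p >= 0, mean_p <= 1)
  verdict <- if (mean_p < thresholds[1]) "likely_conspecific"
  else if (mean_p > thresholds[2]) "likely_distinct"
  else "ambiguous"
  structure(list(mean = mean_p, verdict = verdict, thresholds = thresholds,
                 per_gene = per_gene), class = "synonymy_verdict")
}

#' NG86 rates for every shared PCG of two genomes
#'
#' @param genome_a,genome_b `mitogenome` objects.
#' @param table a [codon_table()].
#' @return Data frame: gene, codons, Ka, Ks, omega.
#' @export
genome_kaks <- function(genome_a, genome_b, table = codon_table()) {
  genes <- intersect(intersect(genome_a$features$name, PCG_GENES),
                     genome_b$features$name)
  do.call(rbind, lapply(genes, function(g) {
    r <- ng86(extract_gene(genome_a, g), extract_gene(genome_b, g),
              table = table, gene = g)
    data.frame(gene = g, codons = r$codons, S_sites = r$S_sites,
               N_sites = r$N_sites, Ka = r$Ka, Ks = r$Ks, omega = r$omega,
               stringsAsFactors = FALSE)
  }))
}
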