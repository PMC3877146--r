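# Independent oracles, written naively and without reference to the package
# internals: exhaustive global-alignment scoring, per-codon site counting by
# enumerating all nine single-nucleotide mutations, and pathway enumeration
# for multi-hit codons.

oracle_code <- Biostrings::getGeneticCode("5")

# best global alignment score by plain recursion over all alignments
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substring(a, i, i) == substring(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

oracle_mutate1 <- function(codon, pos, nt) {
  paste0(substring(codon, 1, pos - 1), nt, substring(codon, pos + 1, 3))
}

# synonymous site count of one codon: each position contributes the fraction
# of its non-stop single mutations that preserve the amino acid
oracle_codon_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    cur <- substring(codon, pos, pos)
    syn <- 0; ok <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), cur)) {
      mut <- oracle_mutate1(codon, pos, nt)
      if (oracle_code[[mut]] == "*") next
      ok <- ok + 1
      if (oracle_code[[mut]] == oracle_code[[codon]]) syn <- syn + 1
    }
    if (ok > 0) s <- s + syn / ok
  }
  c(S = s, N = 3 - s)
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# pathway-averaged synonymous/nonsynonymous differences between two codons
oracle_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  paths <- list()
  for (ord in oracle_perms(pos)) {
    cur <- ca; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- oracle_mutate1(cur, p, substring(cb, p, p))
      if (oracle_code[[nxt]] == "*" && nxt != cb) through_stop <- TRUE
      if (oracle_code[[cur]] == oracle_code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- c(sd, nd, through_stop)
  }
  m <- do.call(rbind, paths)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(Sd = mean(m[keep, 1]), Nd = mean(m[keep, 2]))
}

oracle_ng86 <- function(cds_a, cds_b) {
  k <- min(nchar(cds_a), nchar(cds_b)) %/% 3
  ca <- substring(cds_a, 3 * (1:k) - 2, 3 * (1:k))
  cb <- substring(cds_b, 3 * (1:k) - 2, 3 * (1:k))
  keep <- oracle_code[ca] != "*" & oracle_code[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  Sa <- sum(sapply(ca, function(c) oracle_codon_sites(c)[["S"]]))
  Sb <- sum(sapply(cb, function(c) oracle_codon_sites(c)[["S"]]))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) oracle_codon_diffs(x, y), ca, cb)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random in-frame CDS without stop codons
random_cds <- function(n_codons) {
  sense <- names(oracle_code)[oracle_code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# adjacency multiset of a circular (gene, strand) order, by direct
# enumeration of neighbour pairs
oracle_adjacencies <- function(genes, strands) {
  n <- length(genes)
  sapply(seq_len(n), function(i) {
    j <- if (i == n) 1 else i + 1
    pair <- sort(c(genes[i], genes[j]))
    paste(pair[1], pair[2],
          if (strands[i] == strands[j]) "same" else "opposite", sep = "|")
  })
}
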