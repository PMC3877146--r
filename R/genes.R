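# Canonical gene inventory for the metazoan mitogenome and GenBank-dialect
# name normalization. Canonical symbols: 13 PCGs (atp6 .. nad6), 2 rRNAs
# (rrnL, rrnS), 22 tRNAs (trnA .. trnY; Leu and Ser duplicates split as
# trnL1 = Leu(CUN), trnL2 = Leu(UUR), trnS1 = Ser(AGN), trnS2 = Ser(UCN)),
# plus "CR" for the control region.

PCG_GENES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
               "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

RRNA_GENES <- c("rrnL", "rrnS")

TRNA_GENES <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                "trnY")

#' Canonical 37-gene mitochondrial inventory
#'
#' @param include_cr also include the control region pseudo-gene `"CR"`.
#' @return Character vector of canonical gene symbols.
#' @export
canonical_gene_set <- function(include_cr = FALSE) {
  genes <- c(PCG_GENES, RRNA_GENES, TRNA_GENES)
  if (include_cr) genes <- c(genes, "CR")
  genes
}

#' Gene class of a canonical symbol
#'
#' @param name canonical gene symbol(s).
#' @return one of `"PCG"`, `"rRNA"`, `"tRNA"`, `"control_region"` per element.
#' @export
gene_kind <- function(name) {
  vapply(name, function(n) {
    if (n %in% PCG_GENES) "PCG"
    else if (n %in% RRNA_GENES) "rRNA"
    else if (n %in% TRNA_GENES) "tRNA"
    else if (n == "CR") "control_region"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Human-readable labels used in reports (tRNA-Leu(UUR) style).
#' @export
display_gene_name <- function(name) {
  aa3 <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
           H = "His", I = "Ile", K = "Lys", M = "Met", N = "Asn", P = "Pro",
           Q = "Gln", R = "Arg", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  vapply(name, function(n) {
    if (n %in% c("trnL1", "trnL2", "trnS1", "trnS2")) {
      switch(n,
             trnL1 = "tRNA-Leu(CUN)", trnL2 = "tRNA-Leu(UUR)",
             trnS1 = "tRNA-Ser(AGN)", trnS2 = "tRNA-Ser(UCN)")
    } else if (grepl("^trn[A-Z]$", n)) {
      paste0("tRNA-", aa3[[substring(n, 4, 4)]])
    } else n
  }, character(1), USE.NAMES = FALSE)
}

# Synonym table: uppercase, punctuation-stripped GenBank names -> canonical.
# Covers NADH dehydrogenase/ND/NAD, COX/CO/COI-III, CYTB/COB, 12S/16S variants
# and both one- and three-letter tRNA spellings. D-loop and misc control
# region notes are both accepted (annotation dialect varies).
.gene_synonyms <- local({
  syn <- c(
    ATP6 = "atp6", ATPASE6 = "atp6", ATPASESUBUNIT6 = "atp6", ATP8 = "atp8",
    ATPASE8 = "atp8", ATPASESUBUNIT8 = "atp8",
    COX1 = "cox1", COXI = "cox1", CO1 = "cox1", COI = "cox1",
    CYTOCHROMECOXIDASESUBUNIT1 = "cox1", CYTOCHROMECOXIDASESUBUNITI = "cox1",
    COX2 = "cox2", COXII = "cox2", CO2 = "cox2", COII = "cox2",
    CYTOCHROMECOXIDASESUBUNIT2 = "cox2", CYTOCHROMECOXIDASESUBUNITII = "cox2",
    COX3 = "cox3", COXIII = "cox3", CO3 = "cox3", COIII = "cox3",
    CYTOCHROMECOXIDASESUBUNIT3 = "cox3", CYTOCHROMECOXIDASESUBUNITIII = "cox3",
    CYTB = "cytb", COB = "cytb", CYB = "cytb", CYTOCHROMEB = "cytb",
    ND1 = "nad1", NAD1 = "nad1", NADH1 = "nad1",
    NADHDEHYDROGENASESUBUNIT1 = "nad1",
    ND2 = "nad2", NAD2 = "nad2", NADH2 = "nad2",
    NADHDEHYDROGENASESUBUNIT2 = "nad2",
    ND3 = "nad3", NAD3 = "nad3", NADH3 = "nad3",
    NADHDEHYDROGENASESUBUNIT3 = "nad3",
    ND4 = "nad4", NAD4 = "nad4", NADH4 = "nad4",
    NADHDEHYDROGENASESUBUNIT4 = "nad4",
    ND4L = "nad4l", NAD4L = "nad4l", NADH4L = "nad4l",
    NADHDEHYDROGENASESUBUNIT4L = "nad4l",
    ND5 = "nad5", NAD5 = "nad5", NADH5 = "nad5",
    NADHDEHYDROGENASESUBUNIT5 = "nad5",
    ND6 = "nad6", NAD6 = "nad6", NADH6 = "nad6",
    NADHDEHYDROGENASESUBUNIT6 = "nad6",
    RRNL = "rrnL", `16S` = "rrnL", `16SRRNA` = "rrnL", `16SRIBOSOMALRNA` = "rrnL",
    LRRNA = "rrnL", LSU = "rrnL", LARGESUBUNITRIBOSOMALRNA = "rrnL",
    RRNS = "rrnS", `12S` = "rrnS", `12SRRNA` = "rrnS", `12SRIBOSOMALRNA` = "rrnS",
    SRRNA = "rrnS", SSU = "rrnS", SMALLSUBUNITRIBOSOMALRNA = "rrnS",
    DLOOP = "CR", CONTROLREGION = "CR", CR = "CR", ATRICHREGION = "CR",
    PUTATIVECONTROLREGION = "CR", MAJORNONCODINGREGION = "CR"
  )
  aa31 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
  for (aa in names(aa31)) {
    one <- aa31[[aa]]
    if (one %in% c("L", "S")) next  # handled with their anticodon qualifier
    can <- paste0("trn", one)
    syn[paste0("TRNA", aa)] <- can
    syn[paste0("TRN", aa)] <- can
    syn[paste0("TRN", one)] <- can
    syn[paste0("TRNA", one)] <- can
  }
  # Leu/Ser duplicates: bare names default to nothing; codon-qualified forms:
  syn[c("TRNALEUCUN", "TRNLEUCUN", "TRNL1", "TRNAL1", "TRNALEU1")] <- "trnL1"
  syn[c("TRNALEUUUR", "TRNLEUUUR", "TRNL2", "TRNAL2", "TRNALEU2")] <- "trnL2"
  syn[c("TRNASERAGN", "TRNSERAGN", "TRNS1", "TRNAS1", "TRNASER1")] <- "trnS1"
  syn[c("TRNASERUCN", "TRNSERUCN", "TRNS2", "TRNAS2", "TRNASER2")] <- "trnS2"
  syn
})

#' Normalize a GenBank gene name to its canonical symbol
#'
#' Strips punctuation/case and looks the result up in a synonym table that
#' covers the common GenBank dialects (ND/NAD/NADH dehydrogenase subunits,
#' COX/CO/COI-III, CYTB/COB, 12S/16S rRNA spellings, one- and three-letter
#' tRNA names with or without codon qualifiers, D-loop/control region).
#'
#' @param raw raw name(s) as found in a `/gene`, `/product` or `/note`
#'   qualifier.
#' @return Canonical symbol, or `NA` where no mapping is known.
#' @export
normalize_gene_name <- function(raw) {
  vapply(raw, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    key <- toupper(gsub("[^A-Za-z0-9]", "", x))
    key <- sub("^MT", "", key)
    if (key %in% names(.gene_synonyms)) return(unname(.gene_synonyms[[key]]))
    # already canonical?
    if (x %in% canonical_gene_set(include_cr = TRUE)) return(x)
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Standard insect mitochondrial tRNA anticodons (coding orientation, DNA).
STANDARD_ANTICODONS <- c(
  trnA = "TGC", trnC = "GCA", trnD = "GTC", trnE = "TTC", trnF = "GAA",
  trnG = "TCC", trnH = "GTG", trnI = "GAT", trnK = "CTT", trnL1 = "TAG",
  trnL2 = "TAA", trnM = "CAT", trnN = "GTT", trnP = "TGG", trnQ = "TTG",
  trnR = "TCG", trnS1 = "GCT", trnS2 = "TGA", trnT = "TGT", trnV = "TAC",
  trnW = "TCA", trnY = "GTA")

#' Invertebrate mitochondrial codon table (translation table 5)
#'
#' Wraps the NCBI translation table 5 (invertebrate mitochondrial) genetic
#' code with the start-codon set and the synonymous-family partition used for
#' RSCU. Two family modes are supported: `by_trna_family` splits Leu into
#' Leu(UUR)/Leu(CUN) and Ser into Ser(AGN)/Ser(UCN), matching the
#' mitochondrial convention; `by_amino_acid` pools all codons of an amino
#' acid.
#'
#' @param family_mode `"by_trna_family"` (default) or `"by_amino_acid"`.
#' @return An object of class `codon_table` with elements `code_id`, `aa`
#'   (named codon -> amino-acid map, `*` = stop), `starts`, `stops`,
#'   `family` (named codon -> family label, stops excluded) and
#'   `family_mode`.
#' @export
codon_table <- function(family_mode = c("by_trna_family", "by_amino_acid")) {
  family_mode <- match.arg(family_mode)
  aa <- Biostrings::getGeneticCode("5")
  stopifnot(length(aa) == 64)
  stops <- names(aa)[aa == "*"]
  sense <- names(aa)[aa != "*"]
  fam <- vapply(sense, function(cod) {
    a <- aa[[cod]]
    if (family_mode == "by_amino_acid") return(a)
    if (a == "L") {
      if (substring(cod, 1, 1) == "T") "Leu(UUR)" else "Leu(CUN)"
    } else if (a == "S") {
      if (substring(cod, 1, 2) == "AG") "Ser(AGN)" else "Ser(UCN)"
    } else a
  }, character(1))
  structure(list(
    code_id = "5",
    aa = aa,
    starts = c("ATA", "ATT", "ATC", "ATG", "TTG", "GTG"),
    stops = stops,
    family = fam,
    family_mode = family_mode
  ), class = "codon_table")
}
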