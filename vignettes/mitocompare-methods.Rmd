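---
title: "Methods: comparative mitogenomics with mitocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

## The problem

Insect mitochondrial genomes are compact circular molecules of roughly
16 kb carrying a nearly invariant inventory: 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and one large non-coding control region (CR).
When two nominal species are suspected of being the sexes of a single
species — a recurring situation in groups with strong sexual dimorphism —
their complete mitogenomes offer a decisive molecular test: conspecific
individuals show per-gene divergences an order of magnitude below typical
congeneric distances. `mitocompare` implements the complete analysis such a
test needs: annotation auditing, composition and strand-skew statistics,
codon usage, per-gene genetic distances, Ka/Ks, tRNA structural
comparison, and the final distance-threshold decision, plus a seeded
simulator so every stage is testable without any external data.

## Representation and coordinate conventions

A `mitogenome` holds a nucleotide string over `{A,C,G,T,N}` plus an ordered
feature table. Internally coordinates are 0-based and half-open, which
keeps overlap and wrap-around arithmetic free of off-by-one corrections;
GenBank's 1-based inclusive convention is applied only at the file
boundary. A feature crossing the origin of the circle is *virtually
linearized*: its `end` exceeds the genome length and every extraction is
performed modulo the length, so a single code path serves wrapped and
unwrapped features. Minority-strand ("N-strand") features are extracted as
reverse complements. `N` bases are allowed in the sequence but excluded
from every downstream count.

Gene names arriving from GenBank dialects (ND/NAD/NADH subunits, COX/CO/COI
forms, CYTB/COB, 12S/16S spellings, one- and three-letter tRNA names,
D-loop vs control-region notes) are mapped to canonical symbols through an
explicit synonym table; both `D-loop` keys and control-region
`misc_feature` notes are accepted because public annotations use either.

## Annotation audit

`junction_accounting` walks the features in circular order and emits one
record per adjacent pair — `overlap`, `spacer` or `abutting` — including
the wrap-around junction. Its internal conservation identity,

$$\sum_i \mathrm{len}_i \;-\; \mathrm{overlap_{total}} \;+\;
\mathrm{spacer_{total}} \;=\; L,$$

is enforced by property tests on rotated and unrotated synthetic genomes.
A feature nested inside another cannot participate in this identity and is
excluded with a warning. Overlaps between genes on opposite strands are
counted identically to same-strand overlaps.

Start codons are classified from the first three coding nucleotides
(`canonical_ATN`, `TTG`, `GTG`, `other`); the stop class is derived from
the extracted length modulo 3 — a length of $3k+1$ ending in `T` (or
$3k+2$ ending in `TA`) is an *incomplete* stop completed by
polyadenylation, a hallmark of compact mitochondrial gene packing. The
reading frame is always taken from the annotation, never re-inferred, and
internal translation is scanned for premature stops.

Gene order is compared via rotation-invariant adjacency sets anchored at
tRNA-Ile (the conventional start of insect mitogenome maps; configurable).
An adjacency is an unordered neighbour pair with relative orientation, so
the broken-adjacency count is symmetric. The named flag `cw_swap` reports
the derived arrangement in which tRNA-Cys sits immediately upstream of
tRNA-Trp rather than downstream — a rearrangement characteristic of
lacewing (Neuroptera) mitogenomes against the ancestral insect order.
Both orders ship as packaged TSV templates.

## Composition and codon usage

AT-skew $=(A-T)/(A+T)$ and GC-skew $=(G-C)/(G+C)$ are computed from raw
counts, never from rounded percentages; a zero denominator yields `NA`
rather than a fabricated zero. Skews are antisymmetric under reverse
complement, which the test suite exercises as a property.

Relative synonymous codon usage (RSCU) divides each codon's count by its
family mean, so an unbiased family has RSCU 1 everywhere and family sums
equal family sizes. Under the invertebrate mitochondrial code
(translation table 5) the default family partition is *by tRNA family* —
Leu(UUR)/Leu(CUN) and Ser(AGN)/Ser(UCN) are separate families, matching
the mitochondrial convention; a pooled by-amino-acid mode is provided
because published tables do not always state their convention. Codon
percentages use all counted sense codons as the denominator, with complete
stop codons tallied separately; the alternative (stops included) shifts
values by under 0.3% and is deliberately not the default. Trailing 1-2 nt
incomplete stops are dropped before counting, and codons containing gaps
or `N` are skipped with a warning.

## Distances, Ka/Ks, and the conspecificity rule

Per-gene distances are uncorrected p-distances over globally aligned gene
pairs with *pairwise deletion*: a column containing a gap or `N` in either
row leaves both numerator and denominator. The uncorrected p-distance is
the default because the decision thresholds used in the insect barcoding
literature are expressed on that scale and because identical genes must
report exactly 0.0000; a Jukes–Cantor option (`model = "jc"`) is provided.
Global alignment is Needleman–Wunsch with match +1 / mismatch −1 and a
linear gap penalty of −2 per gap column; the dynamic programme is
delegated to `Biostrings::pairwiseAlignment`, which is deterministic
(tie-breaking among co-optimal paths follows that implementation; tests
assert optimal scores and gap counts, which are tie-independent).

Ka and Ks follow Nei & Gojobori (1986). Each codon position contributes a
synonymous-site fraction equal to the share of its non-stop single-nucleotide
changes that preserve the amino acid, so $S + N = 3$ per codon and site
totals are averaged over the two sequences. Differences in codons hit at
2-3 positions are averaged over all minimal mutational pathways with equal
weights; pathways through stop codons are excluded unless every pathway is
blocked (a degenerate case, in which all are kept). The Jukes-Cantor
correction $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$ is applied to $p_S$ and
$p_N$ separately; $\omega = K_a/K_s$ is undefined when $K_s = 0$ or a
correction leaves its domain ($p \ge 3/4$). The implementation is verified
codon-for-codon against an exhaustive enumeration oracle on random short
CDS pairs.

The conspecificity rule is deliberately simple and transparent: the
unweighted mean p-distance over the 13 PCGs and 2 rRNAs is compared with
two thresholds, default 0.01 (below: `likely_conspecific`) and 0.03
(above: `likely_distinct`), the bands reported for intraspecific vs
congeneric divergence of insect mitochondrial markers; anything between is
`ambiguous`. The thresholds, distance model and gap handling are echoed in
every report so a verdict is always reproducible from its inputs.

## tRNA structures

Cloverleaf structures are *input* (a TSV of per-arm pair coordinates and
loop spans), not inferred — structure prediction is an external,
curation-heavy step, while the statistics of interest (Watson–Crick vs G–U
wobble vs mismatched stem pairs, arm sizes, position-level differences
between two genomes) are pure bookkeeping once the pairing is fixed. The
DHU-armless serine tRNA is represented as a DHU stem with zero pairs.
Classification is independent of the (i, j) orientation convention, and
planted-wobble round trips with the generator pin the arithmetic down.

## The synthetic-mitogenome generator

The generator emulates a strongly AT-biased lacewing-like mitogenome and
is the package's test bed; its defaults are fixed study conditions, not
tuning knobs:

* **Layout**: 37 genes + CR in the derived lacewing order (`neuroptera_cw`;
  the ancestral `dyakuba` order is available), 23 features on the majority
  strand and 14 on the minority strand.
* **Lengths**: PCG and rRNA lengths from a packaged table of typical
  insect values (PCG total 11,176 bp; rrnL 1,316 bp; rrnS 777 bp), tRNAs
  63-71 bp from sampled cloverleaf dimensions, CR 1,167 bp — the assembled
  circle lands near 16 kb.
* **Composition**: nucleotide sampling probabilities are derived per
  region from an A+T proportion (0.80 coding/RNA, 0.95 CR) and fixed
  genome-strand skews (AT-skew −0.0675, GC-skew −0.185), applied in coding
  orientation with complement-swapped probabilities for minority-strand
  genes so the *genome strand* shows the configured skews. An iid
  nucleotide model reproduces composition and skews but not an empirical
  codon-preference ranking; codon-level statistics of generated genomes
  are therefore realistic in bias but not in exact codon ranks, and tests
  assert the former only.
* **Codon structure**: per-PCG start codons (ATG/ATT/ATA/TTG assignments
  typical of lacewing mitogenomes), complete TAA/TAG or incomplete single-T
  stops (cox1, cox2, nad4, nad5), and stop-free interiors by rejection
  sampling.
* **Junctions**: planted overlaps realise 11 overlap junctions totalling
  35 bp — the conserved coding-orientation heptamers `ATGATAA` (atp8/atp6)
  and `ATGTTAA` (nad4l/nad4), an 8 bp `ATGATTAA` overlap at nad6/cytb, and
  eight 1-2 bp tRNA-junction overlaps — plus ten spacers of 1-29 bp. The
  per-junction placement of the small overlaps and spacers is the
  package's own choice; only the summary (11/35/8, spacers 1-29) is
  externally anchored.
* **Determinism**: one seed (Mersenne-Twister) fixes every byte of output;
  the config travels with the genome as an attribute.

The divergence process `mutate_genome` plants substitutions per NG86 site
classification — a synonymous event never changes the amino acid, neither
class creates a stop — with per-position Bernoulli draws (one uniform per
site, so an equal syn/nonsyn rate *d* gives every eligible site exactly
probability *d* of change; this exactness is what the parameter-recovery
tests lean on). Start/stop codons and all overlap positions are protected.
RNA genes and the CR mutate uniformly per site; the CR additionally
undergoes a deletion-biased indel process (per-site event rate 0.004,
lengths 1 + Poisson(4.6), ~26 bp removed in expectation). Every event is
logged, and replaying the log against the parent must reproduce the child
byte-for-byte — the log is the ground truth for recovery tests.

The packaged `rapisma_like` profile emulates a conspecific pair: its PCG
rates were set in closed form so the expected PCG mean p-distance is
0.0034 (given the code's realized synonymous-site fraction of ~0.20 and a
purifying Ka/Ks of ~0.057), with rRNA divergence 0.0021 — the divergence
regime of two sexes of one species. `distinct_like` raises the RNA rate to
0.085 so rRNA-fragment distances land in congeneric territory above the
0.03 threshold.

## Problem sizes and numerical choices

The test suite runs the NG86-vs-oracle comparison on 1,000 random CDS
pairs of up to 5 codons, the junction conservation identity on 100 seeded
genomes (half rotated to create origin-spanning features), and
parameter recovery at planted divergences 0.001/0.005/0.02 with 200
replicates each, pooling differences over all PCG sites and requiring
agreement within 3 binomial standard errors. Distance output is reported
to 4 decimals and omega to 2 in formatted reports, matching the precision
conventions of the field; all comparisons in code use full precision.
Ranking ties in codon tables are broken lexicographically so reports are
stable across platforms.

## What passing tests do and do not show

The generator validates the *arithmetic* of every pipeline stage against
planted ground truth. It does not emulate several features of real data:
codon-preference rankings beyond the AT bias, rate heterogeneity across
sites and genes, tRNA post-transcriptional edits, CR tandem repeats, or
annotation errors in public records. Accordingly, agreement on synthetic
data demonstrates correctness of the computations, not robustness to
messy third-party annotation; the GenBank reader's dialect handling is
tested separately on constructed dialect cases. The accession-level checks
in the acceptance suite require the two published ~16 kb records to be
fetched once (`inst/scripts/fetch_accessions.sh`) and are the only part of
the suite that touches external data.

## Known limitations

* No Kimura/HKY/GTR distances and no ML-based omega; NG86 with
  Jukes-Cantor is the classical, auditable choice for near-identical
  sequences.
* Multi-span GenBank locations other than a two-span origin join are
  merged to their extremes with a warning.
* tRNA structure *prediction* is out of scope by design.
* The simulator's substitution process is per-site Bernoulli, not a
  branch-length model; it is sufficient for distance-recovery validation
  but not for simulating deep divergence.
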