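---
title: "BCR repertoire simulation and analysis with vdjrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BCR repertoire simulation and analysis with vdjrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjrep)
```

## Scope and scientific background

Antibody heavy-chain variable regions are assembled somatically from
germline V, D and J gene segments; light (kappa) chains from V and J.
Junctional processing — exonucleolytic trimming of the joining ends,
templated palindromic (P) nucleotides at untrimmed ends, and non-templated
(N) nucleotide insertion — concentrates enormous sequence diversity in the
third complementarity-determining region (CDR3), which spans the junction
between the conserved Cys104 of the V segment and the conserved Phe/Trp118
of the J segment. After antigen exposure, somatic hypermutation (SHM)
accumulates point mutations in the rearranged variable region, with a bias
toward the CDRs, and clonal selection expands particular lineages.

`vdjrep` provides the computational side of this biology as a tested,
reusable pipeline: a generative simulator whose emitted reads carry full
ground truth, an annotator that recovers that structure from sequence
alone, and the descriptive and comparative statistics used to profile
repertoires — segment usage, combination links, CDR3 properties,
Shannon-Weaver diversity, clonotype/lineage structure, positional SHM
profiles, a between-sample divergence odds score, and humanness scoring of
antibody sequences. All coordinates throughout the package are 0-based and
half-open; every stochastic operation is seeded.

## The germline reference

A reference is a FASTA of segment sequences plus a tab-separated metadata
sidecar (`id`, `locus`, `segment_type`, `functionality`, `anchor_offset`,
`reading_frame`, optional CDR1/CDR2 intervals for V segments). Anchors are
explicit offsets of the Cys104 (V) and Phe/Trp118 (J) codons rather than a
full IMGT unique numbering — the offsets are sufficient for CDR3
extraction and keep toy references easy to construct and validate. The
loader enforces the biological invariants (anchor codons translate to
C and F/W respectively, anchors inside the sequence, unique ids, exact
FASTA/metadata correspondence). Functionality labels follow the IMGT
classes `functional`/`ORF`/`pseudogene`; because usage conventions differ
on whether "potentially functional" includes ORFs, `functional_segments()`
exposes ORF inclusion as a switch (default off).

The bundled `toy_germline()` reference is synthetic: 100-codon V segments
with the anchor at offset 291 and CDR1/CDR2 at nt 75–99 and 150–174,
short random D segments, and J segments with the anchor at offset 9. It is
built for testing and demonstration, not for annotating real reads.

## The repertoire generator

`simulate_rearrangement()` draws a segment triple from the configured
usage vectors (default uniform over functional segments) and assembles

```
V + P? + N1 + P? + D + P? + N2 + P? + J      (IGH)
V + P? + N1 + P? + J                         (IGK)
```

* **Trimming.** Each junction-facing end (V 3', D 5', D 3', J 5') loses a
  geometric number of bases with mean `trim_mean` (default 1.5 nt).
  Trims that would consume a whole segment are resampled.
* **P nucleotides** occur only at untrimmed ends (the standard immunology
  convention: P additions are templated from an intact hairpin end), with
  probability `p_prob` (default 0.3) and truncated-geometric length capped
  at `p_maxlen` (default 4). A P extension is the reverse complement of
  the adjacent terminal bases, so it is fully determined by the germline
  and its length.
* **N inserts** have geometric length with mean `n_mean` (default 4 nt)
  and uniform base composition. Published repertoires suggest junction-
  dependent means and GC bias; both are deliberately left as configuration
  rather than calibrated defaults, since no authoritative distribution is
  available at this scale.
* **SHM** (`apply_shm`) mutates each position independently at `shm_rate`,
  multiplied by `hotspot_multiplier` inside CDR positions (CDR1/CDR2 from
  the germline metadata plus the CDR3 junction span), to a uniformly
  chosen different base.
* **Clonal structure.** With `n_lineages` set, founder rearrangements are
  expanded into copies (fixed or multinomial counts) and each copy is
  mutated independently from the founder — a star topology. Tree-shaped
  within-lineage evolution is a non-goal; the star is sufficient for
  testing positional profiles and divergence statistics, but it cannot
  produce the nested mutation sharing a real genealogy would.

### Canonical junction truth

A subtle identifiability problem drives one design decision. If a random
N base happens to continue the germline segment next to it (or to extend a
palindrome, or to blur where the D segment sits), then the generated
decomposition and the maximal-match decomposition of the very same read
differ — no annotator, however good, can recover the generated one. The
generator therefore emits only reads whose sampled decomposition *is* the
canonical (maximal-match) one, by rejection. Two measures keep the
configured distributions honest under this conditioning:

* N lengths are drawn once per rearrangement outside the rejection loop,
  so their geometric marginal is preserved exactly; conflicts are resolved
  by resampling N base *contents* at fixed lengths where possible, and
  skeleton (trim/P) choices otherwise.
* The canonicality test inside the generator is coded independently of
  the annotate module's decomposition routine, so annotator/simulator
  agreement remains a two-route check rather than a tautology.

The residual cost is a slight conditioning of trim lengths and of N base
composition adjacent to segment boundaries (measured at about 3% on the
mean trim under defaults), documented here rather than hidden. Reads whose
kept D portion would fall below the identifiability threshold
(`min_d_match`, default 5 nt) are likewise resampled, so emitted IGH truth
always has an identifiable D.

Every read carries a truth record (segment calls, trims, P lengths, N
strings, substitution list, lineage id) from which `reconstruct_read()`
rebuilds the read byte-exactly; this invariant is enforced in the test
suite.

## The annotator

`annotate_reads()` is a deterministic, desk-scale stand-in for IgBlast,
sufficient for synthetic and toy data; full IgBlast feature parity
(indels, allele-level SHM correction, constant-region calling) is a
non-goal.

* **Alignment** is gapless local alignment with match +1 / mismatch −1
  (gaps effectively disabled). V is chosen over the whole read by best
  score, J over the region downstream of the V, and D (IGH) as the longest
  exact germline substring of the V–J gap, `unassigned` below
  `min_d_match` consecutive matching bases. Score ties break to the
  lexicographically smallest segment id and are flagged — reproducibility
  over cleverness.
* **Junction decomposition** assigns trims from the aligned germline
  spans, then splits each inter-segment region greedily: maximal P first
  (only at untrimmed ends, up to `p_maxlen`), remainder N. The P/N split
  of an underdetermined region is a convention, and the greedy-maximal-P
  rule is applied identically in the generator's canonicality check.
  Both P and N are reported separately, plus pooled `np1`/`np2` columns.
* **CDR3** runs from the first base of the codon aligned to the V anchor
  (Cys104, included) to the base before the codon aligned to the J anchor
  (Phe/Trp118, excluded); `junction` adds both anchor codons. The
  convention is recorded in an output attribute. Reads whose anchors are
  lost to trimming or whose anchor codons no longer translate to C / F or
  W are flagged `cdr3_unresolved` and retained.
* **Productivity** requires the V and J anchors in frame
  (junction length ≡ 0 mod 3) and a stop-free translation of the aligned
  V-through-J span. Out-of-frame reads keep their nucleotide CDR3 but an
  empty `cdr3_aa` and `productive = FALSE`.
* **Quality control.** Reads whose best V identity falls below 70% over at
  least 50 aligned nt are excluded from the output and counted in the `qc`
  attribute, never silently dropped.

On simulated data the annotator is oracle-equivalent: at `shm_rate = 0`
all of 1,000 reads receive the truth V/J calls and byte-exact N strings;
at 2% SHM at least 95% of V calls are correct at the gene level (both are
acceptance-tested). Equivalence is claimed against the simulator oracle
only, not against IgBlast output.

## Repertoire statistics

Usage frequencies are computed over annotated reads including
nonproductive ones by default (the restriction to productive reads is a
flag), whereas CDR3 length and amino-acid composition are restricted to
productive rearrangements, where a CDR3 protein sequence is defined.
Unassigned D calls are excluded from the D-usage denominator and reported
separately. Duplicate-count weighting is exposed as a flag everywhere it
matters, since conventions differ on whether figures weight unique reads
or copies.

The Shannon-Weaver index is computed directly from its defining sum with
the natural logarithm; no log-base option is offered, to avoid silent unit
drift. The "species" unit is the clonotype (joined CDR1-2-3 amino-acid
key) by default, with unique annotated reads as an alternative — the
abundance unit is ambiguous in common usage, so both are supported and the
default is stated. Rarefaction subsamples reads uniformly without
replacement; the curve is monotone and bounded by the clonotype count, and
its small-sample expectation is verified against exhaustive enumeration in
the tests. Combination links can be exported as Circos karyotype + links
text files (band sizes proportional to observed group frequencies);
drawing is delegated to Circos itself.

## Clonal analysis

Two grouping notions are distinguished deliberately. A **clonotype** is an
exact identity key — the joined CDR1-CDR2-CDR3 amino-acid sequence. A
**clone lineage** approximates "descends from one rearrangement event",
operationalized as the V-D-J segment typing (gene level by default;
allele level and an optional stricter mode adding CDR3 length are
available). Lineages are named `CLH001…`/`CLL001…` in descending
copy-count order with deterministic tie-breaking.

The positional SHM profile of a lineage reports, at every germline V
position, the percentage of member reads mutated there. The denominator is
the reads whose V alignment *covers* the position, not all members — a
read whose alignment ends before a position carries no information about
it. Because variable-region lengths differ between reads, profiles are
normalized: position p maps to index `round(100 (p+1) / L̄)` (clipped to
1..100), where L̄ is the lineage's mean variable-region length; rates are
averaged within an index bin, and bins receiving no position get rate 0.
One index unit is then close to one amino-acid position, and lineages of
different lengths are comparable. When profiles are aggregated across top
lineages, the unweighted mean is the default (a weighted option exists via
copy counts) so that one huge lineage does not dominate the landscape.
Region labels (FR1…CDR3, with FR4 beyond the V) come from the germline
annotation.

Dendrograms use neighbor joining (via `ape`) on normalized Levenshtein
distances between clonotype CDR3 amino-acid sequences (edit distance over
the longer length); substitution-matrix distances are a non-goal. Leaf
copy overlays are capped at 50 reads with the cap flagged, so expanded
clonotypes remain drawable. One- and two-taxon inputs return the obvious
degenerate trees. On additive distance matrices NJ is exact; the test
suite verifies 4- and 5-taxon recovery against a brute-force topology
enumeration with least-squares branch fitting.

Expansion fold change between two samples normalizes lineage copies per
10,000 reads before dividing; lineages absent from the pre sample receive
a pseudocount of one normalized copy and are flagged, never silently.

## Divergence odds score

For two samples (e.g. immunized vs unimmunized), each read contributes a
V-segment %diversity — 100 × mismatches / aligned V span, junction
excluded, so the statistic reflects SHM rather than junctional diversity.
Lineages present in both samples with at least `min_copies = 100` reads
each are tested (below that, the per-lineage mean is too noisy to compare);
the two per-read samples are compared by Welch's unequal-variance t test,
and lineages are classified at raw P < 0.01 into four groups: more
diverged in sample 1 and significant (1) or not (2), less diverged and
significant (3) or not (4). Exact mean ties go to groups 3/4 —
conservative toward "not more diverged in sample 1". The odds score
`(n1/n2)/(n3/n4)` summarizes the repertoire-wide trend; swapping the
sample labels maps it to its reciprocal exactly. Zero cells receive a
Haldane-Anscombe +0.5 on all four counts, flagged in the result. No
multiple-testing correction is applied by default — the classification is
defined on raw P values — but a Benjamini-Hochberg option is exposed.
Degenerate Welch inputs are defined explicitly (two zero-variance samples
with equal means: t = 0, p = 1) rather than erroring mid-pipeline.

## Humanness

`t20_score()` scores a query variable region as the mean percent identity
of its 20 best matches in a user-supplied human reference set, from global
pairwise alignment (BLOSUM62, affine gaps); identity is matches over the
alignment length. The original method queried a curated hosted database
whose composition is not public; an explicit reference set keeps the
computation reproducible, at the cost that scores are only comparable
against the same set. With fewer than 20 references all are used and the
result is flagged. The conventional thresholds — above 79 for the full
FR+CDR sequence, above 86 for framework-only — are applied according to
the scoring mode; `extract_framework()` removes CDR intervals for the
latter.

## Determinism and problem sizes

Every stochastic stage consumes a named sub-seed derived from the global
seed; `run_pipeline()` records them, a configuration hash and the output
list in a JSON manifest, and reruns reproduce all non-manifest outputs
byte-identically (acceptance-tested at 2,000 reads). The test suite's
simulation sizes — 1,000 reads for oracle equivalence, 10,000 for
parameter recovery, 100 replicate lineages of 30 reads for hotspot
recovery, 200 lineages × 100 reads for the odds-score null — were chosen
to make three-standard-error assertions meaningful while keeping the
default suite comfortably runnable on a laptop.

## What passing tests do and do not show

The simulator emulates the structure the analyses measure (usage,
junctional diversity, clonal expansion, CDR-biased SHM), so green tests
demonstrate that the pipeline recovers known structure faithfully. Real
data differ in ways the generator deliberately omits: sequencing error and
paired-end merging artifacts, chimeras, indel SHM, selection-driven frame
and stop-codon depletion (real repertoires are >90% productive; random
junctions are not), allele-level reference ambiguity, and tree-structured
lineage genealogies. Conclusions about real repertoires therefore inherit
the annotator's conventions (greedy P/N split, gapless alignment) rather
than being guaranteed by the tests.
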