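---
title: "Methods: gene-neighborhood and domain-context analysis with hepnscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-neighborhood and domain-context analysis with hepnscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepnscape)
```

## The problem

HEPN-like domains are small all-α modules that act, in most characterised
cases, as metal-independent endoRNases. They rarely work alone: they appear
as the toxin half of two-gene toxin-antitoxin (TA) modules, as cargo of
restriction-modification (R-M) and abortive-infection loci, as fusion
partners of nucleotidyltransferases and helicases, and in eukaryotes as
families that occasionally explode into dozens of paralogs in a single
lineage. Characterising such a superfamily is therefore less a question of
one sequence search than of *context*: which genes travel together in
operons, which domains fuse, which active-site residues persist, and where
in the tree the family expands.

`hepnscape` implements that contextual workflow as composable, tested R
functions over tidy tables: every stage takes a data frame and returns a
tibble, so analyses chain with the pipe. Because the original census-scale
inputs (whole protein databases, thousands of genomes) are not
reproducible at desk scale, the package pairs each analysis stage with a
seeded synthetic-genome generator that plants known structure, making every
stage testable end to end without downloads.

## Operon and divergon model

Transcription units are approximated by two rules applied to genomically
sorted CDS features:

1. **co-directionality** — consecutive genes must share a strand, and
2. **proximity** — their intergenic distance (`start2 − end1` under
   0-based half-open coordinates) must not exceed `max_gap`, default
   **100 nt**.

Maximal runs passing both rules are operons; every gene belongs to exactly
one (singletons allowed). The proximity rule is a deliberate proxy for
shared-promoter membership: annotated genomes carry no promoter model, and
the 100-nt cutoff is the standard filter for prokaryotic operon calls.
Overlapping genes (negative distance, permitted to −50 nt by the
generator) always pass the rule — overlap is stronger evidence of
co-transcription than a short gap. On circular contigs the first and last
runs merge when the origin-spanning gap passes the rule; the merged operon
is reported once, anchored at its 5′-most gene.

Head-to-head pairs (strand pattern `−,+`, 5′ ends facing) are reported as
divergons when the head gap is between 0 and `max_head_gap` (default
**300 nt**, chosen to cover typical bidirectional-promoter spans; the rule
itself is the contribution, the number is configurable).

Choices a user may care about:

* The distance rule is applied to annotated CDS boundaries, not to
  transcription-start estimates.
* Non-CDS features (RNAs, pseudogene annotations without translations) are
  excluded from neighborhoods.
* `predict_operons` is checked against an exhaustive oracle that
  enumerates every segmentation of small contigs and keeps the unique one
  that is both valid and maximal.

## Active-site model

The catalytic signature scanned by `scan_rxh()` is **R-x(4..6)-H**: an
arginine, a spacer of 4-6 arbitrary residues, then a histidine. Spacers 4
and 6 are the forms seen in real families; 5 is accepted because the
printed range covers it. Two secondary signals are recorded as *evidence,
never requirements*: a polar residue immediately after the R (preferred
set N/D/H, falling back to the full polar class) and an upstream
E-x3-[KR] element.

`classify_active_site()` works at family level on an alignment:

* **active_canonical** — rows are degapped, scanned, and hit positions
  mapped back to columns; an (R column, H column) pair carried by at least
  the conservation threshold (default **0.8**) of non-empty rows calls the
  family active. The threshold is a package default: published
  family-level conservation values run around 80-95% without a stated
  cutoff, so 0.8 is a documented, configurable choice.
* **active_alternative** — no canonical site, but a conserved H column
  lies N-terminal to a conserved basic (K/R) column; this captures
  families that lost the canonical histidine yet retain a plausible
  alternative site.
* **inactive_binding** — no conserved R/H/E/K/D column at all: the domain
  is treated as a catalytically dead RNA-binding version. Families with
  partially conserved charged columns that satisfy neither active rule
  also land here, with the evidence table recording exactly which criteria
  failed, so the call is always one of the three.

Classification is invariant to row order and to fully gapped rows (the row
denominator counts rows with at least one residue).

Consensus lines follow the three printed residue classes — hydrophobic
`h` = WFYMLIVACTH, polar `p` = EDKRNQHTS, small `s` = ACDGNPSTV — with
fixed precedence h > p > s when several classes pass the threshold
(classes overlap: H is both hydrophobic and polar). A single residue
reaching the threshold always beats its class. Consensus fractions use all
rows in the denominator, so gap-heavy columns fall to `.`; per-column
conservation (`column_conservation()`) uses non-gap rows, which is why an
uppercase consensus letter always implies conservation at or above the
threshold but not conversely.

## Homology clustering

Neighbor proteins are grouped the way census pipelines group them: all
pairwise similarities, thresholded, then single linkage (connected
components of the pair graph). The alignment scoring is fixed and
documented rather than matrix-based, keeping results bit-reproducible:
match +1, mismatch −1, gap opening −5 and each gapped position −1 (a
length-L gap costs 5 + L); X matches nothing, including X. Identity is the
fraction of identical columns over the alignment excluding terminal-gap
columns; coverage is the fraction of the shorter sequence's residues
inside that region. Defaults — identity ≥ 0.3, coverage ≥ 0.7 — are
documented choices: the original clustering step was run "at different
thresholds" without publishing them, and clustering here only groups
neighbors for annotation, so the exact values are not load-bearing.
A substitution-matrix option is an extension point, not a current feature.

Two implementation notes. The global alignment itself is computed by
`Biostrings::pairwiseAlignment()` under the scoring above; the test suite
checks it against an independent exhaustive dynamic-programming oracle
(scores exactly; identity/coverage against the set achievable by
co-optimal alignments, since different optimal alignments of the same pair
can have different column statistics). Second, pairs whose shorter/longer
length ratio is below the coverage threshold are skipped before aligning —
provably lossless, because coverage can never exceed that ratio's bound.

## Domain architectures

`annotate_protein()` supports three detector kinds: exact sentinel
subsequences, motif regular expressions, and log-odds position-weight
matrices scored as summed per-position terms over a sliding window.
Profile/HMM searching is intentionally out of scope; intervals from an
external profile tool can be imported as TSV (`read_domain_tsv()`) and
flow through the same downstream stages. Overlaps are resolved greedily —
best score, then earliest start, then domain name — and losing hits are
dropped, not trimmed, which makes the result independent of library order.
Architecture strings join domain names N→C with `+`; proteins with no hit
are `"unknown"`. Fusion adjacency is consecutive-only: `A+B+C` yields
(A,B) and (B,C), never (A,C), and repeats yield self-pairs.

## The domain-context network

`build_network()` connects domains with two edge types: **fusion** edges
between domains adjacent in one polypeptide, and **neighborhood** edges
between domains carried by *different* genes of one operon. Domains of a
single gene never receive a neighborhood edge — that resolves the
ambiguity in rendering conventions where both edge types appear in one
picture. Edges are undirected with lexicographically canonical node order;
the N→C / 5′→3′ direction is retained as the `fwd` count. Weights count
distinct supporting instances (proteins for fusion, operons for
neighborhood): a pair occurring twice inside one protein still counts once
for that protein. This makes two invariants exact, and the tests recount
them independently: total fusion weight = Σ over annotated proteins of
(domain count − 1), and total neighborhood weight = Σ over operons of
distinct cross-gene domain pairs. `collapse_by_category()` conserves total
weight exactly by construction (parallel edges merge, intra-category edges
become self-loops). Layouts use the Kamada-Kawai spring embedder from a
fixed circular start, components placed on a grid, so coordinates are
deterministic for a given seed.

## TA dyads and context categories

`detect_ta_dyads()` is strict: only two-gene operons qualify, one gene
carrying a toxin-set domain (default HEPN) and the other an antitoxin-set
domain (default MNT). Orientation is judged in the operon's own strand
frame — on the minus strand the 5′ gene is the genomic-right one — and is
`canonical` when the antitoxin is 5′, the arrangement that lets the
neutralising partner be translated first. A gene carrying domains from
both sets (an MNT+HEPN fusion) disqualifies the pair rather than being
guessed. Because "almost always 5′" is not a published number, the package
reports orientation fractions instead of asserting a threshold. Larger
defense operons go through `classify_context()`, a majority vote of
rule-matched domains over an editable category table
(`default_category_rules()`, shipped as curation, not computation); ties
break lexicographically and are flagged.

## Phyletic patterns and expansions

`build_matrix()` is a pure tally of gene → (family, taxon) assignments
(taxon = genome/assembly identifier; lineage rollups are a user-supplied
map). `detect_lse()` flags a (family, taxon) cell as a lineage-specific
expansion when the copy number is at least `min_copies` (default **10**)
and at least `min_fold` (default **5**) times the median copy number over
the other taxa, a zero background counting as satisfied. The defaults are
documented choices motivated by the observed contrast between massive
expansions (tens of copies, e.g. 46 in one crustacean genome) and the
typical one-or-two background; both are configurable, and the rule is
monotone (raising a flagged count never un-flags it).

## What the generator emulates, and what it does not

`generate_genome()` lays planted elements (TA dyads, operons with chosen
gaps, divergons, multidomain fusions) and background genes along one
contig. Background intergenic gaps come from a two-component mixture
(short 5-80 nt with weight 0.35, long 150-400 nt) so the operon rule is
exercised on both sides of its threshold; planted elements are insulated
from neighbours by long-component gaps (> 100 nt), making their boundaries
unambiguous in the noise-free setting. Planted domains are fixed 18-mer
sentinels over an alphabet containing neither R nor H, so exact detectors
find them and no spurious active sites arise; every HEPN-carrying protein
receives exactly one planted Rx4H site. `plant_motif()` similarly draws
its background from the R/H-free alphabet, and when asked to plant an
upstream E-x3-[KR] element writes E-x3-K specifically — an R there could
seed a second motif and break the exactly-one-site guarantee.

This is deliberately *not* sequence evolution: no substitution process, no
codon structure, no indels, no phage contamination, no annotation errors.
Passing the recovery tests therefore demonstrates that the inference rules
are implemented exactly as specified and are closed over their own
definitions — it does not demonstrate robustness to noisy annotations or
diverged sequences, which on real data enter through the quality of the
domain library and gene calls supplied by the user.

## Numerical and determinism choices

* Coordinates are 0-based half-open throughout (`end − start` = span);
  GenBank I/O converts at the boundary, and compound `join(...)` locations
  collapse to their outer span. Alignment columns are 1-based, matching R
  matrix indexing; motif and domain positions are 0-based.
* Ambiguous residues other than X map to X with a warning.
* Ties break lexicographically everywhere a tie is possible (conservation
  top residue, cluster numbering by smallest member id, cluster labels,
  category votes), so outputs are order-invariant and reproducible.
* All generator randomness flows from a single integer seed through an
  RNG-state-preserving wrapper; identical plan + seed gives byte-identical
  GenBank/FASTA/TSV output.
* Degenerate inputs have defined behaviour: gap-only alignment columns
  yield `("-", 0)` conservation, empty architecture lists yield
  `"unknown"`, an empty library and a single-taxon matrix are errors.

## Test problem sizes

The suite's end-to-end blocks use: exhaustive operon-oracle enumeration
for contigs of up to 4 genes over the gap grid {−10, 0, 50, 100, 101,
500} plus every strand assignment with sampled gap vectors for 5-8 genes
(≈ 4 700 contigs in total); 100 seeded genomes with 5 planted operons, 3
MNT-HEPN dyads, 2 divergons and 3 fusions each; 1 000 planted motifs
across spacers 4-6; 200 random sequence sets (up to 50 sequences) for the
clustering oracle and 100 pairs for the alignment oracle; a 500-row family
for the 83%-conservation recovery; and exhaustive 2×2 plus randomised
3×3/4×4 matrices for the expansion rule. `scripts/acceptance.R` recomputes
the same quantities at moderately smaller sizes from a fresh seed.

## Known limitations

* No profile/HMM search, secondary-structure prediction, or structural
  comparison: domain assignment quality on real proteomes depends on the
  library the user supplies or imports.
* BLASTCLUST's score-density criterion is approximated by
  identity + coverage single linkage; fine threshold behaviour differs.
* The promoter-sharing rules are proximity proxies; they will merge
  convergent genes that happen to sit close and co-directional.
* All-vs-all clustering is quadratic in the number of sequences; the
  length-ratio prefilter helps only when coverage thresholds are strict.
* Published census figures (family counts, per-family conservation
  percentages) are properties of a database snapshot and are outside what
  this package recomputes.
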