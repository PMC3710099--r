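# hepnscape

Gene-neighborhood and domain-context analysis of HEPN-like defense
systems, in tidy R.

HEPN-like domains are small all-α modules, mostly metal-independent
endoRNases marked by an **R-x(4..6)-H** active-site motif. They are
genomic nomads: the toxin half of MNT–HEPN toxin-antitoxin (TA) dyads,
cargo of restriction-modification (R-M) and abortive-infection operons,
fusion partners of nucleotidyltransferases and helicases, and — in some
eukaryotic lineages — families that expand into dozens of paralogs.
Understanding such a superfamily is a *context* problem, and `hepnscape`
implements the contextual inference workflow as composable, tested
functions over tidy tables:

* **Operons and divergons** — maximal runs of co-directional genes with
  intergenic distance ≤ 100 nt (configurable); head-to-head (−,+) pairs
  within a bidirectional-promoter span.
* **Neighbor clustering** — global pairwise alignment (match +1, mismatch
  −1, gap open −5, gap extend −1; X matches nothing), thresholded on
  identity and coverage, single linkage.
* **Active-site calls** — Rx4-6H scanning on sequences and alignments;
  families classified `active_canonical`, `active_alternative` (conserved
  H N-terminal to a conserved basic residue) or `inactive_binding`;
  Figure-style consensus lines with the h/p/s residue classes.
* **Domain architectures** — sentinel, regex and PWM detectors plus import
  of externally computed domain intervals; `A+B+C` strings and fusion
  adjacencies.
* **Context network** — domains as nodes, fusion edges (same polypeptide)
  and neighborhood edges (same operon, different genes), category
  collapsing, GraphML/SIF/TSV export, deterministic Kamada–Kawai layouts.
* **TA dyads** — strict two-gene rule with orientation judged in the
  operon's strand frame (canonical = antitoxin 5′ of toxin).
* **Phyletics** — family-by-taxon copy-number matrices and
  lineage-specific-expansion (LSE) calls (≥ 10 copies and ≥ 5× the
  background median, configurable).
* **Synthetic genomes** — a seeded generator that plants operons, dyads,
  divergons, fusions and motifs with machine-readable truth, so the whole
  pipeline is testable offline.

## Worked example

Generate a genome with one planted MNT–HEPN dyad, one R-M-style operon, a
divergon and an MNT+HEPN fusion, then run the full pipeline:

```r
library(hepnscape)

plan <- genome_plan(seed = 11, n_background_genes = 10,
  elements = list(ta_dyad(gap_nt = 30),
                  operon_element(c("Methylase", "REase", "HEPN"), c(20, 50)),
                  divergon_element(), fusion_element(c("MNT", "HEPN"))))
gnm <- generate_genome(plan)
res <- analyze_genome(gnm$genes, truth_library(gnm))

dplyr::filter(res$operons, n_genes > 1)
#> # A tibble: 3 × 8
#>   operon_id contig_id strand gene_ids  n_genes start   end wraps_origin
#>   <chr>     <chr>     <chr>  <list>      <int> <int> <int> <lgl>
#> 1 op0007    ctg1      +      <chr [3]>       3  4634  6315 FALSE
#> 2 op0008    ctg1      +      <chr [2]>       2  6555  7983 FALSE
#> 3 op0011    ctg1      -      <chr [2]>       2  9714 10687 FALSE
```

`op0007` is the planted three-gene operon, `op0008` the TA dyad; `op0011`
is a chance co-directional background pair — the generator's background
gap mixture deliberately produces such operons so prediction is
non-trivial. The dyad detector then confirms only the true TA module, with
the antitoxin 5′ of the toxin (the arrangement that lets the neutralising
partner be translated first):

```r
res$dyads
#> # A tibble: 1 × 7
#>   operon_id gene_5p gene_3p antitoxin_gene toxin_gene orientation gap_nt
#>   <chr>     <chr>   <chr>   <chr>          <chr>      <chr>        <int>
#> 1 op0008    g0010   g0011   g0010          g0011      canonical       30
```

The toxin protein carries exactly one active-site motif, at the planted
position, with the preferred polar residue after the arginine:

```r
scan_rxh(gnm$genes$protein_seq[gnm$genes$gene_id == res$dyads$toxin_gene])
#> # A tibble: 1 × 6
#>   r_pos spacer h_pos polar_after_r polar_preferred upstream_exkr_pos
#>   <int>  <int> <int> <lgl>         <lgl>                       <int>
#> 1    29      4    34 TRUE          TRUE                           NA
```

The context network summarises fusion (same polypeptide) and neighborhood
(same operon) associations; `tidy()` and `glance()` give the edge table
and summary, `autoplot()` a spring-embedded rendering, and
`export_graph()` writes GraphML for Cytoscape:

```r
tidy(res$network)
#> # A tibble: 6 × 5
#>   from      to        type         weight   fwd
#>   <chr>     <chr>     <chr>         <int> <int>
#> 1 HEPN      MNT       fusion            1     0
#> 2 HEPN      MNT       neighborhood      1     0
#> 3 HEPN      Methylase neighborhood      1     0
#> 4 HEPN      REase     neighborhood      1     0
#> 5 Methylase REase     neighborhood      1     1
#> 6 unknown   unknown   neighborhood      1     1
```

The HEPN–MNT pair is linked twice — once by fusion (the planted fusion
protein) and once by neighborhood (the dyad) — while HEPN also co-occurs
with the R-M components, the kind of association pattern the network is
built to expose. Real annotated genomes enter through
`read_genbank("genome.gbk")`, and a real domain vocabulary through
`read_domain_library()` (sentinel/regex/PWM detectors) or
`read_domain_tsv()` (intervals from an external profile search).

A thin command-line front end over the same functions is installed at
`inst/cli/hepnscape.R` (subcommands: `simulate`, `operons`, `divergons`,
`motif`, `cluster`, `network`, `ta`, `phyletics`).

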