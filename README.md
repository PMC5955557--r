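# kinomevo

Genome-wide protein kinase (kinome) family analysis in R: identify and
classify kinases from domain-hit evidence, validate the classification with
neighbor-joining phylogenies, fingerprint exon–intron structures inside the
kinase domain, reconstruct duplication history from gene order and homology
with Nei–Gojobori Ka/Ks dating, and screen expression matrices for
differential regulation. A bundled synthetic-genome simulator with complete
ground truth makes the whole pipeline testable end to end.

## Who this is for

Researchers analysing large gene families (the package is written around
plant kinomes, where receptor-like kinases dominate) who want the standard
desk pipeline — HMM-hit gating, subfamily assignment, NJ trees, MCScanX-style
collinearity, Ks-epoch dating, RPKM + fold-change screens — as composable,
tested R functions with tibble inputs and outputs.

## The methods at the core

* **Typicality gate** — a gene is a typical PK iff some domain hit has
  E-value < 0.01 *and* model coverage
  (model_end − model_start + 1)/model_length strictly above 0.5.
* **NG86 Ka/Ks** — per-codon synonymous site counts s (with s + n = 3),
  pathway-averaged difference counts over all mutational orderings
  (stop-codon pathways skipped), Jukes–Cantor correction
  Ks = −(3/4) ln(1 − (4/3) pS); pS ≥ 3/4 ⇒ saturated.
* **Ks epochs** — [0, 0.1) tetraploidization, [0.4, 0.6) the ~16.6 Mya
  whole-genome duplication, [0.6, 3) ancient, otherwise unassigned.
* **Neighbor joining** — Saitou–Nei agglomeration on p-distances
  (pairwise deletion), deterministic tie-breaks, negative branch lengths
  clamped to 0 with the deficit moved to the sibling; column-bootstrap
  supports.
* **Tandem / collinearity** — gene ranks over all genes; tandem links at
  rank gap ≤ 1 among homologs (E ≤ 1e-100); collinear blocks as monotone
  anchor chains (same or inverted), ≥ 5 anchors, rank gaps ≤ 25.
* **Differential screen** — RPKM, log2((mean_trt + 1)/(mean_ctl + 1)),
  two-sided Welch test on log2(RPKM + 1); retained iff |FC| > 1.5 and
  p < 0.01.

## Worked example

```r
library(kinomevo)
report <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)))
print(report)
#> <kinome_report>
#>   n_genes: 240
#>   n_typical: 119
#>   n_atypical: 13
#>   n_non_kinase: 108
#>   n_multi_domain: 6
#>   congruence_fraction: 1
#>   n_conserved_groups: 73
#>   n_tandem_genes: 10
#>   n_tandem_clusters: 3
#>   largest_tandem_cluster: 4
#>   n_collinear_blocks: 3
#>   n_collinear_events: 19
#>   single_correspondence_fraction: 1
#>   n_de_retained: 39
#>   groups: AGC=15 CAMK=9 CMGC=12 other=20 RLK=45 STE=11 TKL=7
#>   epochs: tetraploid=6 wgd_recent=13
```

Reading the output: of 240 simulated genes, 119 pass the typicality gate
(13 are atypical — all their domain hits cover ≤ 50 % of the model — and
108 carry no qualifying kinase evidence); the RLK group is the largest, as
in real plant kinomes. All three planted tandem arrays are recovered as
clusters (largest: 4 genes) and all three planted collinear blocks are
found; of the 19 anchor pairs, 6 date to the tetraploid epoch (planted
Ks 0.05) and 13 to the recent WGD (planted Ks 0.5). Every anchor pair is
single-correspondence, and `congruence_fraction: 1` says every multi-member
subfamily among the tree representatives forms a clade, validating the
score-based classification. The screen retains 39 genes, close to the 40
planted differential effects.

Individual stages are plain functions on tibbles:

```r
sim  <- simulate_genome(sim_config(seed = 1))
hits <- simulate_domain_hits(sim)
classify_kinases(hits$hits, hits$scores, universe = sim$genes$gene_id)
kaks("ATGTTTAAA", "ATGTTCAAA")      # one-row tibble: ka, ks, epoch, ...
autoplot(ks_histogram(c(0.05, 0.5, 0.52)))
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config config.yaml --out DIR`); YAML keys mirror
`pipeline_config()` arguments, with a `sim:` section for `sim_config()`.

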