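---
title: "Methods: kinome classification, duplication history and expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinome classification, duplication history and expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomevo)
```

## The analysis this package implements

Plant protein kinases (PKs) form one of the largest gene families in plant
genomes — several hundred to a few thousand genes — dominated by the
receptor-like kinase (RLK) group. A genome-wide kinome analysis of the kind
this package automates proceeds in five stages:

1. **Identification and classification.** Candidate kinases are recognised
   from alignments of their proteins to the Pfam kinase profiles (Pkinase,
   Pkinase_Tyr). A gene is a *typical* PK only when at least one alignment
   covers more than 50 % of the profile model at an E-value below 0.01;
   genes whose alignments all fail the coverage gate are *atypical*.
   Typical PKs are assigned to subfamilies by the highest-scoring
   subfamily profile HMM, and subfamilies roll up to seven groups (RLK,
   AGC, CAMK, CMGC, STE, TKL, other) via a catalog shipped as an editable
   data file.
2. **Phylogenetic validation.** A neighbor-joining tree of kinase-domain
   sequences under the p-distance model, with bootstrap supports, checks
   that HMM-score subfamilies form clades. Representatives are sampled per
   subfamily (1 for up to 6 members, 2 for 7–30, 3 beyond) to keep trees
   legible.
3. **Gene structure.** Intron phases (cumulative coding length modulo 3)
   restricted to the kinase-domain span yield a compact fingerprint such as
   `"1000"`; identical fingerprints within a subfamily across species mark
   deeply conserved exon–intron architectures.
4. **Duplication history.** Homologous pairs at E ≤ 1e-100 are combined
   with whole-genome gene order to call tandem clusters (consecutive
   homologous ranks) and collinear blocks (monotone anchor chains, in the
   style of MCScanX). Each duplicate pair receives Nei–Gojobori (1986)
   Ka/Ks estimates with Jukes–Cantor correction, and its Ks attributes the
   event to an epoch: 0–0.1 to the recent tetraploidization, 0.4–0.6 to
   the ~16.6 Mya whole-genome duplication, 0.6–3 to older events.
5. **Expression screening.** Counts are RPKM-normalized, treatment vs.
   control log2 fold changes are computed, and genes are retained when
   |FC| > 1.5 and p < 0.01.

Every stage runs on outputs of the bundled synthetic-genome generator, so
the complete pipeline is testable without any external genome or
expression resource.

## The NG86 estimator

For a codon, each of the three positions contributes (number of synonymous
single-nucleotide changes at that position)/3 synonymous sites, so
synonymous plus nonsynonymous sites always total 3. Changes that create a
stop codon count as nonsynonymous sites. For a codon pair differing at
$k$ positions, the substitutions along each of the $k!$ minimal pathways
are classified step by step; pathways through a stop codon are skipped and
the remaining ones averaged. Summing over codons gives $S_d$ and $N_d$;
sites are averaged over the two sequences; and

$$p_S = S_d / S, \qquad K_s = -\tfrac{3}{4}\,\log\!\left(1 - \tfrac{4}{3} p_S\right)$$

(and identically for $K_a$). When $p_S$ or $p_N$ reaches 3/4 the
correction is undefined and the pair is reported as *saturated*. The test
suite validates the whole counting machinery against an independent
exhaustive-enumeration oracle over all sense codons and all codon pairs.

Codon columns containing a gap or a stop in either sequence are dropped
before counting. Pairs of unequal length are codon-aligned through a
global protein alignment (BLOSUM62) before the estimator runs; the
package's own analyses only ever compare equal-length duplicates, so this
path is a convenience for user data.

## Neighbor joining

`neighbor_joining()` is the standard Saitou–Nei agglomeration with three
deterministic choices:

* Q-matrix ties break towards the smallest taxon-index pair.
* A negative branch-length estimate is clamped to zero and its deficit
  moved to the sibling edge (their sum, the joined pair's distance, is
  preserved).
* The final three nodes are joined by the closed-form three-point
  formulas.

On additive matrices the reconstruction is exact; the tests verify exact
topology recovery (Robinson–Foulds distance 0 against the generating
tree, and against `ape::nj` as an independent reference) and path-metric
agreement within 1e-9 over random trees of 4–12 taxa. p-distances use
pairwise deletion: a site is compared for a pair only when neither row has
a gap there. Pairwise (rather than complete) deletion keeps information
from partially gapped columns; a pair with no comparable sites at all is
an error naming the pair. Bootstrap supports resample columns with
replacement, rebuild the tree per replicate, and report the percentage of
replicates containing each internal bipartition of the original tree. The
conventional full analysis uses 1000 replicates; the package tests use
20–100 to keep runtimes in seconds, which is sufficient because only the
degenerate properties (all-identical columns give 100; one replicate gives
0 or 100; fixed seed gives identical supports) are asserted, not support
values themselves.

## Phases and fingerprints

Intron phase is cumulative coding length mod 3, with CDS segments taken in
translation order (reversed on the minus strand) — so the phase sequence
of a gene depends only on its translation-order exon lengths, which the
tests exercise as a strand-invariance property. An intron belongs to the
kinase domain when its coding-nucleotide position lies in
$[3(d_\mathrm{start}-1)+1,\; 3\,d_\mathrm{end}]$; both ends are inclusive,
so an intron exactly at a domain boundary counts as in-domain. Genes whose
total CDS length is not a multiple of 3 are skipped with a warning rather
than silently mis-phased. Conserved-structure groups are exact matches on
(subfamily, phase string); empty fingerprints (domain confined to one
exon) are grouped only on request, because an empty string carries no
positional signal. Published fingerprints sometimes carry a dash
(e.g. "0020–200") whose semantics are not defined anywhere we could
verify; this package emits undashed strings rather than guess.

## Tandem and collinearity detection

Gene ranks are computed per chromosome over *all* annotated genes, not
kinases only — collinearity and adjacency are properties of the whole
genome. Tandem links join homologous genes on the same chromosome at rank
distance ≤ `max_gap` (default 1, i.e. strictly consecutive); clusters are
connected components of links. Collinear blocks are extracted per
chromosome pair by dynamic programming over anchors sorted by rank:
chains must be strictly monotone on both axes (same or inverted
direction) with consecutive anchors at most `max_rank_gap` (default 25)
ranks apart, and chains shorter than `min_anchors` (default 5) are
discarded — mirroring MCScanX's defaults, since these parameters are
rarely reported alongside results. Two tie-breaks make the output
deterministic and robust to decoy homology: among equal-length chains the
smaller total rank span wins, and during the DP a predecessor of equal
chain length is preferred when it sits at a smaller rank gap (compact
chains absorb planted anchors in preference to stray homologs on the same
diagonal corridor).

Recovery of planted blocks is scored by subset containment: a found block
recovers a planted one when it contains all its anchors. This is
deliberate — a random decoy pair landing just beyond a planted diagonal
can legitimately extend the chain, and demanding exact set equality would
count that correct behaviour as an error.

## The differential screen

The published screens behind this design used limma (microarray) and
DESeq2 (RNA-seq). This package deliberately substitutes a two-sided Welch
test on log2(normalized + 1): the analysis surface here is recovery of
planted effects in synthetic data, not replication of empirical-Bayes
moderation, and a plain Welch test keeps the screen fully transparent. The
retention rule is exactly |FC| > 1.5 (linear scale, i.e.
|log2 FC| > log2 1.5 ≈ 0.585) and raw p < 0.01; a Benjamini–Hochberg
adjusted mode exists but is off by default because the screen is defined
on raw p-values. The fold change uses a pseudo-count of 1 on both group
means, which pins all-zero genes at log2 FC = 0 and stabilises ratios of
small values. RPKM library sizes are the column sums of the supplied
matrix — the original "per million mapped reads" denominator is
unavailable without alignments, and column sums are the standard desk
substitute.

## What the simulator emulates — and what it does not

`simulate_genome()` produces, from one seeded configuration: gene models
(1-based, strand ±, multi-exon, frame-consistent, non-overlapping, fixed
intergenic gaps so rank order equals coordinate order), protein and CDS
sequences, domain-hit and subfamily-score tables, homology pairs, count
matrices, and a ground-truth object tying them together.

Key generator conditions and their defaults:

| condition | default | why |
|---|---|---|
| genome | 2 chromosomes × 120 genes | smallest size at which all planted structures coexist |
| kinase fraction | 0.55 | kinases are a minority of genes, but the kinome must be large enough to populate subfamilies |
| atypical fraction | 0.1 | matches the order of magnitude of atypical/typical ratios in real kinomes (a few percent to ~15 %) |
| tandem arrays | 3 arrays of size 3–4 | RLK-dominated, as tandem clusters are in real plants |
| collinear blocks | 3 blocks of 6–7 anchors at Ks 0.5, 0.05 and 0.5 (one inverted) | one block per epoch of interest plus an orientation control |
| duplicate divergence | single-substitution-per-codon targeting | the number of synonymous/nonsynonymous codon changes is derived from the target Ks through the same NG86 site counts the estimator uses, so measurement error reduces to site-count drift of a few percent |
| Ka/Ks ratio of duplicates | 0.2 | purifying selection typical of conserved families |
| subfamily founder domains | members diverge from a founder at Ks 0.3, Ka/Ks 0.5 | gives subfamilies a recoverable sequence signal so tree clades can be checked against HMM labels |
| expression | NB counts, lognormal base means, 4 samples/group, planted log2 FC 2, dispersion 0.05, 40 DE genes | a conventional small two-group design |

The published study gives no noise model for any of its inputs, so every
noise knob above is a conservative package choice, set once.

Deliberate non-realism: HMMER score distributions, read-level sequencing
noise, probe-to-gene mapping, UTRs, overlapping genes, alternative
transcripts (the readers keep the longest-CDS transcript, matching the
one-model-per-gene convention), and real chromosome lengths are all out of
scope. Passing tests therefore demonstrate that the *algorithms* recover
planted structure under controlled conditions — they do not certify
performance on the messiness of real annotations.

## Problem sizes in the tests

The test and acceptance runs use: the full codon-pair space (61 × 61) for
the NG86 oracle; 50 additive trees of 4–12 taxa for NJ; duplicate cohorts
of 200 + 200 pairs of 500 codons for epoch recovery; two-chromosome
genomes of 1000 genes each with 20 planted blocks (6–10 anchors) plus 5 %
decoy homology for collinearity; and 2000-gene count matrices for the
null and power profiles of the screen. These sizes were chosen as the
smallest at which the statistical assertions (≥ 90 % epoch recovery,
precision = recall = 1, ≤ 2 % null retention, ≥ 95 % power) are stable
across seeds.

## Known limitations

* Subfamily assignment consumes scores; it cannot rescue a gene whose
  score table is missing (such genes stay unclassified).
* A gene scored by both Pkinase and Pkinase_Tyr is typical if either
  model's hit passes both gates; published pipelines do not document a
  stricter rule.
* The collinearity chainer is O(m²) in matches per chromosome pair —
  ample for kinome-scale homology, not tuned for all-vs-all whole-genome
  runs.
* Ks saturation is reported, never extrapolated; epochs beyond Ks 3 are
  `unassigned`.
* The Welch-test screen is less powerful than moderated-variance methods
  at very small n; with the default simulated designs this costs nothing
  measurable, but on real 2-vs-2 designs a practitioner should prefer
  limma/DESeq2 and feed the resulting tables into the same retention rule.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1))
report <- run_pipeline(cfg, out_dir = "kinomevo-out")
glance(report)
autoplot(report$ks_profile)
autoplot(report$de)
```
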