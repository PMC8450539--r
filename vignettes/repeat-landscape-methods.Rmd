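---
title: "Methods: desk-scale comparative repeat landscape profiling"
author: "skimrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale comparative repeat landscape profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimrep)
```

## The scientific problem

Two congeneric plants can differ nearly twofold in genome size while
sharing a chromosome number. In the motivating case — *Heloniopsis
umbellata* (1C = 4,680 Mb) versus *H. koreana* (1C = 2,480 Mb), both
2n = 34 — the explanation must lie in repetitive DNA: the differential
amplification and deletion of LTR retrotransposons (Ty1/copia and
Ty3/gypsy lineages), DNA transposons, and tandem satellites. The standard
way to measure this without assembling either genome is *genome
skimming*: sequence a fraction of a percent of each genome with short
paired-end reads, cluster the reads by sequence similarity so that each
high-copy repeat family collapses into one read cluster, and read each
family's *genome proportion* (GP) directly off the cluster sizes. Equal
GP in two genomes of unequal size means proportionally more copies in the
larger genome; GP differences locate the families that drove the size
change.

`skimrep` implements that full chain at desk scale — simulator,
preprocessing, graph clustering, annotation, quantification, solo-LTR
(Rsf) estimation and Brownian-motion ancestral genome-size
reconstruction — so every stage can be exercised and verified against a
known synthetic truth on one CPU in minutes.

## What the simulator emulates (and what it does not)

`build_genome()` places mutated copies of repeat-family templates at
uniform non-overlapping positions on a random background. Templates have
real structure where the downstream statistics need it: LTR elements are
LTR–internal–LTR with identical LTRs before mutation (so solo-LTRs and
junction tags behave correctly), satellites are tandem monomer arrays,
and other families are single segments. Divergence is substitutions only
(no indels), which keeps identity thresholds analytically predictable;
per-copy divergence defaults to 2%, so two copies of one family sit
around 96% identity — comfortably inside the 90% clustering threshold but
far from any other family.

Everything is miniature, roughly 1/2500 of the real system: genomes of
1.0 and 1.9 Mb instead of 2,480 and 4,680 Mb, elements of 200–300 b
instead of 5–10 kb, read samples of a few hundred instead of a few
hundred thousand. The scaling is deliberate and consistent: what matters
for the statistics is reads *per family per template length*, and the
miniature keeps that in the regime where clusters form. The simulator
does **not** model insertion-age distributions, nested insertions,
indels, GC bias or methylation; passing tests therefore demonstrate that
the algorithms are correct and calibrated on clean structured data, not
that real *Heloniopsis* reads would yield these exact numbers.

Reads are 100 nt paired-end (insert 300 b in the demo configuration;
500 b default elsewhere, matching typical shotgun libraries), with
per-base substitution errors (0.5%) and a two-state quality model
(Q38/Q12, low-quality bases at 0.1% per base) — just enough structure to
exercise a full-length Phred-20 filter. Pair provenance is recorded as
the majority-overlap family of the *fragment*; ties are `"ambiguous"`.
Fragment-level provenance is coarse at element boundaries, which is why
recovery tests that need read-level truth re-derive it from read content.

## Preprocessing

- **Quality filter.** "Quality 20 over the full length" is read in its
  strictest sense: a pair is kept only if *every* base of both mates is
  ≥ Q20 (a mean-quality mode is available). The filter is idempotent and
  never alters retained reads.
- **Organelle removal.** Reads are matched against the organelle
  reference by seeded local alignment (shared canonical 13-mers, then
  `pairwiseAlignment`); a pair is removed when either mate matches at
  ≥ 90% identity over ≥ 80% of the read. The synthetic organelle is a
  random sequence — adequate because the test criterion is operational
  (spiked reads removed, nuclear reads kept), not biological.
- **Down-sampling.** `gp_read_budget(gp, 1C, L) = round(gp * 1C / L)`
  reads represent proportion `gp` of a genome; sampling keeps mates
  together and rounds odd budgets down to an even read count. At the
  study's scale this gives 372,000 reads for 2,480 Mb at 1.5% — the
  published pipeline reports slightly different sampled counts, which do
  not follow from the stated formula and are carried only as context in
  `heloniopsis_context()`.

## Graph clustering

Reads are vertices; edges are strand-aware local-alignment hits at ≥ 90%
identity (matches / aligned columns, N never matches) over ≥ 55% of the
shorter read. Scoring is +1/−2 with gap open 4 / extend 2: mismatches are
penalized hard enough that maximal local alignments do not drift through
unrelated flanks, which keeps the 55% span threshold meaningful.
Clusters are connected components; components below
`max(2, ceiling(0.0001 × reads))` fall into the low/single-copy pool.
Community detection is deliberately *not* used — at these scales
connected components match the brute-force all-pairs oracle exactly.
The candidate prefilter (pairs sharing ≥ 1 canonical 9-mer) is
*certified lossless* at the default thresholds by a pigeonhole argument:
a qualifying hit spans ≥ 55 columns of which at most 10% mismatch, so at
least 50 matching columns fall in at most 6 runs and the longest exact
run has ≥ 9 columns. (A longer-seed filter — e.g. two shared 13-mers —
is faster but provably not lossless; it missed a genuine 56-column, 91%
edge on the demo fixture.) The test suite additionally verifies
partition identity against brute force.
Determinism: reads are canonically ordered before labelling, and cluster
ids are assigned by size (ties by smallest read id), so `CL1` is always
the largest cluster and input order is irrelevant.

Superclusters join clusters connected by ≥ 5 read pairs (mate 1 in one,
mate 2 in the other) — the threshold is a package default, chosen to
require repeated mate evidence while remaining reachable at desk-scale
read counts.

Comparative runs simply pool the per-species read sets (distinct
four-letter prefixes required) and run the identical algorithm; species
prefixes provide per-cluster per-species counts and sharing flags.

## Annotation

Clusters are classified against a packaged mini-reference: one exemplar
per simulator template plus random decoy lineages, with the lineage label
carried in the FASTA description (`lineage=...`). A read hits a lineage
at ≥ 80% identity over ≥ 55% of the read; the winning lineage is the one
hitting the largest read fraction (support), with exact ties broken
toward the lexicographically smaller label (determinism over nuance);
support < 0.10 leaves the cluster `"unclassified"`. Searches are
nucleotide-only: the mini-reference derives from the simulator's own
nucleotide templates, so a translated-frame search would add nothing
here; with a real protein-domain reference it would be the natural
extension. Tandem satellites are detected on the cluster consensus as
the smallest period `p ≤ 50` whose shift-by-`p` self-identity is ≥ 80%
over ≥ 2 monomers; a detected monomer overrides the mobile-element label.
The consensus itself is a majority vote of members overlaid on the
cluster's most-connected read (substitution-only divergence makes the
overlays gapless).

## Quantification

GP of a cluster for species *s* is `100 × reads_s / analyzed_s`;
abundance in Mb is `gp/100 × 1C`. Tables carry full precision (the
per-species Mb columns sum to the 1C-value exactly); rounding is left to
display. The comparative table reports per-cluster log2 GP ratios —
zero means equal genome proportion, the only monotone transform
consistent with that convention — and flags shared clusters.

The scatter of per-cluster read counts (species B against species A,
satellites excluded) has expected slope equal to the genome-size ratio
when both species are sampled at equal GP. Two estimator notes, both
consequences of desk-scale counts:

- Plain least squares on counts of this size is *attenuated* toward zero
  because the x-coordinate is itself noisy (classic errors-in-variables;
  measured ≈ 1.5 against a true ratio of 1.9 on the demo fixture). The
  default `scatter_slope()` therefore uses the count-weighted
  through-origin fit `Σy/Σx` — the weighted-least-squares solution with
  Poisson-appropriate 1/x weights — which is unbiased for the ratio. At
  full scale (clusters of thousands of reads) the estimators coincide.
- A single desk-scale sample holds only `gp_read_budget(0.015, 1C)` ≈
  150–285 reads, so one draw's binomial standard error on a 10% family
  is ≈ 2.5 percentage points. The recovery benchmark
  (`gp_recovery_benchmark()`) therefore averages 30 seeded replicates
  (and pools counts for the slope): it measures the estimator, not one
  draw's luck. Measured on the demo fixture: every lineage × species GP
  within ≈ 0.4 pp of truth; slope within ≈ 5% of 1.9.

Per-lineage regressions (`lineage_regressions()`) regress species-B
cluster GP on species-A cluster GP within each lineage and for composite
groups, including the with/without-satellite contrast — the design is a
declared interpretation, since which variables entered the published
regressions is not derivable from their description. OLS is closed-form
with a t-distributed slope test, and is checked against `stats::lm` as an
independent oracle.

## Solo-LTR quantification (Rsf)

Unequal recombination between the two LTRs of an element deletes the
internal region and one LTR, leaving a solo-LTR. Reads alone can see
this: the last 30 nt of the LTR (`ltr3_tag`) occur at *every* LTR end
(two per intact element, one per solo), while the 60-nt junction
(`ltr3_tag + utr5_tag`) occurs only in intact elements. The cascade
counts `Lx` = reads containing the LTR-3' tag (≤ 2 mismatches, either
strand) and `LU ⊆ Lx` = reads that continue across the junction;
`Rsf = (Lx − LU)/LU` grows with the solo:intact ratio.

One counting decision matters: requiring a junction read to *fully*
contain the 60-nt combined tag would make a genome of only intact
elements score Rsf ≈ 2.5 at 100-nt reads (position counting:
2×71 LTR-end placements vs 41 full-containment placements per element),
which contradicts the statistic's intent that intact-only genomes sit
near 1 (the 3' LTR being the only Lx-only source). `rsf_count()`
therefore requires the read to contain the LTR-3' tag plus at least
`min_junction_overhang = 10` bases of 5'-UTR (a minimal credible local
hit), giving an intact-only expectation of ≈ 1.33; setting the overhang
to 30 recovers strict containment. `rsf_expected()` computes the exact
position-counting expectation under the same rule, and the grid
benchmark verifies monotonicity in the solo:intact ratio and agreement
within 20% at 0.1× coverage. `LU = 0` yields an explicitly undefined
result rather than a division by zero.

## Ancestral genome size under Brownian motion

Given a rooted tree with branch lengths and tip 1C-values, the ML
ancestral states under BM minimize
`Σ_branches (x_parent − x_child)² / branch_length` — a weighted-Laplacian
linear system solved with tips fixed. This coincides with the GLS/BLUE
and with the re-rooting ("each node as the root of its re-rooted tree")
formulation; the rate estimate is ML, `σ² = Q/n` with `Q` the minimized
quadratic form and `n` the tip count, and node intervals use the
conditional-on-tips variances of the re-rooting form (the two classical
implementations differ only in interval conventions, so ours are
labelled). Estimates depend only on relative branch lengths; polytomies
are resolved with epsilon branches (1e-8 of tree height), legitimate
because the solution is continuous in branch lengths. Tests check the
solver against numerical likelihood maximization (1e-6), against
`ape::ace` / `phytools::fastAnc`, and for root recovery over 200
simulated replicates.

The packaged Newick tree and tip table are **synthetic demonstrations**
(only the two focal 1C-values are published figures); the published
ancestral value of 3,022 Mb depends on an external genus phylogeny and is
used here only as an input to delta arithmetic
(`branch_deltas(c(umbellata = 4680, koreana = 2480), 3022)` →
+1,658 / −542 Mb).

## What is, and is not, reproducible here

Printed arithmetic — the ~477 Mb satellite abundance (10.20% of
4,680 Mb), the c. 1.90 genome-size ratio, the ±1,658/−542 Mb deltas, the
1,015,000-read comparative pool, the >6× satellite contrast — is
recomputed exactly from the published context inputs. The full
per-lineage GP table, the regression coefficients, the Rsf values
(11.41/4.22/7.94/3.88) and the 3,022 Mb reconstruction themselves
require the original sequencing runs (SRA SRR15208642/SRR15208643) and
the external phylogeny; `heloniopsis_context()$requires_original_data`
flags them, and the seeded simulation benchmarks above stand in as the
verification that the *methods* behave correctly.

## Numerical and design choices, collected

- Alignment scoring +1/−2, gaps 4/2; identity = matches / aligned
  columns; a 1e-9 epsilon on fractional span thresholds guards exact
  boundary cases (55 columns at 55% of 100) against floating-point
  representation.
- k-mer prefilter: canonical 9-mers, ≥ 1 shared — lossless by
  construction at 90%/55% and verified partition-identical to brute
  force on the fixture scale.
- Cluster floor of 2 reads (a cluster is a connected group by
  definition) in addition to the 0.01% threshold.
- Tag matching ≤ 2 mismatches per 30-nt tag (≈ 93% identity), full
  containment required — no partial-tag credit for the tags themselves.
- All randomness flows through explicit integer seeds; identical seeds
  give byte-identical FASTQ and TSV artifacts (provenance headers carry
  version, seed and config hash, never timestamps).
- Demo problem sizes: 1.0/1.9 Mb genomes, 0.03× simulated coverage,
  down-sampling to 0.015, 30-replicate benchmarks — chosen as the
  package's desk-scale study conditions.

## Known limitations

Fragment-majority provenance is coarse at element boundaries; the
simulator has no indels, so the aligner's gap handling is exercised only
lightly; the mini-reference cannot measure annotation performance against
a real curated repeat database; connected-component clustering would
over-merge on genuinely chimeric repeat libraries that the simulator does
not generate; and the demo tree is a synthetic stand-in, so ancestral
reconstructions on it demonstrate the machinery, not *Heloniopsis*
history.
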