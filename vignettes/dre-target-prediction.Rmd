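---
title: "Predicting distal regulatory element targets from Hi-C and phylogenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting distal regulatory element targets from Hi-C and phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dretarget)
```

## The problem

Distal regulatory elements (DREs) — enhancers, repressors, insulators — act on
genes hundreds of kilobases away or on other chromosomes, so proximity alone
cannot identify their targets. Hi-C captures chromatin contacts genome-wide:
when one end of a contact falls in a DRE and the other in a gene, the gene is
a candidate target. But Hi-C is noisy and also records random collisions, so
raw contact counts alone produce many false pairs.

`dretarget` combines two orthogonal signals:

1. **Hi-C read counts.** A DRE here is a DNase I hypersensitive site (DHS)
   that overlaps no gene body and lies more than 2 kb from every
   transcription start site. Contacts are counted between the DRE peak and
   the *intragenic DHS* of each gene (a ±1000 bp window around each DHS
   center inside the gene body), because reads concentrate in open chromatin
   inside genes rather than at promoters. Per gene the count is the
   **maximum** over its intragenic DHS, not the sum — the sum grows with the
   number of DHS and therefore with gene length, while the maximum tracks the
   strongest single anchor.
2. **Phylogenetic correlation.** If a DRE regulates a gene through a chromatin
   loop, losing either partner during evolution removes the constraint on the
   other, so presence/absence patterns of true pairs across related genomes
   should correlate. Each element gets a profile over a panel of species
   (45 by default): alignment-block boundaries partition the genome into bins
   with binary per-species indicators, and a region's profile is the
   bin-length-weighted average over the region. The evidence score for a pair
   is the Pearson correlation (PCC) of the two profiles.

Only *distal* pairs — different chromosomes, or a gap above 500 kb — are
predicted. Below 500 kb the profile correlation is dominated by shared local
genomic context (neighbouring regions rise and fall together in alignments),
so a high PCC there is not regulatory evidence; beyond 500 kb that bias is
negligible and the contact background is treated as flat.

## The decision rule

Within one cell line with two replicates, a distal candidate pair (at least
one supporting read somewhere) is accepted when its PCC exceeds the
correlation cutoff (default 0.8) and either

* **count rule** — some replicate has strictly more than `read_cutoff`
  (default 2) reads, or
* **rescue rule** — every replicate of the cell line has at least one read:
  a single read is weak evidence, but its independent recurrence in a second
  replicate is not.

Predictions are the union over cell lines, with provenance recorded. The
operating point is chosen from a **repeatability grid**: for each cutoff pair
(PCC 0.7/0.8/0.9 × reads 1/2/3) the replicate with fewer total reads defines
the reference set of cutoff-passing pairs, and repeatability is the fraction
confirmed by at least one read in the other replicate. The count rule is
applied per replicate ("strictly greater than 2" means at least 3 reads in
one replicate, never the pooled sum) so that the rescue rule remains the only
cross-replicate aggregation; pooling would double-count that evidence.

Geometric conventions (the literature states thresholds, not geometry, so the
package fixes them explicitly): every interface uses 0-based half-open
coordinates; DRE–gene distance is the minimum gap between the DRE interval
and the gene body; TSS distance is the gap between the TSS point and the DHS
interval; a DHS overlapping several gene bodies is intragenic for each host.
These are the most permissive consistent readings, and each is a single
parameter or helper if a different convention is needed.

## Downstream analyses

* **DRE clusters.** DREs are chained single-linkage with a 5 kb gap
  threshold; a cluster's target set is the union of its members' predicted
  targets. Single linkage is deliberate: regulatory archipelagos are long
  runs of nearby elements, and chaining reproduces many-member clusters that
  a fixed-window rule would split.
* **Functional coherence.** For clusters with ≥ 3 targets, the mean pairwise
  Resnik similarity (information content of the best common GO ancestor,
  biological process only, IEA evidence removed, terms with < 3 annotated
  genes dropped) or the mean pairwise expression correlation across tissues
  is compared against controls that redraw equal-sized random gene sets from
  the universe where the metric is defined. The reported p-value is the
  resampling probability that a control replicate's
  proportion-above-cutoff curve, averaged over cutoffs, reaches the observed
  one — a directly interpretable permutation-style tail probability, chosen
  because the analysis compares whole curves rather than a single statistic.
  An optional filter removes same-chromosome gene pairs closer than 500 kb
  (from observed *and* control sets alike) to show coherence is not an
  artefact of genomic neighbourhood.
* **Marker-combination enrichment.** The observed fraction of predicted
  pairs carrying a DRE marker (e.g. H3K4me1) and a gene marker (e.g.
  H3K36me3 at the gene body) is compared with the product of the marginal
  frequencies over the unique DREs and unique genes of the prediction set.
  The chi-square statistic is the closed form `sum((O - E)^2 / E)` over the
  four marker cells with 1 df and no continuity correction; marginals are
  computed within the analysed set (not genome-wide) because the question is
  whether the *pairing* is non-random, not whether predicted elements are
  unusual.
* **Knockout enrichment.** Differential expression (p < 0.05 and fold change
  > 1.5 or < 0.7) among predicted targets whose DRE is bound by a TF versus
  all predicted targets, two-sided Fisher's exact test. Sidedness is a
  convention choice; two-sided is the conservative default.

## The synthetic-data generator

All tests run on generated data with planted truth; `simulate_dataset()` is a
first-class, tested module. Its defaults are the study conditions the
package's claims are evaluated under:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 45 | species panel length |
| `n_chromosomes`, `chrom_length` | 4 × 3 Mb | enough territory for > 500 kb geometry |
| `n_genes`, `n_dhs` | 60, 420 | gene models and DHS (intragenic + promoter + DRE) |
| `fraction_true_pairs` | 0.25 | DREs given a planted distal target |
| `rho_true` | 0.9 | presence/absence correlation of true pairs |
| `lambda_signal`, `lambda_noise` | 5, 0.05 | Poisson contact means per pair and dataset |
| `n_cell_lines`, `n_replicates` | 2, 2 | dataset roster |
| `n_tissues` | 79 | expression matrix width |
| `go_modules` | 8 | functional modules (GO subtree + shared expression) |

Species-specific retention probabilities are drawn from a U-shaped
Beta(0.5, 0.5): some species retain almost everything, some almost nothing,
which gives *all* profile pairs a positive baseline correlation — the
synthetic analogue of shared phylogenetic structure, and the reason a high
PCC cutoff is needed at all. A true pair's DRE vector is its target's vector
with independent symmetric bit flips at rate `(1 - rho_true)/2`, which makes
the realised correlation equal `rho_true` exactly in expectation (the flips
replace the baseline structure rather than adding to it). A shared-latent
flip model was chosen over a birth–death process on a real phylogeny because
the method consumes only the correlation structure; tree topology would add
machinery without changing what is tested. Contacts are Poisson:
`lambda_signal` per true pair and dataset between the DRE and a random
intragenic DHS of the target, `lambda_noise` on every random (DRE,
intragenic-DHS) combination, uniform in space. Background contacts ignore
genomic-distance decay deliberately: predictions are restricted to > 500 kb,
where a flat background is the working assumption of the distance filter
itself.

Planted DREs come in spatial groups (3 within ≤ 5 kb gaps) whose targets are
distinct genes of one module, so predicted clusters have coherent target
sets; module genes share a GO subtree and a latent tissue-expression profile
(noise sd 0.5, giving within-module expression correlation around 0.8).
Marker peaks are assigned independently with probability 0.3 — the
enrichment statistics are therefore *calibrated* (ratio ≈ 1) on synthetic
data, not enriched; their correctness is tested, not their effect size.

What the generator does **not** emulate: restriction-fragment structure and
distance decay of real Hi-C, cell-type-specific DHS usage, realistic GO DAG
depth, alignment gaps inside elements. Passing tests therefore demonstrate
that the algorithms implement their definitions and that the statistical
machinery is calibrated — not that the biological effect sizes of any real
dataset will be reproduced.

## Numerical choices and degenerate inputs

* The profile denominator is the **full region length**: unaligned sequence
  has no homolog in any species, so it contributes 0 to every species rather
  than being excluded. This keeps profiles comparable across regions;
  `denominator = "aligned"` switches to overlapped-bin length.
* A zero-variance profile yields an **NA** correlation; such pairs are
  excluded from prediction rather than coerced to 0 — no correlation
  evidence exists either way. Undefined repeatability cells (empty reference
  set) are NA, never 0 or 1.
* Ties in the per-gene maximum rule are broken by genomic position, then DHS
  id, so outputs are deterministic.
* Clusters are labelled in genomic sort order; writers sort by locus and id,
  so equal inputs give byte-identical files.
* `build_bins()` emits a bin only where at least one species aligns;
  multiple overlapping blocks of one species still give indicator 1.
* Empty contact lists, targets without background reads, unannotated genes
  and empty prediction sets raise errors or are skipped with a message, as
  documented per function.

## Problem sizes

The test suite checks the oracle equivalences at the sizes it states: 200
random regions against a per-base coverage oracle, 1,000 contacts × 50 DREs
× 20 genes against a quadratic counting oracle, 10,000 pair rows and 500
DREs against brute-force rule evaluation, exhaustive Fisher enumeration for
all tables with n ≤ 30 plus 200 random tables with margins ≤ 30, and 1,000
null simulations for chi-square calibration. The end-to-end recovery runs use
the default generator configuration above (~5,500 candidate pairs, ~70 true
pairs). These sizes were chosen so the full suite exercises every code path
at scales where the oracles are exact.

## Known limitations

* Intragenic DHS are only gene-side anchors; a DHS inside one gene acting as
  a DRE for another is out of scope, as are pairs within 500 kb.
* Phylogenetic correlation is insensitive to recently evolved relationships
  (no time to diverge) and can be inflated by nearby genomic context.
* The GO corpus handles `is_a` edges only; `part_of` and cross-namespace
  relations are ignored.
* Hi-C input is pre-mapped BEDPE; mapping, deduplication and matrix
  normalisation are upstream concerns, and counts are raw record counts.
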