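---
title: "Methods: methylation quantification and classification from MSRE + smMIP sequencing"
author: "msremip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation quantification and classification from MSRE + smMIP sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msremip)
```

## The assay model

The assay quantifies DNA methylation without bisulfite conversion by
combining two molecular steps:

1. **MSRE digestion.** Four methylation-sensitive restriction enzymes —
   HpaII (C^CGG), HpyCH4IV (A^CGT), AciI (C^CGC) and HinP1I (G^CGC) —
   digest the sample together. Each recognition motif carries a CpG in
   the middle; methylation of that CpG blocks cleavage. After the
   digest, a target fragment survives only if every recognition site it
   contains was methylated (or escaped digestion).
2. **smMIP capture.** Single-molecule molecular inversion probes
   hybridize two ~20 nt arms around a 50 nt insert, are gap-filled,
   ligated into circles, and sequenced. Each probe copy carries a 10 nt
   single-molecule tag (5 nt per side) so that PCR duplicates can be
   collapsed and counts refer to unique captured molecules.

Three probe classes make the count data interpretable:

* **CpG smMIPs** target regions containing at least one recognition
  site; their deduplicated count is proportional to the abundance of
  fully methylated fragments.
* **Reference smMIPs** target regions with no recognition site, or no
  CpG at all; they are never cleaved, so their summed count measures the
  effective DNA input. The *normalized count* of CpG smMIP $i$ in sample
  $A$ is
  $$\tilde c_{iA} = \frac{c_{iA}}{\sum_{r \in \text{ref}} c_{rA}},$$
  which removes the input-amount dependence (it is invariant to scaling
  all counts of a sample).
* **Lambda smMIPs** target spiked-in, never-methylated phage DNA. Any
  surviving lambda CpG-target signal measures incomplete digestion. The
  per-sample non-digestion percentage is the sample's lambda
  CpG/reference count ratio divided by the mean of the same ratio over
  undigested control aliquots, times 100. Samples are failed when this
  exceeds 5% (strictly: the rule removes samples that *exceed* the
  threshold, so exactly 5.0% passes), or when their total count is below
  5,000 (inclusive minimum).

## Classifier construction

Tumor-versus-normal classification uses an ensemble of univariate
linear discriminant models, one per CpG smMIP, built on normalized
counts of digested samples (blood counts as non-tumor):

1. **Cross-validated screening.** Five-fold cross-validation, stratified
   jointly on tissue and condition so tumor types are proportionally
   represented per fold. Per smMIP and fold, a one-dimensional
   equal-variance Gaussian discriminant (class means, pooled
   within-class variance with an $n-2$ denominator, priors equal to
   class proportions) is fitted on the training folds and the held-out
   samples are scored; the fold AUC is the Mann–Whitney pair statistic
   (ties count one half). The cvAUC is the mean of the fold AUCs; folds
   whose held-out set is single-class are skipped and recorded.
2. **Filters.** smMIPs are kept when the cvAUC is at least 0.8 and the
   cumulative count over undigested controls is at least 1,000 (both
   thresholds inclusive; "below 0.8" is removed, so 0.8 survives).
   The efficiency filter needs the undigested controls because capture
   efficiency must be judged where digestion plays no role.
3. **Double-tile resolution.** CpG sites are tiled by one smMIP per
   strand; the tile with the higher cvAUC is kept (ties: higher
   cumulative undigested count, then lexicographic id).
4. **Per-model cutoffs.** Each surviving model is refitted on the full
   training set and given a score cutoff minimizing FP + FN over the
   midpoints of adjacent distinct scores (plus one candidate below the
   minimum and one above the maximum). Ties resolve to the *largest*
   cutoff, favoring specificity. Cutoffs are refitted on the full
   training set after CV-based selection; the alternative (choosing
   them on cross-validated scores) was left aside because the final
   model is also refitted on all training data.
5. **Ensemble vote.** A sample is called tumor when at least $k$ single
   models vote tumor; $k$ maximizes training accuracy, ties resolving to
   the smallest $k$ (favoring sensitivity).

Normalized rather than raw counts feed the LDA because the raw scale
depends on DNA input, which normalization exists to remove. The
normalization denominator is the full reference smMIP set surviving the
dead-probe filter; restricting it to the "efficient" (≥ 1,000
cumulative-count) subset is possible via the `reference_ids` argument
but is not the default, since normalization logically precedes the
efficiency selection.

## Read processing

The synthetic read layout places, on read 1, a 5 nt molecule tag, the
ligation arm and the insert prefix; on read 2, the other 5 nt of the
tag, the extension arm and the reverse-complemented insert suffix; the
dual sample barcodes travel on two index reads. Processing is:

* **Demultiplexing** with at most one mismatch per barcode; a pair is
  assigned only when exactly one sample matches. Barcode designs are
  validated to be pairwise ≥ 3 mismatches apart, which makes ambiguous
  hits impossible; ambiguous hits are nonetheless unassigned, not
  best-matched.
* **Arm assignment** by dictionary lookup of the arm sequence (exact,
  then one mismatch) at read offsets 0–5. Both mates must agree on the
  smMIP and start within the 5-base positional margin (inclusive: an
  offset of 5 passes, 6 fails). Full-genome alignment is deliberately
  not used: the targets are known, and exact arm lookup against the
  panel is complete for this design.
* **Quality filtering**: a per-pair alignment quality (42, minus 14 per
  mismatched arm) must be strictly above 15, and the pair must be
  properly paired (both mates, same smMIP).
* **Deduplication** collapses exact (sample, smMIP, 10 nt tag) keys,
  keeping the first occurrence; tags containing N are discarded and
  tallied. No UMI-network error correction is attempted — with 5' tags
  of 10 nt and desk-scale depth, exact-key collapse loses little, and
  the extension point is documented.

## The synthetic-data generator

`simulate_counts()` draws, per sample and smMIP, a Binomial number of
unique captured molecules with success probability
`capture_efficiency × survival`, where survival through the digest is
$m + (1-m)\,\varepsilon_{nd}$ for a CpG target with methylated fraction
$m$, $\varepsilon_{nd}$ for lambda CpG targets ($m = 0$ by
construction), and 1 for reference targets and for every target of an
undigested aliquot. Defaults: 500 molecules per target, capture
efficiency 0.3 (≈ 150 expected molecules per probe), non-digestion rate
$\varepsilon_{nd} = 0.013$ (the level the lambda control estimates in
practice), PCR duplication geometric with mean 3, substitution error
rate 0.001 per base.

The methylation model is hierarchical. Each CpG target draws one mean
level per condition — tumor uniform on [0.5, 0.9] and normal uniform on
[0.05, 0.3], mirroring the panel selection rule that targets be
hypermethylated (≥ 0.5) in tumors and hypomethylated (≤ 0.3) in normal
tissue and blood, with blood at half the normal mean as the
lowest-methylation condition — and every sample then draws its level
from a Beta distribution around the target mean with concentration 12
(per-sample SD ≈ 0.13 at mid-range means). A flat per-condition model
matching only the marginal moments 0.50 ± 0.24 versus 0.30 ± 0.20 would
describe the *worst* marker (the smallest effect size used in the power
calculation) and would leave almost every probe below the 0.8 cvAUC
filter; per-target means are what make a panel a panel.

`simulate_reads()` reproduces the counts of `simulate_counts()` under
the same seed and then emits reads per molecule. Single-molecule tags
are drawn *without replacement* within a (sample, smMIP) cell: tags are
modeled collision-free, so deduplication recovers molecule counts
exactly and the read-level round trip is an identity at zero error
rate. `simulate_spikein_series()` mixes per-target tumor and background
levels linearly, $m = f\,m_T + (1-f)\,m_B$, emulating spike-in dilution
experiments.

What the generator does **not** emulate: fragment-length distributions
and cfDNA fragmentation, enzyme-specific digestion biases, base-quality
profiles and indels, empty-capture ("empty smMIP") events, UMI
collisions and sequencing of the 30 nt backbone. Passing tests
therefore demonstrate the correctness of the computational procedure
under the stated generative model, not assay performance on real
libraries.

## Characterization statistics

* **Repeatability**: Pearson correlation and Bland–Altman bias ±
  1.96 SD limits on paired normalized counts of two runs.
* **Mann–Whitney U** (two-sided) with midrank ties; the p-value is an
  exact enumeration over group assignments up to combined $n = 10$
  (ties included) and a continuity- and tie-corrected normal
  approximation beyond. $U/(n_1 n_2)$ equals the AUC of the same data.
* **Spike-in calibration**: least squares of measured normalized count
  on expected percentage, inverted classically
  ($\hat p = (y - b)/a$).
* **Limits of blank/detection** (Armbruster):
  $\mathrm{LOB} = \bar x_{blank} + 1.645\, s_{blank}$,
  $\mathrm{LOD} = \mathrm{LOB} + 1.645\, s_{low}$, with sample SDs
  ($n-1$) and the one-sided 95th-percentile constant 1.645; the
  methylation level at the LOD comes through the calibration line.
* **Power**: two-sided unequal-variance normal approximation at
  Bonferroni-corrected per-test level,
  $\Phi(\delta - z_{1-\alpha/2}) + \Phi(-\delta - z_{1-\alpha/2})$ with
  $\delta = |\mu_1-\mu_2| / \sqrt{s_1^2/n_1 + s_2^2/n_2}$. The normal
  rather than noncentral-t form is used because the supported claims
  are lower bounds and the approximation error at $n \ge 67$ is far
  below them.
* **Digestion efficiency from qPCR**: undigested fraction
  $2^{-\Delta Ct}$ with $\Delta Ct = Ct_{dig} - Ct_{undig}$.

## Numerical and design choices

* Coordinates are 0-based, half-open throughout.
* Motif scanning reports forward-strand occurrences of each motif plus
  forward-strand occurrences of the reverse complement of the one
  non-palindromic motif (CCGC → GCGG, minus strand); an enzyme cuts
  double-stranded DNA regardless of strand. CpG coverage counts a CpG
  as covered when it is the **central** CG of an occurrence — the
  methylation-sensing position — which also makes the statistic
  invariant under reverse complementation (an "anywhere inside the
  occurrence" rule is not, when a second CG overlaps a motif edge).
* Target selection applies the tumor threshold per tumor type (every
  type's mean ≥ 0.5), with a `mode = "pooled"` switch; the per-type
  reading is stricter and matches the multi-type intent of the panel.
* Threshold conventions: depth ≥ 5,000 inclusive; digestion failure
  > 5% strict; cvAUC ≥ 0.8 and cumulative undigested count ≥ 1,000
  inclusive; positional margin ≤ 5 inclusive; pair quality > 15 strict.
* Degenerate one-dimensional LDA (zero pooled variance) is flagged and
  scores ±∞ by side of the class-mean midpoint, 0 at the midpoint.
* The fold seed is the only stochastic element of training; all tie
  breaks are deterministic and stated per operation.
* The undigested-control mean for the digestion statistic uses the
  controls that pass the depth filter.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data built at run time: a 48-target/68-smMIP panel; a 12-sample
fixture (two undigested controls, two blood) at 1,100 molecules per
target, chosen so every sample clears the 5,000-count threshold and
every probe can clear the 1,000 cumulative-undigested-count filter with
two controls; digestion-recovery checks at $10^5$ molecules per target;
and five simulated train/held-out cohorts of 128 training plus 40
held-out samples for end-to-end classification. These sizes are the
package's reference study conditions for a desk-scale reproduction.

## Known limitations

* Arm assignment assumes the synthetic read layout (tag and arm at
  fixed offsets); real instrument run folders and arbitrary library
  layouts are out of scope.
* The classifier is binary; tissue-of-origin prediction and
  multivariate or regularized models are out of scope.
* No SNP/repeat masking or probe thermodynamics: synthetic panels make
  arms unique by construction rather than by genomic design.
* The exact-key UMI collapse slightly overcounts molecules under
  sequencing errors in the tag (an error forges a new molecule); the
  simulator's error model exercises this path, and the effect is
  bounded by the tag error rate.
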