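---
title: "Methods: depth-based sexing, Wolbachia strain typing and COI haplotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-based sexing, Wolbachia strain typing and COI haplotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radwolb)
```

## Scope and motivation

Field surveys of *Aedes albopictus* routinely produce three kinds of data
that this package turns into biology: double-digest RAD sequencing
(ddRAD) read depths, which carry a sex signal because depth at
pseudosex-linked regions differs between males and females; sequencing
observations at sites that distinguish the two natural *Wolbachia*
endosymbionts of this mosquito (wAlbA and wAlbB), which allow strain
typing of single wAlbB infections versus wAlbA+wAlbB superinfections;
and qPCR crossing points, which yield infection calls and relative
symbiont densities. A fourth component handles mitochondrial COI
barcoding: haplotype collapsing, Kimura 2-parameter (K2P) distances,
neighbour-joining trees with bootstrap support, and haplotype networks.

Every stage accepts and returns plain tables (tibbles), so pipelines
compose with the usual tidyverse verbs, and every stage has a seeded
synthetic generator that emulates its input. The generators are
first-class, tested code: they let the complete chain be exercised, and
its statistical behaviour measured, without any sequencing data.

## Depth-based sex classification

**Normalization.** Raw per-feature depths are converted to log2 relative
depths, `log2((d + 0.5) / s)`, where the per-sample scale `s` is either
the median depth over negative-control ddRAD tags (tags chosen to carry
no sex signal) or the total library size. The +0.5 pseudo-depth keeps
zero counts finite. One consequence worth knowing: with the
pseudo-depth, rescaling a sample changes its normalized values by a
vanishingly small amount (of order `0.5/d`) rather than exactly zero;
at working depths this is far below the biological signal.

**Feature selection.** For every feature an ordinary least-squares model
`norm ~ sex + batch` is fit, with sex coded female = 0 / male = 1 so the
coefficient is the male depth shift in log2 units, and sequencing batch
as a nuisance factor (batches with a single sample are pooled). The sex
coefficient's t-test p-values are corrected across features by
Benjamini–Hochberg, with selection at q ≤ 0.05 by default (Bonferroni
available). BH controls the false discovery *rate*: with ~50 true
sex-linked features among 1,000 one should expect on the order of 5% of
the selections to be spurious, which downstream classification tolerates
easily.

**Label screening.** Morphological sexing of field material is
imperfect, so before training, samples are projected on the first
principal component of the standardized selected features and split by
k-means (k = 2) initialised deterministically at the two PC1 extremes —
the initialisation removes any seed sensitivity. Each cluster takes its
majority morphological label, and samples disagreeing with their
cluster's majority are removed; a tied majority aborts with a
diagnostic rather than guessing.

**Classifier.** A radial-basis support vector machine (cost 1, default
kernel width) with logistic (Platt-type) probability calibration, as is
standard for this task; the probability calibration's internal
cross-validation is seeded so training is reproducible. Two probability
thresholds matter downstream and are plain arguments: 0.7 for keeping
confidently sexed samples during semi-supervised refinement, and 0.6
for joint sex-and-strain reporting. A probability of exactly 0.5 is
called female with `confident = FALSE` — an explicit, documented tie
rule rather than an arbitrary one.

## Wolbachia strain classification

**Diagnostic sites.** Sites differing between the wAlbA and wAlbB
reference assemblies are found by tiling read-length windows (100 bp,
step 25 bp) along the wAlbA-like reference and matching each window
against the wAlbB-like reference at ≥ 95% identity. Only windows with
exactly one such match ("uniquely mapping") contribute; mismatched
columns covered by uniquely mapping windows, with a single consistent
alternate base, become diagnostic sites. Uniqueness is defined
combinatorially (exact substring matching with a mismatch budget)
rather than through an external aligner, which makes the rule
deterministic and testable: a substitution planted inside a duplicated
repeat is provably excluded.

**Score and model.** Per sample, wAlbA-supporting and wAlbB-supporting
observations at diagnostic sites are counted (observations matching
neither allele are dropped and logged); samples with fewer than 10
allelic observations are removed — "fewer than" is strict, a sample
with exactly 10 stays. The score is the Laplace-smoothed wAlbA
fraction, `(a + k) / (n + 2k)` with pseudocount k = 1 added to both
allele classes; the `+2k` denominator is the standard two-category
smoothing rule, keeps the score strictly inside (0, 1), and makes
`ln(score)` always finite (an observation-free sample scores exactly
0.5). Classification is univariate logistic regression of
superinfection on `ln(score)`, fit by Newton iterations to tolerance
1e-8, evaluated on a stratified 20% held-out split. Under perfect
separation the fit switches to a lightly ridge-penalized likelihood
(ridge 1e-3) and flags it.

The logistic form makes one bias explicit: as the training prior of
superinfection grows, the predicted probability for an uninformative
sample (score 0.5) approaches that prior, so in superinfection-heavy
data, low-coverage samples drift toward superinfection calls. This is a
property of the method worth remembering when interpreting results from
populations with different class ratios.

## qPCR processing and statistics

Crossing points come as three replicates per marker (host ITS2, wAlbA,
wAlbB). Replicates are averaged when at least two are present and their
spread is ≤ 1.0 cycles (the consistency rule; a single replicate is
used as-is, a larger spread flags the marker inconsistent); missing
amplification is `NA`, never `Cp = 0`. A strain is present when its
averaged Cp is ≤ 35 cycles (configurable); samples whose ITS2 marker
fails are excluded as failed species/DNA checks. Relative density is
`2^(Cp_host − Cp_target)`, oriented so more target DNA means higher
density; the direction is flippable for labs with the opposite
convention.

The statistics mirror standard field practice: superinfection incidence
is modelled by a binomial GLM with a sex × population interaction tested
by likelihood ratio (populations need more than 5 single-B/AB
individuals per sex to enter); per-population sex differences use
Pearson chi-square, replaced by Fisher's exact test when any expected
count is below 5; densities are log10-transformed (the base does not
affect F ratios, correlations or p-values) and analysed by two-way ANOVA
with Type II sums of squares, chosen because field data are unbalanced;
wAlbA–wAlbB density associations use Pearson correlation and
least-squares regression, computed only for strata with at least 10
individuals.

## COI haplotypes and phylogenetics

Alignment columns containing any gap, N or other ambiguity are removed
for all sequences before analysis. Identical sequences collapse into
haplotypes numbered H1, H2, … by first occurrence. K2P distances use the
closed form `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with P and Q the
transition and transversion proportions; a non-positive log argument
(saturation) is flagged `NA` rather than silently truncated.
Neighbour-joining is the Saitou–Nei algorithm (via ape); negative branch
lengths are clamped to zero and flagged. Bootstrap support resamples
alignment columns, rebuilds the NJ tree per replicate, and reports the
percentage of replicates containing each original bipartition; rare
saturated replicate distances are capped at 0.75 substitutions/site so
every replicate yields a tree.

The haplotype network is a minimum spanning network on Hamming
distances: a Kruskal construction that, within each distance class,
keeps *every* edge joining components that were separate when the class
was reached, so equally parsimonious alternative connections are
retained. This replaces the median-joining network with a 95%
statistical-parsimony connection limit used in the original analyses:
the parsimony-limit calculation is a substantial algorithm in itself and
out of scope here, while the spanning network preserves the analyses the
network supports (mutational steps between haplotypes, hub structure,
disconnection beyond a step cutoff via `max_steps`).

## Synthetic data: what it emulates, and what it does not

The generators encode the statistical structure each stage assumes,
with defaults set to the regimes used throughout the package's tests:

* **Depths**: negative binomial per sample × feature (the standard
  overdispersed model for sequencing depth; the data themselves carry
  no stated noise model), mean = base depth × sex ratio × batch ×
  library factor. Defaults: 40 + 40 samples, 1,000 regions of which 50
  sex-linked at male ratio 0.5, depth 100, dispersion 5, 2 batches.
  Batch and library effects are multiplicative log-normal with sd 0.2
  on the log scale — a moderate, realistic technical spread. A separate
  `region_seed` fixes *which* regions are sex-linked so independent
  cohorts can be drawn from the same simulated genome for train/test
  designs. Desk-scale defaults stay well below the tens of thousands of
  regions of a real genome; the per-feature models are identical at any
  width.
* **Allele counts**: binomial draws at an expected wAlbA fraction of
  0.3 for superinfected samples versus an error rate of 0.01 for
  single-B samples, ~100 observations per sample, 200 + 200 samples.
* **COI alignments**: haplotypes derive from a random root by a
  two-parameter substitution scheme (transition:transversion ratio 4);
  each non-root haplotype receives at least one substitution so
  haplotypes are distinct by construction — consequently a
  mutation rate of zero yields a single haplotype only when a single
  haplotype is requested. 623 bp, matching the trimmed COI fragment.
* **qPCR**: marker Cp = host Cp − log2(density) plus Gaussian replicate
  noise; absent strains never amplify. The generator adds one field
  beyond the minimal contract, a between-sample sd of log2 density
  (default 1), because without density variation the density ANOVA and
  association analyses would see degenerate inputs.

Passing tests on these generators demonstrate that the chain recovers
planted structure under its own assumptions — they do not demonstrate
robustness to what the generators omit: GC- or mappability-driven depth
trends along a genome, contamination between samples, index hopping,
qPCR efficiency differences between markers, recombination or
heteroplasmy in COI, or reference errors in the diagnostic-site
catalogue.

## Numerical and design choices

* Multiple testing: BH at α = 0.05 (Bonferroni available); q-values are
  monotone in p-value rank by construction.
* Pseudo-depth +0.5 before log2; pseudocount k = 1 with denominator
  `n + 2k`; both exposed as arguments.
* MCC with any zero factor under the root is defined as 0.
* Logistic fits: Newton, tolerance 1e-8, max 100 iterations; separation
  triggers ridge 1e-3 and a flag (both in the strain model and the
  incidence GLM, whose likelihood-ratio statistic is then computed from
  the penalized fits).
* Likelihood-ratio statistics are clamped at zero against round-off.
* NJ ties and negative branch lengths: ape's deterministic
  implementation; negatives clamped to 0 with a flag.
* Problem sizes in the test-suite simulations (10–20 seeds for the
  pipeline checks, 500 replicates for the type-I calibrations, 200-1000
  bootstrap replicates) were chosen as the smallest sizes at which the
  measured quantities are stable to well within the asserted
  tolerances.

## Known limitations

The sex classifier is binary and assumes the depth contrast of
pseudosex regions; it does not model intersex karyotypes or coverage
dropouts. The strain classifier deliberately excludes wAlbA-only and
uninfected classes — with too few such samples in realistic data a
two-class model is the honest choice, and novel wAlbA-only samples
would be misclassified as superinfected. Diagnostic-site discovery
assumes single-contig references and substitution-only divergence (no
indels). The spanning network is a topology-preserving substitute for
median-joining networks, not an implementation of statistical
parsimony.
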