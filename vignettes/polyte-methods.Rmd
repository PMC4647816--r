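---
title: "Methods: polyTE population genetics, admixture and marker-subset prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyTE population genetics, admixture and marker-subset prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyTE)
```

## The data and the model

Polymorphic transposable element (polyTE) loci are genomic sites where an
Alu, L1 or SVA insertion is present in some human genomes and absent in
others. Two properties make them unusually clean ancestry markers: a shared
insertion at the same site is essentially always identical by descent
(homoplasy-free), and the ancestral state of every locus is known to be
*absence* of the insertion. The package works throughout on the diploid
insertion **dosage** — 0, 1 or 2 copies of the insertion allele per
individual — arranged as an individuals × loci integer matrix
(`polyte_matrix`), with samples mapped to populations and continental
groups by a panel table.

Everything downstream is phase-free, and loci are treated as unlinked. That
is an assumption the statistics share, not an approximation made for
convenience: allele frequencies, F_ST, delta, L1 allele-sharing distances
and the binomial admixture likelihood are all per-locus quantities combined
additively (or multiplicatively in the likelihood) across loci.

## Per-locus statistics

The insertion allele frequency in a stratum is TEi/2n — the number of
present insertion alleles over the total allele copies. Frequency spectra
are "unfolded" for free because the derived allele is always the insertion.

Two differentiation statistics drive marker selection:

* **delta**: the absolute allele-frequency difference between populations.
  For more than two groups the package reports the maximum pairwise
  difference, which equals `max(f) - min(f)`, reduces to the two-group
  definition, and matches how the ancestry-informative-marker (AIM)
  literature extends delta to multi-group comparisons. Classical AIM
  cutoffs (0.3, 0.4, 0.5) are applied as strict exceedances, as are the
  ">5%" common-locus rules.
* **Weir–Cockerham F_ST**: the 1984 theta-hat estimator from the three
  variance components a (among populations), b (among individuals within
  populations) and c (within individuals), with heterozygosity taken from
  *observed* heterozygote counts rather than Hardy–Weinberg expectation.
  Negative estimates are retained (they are informative about sampling
  noise near zero differentiation); loci monomorphic across all strata have
  a + b + c = 0 and are flagged undefined rather than propagated as NaN.
  Undefined loci are excluded from rankings. The implementation is
  vectorised over loci; the test suite checks it against a literal scalar
  transcription of the component formulas on every tiny two-population
  configuration and on random tables, to 1e-12.

Three-way continental comparisons (F_ST, delta) use the non-admixed
African, Asian (East Asian) and European groups only; Indian and American
samples do not enter those statistics, though their frequencies are
reported.

## Distances, diversity, embedding, tree

The allele-sharing distance between two individuals is the L1 distance on
dosage vectors: the total number of presence/absence alleles that differ.
It is a true metric, and a normalised variant (dividing by 2 × loci) is
available for cross-subset comparability; raw distances are the default
input to MDS and trees, and per-TE-family analyses are column masks of the
same code path, never separate implementations.

Population-level matrices average individual distances over all
between-population pairs; within-population pairs are excluded and the
diagonal is zero, as neighbor-joining and MDS input conventions require.
Within-group pairwise distances are the package's diversity measure;
group differences are tested with two-sided Wilcoxon rank-sum tests
(normal approximation with continuity correction — the within-group
multisets are large). When both multisets are completely tied the rank
variance is zero and the p-value is reported as 1.

Classical (Torgerson) MDS is used deliberately: double-centering of
−d²/2 and eigendecomposition, so Euclidean-realisable inputs are
reproduced exactly, and the result is deterministic up to axis sign. A
sign convention (orienting a chosen label negative) makes plots
reproducible. Neighbor joining is Saitou–Nei agglomeration; on non-additive
input NJ can produce negative branch lengths, which are clamped to zero
with the deficit transferred to the adjacent edge, preserving path lengths
across the affected node. On additive matrices the tree is exact, which the
tests verify over random topologies.

The **hypothetical ancestor** is the all-zero dosage pseudo-genome (no
insertions anywhere — the known ancestral state). Its placement is
summarised two ways: nearest neighbour by distance (ties reported, never
silently broken) and the bipartition of taxa induced by its attachment
edge in the NJ tree. On serial-founder-structured data that bipartition
separates the African-like clade from the European/Asian-like clades;
admixed cohorts may legitimately fall on either side (a heavily
African-admixed cohort joins the African clade), so the checks constrain
only the ancestral groups.

## Supervised admixture

The admixture model is the standard unlinked binomial mixture: an
individual's genotype at locus l is Binomial(2, p_l) with
p_l = Σ_k q_k f_kl, where f are ancestral-cluster allele frequencies and q
is the individual's ancestry fraction vector on the K-simplex.

Supervision is two-phase:

1. cluster frequencies f are the observed TEi/2n among labelled reference
   individuals (closed form), clamped into [ε, 1−ε] with ε = 1e-4 so the
   log-likelihood stays finite at monomorphic loci;
2. each target's q is estimated by EM with f fixed, from uniform
   initialisation — deterministic, no seed involved. Convergence is a
   log-likelihood improvement below 1e-7 (cap 2,000 iterations), and the
   EM monotonicity property is asserted at every iteration.

A joint block-relaxation (letting targets inform f) would match some
supervised implementations; the two-phase reading was chosen because the
target likelihood given f is identical, the estimator is deterministic,
and the study design never feeds targets back into training. With two
identical clusters the likelihood is flat in q; this is flagged
(`identifiable = FALSE`) rather than hidden. The tests pin the EM against
an exhaustive 0.001-resolution grid search of the likelihood over the
2-simplex.

## Marker-subset prediction

Loci are ranked by descending three-way continental F_ST with deterministic
(chromosome, position) tie-breaks, so top-n subsets are nested. The
cross-validation repeats, for each subset size (500 down to 10 in steps of
10): an 80/20 split stratified within each group (stratification prevents
empty training folds), cluster frequencies from the training 80%, q for
the test 20%, and an ancestry call to the argmax group only when
max q ≥ 0.9. Accuracy is correct calls over calls made — no-calls are
excluded from numerator and denominator, and the call rate is reported
alongside so no information is lost. Error is the mean per-individual RMSD
between the subset-based q and the q computed from the complete locus set
under the same training split ("actual" is the full-data model inference,
not the one-hot panel label). Replicate streams are derived
deterministically from a single master seed by replicate index, making
reports bit-reproducible.

Admixture prediction error for an admixed target cohort compares
subset-based to full-locus-set q (RMSD over the named components, averaged
over individuals, plus the Pearson correlation across individuals); here
training uses the complete reference groups, since targets are disjoint by
construction.

## The synthetic cohort generator

The generator exists so every stage is testable with full ground truth and
no external downloads. It emulates the statistical structure the analyses
assume — not a demographic simulation:

* **Frequency law**: ancestral insertion frequencies are a mixture of a
  Beta(0.3, 40) concentrated near zero and a Uniform(0.05, 0.45) common
  class, weight 0.98/0.02 for shared loci. This reproduces the strongly
  low-frequency-skewed polyTE spectrum (≈93–94% of loci below 5% overall
  frequency) without claiming a mutation–selection model.
* **Exclusivity**: 25% of loci are structurally private to one ancestral
  group (frequency zero elsewhere): 15% African-like, 5% each
  European/Asian-like. Private loci draw their frequency with a larger
  common-class weight (0.92 rare), reflecting polymorphism retained or
  arisen after the group splits; this is what gives the African-like group
  its diversity excess over the admixed cohorts. The weight is kept
  moderate on purpose: group-private common loci add insertion *load* as
  well as heterozygosity, and an overloaded African-like group would drag
  the zero-insertion ancestor off the basal edge of the tree.
* **Drift**: group frequencies drift from the ancestral value under the
  Balding–Nichols Beta model, hierarchically. The European-like and
  Asian-like groups first descend from one *shared* out-of-Africa
  bottleneck pool (drift 0.05), then apply their own residual drift
  (0.015 and 0.08; the African-like group drifts 0.005 straight from the
  ancestral pool). The shared bottleneck is what makes the non-African
  groups cluster together so that the deepest divergence — and the
  attachment point of the insertion-free ancestor — is African vs rest;
  independent per-group drift would instead make the two bottlenecked
  groups the most divergent pair. Diversity comes out ordered
  African > European > Asian because expected heterozygosity scales with
  the accumulated (1 − F) along each group's path. Populations within a
  group drift again by 0.01.
* **Admixture**: admixed individuals draw q from a Dirichlet —
  ASW-like α = (African 12, European 3), i.e. 80/20 mean ancestry with
  realistic spread; Latino-like α = (African 3, European 8, Asian 5), with
  the Asian pole standing in for Native American ancestry — and genotypes
  are Binomial(2, Σ q_k f_kl). Admixed cohorts are labelled continental
  group "American".

The preset sizes (3 ancestral groups × 100 individuals, two admixed
cohorts of 30, 2,000 loci) keep the full pipeline — including the
cross-validation sweep at 10 replicates — comfortably desk-scale while
leaving every statistic well inside its asymptotic regime; the spectrum
test uses 10,000 loci where the binomial noise on the realized fraction
matters.

What the generator does **not** emulate: linkage (loci are independent),
selection, realistic insertion-site models, within-group substructure
beyond one level of population drift, genotyping error, and missingness.
Passing tests on this data therefore validate the statistical machinery
and its contracts, not robustness to those real-data features.

## Numerical and degenerate-input choices

* Missing genotypes on VCF load are a hard error naming the record by
  default; an opt-in policy treats them as dosage 0 (ancestral absence).
* Multi-allelic MEI records collapse to presence of any ALT allele.
* TE family is recognised from the symbolic ALT allele
  (`<INS:ME:ALU>`, `<INS:ME:LINE1>`, `<INS:ME:SVA>`) or the INFO subtype
  text; unrecognised records are skipped with a reported count.
* Frequency thresholds and AIM cutoffs are strict inequalities.
* F_ST at monomorphic-everywhere loci: undefined flag, excluded from
  rankings; negative estimates retained everywhere else.
* NJ ties in the Q-matrix resolve to the implementation's fixed scan
  order (documented determinism rather than randomised tie-breaks);
  negative branches are clamped with deficit transfer.
* MDS axis signs are fixed by an orientation label when reproducibility
  across runs matters.
* EM: uniform initialisation, ε = 1e-4 clamp, tol = 1e-7, max 2,000
  iterations; the monotonicity assertion turns silent numerical failure
  into a loud error.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_polyte(serial_founder_preset(seed = 42))
st  <- locus_stats(sim$matrix, sim$panel)
rk  <- rank_loci(st, 500)
cv  <- ancestry_cv(sim$matrix, sim$panel, c("African", "Asian", "European"),
                   rk, replicates = 10, seed = 42)
head(cv)
```

The `analysis/` directory contains the numbered drivers that run the whole
study on the preset cohort and write their tables under `results/`.

## Known limitations

* The supervised-admixture two-phase estimator does not let reference
  genotypes and targets jointly refine cluster frequencies.
* Between-group F_ST uses group labels as the population unit; hierarchical
  (population-within-group) components are not estimated.
* The Wilcoxon tests treat within-group pairwise distances as exchangeable
  samples; pairs sharing an individual are not independent, so the
  p-values are descriptive rather than strictly calibrated — the same
  caveat applies to any pairwise-distance rank test.
* No support for CRAM/BAM, liftover, haplotype/LD-aware statistics, or
  MEI discovery from reads.
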