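# polyTE

Population genetics of polymorphic transposable element (polyTE)
insertions. The three active human TE families — Alu, L1 and SVA — still
transpose in the germline, leaving insertion sites that are present in some
genomes and absent in others. Because a shared insertion is essentially
always identical by descent, and because the ancestral state of every such
locus is known to be *absence*, polyTE presence/absence genotypes are
unusually clean markers of ancestry. This package implements a genome-wide
analysis of diploid polyTE dosage genotypes for researchers studying human
population structure, ancestry-informative marker (AIM) selection, and
supervised admixture inference — and a ground-truth synthetic cohort
generator so the entire pipeline is testable without any external data.

## What it computes

With dosage `g ∈ {0,1,2}` per individual and locus:

* **Allele frequencies** per population/group: `TEi / 2n` (present
  insertion alleles over allele copies), unfolded frequency spectra, >5 %
  sharing/exclusivity among continental groups.
* **Differentiation per locus**: δ = |f₁ − f₂| (max pairwise difference
  for ≥3 groups) with the classical AIM cutoffs 0.3/0.4/0.5, and
  Weir–Cockerham F_ST, θ̂ = a / (a + b + c), from the 1984 variance
  components with observed heterozygosity; negative estimates retained,
  monomorphic loci flagged undefined.
* **Allele-sharing distances**: d(i,j) = Σ_l |g_il − g_jl| (L1 on dosages),
  population-averaged matrices, within-group diversity distributions with
  Wilcoxon rank-sum tests, classical (Torgerson) MDS, neighbor-joining
  trees with Newick output, and placement of the hypothetical
  insertion-free ancestor (the all-zero genome).
* **Supervised admixture**: the unlinked binomial model
  `g_l ~ Bin(2, Σ_k q_k f_kl)`; cluster frequencies `f` from labelled
  references (closed form, ε-clamped), per-individual ancestry fractions
  `q` by EM on the simplex (deterministic, monotone log-likelihood).
* **Marker-subset prediction**: loci ranked by F_ST into nested subsets
  (500 → 10), 80/20 stratified cross-validation with a ≥0.9 call rule
  (accuracy over calls made, call rate reported), RMSD error against the
  full-locus-set inference, and admixture prediction error for admixed
  target cohorts.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study on
the packaged serial-founder cohort (three ancestral continental groups of
2 populations × 50 individuals, two admixed cohorts, 2,000 loci, seed 42).
Running them in order:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_popgen_stats.R
Rscript analysis/03_distances_diversity.R
Rscript analysis/04_embedding_tree.R
Rscript analysis/05_admixture.R
Rscript analysis/06_prediction_cv.R
```

prints, among other things (seed 42):

```
Overall spectrum: 93.8% of loci below 5% insertion frequency
Within-group median allele-sharing distances:
 African American European    Asian
      80       72       54       47
Ancestor attachment splits the tree into:
  { ASW_SIM, AFR2, AFR1 }
  { EUR2, EUR1, LAT_SIM, ASI2, ASI1 }
Ancestry CV (mean over 10 replicates):
 size accuracy      error call_rate
  500        1 0.06414143 0.9266667
  100        1 0.07497572 0.9250000
   10        1 0.09430966 0.8750000
```

Read: the synthetic cohort reproduces the strongly low-frequency-skewed
polyTE spectrum; within-group diversity is ordered African > admixed
American > European > Asian (the serial-founder signature); the
insertion-free ancestor attaches on the edge separating the African-like
clade (including the heavily African-admixed ASW-like cohort) from the
European/Asian-like clades; and a few hundred top-F_ST loci suffice for
essentially perfect continental ancestry calls, with the RMSD error
against full-data inference growing as the marker panel shrinks.

In code, the same pipeline is four calls:

```r
library(polyTE)
sim <- simulate_polyte(serial_founder_preset(seed = 42))
st  <- locus_stats(sim$matrix, sim$panel)        # freq, F_ST, delta per locus
rk  <- rank_loci(st, 500)                        # nested AIM panels
cv  <- ancestry_cv(sim$matrix, sim$panel,
                   c("African", "Asian", "European"), rk,
                   replicates = 10, seed = 42)
```

Real data enter through `read_mei_vcf()` (1000 Genomes-style
mobile-element-insertion VCF, symbolic `<INS:ME:...>` ALT alleles) and
`read_panel()` (sample → population TSV with a packaged 26-population,
5-group continental map).

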