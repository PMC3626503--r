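---
title: "Single-cell exome somatic calling and clonal reconstruction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell exome somatic calling and clonal reconstruction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scexoclone)
```

# The problem

Whole-genome amplification (WGA) of a single cell's DNA introduces two
characteristic errors that dominate downstream genetics. **Allele dropout
(ADO)** is the random failure to amplify one allele of a heterozygote, which
then appears homozygous; in tumor/normal single-cell exome data this affects
roughly 40% of heterozygous genotypes. **False positives** make a truly
homozygous site appear heterozygous, at a per-site rate near 6.7e-5. Any
analysis that calls somatic mutations across a population of single cells,
estimates mutant allele frequencies, or reconstructs subclones must model
both.

`scexoclone` implements this analysis for a population of tumor cells and
matched normal cells from the same patient: error-rate estimation from the
normal cells, binomially derived cell-count thresholds for somatic calling,
population-level somatic mutation calling, the somatic mutant allele
frequency spectrum (SMAFS) with its population-genetic tests, and Bayesian
posterior-based subclone reconstruction. A synthetic-data generator with
full ground truth drives all testing.

# Error model estimation

## Allele dropout

ADO is estimated per normal cell by comparing the cell's heterozygous call
rate with the tissue's over a shared germline background subset, depth
stratum by depth stratum:

relative FNR at depth n = (HR_T/CR_T − HR_S/CR_S) / (HR_T/CR_T),

where HR and CR are the heterozygous and covered proportions of the subset
at depth n, T is tissue and S the single cell. Conditioning on depth removes
the coverage-driven part of the het-rate difference (at low depth even
tissue misses one allele by read sampling), leaving the amplification
dropout. Depth strata are binned 5 reads wide (`bin_width`), restricted to
the 1st–99th percentile of the cell's depths, and skipped below 50 subset
sites; strata where the relative FNR is negative (tissue below the cell) are
outliers and excluded. The cell's ADO is the **median** over the remaining
strata; the population ADO is the mean over qualified normal cells. The
estimator is validated on an injected grid 0.1–0.6 (monotone recovery, bias
below 0.03 with 1.5e4 germline sites per cell).

ADO in a homozygous genotype (`ado_hom`) cannot be observed — dropout does
not change a homozygote — but the genotype likelihoods below include the
factor the model prescribes, so it defaults to `ado_het` and is
configurable.

## False discovery rate

The per-site false-het rate is the fraction of heterozygous calls over a
high-confidence homozygous subset: top-tier genotype quality, depth inside
the central 95% interval of a Poisson with the cell's mean depth. The
population FDR is again the mean over normal cells. A mitochondrial
cross-check (`mito_fdr_crosscheck`) treats every retained singleton
mitochondrial variant (at least five mutant reads, shared by no second cell)
as a false positive over cells × 16,561 bp; the callable denominator is
exposed because conventions differ.

# Calling thresholds

A false heterozygote arises independently across cells, so requiring a
mutation in at least *i* of *n* cancer cells bounds the genome-wide expected
number of coincidental calls by C(n,i) p_f^i (1−p_f)^(n−i) · S for exome
size S. `min_mutant_cancer_cells` returns the smallest *i* that drives this
expectation below one — the boundary of the feasible region; all larger *i*
also satisfy it at these tiny rates. At p_f = 6.7e-5, n = 44, S = 5e7 the
threshold is 3 cancer cells.

The corresponding criterion for covered normal cells guards against a
germline heterozygote hidden by dropout in every observed normal cell. No
single-term binomial in the ADO reproduces the published operating point of
six covered normal cells, and the generative event the published formula
intends is ambiguous, so `min_normal_cells_covered` exposes the probability
model: the shipped default is the fixed operating point 6; a
`(p_a/2)^i · S < 1` dropout-power model and a binomial model are available.

Somatic calls then require: (1) every covered normal cell homozygous
reference with at least 6 covered; (2) the matched tissue homozygous
reference; (3) at least 3 mutant cancer cells. On synthetic data the planted
clonal mutations are recalled essentially completely, and populations with
error processes only produce zero calls.

# Mutant allele frequencies and the SMAFS

The count estimator at a site is (n_het + 2 n_hom_mut) / (2 n_covered). The
likelihood estimator maximizes over f the marginal likelihood
Σ_cells log Σ_g P(obs | g) P(g | f) with Hardy–Weinberg weights
P(g | f) = ((1−f)², 2f(1−f), f²) and the ADO/FDR-calibrated genotype
likelihoods described below; the search is a 1e-3 grid with golden-section
refinement (oracle-checked against a 1e-4 grid). Under dropout the
likelihood estimator has visibly smaller sampling variance than counting;
the pipeline uses it by default (`estimator = "ml"`).

The SMAFS uses ten left-closed bins with the last bin closed; 0.5 falls in
bin 6. The hyperbolic fit models expected counts c/f_mid — the neutral
expansion spectrum — with c fitted by minimum chi-square on the non-excluded
bins (the pipeline excludes the clonal bins 5–6), and a Pearson
goodness-of-fit statistic over all ten bins (df = 8), so a clonal
heterozygous peak near 50% inflates the statistic. Two caveats are inherent
and worth stating. First, a heterozygous-only somatic process cannot exceed
frequency 0.5, so bins 7–10 are structurally empty and already contribute
misfit; second, the three-cancer-cell calling threshold truncates the first
bin. Both push the statistic up for *called* spectra; the p-value is
therefore evidence of departure from a pure hyperbola (which is what the
clonal-origin argument needs), not a calibrated tail probability for the
peak alone. The separate `peak_excess` flag marks a 40–60% bin exceeding
three times its fitted expectation; with a 400-mutation neutral tail the
genuine neutral shoulder under the peak keeps typical clonal excesses below
that multiple, so the flag is reserved for strong peaks and its false-positive
rate on pure-neutral simulations is ~0 (bounded at 10% in the tests, where
the p-value's null calibration is checked against spectra drawn from the
hyperbolic law itself).

The selection test asks whether nonsynonymous mutations are enriched above
frequency 0.1 relative to synonymous ones (one-sided Fisher), also after
excluding the 40–60% peak. The synthetic generator plants no selection, so
on simulated data this p-value is only exercised, not expected significant.
Cell-population frequencies are also correlated against bulk-tissue
mutant-read frequencies (R² of the least-squares fit); at 137× bulk depth
the default synthetic run exceeds 0.89.

# Genotype posteriors and the H matrix

For each covered cell × site, the prior over genotypes {NN, NC, CC} comes
from the matched tissue call with weight tiers Pn = 1/3 (quality < 10 or
rank-sum p < 0.05), 0.9 (10 ≤ q < 20), 0.99 (q ≥ 20); the tissue genotype
receives Pn, homozygous-mutant always receives (1−Pn)/2, and the remaining
diploid genotype the rest. The likelihoods calibrate the observed genotype
and read counts (m mutant of n reads) by ADO and FDR:

* P(O|NN) = (1−f_homo) · C(n,m) f_p^m (1−f_p)^(n−m)
* P(O|NC) = ½ f_heter · C(n,m) f_p^m (1−f_p)^(n−m) if observed NN;
  1−f_heter if observed NC; the mirrored expression if observed CC
* P(O|CC) = (1−f_homo) · C(n,n−m) f_p^(n−m) (1−f_p)^m

The (1−f_homo) factor on the homozygous branches is kept as the model
states it, although dropout cannot change a homozygote's genotype; a
`corrected` flag removes it (it cancels in the posterior unless branches
mix). The published heterozygous-observed-CC branch contains an obvious
typographical slip in its error-rate symbol; it is implemented as the exact
mirror of the heterozygous-observed-NN branch. The H score is the posterior
log-odds log10[(Pp(NC)+Pp(CC))/Pp(NN)] with probabilities floored at 1e-12.

Site scores are aggregated per gene by maximum (a gene is mutant if any of
its sites is; sum is available). Sites uncovered in a cell are imputed with
the mean H of the covered cells at that site. Genes that look mutant in any
normal cell — gene-level H ≥ 0.5 — are suspicious (paralogous alignment,
residual false positives) and are removed; this filter uses **observed**
values only, because imputed entries average over the mostly-tumor
population and would wrongly flag clean genes.

# Clustering into subclones

Two design choices matter and were made deliberately:

* **Saturation.** H is a log-odds: its magnitude keeps growing with read
  depth long after the mutant/not-mutant question is settled, so Euclidean
  distances on raw H measure depth, not biology. H is capped at ±3 before
  clustering — exactly what a heatmap's color scale does.
* **Recursive cut.** Clonal structure is hierarchical: the tumor/normal
  divide is far larger than any subclone divide. A global silhouette
  criterion therefore stops at 2–3 clusters. Instead, successive splits of
  the Ward tree (k = 2, 3, …) are accepted while the split's *local*
  silhouette — computed only over the cells of the cluster being split —
  stays at or above tau = 0.10. On the default synthetic conditions true
  splits score 0.11–0.18 locally and spurious ones 0.03–0.08, so the rule
  separates them with margin; 20/20 seeded replicates recover the planted
  A/B/C/N partition exactly (adjusted Rand index 1.0), versus 16/20 for the
  global-silhouette cut.

Gene-pair concurrence/exclusivity uses Fisher's exact test on the 2×2 cell
table, one-sided in each direction, with an optional permutation version;
p ≥ 0.3 is flagged "not shown" as such maps are usually displayed. Because
single-pair tests are underpowered at the margins dropout leaves (~10–11
visible carriers of a 15-cell clone), the subclone-exclusivity summary
tests each clone-private gene against the pooled pattern of the other
clone's gene set. Clone divergence in generations is count / (mu·S) rounded
up, defaults mu = 5e-9 per bp per generation and S = 60 Mb callable — 12
clone-private genes give at most 40 generations. PCA of the genotype matrix
imputes missing entries by iterated truncated-SVD completion before a
standard decomposition.

# The synthetic generator

`sim_config()` defaults describe the study conditions: 44 tumor and 11
normal cells; three subclones at fractions 0.30/0.35/0.35; 22 ancestral
mutations heterozygous in every tumor cell; 7 and 12 clone-private
mutations; a 400-mutation neutral tail; 3,000 germline heterozygous and
30,000 homozygous background sites; ADO 0.41, per-site FDR 6.7e-5; mean
depth 40× with negative-binomial dispersion 0.3; per-site coverage 0.886.
Values the study does not state were chosen once as field-typical and are
knobs, not claims: the per-read error (1e-3) only feeds mutant-read counts
at homozygous sites, and the depth dispersion matches the heavy-tailed
coverage WGA produces. Quality scores are tiered (≥20 with probability
0.95) so every prior tier is exercised.

Neutral-tail carrier counts k follow P(k) ∝ 1/k — the stationary spectrum of
a neutrally expanding population — truncated at the cell count. The *cells*
carrying each tail mutation are drawn clade-consistently within the clone
tree ((B,C),A): a neutral mutation arises on one lineage branch, so its
carriers sit inside one clade, which is why real mutation heatmaps show
within-clone blocks rather than salt-and-pepper noise. Among clades large
enough for k carriers, smaller clades are favoured (weight 1/size),
mirroring the larger number of recent branches. The marginal distribution
of k — and hence the frequency spectrum — is unchanged by this choice.

What the generator does **not** emulate: read-level partial dropout (a
dropped allele here leaves ~no residual mutant reads), amplification-bias
correlation along the genome, copy-number change and loss of
heterozygosity, doublets, or contamination. Passing recovery tests
therefore show the estimators are correct under the stated error model, not
that they are robust to every artifact of real WGA data.

# Numerical choices and problem sizes

Grid resolution 1e-3 with local refinement for the frequency MLE; posterior
flooring 1e-12; depth-stratum width 5 reads, minimum 50 sites, 1st–99th
percentile window; Poisson central-95% depth interval for the homozygous
subset; silhouette threshold tau = 0.10; H cap ±3. The test suite sizes
simulations to the statistics they check: error-rate recovery uses up to
4e5 homozygous sites × 11 cells (≈3.7e6 site–cell pairs, standard error
~4e-6 on the FDR) and 2–3e4 germline sites per cell for ADO; clone-recovery
properties use 20 seeded replicates of the default configuration; null
calibration uses 200 spectra. These sizes are the package's choices and can
be scaled up through the same interfaces.

# Limitations

The criterion-1 threshold is an operating point, not a derivation; the
mitochondrial FDR denominator is a convention; the hyperbolic
goodness-of-fit p-value is a departure statistic, not a calibrated peak
test, for called spectra; clustering labels are partitions, not a rooted
phylogeny — the dendrograms are descriptive. Estimates of ado_hom are not
possible from genotype data and the value is a configured assumption.
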