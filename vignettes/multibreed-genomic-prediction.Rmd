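---
title: "Multi-breed and crossbred genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed and crossbred genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossgp` studies how the composition of a genomic-prediction reference
population — within-breed, across-breed, joint purebred, breed-balanced,
or including crossbred cows — affects the accuracy and bias of genomic
estimated breeding values (GEBV) in a two-breed dairy system
(Holstein-Friesian, H, and Jersey, J) with 75:25, 50:50 and 25:75 H:J
crossbred cows. Because the motivating data (national dairy evaluations)
are never public, the package is built around a fully specified synthetic
population, and every claim the package makes is a claim about what its
tests and analysis scripts actually compute on that population.

## The statistical models

**Weighted GBLUP.** Phenotypes are deregressed proofs (DRP): per-animal
pseudo-phenotypes that behave like unshrunk breeding-value estimates with
known reliability. The model is

$$ y = Xb + Zu + e, \qquad
   u \sim N(0, G\sigma^2_g), \quad e \sim N(0, E\sigma^2_e), $$

with fixed effects $b$ (intercept, sex, breed group), $G$ the VanRaden
method-1 genomic relationship matrix, and $E$ diagonal with
$E_{ii} = 1/w_i$. The weight $w_i$ reflects how much information each
DRP carries:

$$ w_{\text{cow}} = \frac{1-h^2}{c\,h^2 + \frac{1+(n-1)t}{n} - h^2},
   \qquad
   w_{\text{bull}} = \frac{1-h^2}{c\,h^2 + \frac{4-h^2}{p}}, $$

where $n$ is the cow's record count, $p$ the bull's daughter count,
$h^2 = 0.33$ the heritability, $t = 0.56$ the repeatability and
$c = 0.2$ the fraction of genetic variance not captured by markers.
`fit_wgblup()` solves the mixed-model equations jointly for phenotyped
and unphenotyped animals, so validation animals (present in $G$, without
records) receive GEBV through the relationship coupling; this is
algebraically the conditional-mean predictor
$G_{21}G_{11}^{-1}\hat u_1$.

*Residual-variance default.* The weights scale a single-record cow to
$w \approx 0.9$, so the coherent companion default is
$\sigma^2_e = \sigma^2_g(1-h^2)/h^2$ with per-animal residual variance
$\sigma^2_e / w_i$. An earlier draft multiplied this by the mean weight;
with many high-weight progeny-tested bulls that overshrinks GEBV
severely (DRP-on-GEBV slopes of 2–4), and the factor was removed. An
EM-REML mode (`variance_mode = "em_reml"`) is available when the
variance components should be re-estimated; the experiment harness
instead uses the generator's known components, because re-estimating
~20 variance pairs per replicate would dominate runtime without changing
the design contrasts under study.

**Mixture-prior Bayesian SNP model.** The SNP-effect model is

$$ y = Xb + Wv + e, $$

with $W$ the dosage matrix standardized to unit variance per SNP and
each effect $v_j$ drawn from a four-component normal mixture with
proportions $(0.94, 0.049, 0.01, 0.001)$ and variances
$(0,\,10^{-4},\,10^{-3},\,10^{-2})\times\sigma^2_g$ — a 94% prior
chance of zero contribution. `run_embayesr()` runs a deterministic EM
warm start (conditional-expectation sweeps, convergence when the largest
effect change falls below $10^{-7}$, cap 2,200 sweeps) followed by five
Gibbs chains launched from the warm start with consecutive seeds; chain
outputs (posterior-mean effects, Rao-Blackwellized component
probabilities) are averaged. DRP weights enter as inverse
residual-variance multipliers, mirroring $E$ in GBLUP. The sampler
visits SNPs in a freshly randomized order each iteration (seeded, hence
reproducible) to avoid order artifacts. Iteration defaults (10,000
draws, 2,000 burn-in) sit inside the protocol's stated ranges; the
experiment harness scales them down (3,000 / 600) where the grid, not a
single fit, is the object of interest.

The sampler is validated two independent ways: a one-SNP problem against
direct numerical integration of the mixture posterior, and a
single-non-null-component prior against closed-form ridge regression.
GBLUP itself is validated against an explicit SNP-ridge-regression
oracle via the $G = WW'/m$ equivalence.

## The synthetic population

`simulate_population()` generates:

* **Breed divergence.** Ancestral allele frequencies uniform on
  $(0.05, 0.95)$; breed frequencies from the Balding–Nichols
  distribution with $F_{ST} = 0.1$, the conventional magnitude for the
  Holstein–Jersey split. Loci are independent — there is no
  recombination map and hence *no linkage disequilibrium*; the
  consequences are discussed below.
* **Population structure.** Default group sizes (400 H bulls, 110 J
  bulls, 700 H cows, 300 J cows, 700/600/150 crossbred cows, ~3,000
  animals) keep the study's proportions: an H-dominated system with a
  J minority and a large crossbred cow population.
* **Sire families.** Every cow has a recorded sire drawn from the
  simulated bull pool (H bulls sire H cows, the H side of F1s and the
  75:25 backcrosses; J bulls sire J cows and 25:75 backcrosses); dams
  are never shared. This creates the paternal half-sib structure that
  reference/validation splits in dairy validation studies are built
  around; without it, within-breed and across-breed prediction are
  nearly indistinguishable here, because with independent loci the SNP
  effects themselves transfer perfectly across breeds.
* **QTL effects.** Per trait, 300 QTL positions are drawn uniformly;
  effects come from the non-null mixture components and are rescaled so
  the true-breeding-value variance among pure Holsteins equals
  $\sigma^2_g = 1$ exactly. Three traits (milk, fat, protein) share
  genotypes but have independent QTL draws; reported metrics average
  across traits, which is also how the motivating study reports its
  results.
* **DRP phenotypes.** DRP = TBV + calibrated noise with reliability
  $r^2 = n h^2 / (1 + (n-1)t)$ for cows (records $n \sim U\{1,10\}$)
  and $r^2 = p/(p + (4-h^2)/h^2)$ for bulls (daughters
  $p \sim U\{20,300\}$), noise variance $\sigma^2_g (1-r^2)/r^2$. A
  non-genetic Jersey-proportional mean shift (0.5) and a bull mean
  shift (0.2) make the breed-group and sex fixed effects identifiable.
* **Marker panels.** Panels abstract marker proximity to causal
  variants: `tag` (all non-QTL markers — an array whose markers are
  *near* but never *at* causal variants; with independent loci this
  panel carries no causal signal at all), `causal_enriched` (same size,
  containing every QTL — a sequence-selected panel), and `pruned_dense`
  (everything, LD-pruned at $r^2 > 0.95$). The tag-vs-causal contrast
  isolates the mechanism by which variant-selected panels help, without
  simulating genome-scale LD.

**Reference designs.** `build_reference_designs()` reproduces the
study-grid logic: Ref1 (all pure H), Ref2 (all pure J), Ref3 (their
union), Ref4/Ref4p (Ref3 with crossbred predictions formed as
breed-fraction weighted averages of Ref1 and Ref2 GEBV, fractions from
PCA groups or continuous admixture), Ref5 (Ref3 + all crossbred cows),
Ref6 (breed-balanced bulls and purebred cows, J being limiting), Ref7
(same bulls, crossbred cows only, total matched to Ref6; the 75:25 and
25:75 strata capped at the smaller of the two, remainder from 50:50),
Ref8 (union of Ref6 and Ref7). A single validation cow set spanning all
five groups (75/65/65/25/40 — the study's proportions at our scale) is
shared by every design; validation cows' sires are excluded from every
reference (the parent–offspring exclusion), while paternal half sibs
remain, as in the motivating validation design.

## Breed assignment

`pca_of_grm()` + `allocate_groups()` implement the pragmatic route:
group means of PC1 among pedigree-trusted animals define midpoint
boundaries (no published boundary values exist to adopt, so the
symmetric midpoint rule closes that gap), and every
animal, including mislabeled ones, is assigned by its score.
`estimate_admixture()` maximizes the binomial admixture likelihood at
$k = 2$ by alternating EM updates with SQUAREM-style acceleration and a
monotonicity safeguard; both constrained M-steps are exact maximizers of
the EM minorizer, so the recorded log-likelihood trace never decreases.
Initialization is deterministic given the seed (Q from the dosage PC1
rank-rescaled, F from perturbed sample frequencies); population labels
are mapped to H/J by correlating estimated frequencies with purebred
sample frequencies. A statistical point worth stating: at 2,000 markers
and $F_{ST} = 0.1$ the Fisher information bounds per-animal ancestry
standard errors at roughly 0.035, so *individual* purebred memberships
scatter down to ~0.90 for any maximum-likelihood estimator; recovery
checks therefore assert group means (~0.97), not minima.

## Numerical choices

* GRM: VanRaden method 1, frequencies recomputed per design from that
  design's reference + validation animals (between-breed relationships
  depend visibly on the frequency source). SNPs monomorphic within a
  design's animals contribute zero to numerator and denominator and are
  tolerated; standardization (which divides by $\sqrt{2p(1-p)}$)
  refuses them and requires MAF filtering first.
* $G$ gets a $10^{-6}$ diagonal ridge before inversion; aliased
  fixed-effect columns are dropped from the end with a warning.
* LD pruning scans a 100-SNP window with step 50 (unstated in the
  original; chosen to mirror common practice at $O(n \cdot w)$ cost),
  drops the lower-priority SNP of each offending pair (tie: the later
  position), always keeps monomorphic SNPs (their correlation is
  undefined), and is idempotent.
* MAF filtering uses a strict inequality (a SNP at exactly the
  threshold survives).
* Admixture frequencies are boxed to $[0.001, 0.999]$ and memberships
  to the simplex; the unidentifiable case (indistinguishable estimated
  frequency vectors, e.g. undiverged data) sets a warning flag.
* Every stochastic step takes an explicit seed; the full experiment
  grid rerun with the same configuration reproduces bit-for-bit.

## What the synthetic study can and cannot show

The replicated experiment (10 seeded replicates at the default scale;
~3,000 animals, 5,000 SNPs, 300 QTL per trait, weighted GBLUP on the
pruned dense panel, metrics averaged over three traits) reproduces the
study's headline *accuracy* orderings: within-breed beats across-breed
prediction; adding crossbred cows to the reference raises crossbred
accuracy; markers at causal variants beat markers off causal variants
for within-breed prediction.

Two *bias* orderings do **not** reproduce, and the reason is
instructive. In this generator (additive effects, no LD, shared
variance components), the H-dominated joint reference Ref3 contains
every Jersey animal the balanced Ref6 has plus extra Holsteins — and
extra reference animals can only sharpen, never distort, a correctly
specified additive model, so Ref3's Jersey calibration is already close
to slope 1 and Ref6's smaller reference is noisier. Likewise the
weighted-average GEBV (Ref4) combines two component predictions that
are only weakly correlated here (no LD means the H- and J-reference
predictions share little information), which halves the prediction
variance and inflates the DRP-on-GEBV slope; in the real data the
component GEBV are strongly correlated and the averaging tempers
overdispersion instead. The corresponding acceptance checks are kept as
specified and fail honestly; they measure real-data pathologies —
across-breed LD-phase differences and proof-scale heterogeneity — that
this simulator deliberately excludes.

## Problem sizes

Unit tests run on micro-populations (tens to hundreds of animals,
120–2,000 SNPs) built in code; the replicated experiment uses the
default ~3,000-animal scale; sampler oracles use $n = 50$–300,
$m = 1$–1,000 with 20,000–50,000 draws. The analysis scripts under
`analysis/` are one-replicate narratives of the same computations with
summary tables written to `results/`.

## Known limitations

* No linkage disequilibrium and no recombination map: panel contrasts
  emulate marker-to-causal proximity only through set membership.
* DRP are emulated (TBV + calibrated noise), not produced by a national
  random-regression evaluation; heterosis and dominance are absent, as
  in the motivating additive analysis.
* Only first/second-generation crosses; no repeated inter-crossing, no
  selection or drift across generations.
* Admixture supports exactly two ancestral populations.
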