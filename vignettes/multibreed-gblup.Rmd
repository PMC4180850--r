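---
title: "Genomic prediction from purebred and crossbred reference populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction from purebred and crossbred reference populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sheep and beef-cattle reference populations are rarely purebred: phenotyped
and genotyped animals come from several breeds and their crosses, with one
numerically dominant breed (in Australian sheep, the Merino) supplying most
purebred records and most crossbred dams. `crossblup` provides a tested,
reusable pipeline for asking how the composition of such a reference
population affects the accuracy of genomic best linear unbiased prediction
(GBLUP) for purebred selection candidates, and whether accounting for
breed-specific marker allele frequencies in the relationship matrix helps.

Because the motivating industry datasets are proprietary, the package is
built around a forward-in-time simulator that reproduces the *statistical
structure* the analysis assumes — diverged breeds, paternal half-sib
families, purebred and crossbred progeny cohorts, maternal and
sire-by-flock variance, progeny-tested validation sires — and every claim
the package makes is a property checked on that simulator, not a replica of
any proprietary number.

## The model

Phenotypes are analysed with the mixed model

$$
\mathbf{y} = \mathbf{Xb} + \mathbf{Z}_1\mathbf{g} + \mathbf{Ww}
           + \mathbf{Z}_1\mathbf{Qq} + \mathbf{Z}_2\mathbf{s} + \mathbf{e},
\qquad \mathbf{g} \sim N(0, \mathbf{G}\,\sigma_g^2),
$$

where **b** holds fixed effects (birth type, rearing type, gender, an age
covariate and the contemporary group site x birth year x management group),
**g** the additive genomic values, **w** random maternal effects, **q**
breed effects regressed on the pedigree breed-proportion matrix **Q**, and
**s** random sire-by-flock interactions. All random terms except **g** are
i.i.d. `solve_mme()` builds and solves Henderson's equations directly;
animals present in **G** but without records (the validation sires) obtain
their GBV through genomic relationships.

Two relationship matrices are implemented (`build_g1()`, `build_g2()`):

* **G1** — VanRaden's genotype-based matrix,
  $\mathbf{G1} = \mathbf{ZZ}'/2\sum_j p_j(1-p_j)$ with
  $\mathbf{Z} = \mathbf{M} - 2p$, 0/1/2 dosages centered by the observed
  reference-population frequencies.
* **G2** — the gametic variant with breed-of-origin allele frequencies:
  each parental haplotype (0/1 alleles) is centered by the frequency of the
  breed that haplotype derives from,
  $\mathbf{G2}_i = \mathbf{Z}_i\mathbf{Z}_i'/\sum_j p_j(1-p_j)$ for the
  paternal ($i=1$) and maternal ($i=2$) haplotype sets, and
  $\mathbf{G2} = (\mathbf{G2}_1 + \mathbf{G2}_2)/2$. Haplotype
  breed-of-origin labels come from the pedigree: a haplotype is labelled
  only when the transmitting parent is more than 97% purebred, and animals
  with an unlabelled haplotype are excluded from the G2 reference.

Two formula details are not fixed by the printed equations and were decided
here:

* **The G2 denominator with mixed breeds.** One $\sum p(1-p)$ appears per
  gametic matrix, but a gametic matrix can contain haplotypes of several
  breeds. We use the haplotype-count weighted average of the per-breed sums
  $\sum_j p_{bj}(1-p_{bj})$, recorded in the matrix metadata; SNPs
  monomorphic within a breed contribute zero variance for that breed and
  nothing to its denominator term. This keeps the scaling comparable across
  gametic matrices without discarding panel-wide information.
* **Cross-gamete products.** $(\mathbf{G2}_1+\mathbf{G2}_2)/2$ omits the
  two paternal x maternal cross-products that G1 contains. We implement the
  formula exactly as printed; a `full_gametic = TRUE` variant that keeps
  all four products is available for comparison but off by default. The
  omission has a measurable consequence discussed below.

`em_reml()` estimates $\sigma_g^2$ and $\sigma_e^2$ for the reduced model
(additive + residual) by EM on the REML likelihood after a one-off
eigendecomposition of **G**; the likelihood is non-decreasing at every
iteration and boundary estimates stay non-negative. The full model's
maternal and sire-by-flock components default to the simulator's truth:
re-deriving multi-term REML is deliberately out of scope, and in the
pipeline those components are inputs, as they were in the original
ASReml-based analyses.

## What the simulator emulates

`sim_config()` / `sheep_sim_config()` control a forward-in-time simulator:

* **Base population and LD.** Allele frequencies are drawn from Beta(2, 2);
  linkage disequilibrium is induced by 50 random-mating burn-in generations
  (uniform marker map, Poisson crossovers, no interference). Real ovine LD
  structure is unknowable at this scale; the burn-in length is an explicit,
  tunable stand-in.
* **Breeds.** Each breed drifts independently from the base at effective
  size `effective_size` (default 100) for its own number of generations
  (preset 150/100/60/60 for the Merino-, maternal- and two terminal-breed
  analogs). The star topology with unequal branch lengths reproduces the
  observed layout: the two terminal analogs end up mutually closer than
  either is to the Merino analog, and a GRM PCA separates all four breeds.
  Wright's expectation $F_{ST} = 1-(1-1/2N_e)^t$ is a calibration check,
  not an input.
* **QTL.** `n_qtl` loci (default 100) receive per-breed additive effects
  with pairwise correlation `across_breed_qtl_correlation` (preset 0.2:
  marker-QTL phase *and* QTL effects differ across these strongly diverged
  breeds, which is the regime in which across-breed prediction is expected
  to collapse). Effects are scaled once so the focal-breed additive
  variance equals $h^2\sigma_P^2$. QTL are excluded from the genotyping
  panel by default, mimicking a 50k chip that tags but rarely types causal
  variants; a flag includes them (used when testing REML recovery, where
  the estimand should be the full additive variance).
* **Crossbreeding design.** Purebred focal-breed families, F1 crosses
  (other-breed sires x focal dams) and three-way crosses on F1 dams, in
  paternal half-sib families of 10-30 progeny (the published family-size
  range scaled to desk size), one flock per family.
* **Validation sires.** Withheld purebred sons of the family sires, never
  phenotyped. This makes them paternal half-sibs of reference progeny: the
  mean genomic relationship between a validation sire and the reference is
  of order 0.01 — the scale reported for real industry sires — and the
  relatedness runs through the *paternal* line, which is exactly the
  mechanism proposed for why n purebreds out-predict 2n crossbreds (the
  crossbreds' focal-breed haplotypes arrive through dams). Their
  progeny-test EBVs are simulated at a target accuracy r (see below) and a
  reliability floor is applied as in the real validation sets.
* **Phenotypes.** One trait per run, post-weaning-weight-like units (mean
  36.6, SD 7.6); $h^2 = 0.3$, maternal and sire-by-flock ratios 0.05 each.
  The source study does not report variance components, so these are config
  choices in the range typical for sheep body-composition traits, stated
  once and never tuned. Mean breed effects (0/7/9/9 units) reproduce the
  observed purebred-vs-crossbred phenotype gap and give the **Qq** term
  something real to absorb.

**Reliability vs accuracy.** The validation floor ("0.64/0.70") is treated
as a *correlation* (accuracy r), not a squared correlation, matching the
published definition of EBV accuracy as the correlation between predicted
and true breeding values. `simulate_progeny_test_ebv()` generates
$\mathrm{EBV} = r\,z(g) + \sqrt{1-r^2}\,\varepsilon$, so realized
cor(EBV, g) converges to r.

What the simulator does **not** reproduce: real LD decay profiles and
marker ascertainment, selection during breed divergence, mutation,
dominance/epistasis, Merino strain substructure, genotype-by-environment
beyond the sire-by-flock term, and multi-trait covariance. Passing tests
therefore demonstrate internal consistency of the method under the stated
genetic architecture — not that any particular real-data accuracy will be
attained.

## Quality control

`qc_snps()` applies, in a fixed documented order: per-call confidence
masking (< 0.6), SNP call rate (< 95%), per-SNP heterozygosity beyond 3
panel SDs, MAF < 0.01, sex-chromosome drop, and a Hardy-Weinberg
chi-square filter at $p < 10^{-15}$. The source text does not state an
order; ours is recorded in the QC report, and a SNP is attributed to the
first filter that catches it. Two ambiguities were resolved as follows:
heterozygosity is per-SNP (a per-sample variant would target different
artefacts and is out of scope); HWE is pooled by default but the pipeline
stratifies it within purebred groups, because pooling strongly diverged
breeds fails SNPs wholesale through the Wahlund effect — crossbred cohorts
are excluded from the HWE test since Hardy-Weinberg proportions do not
apply to structured crosses. `qc_samples()` removes the later-indexed
member of any pair with genotype correlation >= 0.99. Missing genotypes
are mean-imputed (2p per SNP): the GRMs operate on dosages, mean imputation
preserves allele frequencies exactly, and at the <= 5% missingness left
after QC its effect on G1 is negligible on structured panels — a
deliberate, documented stand-in for phasing-based imputation. Phenotypes
beyond 4 SD of the overall mean are trimmed once (not iteratively).

## The scenario runner

`run_scenario()` executes, per replicate seed: simulate → QC → **Q** →
haplotype origin labels → validation EBVs → per reference design and GRM
flavor: build the GRM over reference + validation animals (G1 frequencies
from the reference; G2 breed frequencies from the labelled haplotypes of
the analysis set), trim outliers, solve the mixed model with truth variance
components, and record within-breed validation accuracy. The preset
(`sheep_scenario_preset()`) contrasts nested purebred references of 200,
400 and 600 animals, a 400-animal F1 crossbred reference selected by the
45% breed-proportion rule, and their combination — about one fifth of the
published design sizes, preserving its ratios (crossbred selection
thresholds 45%/45%/35%, haplotype accounting 2 x size x proportion).
Ten seeds, roughly a thousand markers on three 1-Morgan chromosomes and a
few thousand animals keep a full run in minutes on one core; these sizes
are stated here as the package's desk-scale choice.

Reproduced trends (asserted in the test suite, means over 10 seeds):
purebred accuracy for the focal breed rises strictly with reference size;
a crossbred-only reference with the same number of focal-breed haplotypes
is less accurate than the purebred one; predicting a diverged breed from
another breed's data alone gives accuracy near zero; and G1 and G2 give
similar mean accuracy (gap below 0.05).

## Numerical choices and degenerate inputs

* G inversion uses Cholesky; on failure 0.01 is added to the diagonal once
  and the stabilization is recorded in the fit.
* Aliased fixed-effect columns are dropped with a warning (recorded);
  constant **Q** columns (purebred-only references) are dropped silently
  since they carry no contrast.
* `breed_proportions()` caps recursion at `max_depth` (default 6)
  generations; deeper ancestry and unlabelled founders accrue to an
  explicit `"unknown"` pseudo-breed rather than being prorated, keeping
  rows exact partitions. Pedigree cycles are detected and rejected.
* Monomorphic SNPs are an error in `build_g1` (filter first); breed-wise
  monomorphic SNPs in G2 contribute zero variance for that breed only.
* EM-REML floors variance components at 1e-12; convergence is declared on
  a log-likelihood change below 1e-8.
* `grm_pca()` reports purity as `NA` for isotropic (all-equal-eigenvalue)
  matrices instead of forcing a meaningless clustering.
* Duplicate-sample removal keeps the first-indexed member of a flagged
  pair (the source does not say which member was dropped).

## A known, quantified limitation

Because $(\mathbf{G2}_1+\mathbf{G2}_2)/2$ omits the cross-gamete products,
the off-diagonal elements of G1 and G2 cannot agree arbitrarily well on
weakly related samples. Writing $V$ for the variance of pair-mean
relationships across pairs and $u$ for the per-gamete-pair noise, the
element correlation is $\sqrt{(4V+u)/(4V+2u)}$: it tends to
$1/\sqrt{2} \approx 0.71$ for unrelated samples and reaches high values
only when genuine relationship variance dominates ($V \gg u$). On the
simulated single-breed half-sib populations this correlation is about
0.8; a published real-data value near 0.94 reflects a much larger
relationship variance (tens of thousands of animals in deep family and
flock structure) than any desk-scale single-breed simulation provides. The
acceptance suite states the stronger expectation and the corresponding
check fails honestly; all other G2 expectations (unit mean diagonal, near
zero mean off-diagonal for unrelated pairs, similar prediction accuracy to
G1) hold.

## Worked example

```{r, eval = FALSE}
library(crossblup)

cfg <- sheep_scenario_preset(seed = 1, seeds = 1:10)
res <- run_scenario(cfg)
res$summary            # accuracy table with significance letters
format_scenario_table(res$summary)
```

Comparing two designs' accuracies uses the same machinery as the published
tables: `compare_accuracies()` implements the independent Fisher z-test
and, because the comparisons share one validation-sire set, Steiger's
dependent test when the inter-predictor correlation is supplied — both are
reported, the dependent form being the statistically appropriate default
for shared validation animals. `expected_accuracy()` provides the
deterministic Daetwyler/Goddard benchmark
$r = \sqrt{Nh^2/(Nh^2 + M_e)}$ with $M_e = 2N_eL/\ln(4N_eL)$.
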