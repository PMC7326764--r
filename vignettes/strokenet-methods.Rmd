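---
title: "Methods: integrative genetic analysis of ischemic stroke risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative genetic analysis of ischemic stroke risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strokenet analyzes a case-control candidate-gene study of ischemic stroke
(IS) at three levels: single-locus quality control and association, causal
mediation through clinical risk factors, and two systems-level interaction
analyses — SNP–SNP epistasis by multifactor dimensionality reduction (MDR)
and a shared-miRNA competing-mRNA (ceRNA) network. This vignette documents
the models, the defaults and why they were chosen, the numerical decisions,
and what the synthetic-data generators do and do not emulate.

## Cohort and codings

The cohort is a retrospective case-control sample (defaults 507 cases / 503
controls, matching a typical single-center IS study) genotyped at 14
candidate SNPs in RNLS, ALOX5AP, CD137, KALRN and SOCS1, with clinical risk
factors per subject: BMI (kg/m²), systolic/diastolic blood pressure (mmHg),
glucose, total cholesterol, triglycerides, HDL and LDL (mmol/L), plus age,
sex, smoking and drinking. Genotypes are stored as minor-allele dosages
0/1/2; the minor allele is defined by observed frequency in the dataset
(ties broken lexicographically by allele string), because candidate-SNP
panels rarely come with a guaranteed reference orientation. Missing dosages
are excluded pairwise per analysis; no imputation is attempted, the
conservative default for a 14-SNP panel.

`recode()` maps dosages onto the genetic models used throughout: additive
(0/1/2), dominant (carrier of the minor allele vs not), recessive
(homozygous minor vs rest), or a 3-level genotypic factor. Dominant is the
package-wide default contrast because two-group genotype pooling (e.g.
"GG + AG vs AA") is how candidate-gene association results are usually
reported for this panel.

## Hardy-Weinberg QC

`hwe_test()` is the Pearson goodness-of-fit chi-squared test of observed
genotype counts against (p², 2pq, q²) at the estimated allele frequency, 1
degree of freedom. Monomorphic SNPs are returned with chi2 = 0, p = 1 and a
flag rather than an error, so scans over panels do not abort. One property
worth knowing: in a case-control sample, a locus associated with the
outcome is *expected* to deviate from equilibrium in the pooled sample even
when the source population is in HWE — ascertainment enriches carriers
among cases. The analysis scripts therefore also run the scan on controls
only, the textbook QC.

## Association scans

The association between a coded genotype and a risk factor is
"correlation" in the loose sense; concretely the package uses:

* binary coding × continuous factor — point-biserial correlation test
  (identical p to the two-sample t and to linear regression on the coding);
* genotypic coding × continuous factor — one-way ANOVA F (identical p to
  regression on the 3-level factor);
* any coding × binary factor (smoking, drinking, subtype) — Pearson
  chi-squared on the contingency table, uncorrected by default with a
  `yates` flag, since uncorrected is what most genetics software reports.

These choices make every continuous-factor p equal to the corresponding
linear-model p, which is the most defensible reading of an unadjusted
"correlation method". No covariate adjustment is applied in scans, and raw
p-values are reported; a Benjamini–Hochberg column is available via
`adjust = "BH"` but off by default, since the scan is exploratory and
single-locus results in this design are conventionally reported raw.

## Causal mediation

For a pathway genotype T → risk factor M → outcome Y the package fits two
parametric models on complete cases:

* mediator model: `M ~ T (+ X)`, Gaussian linear;
* outcome model: `Y ~ T + M (+ X)`, logistic for the binary IS/subtype
  outcome (linear for continuous outcomes).

Effects are computed by the quasi-Bayesian Monte-Carlo algorithm:
`nsim` parameter vectors are drawn from each model's asymptotic normal
(mean = MLE, covariance = estimated vcov; the mediator residual SD is held
at its estimate), potential mediators `M(0), M(1)` are simulated per draw
(linear predictor plus Gaussian noise), and the four potential-outcome
expectations are averaged over subjects on the risk-difference scale.
Writing `Y(t, M(t'))` for the expected outcome at treatment `t` with the
mediator drawn under arm `t'`:

* ACME(t) = mean\[Y(t, M(1)) − Y(t, M(0))\],
* ADE(t) = mean\[Y(1, M(t)) − Y(0, M(t))\],

and the reported ACME/ADE average the two arms, so ACME + ADE equals the
total effect *exactly within every draw* — the suite asserts this to
1e-10. Identification rests on sequential ignorability (treatment and
mediator as-if randomized given covariates); no sensitivity analysis for
that assumption is provided.

Defaults and their reasons:

* `nsim = 1000` with percentile intervals — standard for quasi-Bayesian
  mediation; the Monte-Carlo p is `2·min(P(draw ≤ 0), P(draw ≥ 0))`
  floored at `1/(nsim+1)` so p = 0 is never reported.
* treatment contrast 0 vs 1 on the dominant coding (flag for 0 vs 2
  additive), matching the dominant pooling used in the association stage.
* covariates default to none — the unadjusted two-model form; age/sex can
  be passed explicitly.
* proportion mediated = median of draw-wise ACME/total ratios, clipped to
  \[−1, 2\] with an out-of-range flag, and flagged unstable when the total
  effect is numerically zero in more than 10% of draws: the ratio is not a
  well-behaved statistic when the total effect is near zero.

Two numerical points. First, `glm` does not always emit its separation
warning on separated designs (we observed converged fits with fitted
probabilities at the boundary), so the outcome fit is additionally declared
separated when any fitted probability is below 1e-8 or above 1 − 1e-8, and
the error advises reducing the model. Second, a calibration fact that
shapes the test suite: when *both* paths are null (a = 0 and b = 0), any
product-structured mediation test is super-conservative — the rejection
rate at the 5% level is essentially zero, the familiar behavior of
product-of-coefficients tests at the null cone. Type-I-error calibration
is therefore run at the boundary null that matters in practice — treatment
randomized, a ≠ 0, b = 0, so the true ACME is exactly zero but the
statistic is non-degenerate — where the measured rejection rate at n = 250,
reduced nsim = 100, 500 replicates, is ~0.04.

## MDR

For an attribute subset of k SNPs (k ≤ 4; the 14-SNP panel gives at most
C(14,3) = 364 subsets at k = 3), `mdr_fit()` forms the 3^k multilocus
genotype table and labels each observed cell high- or low-risk by whether
its case:control ratio reaches T = total cases / total controls. Ties are
labeled high, and a cell with cases but no controls is high — the
canonical "≥ threshold" rule. The labeled cells pool into one 2×2 table
(high/low × case/control) from which the package reports the odds ratio,
a Woolf log-interval `exp(ln OR ± 1.96·√Σ1/cell)` (Haldane–Anscombe +0.5
on all cells only when a zero occurs, flagged), and an uncorrected Pearson
chi-squared p. Accuracy is balanced accuracy — mean of sensitivity and
specificity treating high-risk as predicted case — which coincides with
plain accuracy at 1:1 case:control but stays honest on imbalanced subtype
subsets.

`mdr_search()` evaluates every subset of each size by stratified 10-fold
cross-validation with one shared fold assignment: the labeling is learned
on each 9/10, tested on the held-out 1/10, and genotype cells unseen in
training are predicted low-risk. Within each fold the subset with the best
training accuracy is that fold's selection; cross-validation consistency
(CVC) counts how many folds select a subset. Best-per-size is by mean
testing accuracy; the overall winner is best testing accuracy with CVC as
tie-break. The substitution (permutation) test permutes the labels and
re-runs the *entire search* per permutation, `p = (1 + #{perm ≥ obs}) /
(n_perm + 1)`; at least 19 permutations are required so that α = 0.05 is
resolvable. Folds that come out single-class trigger a logged refold under
a new derived seed.

The entropy graph reports, in bits and as % of the class entropy H(C):
per-SNP information gain IG(A;C) = H(C) − H(C|A), and per-pair interaction
gain IG(A,B;C) = I(A,B;C) − I(A;C) − I(B;C) — positive means synergy,
negative redundancy (duplicated SNPs give exactly −I(A;C)). Implementation
uses the conditional-entropy decomposition; the suite checks it against
direct mutual-information summation to 1e-12. The interaction dendrogram
clusters SNPs by average linkage on d = 1/(synergy − min synergy + ε),
ε = 1e-6, so the most synergistic pairs join first; it is exported as
Newick.

## Competing-mRNA network

Target predictions arrive as a (miRNA, gene, energy) table; pairs with
predicted binding free energy above −20 kcal/mol are dropped on load (the
conventional reliability filter; a table without an energy column passes
through untouched). For two genes targeting t and n of the map's m miRNAs
and sharing r of them, the competition p-value is the upper-tail
hypergeometric probability

p = 1 − Σ_{i=0}^{r−1} C(t,i)·C(m−t,n−i) / C(m,n),

computed in log space via log-gamma binomial coefficients so it is stable
at m in the hundreds; r = 0 returns exactly 1. Only gene pairs sharing at
least one miRNA are tested (all others have p = 1 by construction), and
when focal (seed) genes are given only seed-incident pairs are tested —
the five-candidate-gene-centric design. Edges are kept at raw p < 0.05 by
default; no multiple-testing correction, with BH available downstream.
The suite verifies the tail against an independent hypergeometric CDF to
1e-12 and checks that null-map edge p-values are super-uniform.

Topology: degree; betweenness normalized by (N−1)(N−2)/2; closeness
computed within connected components with the Wasserman–Faust reachability
correction ((n_c−1)/Σd · (n_c−1)/(N−1)), singletons 0 — so values remain
comparable on disconnected graphs. Rankings use minimum-tie ranks for
display, but the top-5 intersection admits a tied group only if the whole
group fits (max-tie rule); otherwise a large tie at the boundary floods
the head of the list and the intersection degenerates (on a star graph
every leaf would count as "top 5"). `powerlaw_fit()` is the conventional
least-squares line on the log10 degree–frequency histogram, a diagnostic
of scale-free shape, not a rigorous tail estimator.

Over-representation (`ora()`) is the upper-tail hypergeometric test of a
query list against GMT gene sets intersected with a stated universe. Gene
sets are taken as provided — no GO DAG propagation; if ancestor
propagation is wanted, it must be baked into the GMT.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, under the
statistical structure the analyses assume:

* `simulate_genotypes()` — dosages at stated MAFs under exact HWE,
  independent across SNPs and subjects.
* `simulate_cohort()` — the retrospective design: a source population with
  risk factors from independent truncated normals at textbook clinical
  means, planted pathways M = μ + a·coded(T) + noise and
  logit P(case) = β₀ + c′·coded(T) + b·(M − μ), sampled by rejection until
  the exact case/control counts are reached. The mediator enters the
  outcome model centered at its null mean, so β₀ is the log-odds at the
  mediator mean for non-carriers.
* `simulate_epistasis()` — planted SNPs under HWE with case status drawn
  from a k-locus penetrance table; `xor_penetrance()` gives the
  checkerboard table whose single-locus margins are flat at MAF 0.5 (pure
  epistasis).
* `simulate_target_map()` — genes draw targets uniformly; planted modules
  share a fixed miRNA block.

Deliberately *not* emulated: linkage disequilibrium and haplotype
structure, realistic covariance among lipids/BP/glucose, population
stratification, genotyping error, sequence-level miRNA biology. Passing
tests therefore certify the statistical machinery — calibration, oracle
equivalence, planted-signal recovery — not robustness to the
correlational structure of real cohorts. Every generator is a pure
function of its parameters and a mandatory seed; one master seed is
expanded per sub-task by an integer hash so streams are independent and
the whole pipeline is bit-reproducible.

## Problem sizes

The suite and the reproduction script run at sizes chosen to make their
statistical assertions sharp while staying desk-scale: HWE calibration at
n = 1010 subjects × 1000 replicates; mediation type-I at n = 250 × 500
replicates with nsim = 100; planted-XOR recovery at n = 1600 over 20
seeds; oracle-equivalence sweeps at 200 random instances (MDR) and 50
random graphs (centralities); edge-test calibration at 2000 null pairs.
The full suite completes in about two minutes on one core.

## Known limitations

* Mediation assumes sequential ignorability and correctly specified
  parametric component models; no sensitivity analysis is provided.
* The proportion mediated is unstable when the total effect is near zero;
  it is clipped and flagged, not rescued.
* MDR's exhaustive search is capped (default 5000 subsets); the package
  is not a GWAS-scale epistasis scanner.
* The power-law fit is the conventional log-log regression, adequate as a
  diagnostic but not a maximum-likelihood tail estimate.
* The ceRNA stage consumes target predictions; it does not predict
  targets, and database-version-dependent counts are out of scope.
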