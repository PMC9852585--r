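---
title: "Methods: phenotype-imputation-boosted GWAS on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-imputation-boosted GWAS on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(proxygwas)
```

# The problem

Gold-standard body-composition phenotypes (DXA-style measurements) are
expensive, so they exist for only a small subset of a biobank cohort, while
cheap anthropometric proxies (weight, BMI, impedance-style measurements)
exist for everyone. `proxygwas` implements the resulting study design
end-to-end on synthetic data with known ground truth:

1. fit a linear imputation model for the expensive trait from the cheap
   proxies in the measured subset (per sex),
2. impute the trait across the full cohort and run GWAS on the imputed
   values at full-cohort scale,
3. adjust the genome-wide significance level for the effective number of
   correlated analysis traits,
4. cluster significant variants into loci, filter out known associations,
   and annotate candidate genes,
5. predict replication power, test replication with one-sided P values,
   Benjamini–Hochberg FDR and a binomial sign test, and
6. probe whether a GWAS signal and an eQTL signal share one causal variant
   (Wakefield ABFs + posterior colocalisation; SMR + HEIDI).

Because every cohort is simulated, each analysis answer can be compared to
the generating truth, which is what the test suite does.

# Generative model

## Latent factor and phenotypes

For individual $i$ with genotype dosages $g_{ik} \sim \mathrm{Binom}(2,
p_k)$ (Hardy–Weinberg, linkage-free panel) and covariates $z_i$ (age
$\sim U(40, 70)$, batch $\in \{1..5\}$, two standard-normal PCs), sex
stratum $s$:

$$A_i = \mu_s + \sum_k \delta_k b_k (g_{ik} - 2p_k) + z_i'\gamma_A +
\varepsilon_{A,i}$$

$$x_{ij} = c_s \lambda_j A_i + z_i'\gamma_x + \varepsilon_{x,ij}
\qquad (\text{proxies } j = 1..J)$$

$$y_i = A_i + \sum_k (1-\delta_k) b_k (g_{ik} - 2p_k) + z_i'\gamma_y +
\varepsilon_{y,i} \qquad (\text{target})$$

$A$ is a latent adiposity factor; $b_k$ are per-allele causal effects;
$\delta_k \in [0,1]$ is the *mediation fraction* — the part of the genetic
effect on the target that flows through the factor, and hence through the
proxies. With $\delta_k = 1$ the proxies carry the whole genetic signal and
imputation transfers it to the full cohort; with $\delta_k = 0$ the imputed
phenotype carries none of it, which is the attenuation mode the tests
measure. With `positive_scale = TRUE` all phenotypes are mapped onto a
positive measurement scale as $\exp(\mu + s \cdot \text{value})$ (defaults
$\mu = 3$, $s = 0.25$), so the analysis cascade's log step recovers the
latent scale up to an affine map.

## What the simulator emulates, and what it does not

Emulated: a measured subset nested in a large cohort, sex-specific proxy
loadings and factor shifts, covariate structure (age, batch, PCs), variant
info scores, per-variant missing dosages, a replication cohort drawn from
the same variant panel with new individuals.

Not emulated: linkage disequilibrium between panel variants (the cohort
panel is LD-free by design, so locus clustering is exercised on positions,
not on correlated dosages — LD enters only in the summary-statistic
colocalisation module), population stratification beyond the two synthetic
PCs, genotype uncertainty beyond the info score annotation, relatedness,
and non-linear proxy–target relationships.

## Default parameters

Defaults in `sim_config()` describe a mid-size study: `n_total = 20000`,
`n_measured = 1000`, `m_variants = 500`, 5 causal variants with per-allele
effect 0.25 and mediation fraction 1, 3 proxies with loadings (0.9, 0.8,
0.7) and noise SD 0.5, factor noise SD 1, target noise SD 0.5, female
loading scale 1.15 and factor shift −0.3, MAF range (0.05, 0.5). These are
study conditions, not tuning knobs: tests that need other regimes (a 90:1
cohort-to-subset ratio for the power-transfer property, a latent-scale
configuration for analytic comparisons) override them explicitly. The
replication cohort reuses the variant panel and draws `n_replication`
(default 2000) new individuals from a seed offset of the main seed
(+500009), so discovery and replication are independent given the panel.

## Analytic imputation accuracy

`simulate_cohort()` records a `TruthRecord` with the theoretical imputation
$R^2 = \Sigma_{xy}'\Sigma_{xx}^{-1}\Sigma_{xy} / \mathrm{Var}(y)$, computed
from the model's covariance algebra (including the covariate covariance
$\mathrm{diag}(75, 2, 1, 1)$ and the marginal genetic contributions). It is
defined on the latent (log) scale; because the positive-scale map is a
fixed exponential, the log step of the analysis cascade makes the empirical
$R^2$ comparable to it, and the tests verify convergence at $n = 50{,}000$.

# Analysis methods

## Preprocessing cascade

Per sex stratum: natural log (non-positive values excluded, reason
`log-undefined`), 6 SD trim, OLS residualisation on covariates (one-hot for
categoricals; rank deficiency is an error), inverse rank-normal transform
with the Blom offset $\Phi^{-1}((r - 3/8)/(n + 1/4))$ and average ranks for
ties, 4 SD trim, then strata are merged. Trimming is *single-pass*: each
trim uses the mean/SD of the currently included values once and does not
iterate. Every excluded row carries a reason code. A stratum whose log
values are exactly constant is rejected before residualisation with an
error naming the stratum, because residualisation would convert the exact
ties into floating-point noise and hide the degeneracy from the
rank-normalisation guard.

## Association engine

Per-variant simple regression in closed form: $\hat\beta =
S_{gy}/S_{gg}$, $\mathrm{se} = \sqrt{\mathrm{RSS}/((n-2) S_{gg})}$, P from
the $t_{n-2}$ distribution floored at $10^{-300}$. Missing dosages are
mean-substituted per variant and counted. Variants fail with reasons at
MAF < 0.001, info < 0.4, or zero dosage variance. The implementation is
vectorised over variants; `lm()` is the independent oracle in the tests,
never part of the engine.

## Multiple testing

The effective number of tests over the analysis-trait correlation matrix
uses the Li–Ji estimator $M_\mathrm{eff} = \sum_\ell [\mathbb{1}(\lambda_\ell
\ge 1) + (\lambda_\ell - \lfloor \lambda_\ell \rfloor)]$ by default, with
Nyholt's $1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)$ also reported. The
adjusted threshold divides $5\times10^{-8}$ by the *ceiling* of the chosen
estimate, so four effective traits give $1.25\times10^{-8}$.

## Locus discovery

Significant variants (across all analysis traits, best P per variant) are
chained per chromosome by single linkage with a 1 Mb gap; the lead variant
carries the locus minimum P. Known-association filtering flags loci whose
lead falls within 1 Mb of a catalogue entry or whose lead replicates at
P < $10^{-12}$ in a reference scan; the remainder are novel. Gene
annotation lists genes whose span intersects the closed ±500 kb window
around the lead, ordered by distance (overlapping genes first).

## Replication

The predicted replication standard error for a standardised trait is
$1/\sqrt{2 n f (1-f)}$; the expected replication P is the upper-tail
normal probability at the expected $|z|$ (an open design question resolved
as the one-sided tail, which reproduces the published magnitudes). Loci
pass to replication when that expected P is below 0.05. Observed
replication uses the one-sided P in the discovery direction,
Benjamini–Hochberg FDR at 0.1 (via `stats::p.adjust`), and a one-sided
exact binomial sign test (via `stats::binom.test`) on direction
consistency; a replication effect of exactly zero counts as inconsistent.

## Colocalisation

Wakefield's log approximate Bayes factor is $\tfrac12[\log(1-r) + r z^2]$
with $r = W/(\mathrm{se}^2 + W)$ and prior SD $\sqrt W = 0.15$. Posterior
probabilities for H0–H4 enumerate single-causal configurations with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, computed in log space
(log-sum-exp; the H3 sum uses a log-difference to subtract the shared
configurations); H4 > 0.75 declares colocalisation. Note that only the
H1 : H4 and H2 : H4 posterior ratios are invariant to a common scaling of
the priors — H3's weight is $p_1 p_2$ and scales quadratically.

SMR tests the mediated effect $b_{xy} = \hat\beta_\mathrm{GWAS} /
\hat\beta_\mathrm{eQTL}$ at the top eQTL SNP with $T = z_g^2 z_e^2 /
(z_g^2 + z_e^2)$ against $\chi^2_1$. HEIDI compares $b_{xy}$ at
surrounding SNPs ($r^2$ with the top SNP in $[0.05, 0.9]$, at most 20;
fewer than 3 means no test) to the top-SNP value, with the delta-method
covariance of the differences derived from the LD matrix; the sum of
squared standardised differences is referred to its weighted-chi-square
null distribution.

## Numerical choices

* **Imhof tail evaluation.** The weighted-chi-square tail
  $P(\sum_\ell \lambda_\ell \chi^2_1 > q)$ uses Imhof's integral
  $\tfrac12 + \tfrac1\pi \int_0^\infty \sin\theta(u) / (u\,\rho(u))\,du$.
  The integrand oscillates with slowly decaying amplitude, so a single
  adaptive quadrature over $(0, \infty)$ is unreliable; the implementation
  integrates up to the first phase zero past the point where the phase is
  provably monotone, then sums one integral per half period and collapses
  the alternating series by iterated averaging (Euler transformation).
  This matches closed-form $\chi^2_1$ and $\chi^2_2$ tails to about
  $10^{-12}$. A non-positive statistic returns P = 1.
* **Ties and floors.** Rank normalisation uses average ranks for ties;
  GWAS P values are floored at $10^{-300}$; posterior and tail
  probabilities are computed in log space to avoid underflow.
* **Determinism.** `set_sim_seed()` fixes the RNG kind
  (Mersenne-Twister / Inversion / Rejection), so a `sim_config()` seed
  reproduces a cohort bit-for-bit across sessions.

# The pipeline and its scale

`run_pipeline(run_config(...))` chains all stages: simulate → impute →
three analysis traits (the imputed target plus two composite indices,
target/proxy1 and target/proxy2²) preprocessed and GWAS'd on the
non-measured individuals → measured-subset GWAS for the power comparison →
effective-test adjustment → locus discovery and novelty filtering →
replication against a freshly simulated replication cohort → an SMR/HEIDI
and colocalisation demonstration on a 50-SNP summary region. Every
threshold lives in `run_config()` (genome-wide α $5\times10^{-8}$, MAF
0.001, info 0.4, 6/4 SD trims, 1 Mb locus gap, ±500 kb gene flank,
reference exclusion P $10^{-12}$, FDR 0.1, expected replication P 0.05,
H4 0.75). The test suite exercises problem sizes from 6-individual
hand-checkable cases through null calibrations at 2000 × 2000 and a
20,000-individual attenuation sweep; the full default configuration runs
in well under a minute on one CPU.

# Limitations

* The cohort panel is LD-free, so fine-mapping-style behaviour inside a
  locus is out of scope; LD appears only in the AR(1) summary-statistic
  regions used for colocalisation.
* Imputation is linear and homoscedastic per sex; no shrinkage, no
  non-linearities, no missing-proxy imputation (incomplete rows are
  flagged, not filled).
* The effective-sample-size rule $N_\mathrm{eff} = r^2 N$ is the standard
  first-order approximation and is reported, not derived, here.
* Single-causal-variant assumptions underlie both the coloc enumeration
  and SMR; the simulator's distinct-causal scenario places the two causal
  variants a few SNPs apart (low but non-zero LD) precisely because fully
  unlinked variants would give HEIDI nothing to test.
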