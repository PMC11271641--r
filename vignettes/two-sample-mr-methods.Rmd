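---
title: "Methods: two-sample Mendelian randomization from summary statistics"
author: "mrtwosample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwosample)
```

# The model

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate the causal effect of an exposure on an
outcome from two independent GWAS. For each instrument SNP $j$ we observe
the SNP-exposure association $\hat\beta_{Xj}$ with standard error
$\sigma_{Xj}$ from one study and the SNP-outcome association
$\hat\beta_{Yj}$ with standard error $\sigma_{Yj}$ from another. Under the
three instrumental-variable assumptions — the variant is (1) robustly
associated with the exposure, (2) affects the outcome only through the
exposure, and (3) is independent of confounders — each SNP provides a Wald
ratio estimate of the causal effect $\theta$:

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}}, \qquad
  \mathrm{se}(\hat\theta_j) \approx \frac{\sigma_{Yj}}{|\hat\beta_{Xj}|}.$$

The ratio standard error is the first-order delta-method approximation,
which conditions on the observed exposure effect; the second-order term
(of size $\theta^2\sigma_{Xj}^2/\hat\beta_{Xj}^2$) is negligible for the
strong instruments this package targets (F well above 10) and is omitted
so the whole estimation surface is a deterministic function of the input
table.

For binary traits the effects are log odds ratios, so $\exp(\hat\theta)$
is reported as an odds ratio per unit (log-odds) increase in exposure
liability.

# Instrument selection

`filter_significant()` applies a strict `p < threshold` comparison. The
conventional genome-wide threshold is $5\times10^{-8}$; for exposures
whose GWAS yields too few hits (small case collections such as panic
disorder or autism) the usual relaxation to $5\times10^{-6}$ is a
per-exposure configuration choice, with the caveat that weaker thresholds
admit weaker instruments.

`ld_clump()` implements the standard greedy procedure (rank by p-value,
keep the best SNP, discard correlated neighbours within the window,
repeat) with defaults $r^2 < 0.001$ within 10{,}000 kb. Rather than
bundling a reference panel, linkage is an *injected dependency*: a
pairwise `snp_a, snp_b, r2` table. This keeps the package free of
downloads and makes clumping exactly reproducible and testable; the cost
is that pairs absent from the table must either be an error (default) or
be assumed independent (`strict = FALSE`). Ties in p-value are broken by
lexicographic SNP id so the output never depends on input row order.

Instrument strength uses the variance-explained approximation
$R^2_j = 2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)\hat\beta_{Xj}^2$ and
$F_j = R^2_j(n-k-1)/\big(k(1-R^2_j)\big)$ with $k = 1$ per SNP
(a joint F over the instrument set is available through
`joint_instrument_strength()`). $F \le 10$ is flagged weak — the
threshold is strict, so $F = 10$ exactly counts as weak. Records without
an allele frequency are flagged unscorable rather than erroring, since
many older GWAS tables omit frequencies.

Confounder screening (in the source literature, a PhenoScanner-style
lookup) is represented by a user-supplied exclusion list of SNP ids with
reasons; the package never queries external services.

# Harmonization

`harmonize()` matches SNPs by identifier only (no chr:pos fallback) and
re-expresses the outcome association relative to the exposure's effect
allele: swapped allele labels flip the sign of $\hat\beta_{Yj}$ and
complement the allele frequency, and pairs that match only after strand
complementing are aligned the same way. Palindromic variants (A/T, C/G)
are unresolvable from labels; they are aligned by allele-frequency
concordance, and dropped as ambiguous when *either* trait's minor-allele
frequency is within `palindrome_eaf_window` (default 0.08, i.e. EAF in
0.42–0.58) of 0.5 or missing. The window is applied to both traits, not
just the exposure, because a near-0.5 frequency on either side makes
concordance uninformative. Instruments missing from the outcome are
dropped and logged — no proxy-SNP search is attempted. Duplicate ids
within one trait keep the lowest-p row. Every exposure SNP appears in the
result exactly once with an `action_taken` label, so
kept + flipped + dropped categories always account for the full
instrument list.

# Estimators

**IVW.** With weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$,
$\hat\theta_{IVW} = \sum w_j\hat\theta_j / \sum w_j$ and the fixed-effect
standard error is $(\sum w_j)^{-1/2}$. Heterogeneity is measured by
Cochran's $Q = \sum w_j(\hat\theta_j - \hat\theta_{IVW})^2$ on $k-1$
degrees of freedom. The random-effects variant is *multiplicative*: the
fixed-effect standard error is scaled by $\max(1, \sqrt{Q/(k-1)})$,
which leaves the point estimate unchanged and never shrinks the standard
error below the fixed-effect one. `model = "auto"` selects fixed effects
when the Q-test p-value exceeds 0.05 and random effects otherwise — the
conventional decision rule. A single instrument degenerates to its Wald
ratio.

**MR-Egger.** Weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with an intercept and weights $1/\sigma_{Yj}^2$, after
orienting every SNP so $\hat\beta_{Xj} \ge 0$ (without this the
intercept, the average directional pleiotropic effect, is not
identified). The slope is consistent under InSIDE (instrument strength
independent of direct effects). Standard errors use multiplicative
overdispersion with the residual scale floored at 1; p-values use
$t_{k-2}$, while confidence intervals use the normal 97.5th percentile
1.959964 — a deliberate asymmetry that matches common reporting practice
and keeps CI construction uniform across methods.

**Weighted median.** Per-SNP ratios are sorted and the weighted empirical
quantile function, defined on the cumulative-weight midpoints
$p_j = (S_j - w_j/2)/S_k$, is linearly interpolated at $p = 0.5$. The
estimator is consistent while valid instruments carry more than half the
total weight. Because interpolation blends adjacent ratios, a SNP
carrying just over 50% of the weight yields the median *near* (not
bit-exactly at) its ratio, converging as its weight grows. The standard
error is a parametric bootstrap (default 1000 resamples): exposure and
outcome effects are redrawn from normal distributions centred at the
observed values with the reported standard errors, and the estimator is
recomputed; a seed argument makes this reproducible.

All methods report $\mathrm{OR} = e^{\hat\beta}$ with the 95% Wald
interval $e^{\hat\beta \mp 1.959964\,\mathrm{se}}$; rendered tables round
OR and CI to two decimals while machine-readable outputs keep full
precision.

# Sensitivity diagnostics

*Leave-one-out* re-estimates the effect excluding each SNP in turn
(IVW by default) and flags exclusions that change the qualitative
conclusion, i.e. the sign category (significantly positive / negative /
null at 95%) of the reduced estimate differs from the full set's.

*Funnel data* returns ratio-versus-precision coordinates; "approximate
symmetry" is operationalized as the inverse-variance-weighted skewness of
the ratios about the IVW estimate, near zero for symmetric sets. Plot
rendering is left to the user (the data frame plots directly with base
graphics or ggplot2).

*MR-PRESSO.* The global test builds each SNP's residual against its
leave-one-out IVW prediction: with
$\hat\theta_{(-j)}$ the IVW estimate excluding SNP $j$, the observed
statistic is
$\mathrm{RSS} = \sum_j (\hat\beta_{Yj} -
\hat\theta_{(-j)}\hat\beta_{Xj})^2/\sigma_{Yj}^2$. The null distribution
comes from parametric simulation: outcome effects are redrawn around the
leave-one-out predictions with the observed standard errors, and the
leave-one-out machinery is re-applied to every simulated data set. The
Monte-Carlo p-value is $(1 + \#\{\mathrm{RSS}^{sim} \ge
\mathrm{RSS}^{obs}\})/(n_{sim}+1)$, so it is bounded below by
$1/(n_{sim}+1)$. Per-SNP contributions are compared with their own
simulated distributions and Bonferroni-adjusted over $k$; SNPs below the
0.05 threshold are outliers, and IVW estimates before and after their
removal are reported. The distortion test compares the observed shift in
the IVW estimate against shifts obtained by removing random SNP subsets
of the same size — a simplified version of the original bootstrap that
preserves its interpretation. Defaults ($n_{sim} = 1000$,
Bonferroni-adjusted 0.05) follow the method's published practice; at
least 4 instruments are required, and smaller sets are reported as "not
applicable" rather than silently skipped.

# Multiplicity

`bh_fdr()` and `bonferroni()` wrap `stats::p.adjust` behind the module
surface; the test suite verifies both against a hand-written step-up
oracle. The hypothesis family for a multi-exposure, multi-outcome study
is genuinely a design choice. The default here is *per outcome across
exposures* ($m$ = number of exposures): for a six-exposure study the
adjusted values this produces agree, within the rounding of printed raw
p-values, with the arithmetic of published per-outcome correction tables
(e.g. a raw $p = 0.18$ ranked second of six gives
$0.18 \times 6/2 = 0.54$). `correction_table(family = "exposure")` and
`family = "all"` are available for other designs. Adjustment always runs
on unrounded raw p-values; rounding happens only in the rendered table.

# The synthetic-data generator

`simulate_two_sample()` emulates the summary-statistics structure of a
two-sample study with known ground truth. For SNP $j$:

* $\mathrm{EAF}_j \sim U(0.1, 0.9)$, true effect
  $\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$ with defaults
  $\mu_\gamma = 0.15$, $\sigma_\gamma = 0.05$;
* $\sigma_{Xj} = 1/\sqrt{2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)\,n_X}$, the
  large-sample standard error of a per-allele regression coefficient for
  a standardized trait, and
  $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$;
* $\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$
  analogously under $n_Y$, where the pleiotropic effect $\alpha_j$ is 0
  for valid instruments and, for the invalid fraction, drawn
  $N(0, \sigma_\alpha^2)$ (balanced) or $N(\mu_\alpha, \sigma_\alpha^2)$
  (directional) independently of $\gamma_j$, so InSIDE holds by
  construction.

Case/control imbalance is absorbed into the effective sample size
$n_{\mathrm{eff}} = 4/(1/n_{\mathrm{cases}} + 1/n_{\mathrm{controls}})$.
The defaults emulate the smallest realistic configuration of a
psychiatric-exposure / cancer-outcome study: 13 instruments, an exposure
cohort of 2,248 cases / 7,992 controls
($n_{\mathrm{eff}} \approx 7{,}017$) and a biobank outcome with 636
cases / 455,640 controls ($n_{\mathrm{eff}} \approx 2{,}540$). With the
default $\gamma$ distribution this yields per-SNP F-statistics of order
20–100, matching instruments admitted at a relaxed threshold.

What the generator deliberately does **not** emulate: linkage
disequilibrium between instruments (clumping is tested against explicit
$r^2$ tables instead), the binary-liability link between effect sizes and
allele frequencies, winner's-curse selection of instruments, overlap
between the exposure and outcome samples, and population stratification.
Passing calibration tests therefore validates the estimators under the
stated sampling model, not robustness to those additional features of
real GWAS data.

All randomness flows from the single `seed` in the configuration;
identical seeds give bit-identical tables.

# Validation design and problem sizes

The test suite checks, among analytic worked examples and
oracle-equivalence tests, the calibration of the whole chain under the
generator's default study conditions: the fixed-effect IVW rejection rate
at nominal 0.05 over 1,000 null replicates (accepted band 0.03–0.07),
95% CI coverage over 500 replicates (0.93–0.97), mean Egger intercept
against the injected mean pleiotropic effect over 200 directional
replicates, and MR-PRESSO behaviour over 50 replicates of clean and
outlier-contaminated 20-SNP studies. These sizes put Monte-Carlo error
well below the accepted bands while keeping the full suite runnable on a
single CPU in minutes; `scripts/acceptance.R` recomputes the same
quantities from scratch.

# A worked example

```{r example}
sim_x <- simulate_two_sample(simulation_config(seed = 11))
sim_y <- simulate_two_sample(simulation_config(seed = 22, causal_beta = 0))
res <- mr_analysis(sim_x$exposure, sim_y$outcome, p_threshold = 5e-6,
                   n_boot = 200, n_sim = 200, seed = 1)
estimates_table(res$estimates, "exposure", "outcome")[,
  c("method", "n_snps", "or_text", "pvalue")]
res$sensitivity$q_pvalue
```

The two traits are simulated independently (no causal link), so all
three methods should — and here do — report odds ratios whose confidence
intervals span 1.

# Known limitations

* Matching is by SNP identifier only; studies reported on different
  variant nomenclatures need pre-mapping.
* No proxy-instrument search and no standard-error imputation from
  p-values: records lacking required fields are dropped with a log entry.
* The MR-PRESSO distortion test uses the simplified random-subset null
  described above.
* Reverse-direction analyses (outcome as exposure) are out of scope; run
  the pipeline twice with roles exchanged if needed.
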