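---
title: "Methods: consensus screening and downstream analytics in paxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus screening and downstream analytics in paxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paxscreen)
```

## The problem

Acquired paclitaxel resistance in epithelial ovarian cancer is heterogeneous:
resistant cell lines derived in different laboratories, on different
platforms, from different parental lines, disagree substantially about which
genes are up-regulated. A single differential-expression analysis therefore
over-fits the idiosyncrasies of one derivation. `paxscreen` implements a
consensus strategy instead: analyse each sensitive/resistant cohort pair
separately, let each cohort cast a vote, and keep the genes that win votes
in several independent cohorts while never being materially down-regulated
in the rest. Screen hits are then followed downstream — patient survival,
co-expression synergy around an anchor gene, interaction-network filtering —
and the package also covers the quantitative analytics of the validation
assays (dose–response/IC50, resistance index, qPCR fold changes).

Every stage operates on plain tabular inputs (TSV expression matrices with a
sample sheet, GMT gene sets, a scored edge table, plate-reader CSVs), and the
package ships generators that synthesize all of them with known ground
truth, so the full pipeline is testable offline.

## Per-cohort differential expression

Within one cohort pair, expression is first quantile-normalized
(`quantile_normalize()`, the deterministic member of the standard
between-array normalization family; applied per cohort-pair dataset and
never across datasets, since cross-dataset normalization would contradict
the per-cohort analysis design). For each gene the two-arm comparison uses
the empirical-Bayes moderated t-statistic. With per-gene pooled variance
$s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom and design factor
$v = 1/n_1 + 1/n_2$:

$$
\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde{t}_g = \frac{\mathrm{log_2FC}_g}{\tilde{s}_g \sqrt{v}},
$$

with two-sided p-values on $d_0 + d_g$ degrees of freedom. The prior
$(d_0, s_0^2)$ is moment-matched across genes on the log-variance scale:
$d_0$ solves $\psi'(d_0/2) = \max\{0,\ \mathrm{var}(\log s^2) -
\psi'(d_g/2)\}$ and $s_0^2$ comes from the corresponding mean equation.
Numerical conventions, chosen once:

* when the observed log-variances are no more dispersed than sampling noise
  alone, $d_0 = \infty$ and $s_0^2$ is the mean raw-scale variance — all
  genes then share one variance and p-values are normal;
* cohorts with singleton arms on both sides (one sensitive vs one resistant
  profile, common in public cell-line series) have no within-group
  replication at all. These fall back to a global variance estimated as
  $\mathrm{var}(\mathrm{log_2FC})/v$ across genes, which is conservative
  and valid when most genes are null. This is an explicit approximation:
  with $n = 1 + 1$ no method can estimate gene-wise variance;
* p-values are two-sided everywhere; directionality is enforced by the sign
  of the fold change at the screening step, not by one-sided tests;
* no multiple-testing adjustment is applied in the screen (candidacy uses
  raw $p \le 0.05$ by design, because the vote-counting across independent
  cohorts is itself the error control); `stats::p.adjust` can of course be
  applied to any returned table by the user.

The cross-cohort confirmation of a hit uses the ordinary paired t-test
(`paired_t_test()`), pairing each cohort's resistant and sensitive
summaries; all-zero and zero-variance difference vectors are flagged rather
than erroring.

## The consensus screen

With default `screen_config()`:

* a cohort votes *up* for a gene when $\mathrm{log_2FC} \ge 1$ and
  $p \le 0.05$ (both inclusive);
* a gene is a **candidate** when it collects at least 3 votes and satisfies
  $\mathrm{log_2FC} \ge -0.2$ in every measured cohort that did not vote
  (the floor only needs checking in non-voting cohorts, since a voting
  cohort's fold change already exceeds it);
* candidates are ranked by vote count, descending, ties broken
  lexicographically for reproducibility; **resistance genes (PRGs)** are
  candidates whose support is *strictly greater* than the minimum — in a
  seven-cohort design this selects the genes supported well beyond the
  candidacy bar (e.g. supports 7 and 4 against a minimum of 3);
* genes measured in fewer than half the cohorts are excluded from candidacy
  (with a warning); support is always counted over measured cohorts only,
  and unmeasured cohorts are tracked as missing, never as failed votes.

These rules are monotone by construction: raising the fold-change bar or
lowering the p cutoff can only shrink support, and raising the floor can
only shrink the candidate set. The tests assert these properties on random
tables against a brute-force reimplementation.

## Patient-side statistics

Survival analysis is implemented from first principles because the
product-limit/log-rank machinery *is* part of what this package is for:
`median_split()` (ties at the median go to the low group — a recorded
convention, since roughly half-split group sizes matter for the log-rank
test), `km_estimate()` (product-limit estimator, deaths processed before
censorings at tied times), and `log_rank_test()` (observed-minus-expected
deaths with hypergeometric variance at each distinct death time, referred
to $\chi^2_1$). The test suite cross-checks both against the `survival`
package and against a label-permutation reference, and verifies that with
no censoring the estimator reduces exactly to the empirical survival
fraction. Cox modelling is deliberately out of scope — the screen's
survival claims are made with KM + log-rank only.

Correlation (`pearson_correlation()`) and univariate regression
(`ols_univariate()`) delegate to `stats::cor.test()`/`stats::lm()`; the
reported `r_sq` is defined as $r^2$, which in the univariate case is the
model R² identically, and the regression p-value equals the correlation
p-value by the same analytic identity.

## Synergy discovery

Given a patient matrix and an anchor gene (the screen's top survival-
relevant hit), `co_upregulated_genes()` median-splits the patients on the
anchor and reuses the moderated-t machinery for high-vs-low differential
expression, keeping genes with $\mathrm{log_2FC} \ge 0.6$ and $p \le 0.05$.
`triple_intersection()` intersects these with a lipid-metabolism and an
oncological gene set (GMT-backed, user-supplied); `ppi_core_filter()` keeps
the synergy genes with a *direct* interaction edge to the anchor scoring
*strictly above* 0.7 (multi-hop connectivity deliberately does not count,
and a score of exactly 0.7 is excluded), plus the anchor itself;
`lrg_select()` intersects that core with a literature-curated list of nine
lipid-metabolism resistance enzymes (shipped as an editable GMT resource)
and removes the anchor. Gene symbols are uppercased and whitespace-stripped
at every set boundary; no alias resolution is attempted. Edge tables on the
0–1000 integer score convention are auto-detected and rescaled.

## Assay analytics

Viability normalization is the standard blank-corrected ratio. Dose–response
fitting (`fit_4pl()`) uses the decreasing four-parameter logistic
$y = b + (t - b) / (1 + (x/\mathrm{IC50})^h)$ with $h > 0$, fitted by
Levenberg–Marquardt least squares from multiple log-spaced IC50 starts
(best residual sum of squares kept), with bounds $b \ge 0$ and
$t \le 1.2\,\max(y)$ to stabilize the asymptotes. The reported IC50 is the
concentration at the midpoint of the fitted asymptotes (relative IC50).
Zero-dose wells anchor the top asymptote by placement at
$10^{-3} \times$ the smallest nonzero dose (configurable). Monotone
*increasing* dose–response data is rejected. The resistance index is the
plain IC50 ratio of resistant over sensitive and is dimensionless. qPCR
fold changes use $2^{-\Delta\Delta C_t}$ with $C_t$ values validated to
$(0, 45)$; multi-group assay summaries use ordinary one-way ANOVA.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their specification (seed included).

`gen_cellline_panel()` emulates the multi-cohort screening input: log2
baseline means $\sim N(8, 2)$, additive per-cohort batch shifts
$\sim N(0, 0.5)$ by default, planted effects added to resistant arms of
chosen cohort subsets, i.i.d. Gaussian measurement noise (0.3 by default —
the within-arm spread typical of well-behaved array replicates).
`gen_patient_cohort()` emulates a 368-patient tumor cohort: the anchor is a
unit-variance log2 z-score; each synergy gene is
$r\,z_{\mathrm{anchor}} + \sqrt{1 - r^2}\,\varepsilon$ so its population
correlation is exactly $r$; survival is exponential with hazard
$h_0 \exp(\sum_g \beta_g z_g)$ ($h_0 = \log 2 / 1000$ per day, i.e. a
1000-day median at baseline) and independent exponential censoring whose
rate is solved numerically so the expected censored fraction matches the
requested rate (40% by default). `gen_interaction_table()` scores true
anchor partners Uniform(0.75, 0.99) and decoys Uniform(0.10, 0.69),
straddling the 0.7 cutoff.

None of this mimics platform probe effects, RNA-seq count distributions, or
real tumor-cohort marginals; a passing recovery test demonstrates that the
algorithms do what they claim under the stated statistical model, not that
any particular biological dataset will behave as cleanly.

## The deterministic demonstration fixture

`build_paper_fixture()` wires the generators into a fully determined
end-to-end example: seven cohorts with three replicates per arm; one gene
up-regulated (log2FC 3) in all seven cohorts, two in four cohorts, sixteen
more (log2FC 2) in three cohorts each — 19 candidates with PRG supports
7/4/4 — plus decoys that exercise the floor rule (up in three cohorts but
log2FC −0.5 in a fourth), the effect-size bar (log2FC 0.5), and the support
bar (up in two cohorts only). Two constructions make the outcome
deterministic rather than merely probable:

* *p-forcing replicates*: within-arm jitter has SD 0.05, so pooled
  variances are tiny and every planted fold change is significant at
  machine-level p-values, while null fold changes (SD ≈ 0.04) sit far from
  every threshold;
* *balancer genes*: each planted effect is paired with a mirror gene whose
  baseline occupies the planted gene's shifted expression slot and moves
  down by the same amount in the same arms. Each cohort's per-sample value
  distribution is therefore invariant under the planting, and per-cohort
  quantile normalization — which equalizes exactly those distributions —
  passes the planted fold changes through intact.

The patient side wires 18 partner genes to the anchor at correlation 0.8
(high-vs-low fold change ≈ 1.28, comfortably above the 0.6 bar at n = 368)
and an interaction table with partner edges at 0.9 plus decoy edges at 0.5,
at exactly 0.7, off-anchor, and to a non-synergy gene — so the interaction
core has exactly 19 nodes and the literature intersection returns ACACA,
CPT2, FASN, SCD. The discrete outputs are invariant to the fixture's seed;
the seed only moves the jitter.

## Problem sizes and numerical tolerances in the test suite

The suite validates the moderated t against a straight-line formula oracle
(200 genes, 1e-10) and against an independent `limma::eBayes` run; the
log-rank p against a 5000-permutation reference (n = 100, ±0.02); type-I
error of the moderated test on 200 null panels of 2000 genes (0.05 ± 0.01);
prior recovery from 5000 genes drawn at $d_0 = 4$, $s_0^2 = 2$ (within
25%/10%); and log-rank power ≥ 90% over 200 seeds when the high-expression
arm carries a hazard ratio of 2 at n = 368 with 40% censoring. For the
IC50 recovery claim under noise SD 3, the per-seed error is unbiased but
design-limited at ≈ 7.5% relative SD (indistinguishable from a true-start
reference fit), so the 10% bound is asserted on the median over a fixed
30-seed panel — the robust statement of the same property. Quantile
normalization is checked for idempotence at 1e-12 and exact total-sum
preservation.

## Known limitations

* The screen assumes two-group designs within each cohort; no covariates,
  no expression-intensity trend in the variance prior.
* The singleton-arm fallback cannot detect genuinely variance-heterogeneous
  genes; its p-values lean on the null-majority assumption.
* Median-split survival analysis is the only cutpoint supported; optimal
  cutpoint scanning is intentionally absent.
* Gene identity is symbol-string based; cross-platform alias mismatches
  must be resolved upstream.
* The 4PL IC50 is the relative (half-asymptote) IC50; if absolute
  half-maximal inhibition is wanted, compute it from the fitted parameters.
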