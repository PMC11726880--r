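---
title: "Shapley-value differential expression: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shapley-value differential expression: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In case/control transcriptomic comparisons of heterogeneous disorders —
neuropsychiatric conditions are the motivating example — a real expression
change is often present in only a fraction of the patients. Per-gene mean
tests (Welch's t, moderated t) average the affected and unaffected patients
together, and after multiple-testing correction across thousands of genes
they frequently report nothing at all. `cashr` implements an alternative
that asks a different question: not *"do the group means differ?"* but
*"how much does each gene contribute to the abnormal expression observed in
each group, and do those contributions differ between groups?"*

## The model

**Discretization.** For each gene $g$, the control samples define a
reference band: mean $\mu_g$ and standard deviation $\sigma_g$ (sample SD,
$n-1$ denominator) of the control expression on the log2 scale. Every
sample $j$ (cases and controls alike) is coded in two directions:

* over-expressed: $b_{gj} = 1$ iff $x_{gj} \ge \mu_g + \sigma_g$ (inclusive);
* under-expressed: $b_{gj} = 1$ iff $x_{gj} < \mu_g - \sigma_g$ (strict).

The boundary conventions are deliberate and tested: *at or above* flags,
*exactly at* the lower bound does not. Genes with $\sigma_g = 0$ are
non-informative (the band is degenerate) and receive all-zero rows in both
directions rather than flagging everything or nothing vacuously.

**Microarray games.** For one direction and one sample group with $m$
samples, each sample $j$ has a support $sp(j) = \{g : b_{gj} = 1\}$ with
$k_j = |sp(j)|$. A coalition of genes $S$ is worth

$$v(S) = \frac{1}{m}\,\#\{\,j : sp(j) \ne \emptyset \text{ and } sp(j)
\subseteq S\,\},$$

the fraction of samples whose abnormality is entirely explained by $S$.
Samples with empty support still count in $m$: $v$ is a fraction of all
samples in the group, so uninformative samples dilute every gene's value.
By unanimity-game decomposition, the Shapley value of this game has the
exact closed form

$$\Phi_g = \frac{1}{m} \sum_{j\,:\,k_j > 0} \frac{b_{gj}}{k_j},$$

i.e. each sample splits one unit of worth equally among the genes it flags.
The package also ships `shapley_bruteforce()`, an independent oracle that
evaluates the textbook coalition-enumeration definition (all $2^n$
coalitions, $n \le 10$); the test suite requires agreement within 1e-12 on
exhaustive 2×2 ensembles and random small games, and verifies efficiency,
symmetry, dummy-player and monotonicity on thousands of random games.

**The comparison statistic.** Genes are first preselected at raw Welch
p below a stringency $\alpha \in \{0.01, 0.05\}$ (configurable to the
moderated t). For each direction, games are built separately for cases and
controls over the preselected genes, and the statistic is
$d_g = \Phi^{case}_g - \Phi^{ctrl}_g$.

**Bootstrap significance.** Each of $B$ iterations (default 1000) draws,
with replacement, $m_{case}$ pseudo-case columns from the case matrix and
$m_{ctrl}$ pseudo-control columns from the control matrix, recomputes
$d^*_g$, and centers it at the observed $d_g$. The two-sided p-value with
add-one correction is

$$p_g = \frac{1 + \#\{b : |d^*_{gb} - d_g| \ge |d_g|\}}{B + 1},$$

so p-values live on the grid $\{1/(B+1), \dots, 1\}$ and are never zero.
Column draws are shared across genes, preserving gene–gene dependence.

**Why within-group resampling, and why centering.** The resampling unit
and centering were genuinely open design choices, settled by calibration
testing on fully null synthetic data. A pooled-column null (treating case
and control columns as exchangeable) is measurably miscalibrated here, and
the reason is instructive: the coding thresholds are *estimated from the
control samples themselves*, which makes the control flag counts
quasi-deterministic — the threshold adapts to whatever the controls did —
while case flags vary binomially. The groups are therefore not
exchangeable even when no gene is differentially expressed, and a pooled
null over-disperses (measured type-I error ≈ 0.016 at nominal 0.05).
Within-group resampling with centering respects the per-group variance
structure and is what the package implements.

Two residual sources of conservatism remain and are documented rather than
hidden. First, $d$ is lattice-valued (sums of $1/k_j$), so
$|d^* - d| = |d|$ has genuine point mass (for example $d^* = 0$ whenever
no flagged column is redrawn); ties must count as exceedances — that is
what makes $d = 0$ give $p = 1$ by construction — and the tie mass inflates
borderline p-values. Second, the adaptive coding induces negative
dependence among control columns that iid column resampling cannot see.
The acceptance suite measures the consequence honestly: on all-null data
the empirical rate of $p < 0.01$ falls inside [0.005, 0.02], while the rate
of $p < 0.05$ sits near 0.028, conservative of the nominal level. The test
never over-rejects, so reported DEGs do not ride on anti-conservatism.

**Calling rule.** The over- and under-expression games are separate
analyses, as in the protocol this package implements, whose headline
tables report up- and down-regulated counts per side. A gene is
raw-significant (`sig_raw`) when either direction's bootstrap p falls
below the stringency, with `direction` naming the firing side (exact ties
broken by the sign of the log2 mean difference, then "up"). For the
FDR-corrected column a single per-gene p is needed; the package uses the
Bonferroni combination $p_{gene} = \min(1, 2\min(p_{over}, p_{under}))$,
applies Benjamini–Hochberg across the *preselected* genes (they are the
tested family), and flags `sig_fdr` at $q < 0.05$. Fold change is computed
on the log2 scale, $\Delta = \bar{x}_{case} - \bar{x}_{ctrl}$, reported
with the signed convention $FC = 2^{\Delta}$ (or $-2^{-\Delta}$ for
$\Delta < 0$), and filtered strictly: $|FC| > 2$ means strictly greater.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `preselect_alpha` | 0.05 | raw p cutoff | protocol stringencies 0.01 / 0.05 |
| `n_boot` | 1000 | iterations | protocol value; p-grid resolution 1/(B+1) |
| `fc_threshold` | 2 | fold change | protocol filter, strict inequality |
| `fdr_alpha` | 0.05 | BH level | protocol FDR column |
| `seed` | — | integer | fixes resamples; results are bit-reproducible |

## The synthetic generator

`generate_dataset()` emulates the statistical regime the method targets:
per-gene baselines `Normal(baseline_mean, baseline_sd^2)` on log2 scale
(defaults 7 and 1.5, typical of RMA summaries), iid measurement noise
`Normal(0, noise_sd^2)` (default 0.5), and a minority of planted DE genes
(default 2.5%) shifted by `effect_size * noise_sd` in a *fixed-size* random
subset of case samples — `round(penetrance * n_case)` of them. The
fixed-size choice (rather than per-sample Bernoulli carriers) removes
binomial jitter from sensitivity analyses: the planted truth is exact. The
default shape, 12 cases vs 14 controls at 2000 genes, mirrors a small
peripheral-blood case/control series of the kind the method was applied to.
Because both the coding thresholds and the planted shift scale with
`noise_sd`, the benchmark is invariant to its absolute value.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: probe-level structure, batch effects,
covariates, heavy-tailed or correlated noise, and library-specific
artifacts. The pipeline itself makes no attempt at confounder adjustment.

Under the default benchmark (penetrance 0.4, effect 2 noise-SD), the
planted genes shift the case *mean* by only ≈ 0.8 noise-SD spread over the
whole group, so Welch + BH finds essentially nothing, while affected
samples land ≈ 2 SD above the control band and are flagged with high
probability — the contrast the acceptance suite reproduces.

## Numerical choices

* Exceedance comparisons use a 1e-12 absolute slack so float rounding
  cannot flip an exact lattice tie.
* p-values are floored at the smallest positive double; BH input is
  validated to (0, 1].
* Welch with zero variance in both groups: $t = 0, p = 1$ when the means
  agree, $t = \pm\infty$ with floored p when they differ.
* The moderated-t prior $(d_0, s_0^2)$ is fitted by matching moments of
  $\log s^2_g$ (digamma/trigamma), with the trigamma inverted by Newton
  iteration to 1e-8; `prior_df = 0` reproduces the pooled t exactly and
  `prior_df = Inf` the fixed-variance limit. On heteroskedastic data the
  estimates agree with the standard empirical-Bayes reference
  implementation to 1e-10 (tested).
* Genes with zero control SD are excluded from flagging in both
  directions; constant genes are excluded from the variance-prior moment
  fit.
* DEG tables render floats with 6 significant digits, sorted by gene then
  method, so identical analyses give byte-identical files; expression
  matrices are written at 10 significant digits so read/write round trips
  hold to 1e-9.

## Problem sizes in the test suite

The suite exercises the methods at the scales their behaviour is
established: exhaustive 2×2 Boolean matrices plus hundreds of random games
up to 6×6 against the brute-force oracle; thousands of random games for
the axioms; 2000-gene null datasets across 10–20 seeds for calibration and
null end-to-end behaviour at B = 200; and the heterogeneous benchmark
(2000 genes, 12v14, 50 planted effects) across 10 seeds. These sizes give
stable averages for every property asserted while keeping the full suite
under a minute of bootstrap time.

## Known limitations

* Power is intrinsically modest when preselection is driven by a mean
  test: a heterogeneous effect must first survive the Welch screen before
  the game analysis can see it.
* The bootstrap p at the 0.05 level is conservative (see above); the
  package prefers that direction of error.
* Two-group designs only; no covariates, batch terms, or multi-level
  contrasts.
* The Shapley scale depends on the preselected gene universe (supports are
  computed among preselected genes), so $\Phi$ values are comparable
  within one run, not across runs with different preselections.
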