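---
title: "Methods: random-effects meta-analysis of stress transcriptomic contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-effects meta-analysis of stress transcriptomic contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stressmeta` pools per-contrast differential-expression results across
laboratories, platforms, and chronic-stress paradigms. This vignette is the
package's own account of the statistics it implements, the choices that were
genuinely open, and what its validation does and does not establish.

## The data and the model

The unit of input is a *contrast*: one stress-vs-control comparison within a
dataset, exported as a probe-level table of log2 fold changes (Log2FC) with
t-statistics and/or standard errors. A dataset may contribute more than one
contrast (e.g., susceptible vs. control and resilient vs. control); these
share control animals in the originating experiment but are treated as
independent here, a simplification discussed under limitations.

For gene $g$ and contrast $i$ the model is the standard intercept-only
random-effects meta-analysis,

$$y_{gi} = \mu_g + u_{gi} + e_{gi}, \qquad
  u_{gi} \sim N(0, \tau_g^2), \qquad e_{gi} \sim N(0, v_{gi}),$$

with $v_{gi}$ the known sampling variance (squared SE) of the contrast's
estimate. $\tau_g^2$ captures real between-study heterogeneity — paradigm,
strain, timing, platform — and is estimated per gene by restricted maximum
likelihood. Pooling is by inverse-variance weights $w_i = 1/(v_i +
\hat\tau^2)$; inference on $\mu_g$ is a two-sided Wald $z$-test, with
Cochran's $Q$ (computed at fixed-effect weights $1/v_i$) and
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$ as heterogeneity descriptions.
Benjamini–Hochberg FDR is applied across genes and differential expression
is declared at $q < 0.05$.

## From probe tables to the gene-by-contrast matrix

Three ingest rules shape the data before any model is fit:

* **SE derivation.** Many exports carry t-statistics but no SE column; the
  SE is then derived from the Wald identity $se = |y/t|$. Rows where that
  division is impossible (t zero, missing, non-finite) are excluded as
  unusable rather than imputed.
* **Probe-to-gene collapse.** Rows mapping to anything other than exactly
  one official gene symbol are excluded (multi-mapped and unmapped counted
  separately). Within a gene, the effect size is the arithmetic mean of
  probe Log2FCs and the gene SE is the arithmetic mean of probe SEs
  (`se_method = "mean"`; a root-mean-square alternative is provided). The
  mean-SE policy deliberately does not divide by $\sqrt{n_{probes}}$: probes
  of one gene are correlated measurements of the same RNA, and treating them
  as independent would overstate precision. For truly independent probes the
  policy is mildly conservative.
* **Alignment.** Genes are matched across contrasts by exact, case-sensitive
  symbol (no alias resolution), and retained when observed in at least
  `min_contrasts = 5` contrasts — under a design where two datasets emit two
  contrasts each, five contrasts guarantees at least three independent
  studies behind every pooled estimate.

Every excluded row lands in exactly one logged category (usable +
multi-mapped + unmapped + unusable = total), and the pipeline log carries
those counts; the tests assert the conservation identity.

## Numerical estimation of $\tau^2$

The REML log-likelihood
$$\ell_R(\tau^2) = -\tfrac12 \sum \log(v_i + \tau^2)
  - \tfrac12 \log \sum w_i - \tfrac12 \sum w_i (y_i - \hat\mu(\tau^2))^2$$
is maximized by Fisher scoring with step-halving, clamped at $\tau^2 = 0$,
starting from the DerSimonian–Laird estimate. Numerical details that matter:

* The problem is standardized by $\bar v$ before optimization, making the
  estimate invariant to the measurement scale (multiplying all $y$ by $c$
  and $v$ by $c^2$ reproduces $z$, $p$, $Q$, $I^2$ to near machine
  precision — an invariant the tests check at $10^{-8}$).
* Convergence is declared when successive $\tau^2$ values differ by less
  than `tol` ($10^{-8}$), but iteration continues to a $10^4\times$ tighter
  step so the returned optimum is accurate well beyond the declaration
  threshold; near the optimum the ascent check is skipped, because
  likelihood comparisons there are floating-point noise.
* If scoring fails (non-finite likelihood, singular information), a bounded
  golden-section search over $[0, 100 \max v_i]$ takes over; if that too is
  unstable the gene is flagged `converged = FALSE`, reported separately, and
  carries no p-value into the FDR step. The BH denominator $m$ is the number
  of converged genes.
* Validation: on random instances ($k \in [5,8]$, $y \sim N(0,1)$,
  $v \sim U(0.01, 1)$) the estimate agrees with a $10^{-4}$-step grid
  maximization of $\ell_R$ to $10^{-4}$, and with `metafor::rma(method =
  "REML")` to about $10^{-5}$; in the equal-variance case it equals the
  closed form $\max(0, s^2 - v)$ to $10^{-8}$.

The 95% interval uses $z = 1.959964$. A Knapp–Hartung adjustment
(`knapp_hartung = TRUE`: scaled SE with a $t_{k-1}$ reference) is available
but off by default, matching the referenced default behaviour of
intercept-only random-effects fits.

## Preranked enrichment

Converged genes are ranked by pooled Log2FC, descending, ties broken by
ascending symbol so the ranking is reproducible. For a gene set, walking the
ranked list adds $|r_i|^p / \sum_{hits} |r|^p$ at members and subtracts
$1/(N - N_{hits})$ elsewhere; the enrichment score is the extreme deviation
of this walk and the leading edge is the run of members at or before (after,
for negative ES) the extremum. The weighting exponent defaults to $p = 1$.

The null is the *simple* permutation scheme: for each distinct set size,
`n_perm` (default 10,000) random gene sets drawn without replacement from
the ranked universe. The p-value conditions on sign,
$p = (1 + \#\{|null| \ge |es|\}) / (1 + \#\,same\text{-}sign\ nulls)$, so it
is never exactly zero; NES divides ES by the mean same-sign null magnitude;
BH runs over all tested sets. The adaptive multilevel refinement of very
small p-values is deliberately not implemented: at $\sim 10^2$–$10^4$ sets,
the $\sim 10^{-4}$ permutation floor is sufficient resolution for FDR < 0.05
decisions, and the simple scheme is exactly reproducible for a fixed seed.
Set-size bounds default to [10, 1000] members within the ranked universe.
The ES implementation is cross-checked against `fgsea::calcGseaStat` to
machine precision in the tests.

## Ortholog resolution and external comparison

Mouse-to-human candidate rows (symbol pairs with a database-support count)
are resolved to a one-to-one map by an ordered cascade: (1) mouse symbols
with a unique human candidate pass through; (2) among conflicts, rows whose
symbols match case-insensitively win; (3) otherwise the highest support
count wins, ties broken by the smallest original row index. The source
material lists these three filters without explicit precedence; reading them
as a decision cascade in the listed order is this package's choice, and the
cascade is idempotent. DEGs joined to an external result table yield Pearson
and Spearman correlations, the OLS slope/intercept, and sign-concordance;
external tables that only report significant genes are accepted with a
warning that correlations on truncated results are biased.

## The synthetic study design

The generator exists so the whole pipeline can be validated against known
ground truth. Its defaults emulate a six-dataset, eight-contrast design: two
microarray and four RNA-seq datasets, two RNA-seq datasets contributing
susceptible/resilient contrast pairs. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 10,000 | genome-scale while desk-fast |
| `pi_de` | 0.10 | a minority of genes truly affected |
| `effect_sd` | 0.4 | true pooled Log2FCs mostly in ±0.8 |
| `tau` | 0.1 | moderate cross-laboratory heterogeneity |
| `base_v` | 0.03 (array), 0.05 (RNA-seq) | SEs of 0.17–0.22, typical of n ≈ 4–38/group designs |
| `df_v` | 10 | gene-to-gene spread of sampling variances |
| coverage | 0.80 (array), 0.90 (RNA-seq) | leaves ≈ 3% of genes below the 5-contrast filter |
| `multi_mapped_fraction` | 0.05 | exercises the exclusion accounting |

Probes are independent measurements $\theta_g + N(0, v)$ with honest
per-probe SEs (microarray genes get 1–3 probes); t-statistics, not SEs, are
emitted so the ingest derivation path is exercised. Heterogeneity is
homoscedastic across genes (one $\tau^2$), which keeps recovery checks
crisp; per-gene heterogeneity is a straightforward extension but off by
default. The external-study generator produces attenuated noisy copies of
the true effects ($b\,\mu_g + N(0, \sigma^2)$) plus an ortholog table with
planted multi-mapping conflicts, including support ties.

What the generator does *not* emulate: correlated contrasts sharing control
animals, batch structure, count-level mean–variance coupling,
platform-specific probe biases, or annotation drift between studies. Passing
tests therefore demonstrate the pipeline's statistical correctness under its
own model assumptions, not robustness to every artifact of real public data.

## Validation scale and determinism

The test suite validates at deliberately modest sizes — 500 grid-oracle REML
instances, 10 replicates of the 10,000-gene default design for error-control
checks, 10,000-permutation enrichment for planted-set detection — sizes at
which every Monte-Carlo bound in the tests is already tight. All randomness
flows from explicit seeds: identical seeds give byte-identical pipeline
outputs (asserted file-by-file in the tests), and the run manifest records
seed and parameters.

## Known limitations

* **Small-$k$ Wald calibration.** With $k \in [5, 8]$ contrasts and
  estimated $\tau^2$, Wald-normal p-values are anti-conservative in the far
  tail, where BH thresholds operate. In the validation simulations the
  empirical false-discovery proportion among called genes runs near 0.09 at
  a nominal 0.05 — sign assignments of strongly affected called genes remain
  perfect. This is a property of the default inference (shared by the
  standard intercept-only random-effects fit it mirrors), not of the
  implementation; enabling `knapp_hartung = TRUE` trades power for
  calibrated small-$k$ inference.
* **Correlated contrasts.** Susceptible and resilient contrasts from one
  dataset share controls; treating them as independent slightly overstates
  the effective number of studies.
* **Symbol joins.** Alignment is by exact symbol; genes renamed between
  annotation releases fragment across rows rather than being merged.
* **Truncated external tables.** Correlations against
  significant-genes-only exports are biased (typically upward); the package
  computes them, but flags the truncation.
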