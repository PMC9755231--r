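---
title: "Mean-variance scaling of host-associated microbiomes with tplext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-variance scaling of host-associated microbiomes with tplext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Taylor's power law states that the variance $V$ of population abundance
scales with its mean $M$ as $V = aM^b$, fitted on the log-log scale as

$$\ln V = \ln a + b \ln M.$$

The intercept $\ln a$ reflects sampling effort and carries little ecological
meaning; the slope $b$ is the heterogeneity scaling parameter: $b < 1$
indicates a uniform (regular) spatial abundance distribution, $b = 1$ random
placement, and $b > 1$ aggregation. Applied to a whole microbiome, the law
takes two forms that differ only in how the $(M, V)$ pairs are constructed
from the OTU-by-sample table:

- **Type-I** (community level): one pair per sampling unit $i$, with $M_i$
  and $V_i$ the mean and variance of abundance across all OTUs present in
  that unit (zeros included — an OTU absent from a sample contributes
  abundance 0). The slope $b_1$ measures the spatial heterogeneity of the
  community.
- **Type-III** (mixed-species population level): one pair per OTU $j$, with
  $M_j$ and $V_j$ taken across sampling units — the pooled conspecific
  populations of that OTU form a "mixed-species population". The slope
  $b_3$ measures its heterogeneity across hosts or sites.

Temporal variants of the extension family (stability across repeated
surveys of the same units) are deliberately out of scope; `tplext` handles
the two spatial forms only.

`type1_mean_variance()` and `type3_mean_variance()` build the point sets;
`fit_ple()` fits the log-linear model; `grouped_fits()` repeats the fit per
host species; `classify_heterogeneity()` maps a fit to
uniform/random/aggregated; `dominant_phyla_fits()` restricts the table to
the most abundant phyla before fitting; and `b_vs_area()` regresses the
per-species $b$ on species-mean skin area to test scale invariance.

## Estimation choices

**Regression.** Ordinary least squares of $\ln V$ on $\ln M$ with the
natural logarithm. The log base only shifts $\ln a$, never $b$. Reduced
major axis regression is available via `fit_ple(..., method = "rma")` for
sensitivity analysis, but OLS on the log-linear form is the conventional
treatment and the default.

**Variance estimator.** The $n-1$ (unbiased) sample variance by default;
`variance = "population"` switches to the $n$ denominator so the
sensitivity of $b$ to that choice can be checked directly. In practice the
difference is a constant factor $n/(n-1)$ on every $V$, which moves
$\ln a$ and leaves $b$ untouched whenever all units summarize the same
number of values.

**Zeros.** Zeros *inside* a unit's value vector are genuine observations
and enter $M$ and $V$. A whole pair with $M = 0$ or $V = 0$ has no
log-transform and cannot enter the regression; such pairs are dropped and
counted (`n_dropped`), so the total number of sampling units remains
auditable. No rare-OTU prevalence filter is applied by default — whether to
drop rare OTUs before a Type-III fit is a substantive choice the user can
make by subsetting the table.

**Confidence interval and classification.** The 95% CI for $b$ comes from
the t distribution with $n-2$ degrees of freedom. Classification on
`basis = "point_estimate"` compares $b$ to 1 with a $10^{-12}$ equality
tolerance (exact float equality is meaningless); `basis = "ci_test"` calls
a fit aggregated only when the whole interval exceeds 1 and uniform only
when it lies below 1, otherwise random. At least 3 retained pairs are
required per fit — the CI is undefined below that — and groups failing the
requirement are reported, never silently skipped.

**Counts versus relative abundances.** The pipeline accepts any
non-negative abundances; whether fits use raw or normalized values is an
explicit option (`normalize`) recorded in output provenance, since scaling
a sample by $c$ maps $(M, V) \to (cM, c^2V)$ and therefore changes $\ln a$
but not $b$ when applied uniformly.

## Skin-area geometry

Host body size enters through two equivalent-geometry models built from
three morphometric traits (millimetres): head length $a$, head width $b$,
body length $h$ (the symbols $a, b$ here are traits, distinct from the
power-law parameters). The 3D model is a cone (base diameter $b$, height
$a$) on a cylinder (diameter $b$, height $h-a$):

$$A_3 = \frac{\pi b}{2}\sqrt{a^2 + \frac{b^2}{4}} + \pi b(h-a) + \frac{\pi b^2}{4},$$

i.e. lateral cone surface + lateral cylinder surface + one base disc. The
single disc is the posterior end; no disc is counted at the cone/cylinder
junction because it is an interior surface — this is an explicit modelling
assumption of the package. The 2D cross-validation model is the silhouette,

$$A_2 = \frac{ab}{2} + b(h-a).$$

Both scale as $k^2$ under uniform trait scaling, and $A_3 \ge A_2$ whenever
$b > 0$. Limbs are deliberately omitted. Species-level areas are arithmetic
means over the sampled individuals (`species_mean_area()`), and
`b_vs_area()` fits $b$ against area on the untransformed scale by default
(`log_area = TRUE` switches), reporting slope, $p$ and $r^2$; what counts
as "barely changing" is left to the user's judgment rather than a built-in
threshold.

## Supporting statistics

Shannon diversity is $-\sum p_k \ln p_k$ in nats (the log base affects
values, not rank-based test results). Kruskal-Wallis (tie-corrected, with
the all-tied degenerate case defined as $H = 0$) compares a per-sample
scalar across hosts. Bray-Curtis dissimilarity
$d = \sum_k |x_{ki}-x_{kj}| / \sum_k (x_{ki}+x_{kj})$ is computed on raw
abundances by default, with a pair of all-zero samples defined as distance
0 under a warning. ANOSIM uses midranks of all pairwise distances (required
to keep $R \in [-1, 1]$ under ties),

$$R = \frac{\bar r_{between} - \bar r_{within}}{N(N-1)/4},$$

permutes group labels with distances fixed, and reports the add-one
permutation p-value $(1 + \#\{R^* \ge R\})/(1 + n_{perm})$, which can never
return 0; the default 999 permutations follow common ecological practice
and a seed is mandatory so every run is reproducible. For small studies
(`exact = TRUE`, $N \le 10$) the full permutation distribution is
enumerated instead.

## The synthetic-data generator

The generator exists so that every stage of the analysis can be exercised
against data with *known* generating structure. A community spec fixes the
number of units and observations, a mean law, and a target law
$V = e^{\ln a} M^{b}$ applied at one level:

- `simulate_community()` (Type-I target): each sample draws its mean $M_i$
  from the mean law and its OTU abundances i.i.d. with mean $M_i$ and
  variance $e^{\ln a} M_i^{b}$.
- `simulate_mixed_population()` (Type-III target): the same construction
  per OTU across samples.

Unit means are log-uniform on $[1, 100]$ by default — two decades, chosen
so the regression design matrix over $\ln M$ is well conditioned — and the
abundance family is gamma with shape $M^2/V$ and rate $M/V$, the simplest
non-negative two-parameter family matching both moments exactly. The
`poisson` family ($V = M$, the random-placement null with $b = 1$) and a
`negative_binomial` family (integer counts; requires $V > M$ for every
unit, otherwise it errors naming the unit) are alternatives. Draws are
independent across units and observations: the fitted law concerns marginal
moments only, and spatial correlation structure is out of the generator's
scope.

`simulate_study()` assembles a multi-host survey: each species gets its own
morphometric trait distribution (normals truncated at zero, $h \ge a$
enforced by bounded resampling) and its own OTU mean profile. The OTU pool
is a shared block (means drawn once, common to all hosts) plus one private
block per species (`shared_fraction` controls the split, default 0.5), so
community composition shifts between hosts and ANOSIM has true structure to
detect. Within a species every OTU with a positive profile mean follows the
species' per-OTU moment law. The per-OTU (Type-III) law is the only one a
study spec accepts: a per-sample law would make all OTUs within a sample
exchangeable, which is incompatible with maintaining species-specific
composition profiles. Phyla are assigned to OTUs with configurable,
geometrically decaying probabilities, giving the long-tailed phylum
abundance ranking typical of 16S surveys.

What the generator does *not* emulate: sequencing noise and chimeras,
rarefaction depth, phylogenetic signal, spatial or co-occurrence
correlation between OTUs, and site effects within species. Tests passing on
synthetic data therefore validate the estimators and the pipeline wiring,
not the biological claims one might make from a real survey.

## Numerical and degenerate-input policy

- Exact log-linear point sets are legitimate inputs: `fit_ple()` returns
  $r^2 = 1$ with a zero-width CI and suppresses the perfect-fit warning of
  the underlying regression machinery.
- A fit with fewer than 3 log-transformable pairs, or with all means
  identical (degenerate design), errors with the group label in the
  message; `grouped_fits()` converts such errors into a `skipped` report.
- Dominance ranking of phyla uses summed abundance across all samples (not
  prevalence), with alphabetical tie-breaks so results are deterministic.
- `b_vs_area()` with a constant $b$ across species reports slope 0 and
  $r^2 = 0$ (no explainable variance) rather than `NaN`.
- All writers emit a sibling `.prov` provenance file; `run_pipeline()`
  additionally hashes the analytic config (the output directory is
  excluded from the hash so reruns into different directories compare
  byte-identical).

## Problem sizes used in the test suite

The shipped tests exercise the estimators at 500 units × 100 observations
for slope-recovery checks (50 replicates per target exponent), a
ten-species study of ~360 samples over a pool of 2200 OTUs for the
end-to-end check, and small hand-verifiable fixtures everywhere else. These
sizes make the whole suite run in well under a minute on a laptop while
keeping Monte-Carlo error far below the asserted tolerances.

## Known limitations

- The OLS confidence interval for $b$ ignores the finite-sample bias of the
  log sample variance. For gamma-distributed abundances with shape
  $k = M^{2-b}/a$, $\mathrm{E}[\ln \hat V] - \ln V \approx -(1 + 3/k)/n$,
  which grows as $b$ does (shapes shrink at large $M$). With many points the
  interval becomes very tight while the bias does not shrink, so nominal
  coverage of the generating exponent degrades noticeably for $b \gtrsim 2$
  even though the point estimate stays within a few hundredths. Slope
  *medians* are robust; CI coverage statements at large $b$ are not.
- The Type-I and Type-III constructions treat samples as exchangeable
  spatial replicates; longitudinal designs need the temporal variants,
  which are not implemented.
- The skin-area models are deliberate idealizations (no limbs, simple
  solids); they are intended for comparing relative body sizes across
  species, not for absolute surface-area measurement.
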