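---
title: "Model-averaged tail area intervals for lognormal factorial designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged tail area intervals for lognormal factorial designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mataboot)
```

## The problem

In a designed experiment with several crossed factors it is rarely known
which interactions belong in the model. Selecting a "best" model and then
computing a confidence interval from it ignores model uncertainty and can
leave the interval's error rates far from nominal; always using the full
model wastes precision when the truth is simpler. Model averaging is the
compromise: with candidate normal linear models $m = 1, \dots, M$ and AIC
weights

$$w_m \propto \exp(-\mathrm{AIC}_m / 2), \qquad \sum_m w_m = 1,$$

the model-averaged estimate of a parameter $\theta$ that has the same
interpretation in every model is $\bar\theta = \sum_m w_m \hat\theta_m$.
`mataboot` implements six confidence intervals around this idea for
balanced two-level factorial designs with a positive, right-skewed
response modelled as lognormal:

* **Full-Wald** — $\hat\theta \pm t_{\nu,1-\alpha}\sqrt{\hat V(\hat\theta)}$
  from the saturated model;
* **MA-Wald** — $\bar\theta \pm z_{1-\alpha}\sqrt{\hat V(\bar\theta)}$ with
  $\hat V(\bar\theta) = \sum_m w_m \{ (t_{\nu_m,1-\alpha}/z_{1-\alpha})^2
  \hat V(\hat\theta_m) + (\hat\theta_m - \bar\theta)^2 \}$;
* **MATA-Wald (z and t)** — limits solving the weighted tail-area equations
  $\sum_m w_m \Pr(T_m \le t_{L,m}) = \sum_m w_m \Pr(T_m \ge t_{U,m}) =
  \alpha$, where $t_{L,m} = (\hat\theta_m - \theta_U)/\sqrt{\hat V_m}$,
  $t_{U,m} = (\hat\theta_m - \theta_L)/\sqrt{\hat V_m}$, and $T_m$ is taken
  as $N(0,1)$ or $t_{\nu_m}$;
* **Percentile bootstrap (PB)** — raw percentiles of per-sample AIC-selected
  estimates over parametric resamples of the full model;
* **MATA-SBoot** — the same tail-area equations as MATA-Wald, with each
  model's tail probabilities estimated from the empirical distribution of
  its studentized parametric-bootstrap statistic
  $T^*_m = (\hat\theta^*_m - \hat\theta_m)/\sqrt{\hat V(\hat\theta^*_m)}$.

The MATA-SBoot construction only requires each $T_m$ to be approximately
pivotal under its model. That matters here because the flagship estimand is
the lognormal cell mean: with $\log Y$ Gaussian,
$\eta_{ijk} = \log \theta_{ijk} = \mu_{ijk} + \sigma^2/2$, estimated by

$$\hat\eta_{ijk,m} = \hat\mu_{ijk,m} + \hat\sigma^2_m / 2, \qquad
\hat V(\hat\eta_{ijk,m}) = \hat\sigma^2_m h_m +
\frac{(\hat\sigma^2_m)^2}{2(\nu_m + 2)},$$

where $h_m = x_0^\top (X^\top X)^{-1} x_0$ and $\nu_m$ is the residual
degrees of freedom. Because $\hat\eta$ and its variance estimate share
$\hat\sigma^2_m$, they are positively correlated, $T_m$ is negatively
skewed for small $r$, and Wald-type intervals place the upper limit too
low. The studentized bootstrap estimates that skewed distribution instead
of assuming it away. All intervals are built on the $\eta$ (log) scale and
back-transformed, which preserves coverage exactly.

The variance estimator above is unbiased for
$\mathrm{Var}(\hat\eta) = \sigma^2 h_m + \sigma^4/(2\nu_m)$ when model $m$
is true: the divisor $2(\nu_m + 2)$ compensates for
$E[(\hat\sigma^2_m)^2] = \sigma^4 (\nu_m + 2)/\nu_m$ under the
$\chi^2_{\nu_m}$ law of the residual mean square. This is why
$\hat\sigma^2_m$ is the residual mean square $\mathrm{RSS}/\nu_m$ and not
the ML estimator $\mathrm{RSS}/n$.

## Model space and fitting

For $k$ two-level factors the candidate set is every subset of main
effects and interactions closed under marginality (an interaction enters
only with all its lower-order terms), plus the null model; $k = 3$ gives
19 models. Canonical order is by model size, then by the ranks of the
terms (main effects before two-way before three-way interactions, each
block ordered by factor indices); AIC ties in selection therefore resolve
toward smaller models.

Fitting uses effect ($\pm 1$) coding, so in a balanced design the columns
of $X$ are orthogonal, $X^\top X = n I_p$, and $h_m = p_m / n$ for every
cell ($1/r$ for the saturated model, $1/n$ for the null model). Every
least-squares fit then depends on the data only through the eight cell
means and the within-cell sum of squares. The AIC convention is the
Gaussian profile-likelihood form $n \log(\mathrm{RSS}/n) + 2(p + 1)$,
counting $\sigma^2$; additive constants cancel in the weights.

`h_mode = "literal_r"` forces $h_m = 1/r$ for every model, the saturated
closed form, as a sensitivity mode: only the general $h_m$ makes the
variance estimator unbiased under every candidate model, but the literal
form is useful for checking how much that refinement matters.

## The bootstrap engine

Parametric resamples are drawn from a fitted model's Gaussian log-scale
law. In a balanced design the refit of any candidate model depends on a
resample only through its cell means — independently
$N(\hat\mu_{\text{cell}}, \hat\sigma^2/r)$ — and its within-cell sum of
squares — $\hat\sigma^2 \chi^2_{K(r-1)}$, independent of the means. The
batch engine samples these sufficient statistics directly; this is the
exact resampling distribution, not an approximation, and it makes
$B = 10^4$–$10^5$ routine on one CPU. `parametric_resample()` still
materializes full long-format datasets for uses that need them.

Tail probabilities use the interpolated plotting-position ECDF through
$(T^*_{(b)}, b/(B+1))$, clamped to $[1/(B+1), B/(B+1)]$: continuous and
nondecreasing, so every tail equation has a unique root, with $\alpha \ge
1/(B+1)$ enforced ($B \ge 39$ for $\alpha = 0.025$). Degenerate bootstrap
refits (zero residual variance — a probability-zero event for continuous
data) are redrawn and counted rather than silently dropped.

## Numerical choices

For the z and t kernels the tail equations are solved by bracketed root
finding (`uniroot`) on the monotone tail function, starting from
$[\min_m \hat\theta_m - 20 \max_m \sqrt{\hat V_m},\;
\max_m \hat\theta_m + 20 \max_m \sqrt{\hat V_m}]$ with up to ten
geometric expansions, at absolute tolerance
$10^{-8} \max(1, |\bar\theta|)$.

For the bootstrap kernel no iteration is needed: with the interpolated
ECDF the weighted tail sum $S(\theta) = \sum_m w_m \hat F_m((\hat\theta_m
- \theta)/\sqrt{\hat V_m})$ is piecewise linear in $\theta$ with kinks
only at $\theta = \hat\theta_m - \sqrt{\hat V_m}\, T^*_{(b)}$. Evaluating
$S$ on the union of kinks and interpolating yields the limits exactly
(upper limit at $S = \alpha$, lower at $S = 1 - \alpha$), satisfying the
tail equations to machine precision and considerably faster than
iterative solving inside the simulation study.

The PB interval uses the order-statistic percentile rule
$\lceil \alpha (B+1) \rceil$ and $\lceil (1-\alpha)(B+1) \rceil$ without
interpolation; conventions differ by $O(1/B)$.

## The synthetic-data generator and the simulation study

`draw_effects()` and `simulate_dataset()` emulate a $2^3$ lognormal
factorial experiment: $\log Y_{ijkl} = \mu_{ijk} + \varepsilon_{ijkl}$,
$\varepsilon \sim N(0, \sigma^2)$, with
$\mu_{ijk} = \mu + \alpha_i + \beta_j + \gamma_k + (\alpha\beta)_{ij} +
(\alpha\gamma)_{ik} + (\beta\gamma)_{jk} + (\alpha\beta\gamma)_{ijk}$ in
sum-to-zero ($\pm v$) coding. A scenario such as `"HML"` fixes the
standard deviations from which each term's value is freshly drawn every
replicate: High = 2, Medium = 1, Low = 0.1, respectively above, equal to
and below the default $\sigma^2 = 1$ (response skewness
$(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1} \approx 6.2$). The overall mean is
fixed at 0; interval performance does not depend on it. The ten scenario
labels run from `LLL` to `HHH` in orderings where lower-order terms
dominate.

`run_scenario()` scores each method by its lower and upper error rates
(fractions of replicate-cell pairs with $\theta_L > \theta$ or
$\theta_U < \theta$, each nominally $\alpha = 0.025$) and by mean relative
half-widths $(\theta_{L} - \theta)/\theta$ and
$(\theta_U - \theta)/\theta$, averaged over the eight cells. Replicates
use deterministic substreams of the scenario seed, so results are
reproducible and order-independent.

What the generator does not emulate: responses whose log-scale errors are
non-Gaussian or heteroscedastic, unbalanced or multi-level factors, and
dependence between replicates. Passing tests therefore certify behaviour
under a correctly specified lognormal factorial model; robustness to
misspecification is a separate question, though the pivotal-statistic
argument suggests MATA-SBoot degrades most gracefully.

The package's test suite exercises scaled-down study conditions chosen to
keep a full run in minutes on one CPU: 1000–2000 replicates per scenario
and $B = 199$, versus $10^5 \times B = 9999$ for a cluster-scale study.
At 2000 replicates the three-binomial-SE acceptance band around
$\alpha = 0.025$ is $\pm 0.0105$, wide enough that genuine method
behaviour, not Monte Carlo noise, decides the outcome. The full-scale
settings remain available through the API (`n_sim`, `B` are ordinary
arguments).

## Known limitations

* Only balanced, fully crossed designs with two levels per factor (at most
  four factors) are supported; unbalanced data are rejected, not
  reweighted.
* AIC weights only — no AICc, BIC, cross-validation or bootstrap-selected
  weights.
* Intervals are per-cell; no simultaneous coverage across the eight
  treatment combinations.
* The MATA construction does not guarantee exact coverage even when its
  distributional assumptions hold; the simulation study is the evidence of
  its practical accuracy.

## A worked example

```{r example, eval = FALSE}
ds <- read_dataset(system.file("extdata", "synthetic_hydronium.csv",
                               package = "mataboot"))
wt <- weight_table(ds$data, ds$design)
wt$weight <- round(wt$weight, 3)
wt[order(-wt$weight)[1:5], ]

intervals_report(ds$data, ds$design, B = 9999, seed = 1)
```

The shipped CSV is a synthetic dataset generated by `simulate_dataset()`
with effects chosen so that pH, irradiance and their interaction dominate,
echoing the structure of the marine ocean-acidification experiment that
motivates the factor naming (`P`, `I`, `V`); it is not the original
experimental data.
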