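---
title: "Base-level beta-binomial modeling of RNA-seq read-start counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-level beta-binomial modeling of RNA-seq read-start counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbdisp)
```

## The model

RNA-seq coverage is far from uniform along a transcript: the number of reads
starting at a given base can vary a hundredfold within one gene, largely
because random-hexamer priming prefers some local sequences over others.
`bbdisp` sidesteps modeling the per-position rate itself by comparing **two
samples at a time**: if both samples see the same local-sequence bias, the
*proportion* of reads falling to sample 1 at each base should be a constant
for the whole gene, and everything position-specific enters only through the
*fluctuation* of that proportion.

Let $n_{ij}$ and $m_{ij}$ be the read counts starting at base $j$ of gene
$i$ in the two samples.  Conditional on the total $t_{ij} = n_{ij} + m_{ij}$
we model

$$n_{ij} \sim \mathrm{BetaBinomial}\left(t_{ij};\, p_i,\, \theta_{ij}\right),
\qquad p_i = \frac{\alpha}{\alpha + \beta},\quad
\theta_{ij} = \frac{1}{\alpha + \beta},$$

so $p_i$ is the gene's expected sample-1 proportion and $\theta_{ij} \ge 0$
the per-position overdispersion rate; $\theta = 0$ recovers the binomial.
In this parametrization the gene log-likelihood has the product form

$$\log \mathcal{L}_i = \sum_j \Big[ \sum_{k=0}^{n_{ij}-1}\log(p_i + k\theta_{ij})
 + \sum_{k=0}^{m_{ij}-1}\log(1-p_i + k\theta_{ij})
 - \sum_{k=0}^{t_{ij}-1}\log(1 + k\theta_{ij}) \Big],$$

which `gene_loglik()` evaluates through log-gamma differences (the
combinatorial constant is omitted; it cancels in every likelihood ratio and
AIC difference).

### A dynamic overdispersion rate

The core empirical observation is that $\theta_{ij}$ is not constant: it
falls with sequencing depth and appears to depend on the sequence
flanking the read start.  Both effects are captured by the log-linear model

$$\log \theta_{ij} = \log D + \sum_{k=1}^{K}\sum_{h \in \{A,T,C\}}
\beta_{kh}\, I(b_{ijk} = h) + \gamma \log t_{ij},$$

where the window of $K = 80$ bases covers 40 nt on each side of the read
start (the start base itself is excluded; whether it should be included is
genuinely ambiguous — we exclude it and note the choice), $G$ is the
reference base so that 240 coefficients are fitted for A, T and C, $\gamma$
is the depth exponent (negative: deeper positions fluctuate relatively
less), and $D$ is a sample-pair-specific scale — the library effect.

Note the sign convention: $\gamma$ is defined as the *regression slope* of
$\log\theta$ on $\log t$ throughout (an equivalent power-law form
$\theta = D\,e^{\sum\beta I}\,t^{\gamma}$).  A depth profile with slope
$-1$ therefore corresponds to $\gamma = -1$.

Four nested variants are named after their free parameters:

| variant | label | $\theta_{ij}$ |
|---|---|---|
| `binomial` | bi | $0$ |
| `constant` | bb+D | $D$ |
| `primer_free` | bb+D+g | $D\,t_{ij}^{\gamma}$ |
| `full` | bb+D+g+coe | $D\,e^{\sum\beta I}\,t_{ij}^{\gamma}$ |

## Estimating the dispersion from replicates

With $R$ replicate pairs that share the neutral proportion
$p_{nr}$ (the genome-wide count ratio of pair $r$), the method-of-moments
estimator is

$$\hat\theta_{ij} = \frac{\frac1R\sum_r \left[
  \sigma_{ijr}/(p_{nr}(1-p_{nr})) - 1/t_{ijr} \right]}
 {1 - \frac1R\sum_r \sigma_{ijr}/(p_{nr}(1-p_{nr}))},
\qquad \sigma_{ijr} = \left(\tfrac{n_{ijr}}{t_{ijr}} - p_{nr}\right)^2 .$$

$\sigma_{ijr}$ is the squared deviation of the observed pair proportion from
the pair's neutral proportion — with a single pair there is no other usable
definition of the "variance of proportion", and averaging the per-pair terms
recovers consistency across pairs.  The estimator inverts the exact
beta-binomial identity
$\mathrm{Var}(n/t \mid t)/(pq) = (1/t + \theta)/(1 + \theta)$,
so it is consistent without any small-$\theta$ assumption.

Three practical decisions matter here:

* **Negative estimates.**  Sampling noise makes $\hat\theta \le 0$ whenever
  the observed deviation falls below its binomial share.  The observation
  table keeps these records (floored to `1e-6`, flagged `floored`), but the
  log-linear regression **excludes** them by default: a point mass at
  $\log 10^{-6}$ sits many log-units below the signal and badly attenuates
  the depth slope (we measured $\hat\gamma \approx -0.39$ with the floored
  rows included versus $\approx -0.83$ without, at a true $\gamma = -0.8$).
  `build_design(include_floored = TRUE)` restores the flooring behaviour.
* **Depth filter.** Positions need a total of at least `min_depth = 5` in
  every pair to enter estimation; the moment estimator is hopeless below
  that.  The depth covariate of a multi-pair estimate is the mean pair
  total.
* **Identifiability.**  The estimator is *informative* about $\theta$ only
  where $t\,\theta \gtrsim 1$.  Below that the per-position noise scale
  $\approx (\theta + 1/t)\sqrt{2/R}$ swamps the signal, most estimates are
  flagged, and the regression slope drifts towards $-1$ (the estimator then
  measures $1/t$, not $\theta$).  This is an information limit of base-level
  moment estimation, not of the implementation: recovery experiments must be
  run at dispersion scales where $t\theta$ reaches a few, and the package's
  own recovery tests document both regimes.

## Two-stage fitting and the test

Training (replicates with no expected biological difference) fixes $\gamma$
and $\beta_{kh}$ by ordinary least squares of $\log\hat\theta$ on the
indicator design — the log of a dispersion estimate is approximately
Gaussian, which makes least squares efficient and fast; coefficients are
fitted per strand, because only the strand synthesized with random hexamers
need carry the priming signature.

For a test pair, `fit_test_pair()` then

1. initializes every gene at the pair's neutral proportion
   $\hat p_i = \hat p_n$;
2. maximizes the summed beta-binomial likelihood over the pair scale $D$
   (1-D search in $\log D$, tolerance $10^{-6}$, Brent-style);
3. re-estimates each $\hat p_i$ by bounded 1-D maximization
   ($p \in (10^{-9}, 1-10^{-9})$);
4. repeats 2–3 until the deviance $-2\log\mathcal{L}$ decreases by less
   than 1% (steps 3–4 are skipped when comparing replicates).

Alternating maximization makes the deviance monotone; an increase beyond
$10^{-9}$ relative aborts with diagnostics.  Per gene and pair the score
$\chi^2_r = -2\log\mathcal{L}(\hat p_n) + 2\log\mathcal{L}(\hat p_i)$ is
$\chi^2_1$ under the null; with groups of samples all (group-1, group-2)
pairs are scored and the statistics and degrees of freedom are summed.
Within-group pairs are used only for training.  Tiny negative scores from
optimizer jitter are floored at zero.  Benjamini–Hochberg adjustment is the
default, configurable.

A caveat the null simulations make visible: $\hat p_n$ is estimated from
*all* genes, so a large differentially expressed fraction contaminates the
null value and inflates every gene's statistic.  The method assumes "most
genes do not change".

### Model comparison

`compare_models()` fixes $p_i = \hat p_n$, fits each variant's per-pair
scale, and reports mean log-likelihood, mean percent change versus the
nested predecessor, a nested $\chi^2$ test, and mean AIC ($2k - 2\log
\mathcal{L}$) under two parameter-counting conventions: `k_pair` counts
only what is free per pair (0, 1, 1, 1 — $\gamma$ and $\beta$ come from
training data), `k_total` counts every parameter (0, 1, 2, $2+3K$).  The
printed `mean_aic` uses `k_pair`, matching the fitting protocol; both are
in the table because the right convention is genuinely ambiguous when
parameters are trained on separate data.

$R^2$ of the linear dispersion fit is cross-validated: 5 random folds,
refit on 4/5, evaluated on the held-out fifth, repeated 10 times, overall
value the mean of the 50 rounds.  Following the verbal definition
("regression sum of squares divided by the total sum of squares") the
reported `r_squared` is $\sum(\hat y - \bar y)^2 / \sum(y - \bar y)^2$ on
the held-out data; the conventional $1 - \mathrm{SSE}/\mathrm{SST}$ is
reported alongside as `r_squared_sse`.  Positions are split at random
ignoring gene structure, matching the definition of the procedure; a
leakage-averse user can split by gene manually.

## The simulator

`simulate_pair()` draws, per position: an expected total from a log-normal
depth model (optionally multiplied by a factor keyed on the first four
downstream bases, e.g. `c(GGGG = 4, AAAA = 0.25)`, emulating
hexamer-priming enrichment), the realized total $t \sim$ Poisson, the
dispersion $\theta(t)$ from the generative variant *using the drawn total
as the depth covariate* (this reproduces the estimable depth dependency
without a circular definition), and finally the beta-binomial split.

`simulate_replicates()` must make *every* unordered pair of samples a valid
replicate pair, which the pair-wise recipe cannot do.  It uses the exact
gamma–Poisson equivalent: sample $s$ draws
$u_{sj} \sim \Gamma(a_j, a_j)$ with $a_j = 1/(2\theta_j)$ and
$x_{sj} \sim \mathrm{Poisson}(\lambda_j u_{sj} / 2)$; conditional on any
pair's total the split is exactly beta-binomial with proportion $1/2$ and
dispersion $\theta_j$.  Two approximations follow and are deliberate:
replicates are balanced (pairwise proportion $1/2$ — the training data the
method expects are depth-matched), and $\theta_j$ is evaluated at the
expected pair depth $\lambda_j$ rather than each pair's realized total
(at the default depths the covariate noise $\mathrm{Var}(\log t \mid
\lambda) \approx 1/\lambda$ is negligible against the depth spread).  An
optional per-sample multiplier jitters the effective pair scale $D$.

### Default study conditions

The defaults describe a deeply sequenced spike-in-like experiment and are
fixed once:

* 200 genes of 500 nt; per-position pair totals log-normal with median 200
  and $\sigma_{\log} = 1.5$ (spanning roughly 10–10^4);
* dispersion truth `primer_free` with $D = 1$, $\gamma = -0.8$, i.e.
  $\theta \approx 0.025$ at depth 100 falling to $\approx 0.004$ at depth
  1000 — magnitudes in the range the depth-dispersion diagnostic targets,
  and a regime where $t\theta \approx 2$–$5$ so the moment estimator is
  informative;
* four replicate samples (six combination pairs) for training;
* neutral proportion $1/2$; sequence-modulated depth and the 3' tail
  inflation off unless a study turns them on.

The simulator emulates position-level counts only: no fragment-length or GC
curves, no positional coverage decay, no isoform structure.  Passing tests
on it show the estimators invert the generative model they target — not
that real libraries satisfy that model.

## Numerical choices

* Likelihood evaluation uses log-gamma differences; positions with
  $\theta(t-1) < 10^{-8}\min(p, 1-p)$ switch to a second-order expansion
  around the binomial to preserve the promised $10^{-8}$ relative accuracy,
  and $\theta = 0$ is the exact binomial.  A term-by-term `method =
  "direct"` path exists as a reference and is tested against the closed
  form.
* OLS fits go through QR (`lm.fit`); constant predictors are dropped with a
  warning and rank-deficient fits set the unidentifiable coefficients to
  zero and flag the model.
* The $D$ search runs over $\log D \in [-30, 10]$; a likelihood range below
  $10^{-8}$ across the bracket (e.g. every position at depth 1, which
  carries no dispersion information) is reported as flat rather than
  "optimized".
* Context windows that would run off the sequence are kept in the
  likelihood with sequence effect 0 and excluded from the regression;
  windows containing `N` are treated the same way.
* All simulations take a mandatory seed; identical configuration and seed
  give byte-identical output.

## Known limitations

* The moment estimator's $t\theta \gtrsim 1$ information limit above: at
  very small dispersion scales the depth exponent cannot be recovered from
  base-level replicate deviations, by any estimator of this family.
* Exchangeable replicate simulation fixes the pairwise proportion at $1/2$;
  unbalanced library sizes in training data are not emulated.
* The LRT degrees of freedom add over cross-group pairs that share samples;
  the summed statistic is treated as $\chi^2_{df}$ exactly as the testing
  procedure prescribes, although pairs sharing a sample are not
  independent.  Single-pair comparisons (one sample per group, borrowing
  trained dispersion) avoid the issue.
* Gene models are spliced transcript sequences; projecting genomic
  multi-exon alignments onto transcripts is the caller's responsibility.
* Reads are counted by their 5' start position only; a read starting before
  a trimmed tail but overlapping it still counts at its start.
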