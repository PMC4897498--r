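---
title: "Methods: the 2PNO Gibbs sampler and its block-decomposed execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 2PNO Gibbs sampler and its block-decomposed execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibbs2pno)
```

## The model

The two-parameter normal ogive (2PNO) model describes a binary response
matrix $y$ ($n$ persons $\times$ $k$ items, persons in rows) through one
latent trait per person:

$$P(y_{ij} = 1) = \Phi(\alpha_j \theta_i - \beta_j),$$

with slopes $\alpha_j > 0$, intercepts $\beta_j$, traits
$\theta_i \sim N(0,1)$, and $\Phi$ the standard normal CDF. The linear
predictor crosses zero — and the response curve crosses one half — at the
item's difficulty location $\theta = \beta_j/\alpha_j$. $\Phi$ is evaluated
through `stats::pnorm`, whose erf/erfc route keeps deep-tail probabilities
finite: the lower tail underflows to zero only beyond the double-precision
floor (linear predictors below about $-38$), and the upper tail saturates
at 1 above about $+8.3$ because $1 - 10^{-19}$ is not representable. The
augmentation step depends on finite tail masses, which this guarantees in
the regime any identified fit visits.

## Priors and the two trait-conditional variants

Item priors are the conventional noninformative choice for this sampler:
$p(\beta_j) \propto 1$ and a flat positive prior on $\alpha_j$ (the
indicator $\alpha_j > 0$). The trait prior is $\theta_i \sim N(0,1)$.

With augmented data $Z_{ij} \sim N(\alpha_j\theta_i - \beta_j, 1)$
truncated to the positive half-line where $y_{ij}=1$ and the negative
half-line where $y_{ij}=0$, all full conditionals are (truncated) normal,
and one Gibbs iteration is exactly
$Z \rightarrow \theta \rightarrow \xi$, each step conditioning on the
freshest values.

The trait conditional is exposed in two variants because the commonly
printed update and the stated prior are in tension:

* **`as-printed`** (default, for fidelity to the classical presentation):
  mean $\sum_j (Z_{ij}+\beta_j)\alpha_j / \sum_j \alpha_j^2$, variance
  $1/\sum_j \alpha_j^2$. This is the conditional under a *flat* trait
  prior; it omits the prior-precision term.
* **`conjugate`** (recommended for identifiability): mean
  $\sum_j (Z_{ij}+\beta_j)\alpha_j / (1 + \sum_j \alpha_j^2)$, variance
  $1/(1 + \sum_j \alpha_j^2)$ — the exact normal-normal update under
  $\theta_i \sim N(0,1)$, which also anchors the latent scale.

The difference is $O(1/\sum_j \alpha_j^2)$ and is negligible for long
tests, but the conjugate form is what the stated prior implies, and all
recovery results below use it. We do not silently correct the printed
form; both are first-class modes.

The item conditional for $\xi_j = (\alpha_j, \beta_j)'$ is bivariate
normal with mean $(x'x)^{-1}x'Z_j$ and covariance $(x'x)^{-1}$, where
$x = [\theta, -1]$, restricted to $\alpha_j > 0$. The restriction is
realized by *joint rejection*: the bivariate pair is redrawn until the
slope is positive, matching the indicator form of the conditional rather
than conditioning the intercept on a truncated slope. A rejection budget
(default 10,000 proposals per item per iteration) turns a vanishing
acceptance probability into an informative error naming the item and the
estimated acceptance rate, rather than a silent hang; the chain then
aborts and flags its partial samples unusable. Zero-variance trait vectors
(a singular $x'x$) raise an error rather than being jittered — silent
regularization would change the model.

## The truncated-normal primitive

`rtnorm` draws from $N(\mu, 1)$ restricted to an interval. For
standardized bounds within 5 SD of the location it inverts the CDF on the
truncated uniform mass; beyond 5 SD the inverse-CDF route loses precision,
so a shifted-exponential rejection sampler (the standard tail method,
optimal exponential rate $\lambda = (a + \sqrt{a^2+4})/2$) takes over.
Draws are strictly interior to the interval — boundary landings from
rounding are redrawn — so the augmented matrix never contains exact zeros.
Two-sided intervals whose normal mass underflows double precision raise a
`tail-degenerate` error with the offending bounds; no such interval arises
from the augmentation itself, which only uses half-lines.

## Initialization, burn-in, thinning

Starting traits are standardized person sum scores (zero mean, unit
sample variance; all-equal scores fall back to zeros), starting slopes are
1 and intercepts 0; the augmented matrix is implied by the first $Z$
update. Any fixed starting point is forgotten during burn-in; sum scores
start the chain near the data. The kept-draw count is exactly
$\lfloor (L - \text{burn-in})/\text{thin} \rfloor$. Thinning (default 1)
exists purely for memory control on very long chains; it is not a
statistical recommendation. No convergence diagnostics beyond MCSEs are
built in — draws are stored and exportable so users can run any external
diagnostic suite.

## Block-decomposed execution

The execution scheme mirrors how this sampler is laid out on massively
parallel hardware: the $n \times k$ matrix is partitioned into an
$r \times c$ grid of contiguous blocks (`block_grid`), the cell-wise $Z$
update runs block by block, the trait update runs per row-block with its
per-item sums accumulated as per-column-block partial sums, $x'x$ is
accumulated as per-row-block partial sums, and the item update runs per
column-block. Two contracts make this reproducible and testable:

* **Draw-order canon.** $Z$ cells are drawn row-major, traits in ascending
  person order, items in ascending item order. Every (kernel, block) pair
  owns a private random stream seeded by a deterministic integer mix of
  (chain seed, block row, block column, kernel id). The serial chain *is*
  the $1 \times 1$ instance of this scheme, so a $1 \times 1$ blocked run
  reproduces it bit for bit.
* **Ordered reduction.** Partial sums are combined in ascending block
  index, a fixed association, so blocked results are run-to-run
  deterministic despite floating-point non-associativity. The reduction
  agrees with a single-pass sum to $10^{-10}$ relative tolerance (tested),
  but not bitwise in general.

`stream_mode = "serial-equivalent"` defines the reference behaviour: the
run executes the canonical serial sequence (the grid is validated and
echoed), hence is bit-identical to `run_chain` for *every* grid shape.
This is a definition, not an accident: a single random stream consumed in
global row-major cell order cannot be reproduced by block-at-a-time
execution, so bit-equivalence is specified as the contract of this mode.
`stream_mode = "per-block-stream"` is the genuine decomposition — per-block
streams, ordered partial reductions — and is statistically, not bitwise,
equivalent to the serial chain (tested by comparing posterior means across
grid shapes against combined Monte Carlo standard errors). Blocks may be
executed concurrently by any backend without changing results, because
streams are private and reductions ordered; the built-in backend is a
sequential loop, which is a conforming implementation of the contract.
Uneven partitions give the remainder rows/columns one each to the trailing
blocks; padding would bias the sums.

## Posterior summaries

Posterior means are arithmetic means over kept draws. MCSEs use
non-overlapping batch means with $\lfloor\sqrt{M}\rfloor$ batches of equal
size (trailing remainder dropped): robust to the chain's autocorrelation
with no tuning and no extra dependencies. The difficulty ratio
$\hat\beta_j/\hat\alpha_j$ is carried at full precision and rounded only
at report time (4 decimals, half-even, the convention of published item
tables). The trait density table is a Gaussian-kernel KDE with Silverman's
rule-of-thumb bandwidth over a grid spanning the mean $\pm 4$ SD (widened
to the data range), which integrates to 1 within $10^{-3}$ by the
trapezoid rule.

## The synthetic generator

`simulate_responses` draws $\theta_i \sim N(0,1)$, item parameters from
their laws, then $y_{ij} \sim \text{Bernoulli}(\Phi(\alpha_j\theta_i -
\beta_j))$, returning the truth alongside the data. The default slope law,
uniform on $[0.3, 1.3]$, brackets the slope range typically reported for
broad achievement tests (roughly 0.3–0.7) while allowing steeper items;
intercepts default to standard normal. The generator's closed-form oracle
is the probit-normal identity
$P(y_{ij}=1) = \Phi(-\beta_j/\sqrt{1+\alpha_j^2})$ for the marginal
per-item proportion. What it deliberately does *not* emulate: missing
responses, guessing, multidimensional traits, or local dependence between
items — so passing recovery tests show correctness of the sampler under
the model's own assumptions, not robustness to their violation.
`condition_grid` crosses person counts with test lengths row-major (the
usual simulation design: $n \in \{500, 1000, 2000, 5000, 10000\} \times
k \in \{20, 50, 100, 200\}$ in the full version) for scaled-down smoke
harnesses and benchmarks.

## Problem sizes used in the tests

The automated suite validates recovery at $n = 1000$, $k = 20$ with
$L = 4000$ and burn-in 2000 in conjugate mode (correlation of slope
estimates with truth $\ge 0.9$, intercept RMSE $\le 0.15$ across seeds),
statistical equivalence of blocked runs at $n \in \{200, 500\}$ with
$L \in \{2000, 4000\}$, and the conditional samplers against closed forms
and grid-quadrature oracles at $10^4$–$10^5$ draws. These sizes were
chosen as the smallest at which the checks have real statistical power;
the sampler itself has no size-dependent switches.

## Prior propriety at very small data sizes

With the flat item priors, the joint posterior is **improper when the test
is very short**. For $k = 2$ the mechanism is explicit: whatever the
response pattern, there is positive prior probability of a trait ordering
that perfectly separates an item's correct from incorrect responses, and
on that event the flat-$\beta$ window compatible with the data grows
linearly with $\alpha$, so the slope marginal is not integrable. A
dense-grid quadrature of the unnormalized posterior of a 3-person, 2-item
instance shows essentially flat edge mass in $\alpha$ however far the grid
extends, and Gibbs chains on such instances drift to slopes of $10^3$ and
beyond or stall in the slope-rejection step — not a defect of the sampler
but a property of the target. The conjugate trait prior does not repair
this; only informative item priors (out of scope here) or more data do.
Consequently, whole-chain distributional validation in this package is
done where the target exists: per-conditional oracles (analytic
truncated-normal CDFs; a 2-D grid quadrature of the single-item
conditional, which *is* proper for fixed $Z, \theta$) and parameter
recovery at identified scale. Users fitting fewer than, say, five items
should treat flat-prior results with corresponding suspicion — slopes have
no finite posterior mean there.

## Benchmark arithmetic

`speedup(t_s, t_p)` implements $S = T_S/T_P$ (serial over parallel time)
and `efficiency(t_s, t_p, p)` implements $E = S/P$, the per-unit share of
the speedup, which can exceed 1 when distributing a problem removes a
sequential memory bottleneck. The `bench` CLI subcommand reports measured
wall-clock times with these statistics; the times are hardware-dependent
and only the arithmetic identities are tested.

## Known limitations

* Logistic-link (2PL), guessing (3PNO) and multidimensional variants are
  out of scope.
* No built-in convergence diagnostics beyond batch-means MCSEs; export the
  draws for anything richer.
* Flat item priors: no posterior propriety guarantee for very short tests
  (see above), and no informative-prior option.
* The block backend executes sequentially; the contract (private streams,
  ordered reductions) is what enables a concurrent backend, which is not
  shipped.
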