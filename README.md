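# gibbs2pno

Fully Bayesian estimation of the **two-parameter normal ogive (2PNO)** item
response model by Gibbs sampling with truncated-normal data augmentation,
for psychometricians and biostatisticians fitting latent-trait models to
binary response matrices (achievement tests, diagnostic instruments,
symptom checklists).

## The model and the sampler

For persons *i* = 1, …, *n* and items *j* = 1, …, *k*, a binary response
matrix **y** follows the 2PNO model

P(y<sub>ij</sub> = 1) = Φ(α<sub>j</sub> θ<sub>i</sub> − β<sub>j</sub>),

where α<sub>j</sub> > 0 is the item slope (discrimination), β<sub>j</sub>
the item intercept, θ<sub>i</sub> ~ N(0, 1) the latent trait, and Φ the
standard normal CDF. An item's difficulty location is the 50% point
θ = β<sub>j</sub>/α<sub>j</sub>.

Estimation uses the classic data-augmentation Gibbs sampler: a continuous
variable Z<sub>ij</sub> ~ N(α<sub>j</sub>θ<sub>i</sub> − β<sub>j</sub>, 1)
truncated to be positive where y<sub>ij</sub> = 1 and negative where
y<sub>ij</sub> = 0 makes all full conditionals (truncated) normal, so each
iteration cycles exactly through

1. **Z | θ, ξ** — independent unit-variance truncated normals per cell,
2. **θ | Z, ξ** — independent normals per person,
3. **ξ | Z, θ** — per item, a bivariate normal for ξ<sub>j</sub> =
   (α<sub>j</sub>, β<sub>j</sub>)′ with mean (x′x)<sup>−1</sup>x′Z<sub>j</sub>
   and covariance (x′x)<sup>−1</sup>, x = [θ, −1], restricted to
   α<sub>j</sub> > 0.

Post-burn-in draws give posterior means, batch-means Monte Carlo standard
errors (MCSEs), difficulty ratios β̂/α̂, item response curves and a trait
density table.

The chain runner also honours a **block-decomposition execution contract**:
the n × k matrix is partitioned into an r × c grid of blocks, each
(kernel, block) pair owns its own random stream, and the θ- and
item-conditional sums are accumulated as per-block partial sums reduced in
a fixed block order — the layout used to run this sampler on massively
parallel hardware, kept fully reproducible here on one CPU. A
`serial-equivalent` stream mode reproduces the serial chain bit for bit
under any grid; a `per-block-stream` mode runs the genuine decomposition
with independent block streams. Speedup (S = T_S/T_P) and efficiency
(E = S/P) arithmetic for benchmarking is included.

## Worked example

```r
library(gibbs2pno)

sim <- simulate_responses(generator_spec(n = 500, k = 10, seed = 42))
fit <- run_chain(sim$y, chain_config(2000, burn_in = 1000, seed = 7,
                                     prior_mode = "conjugate"))
posterior_means(fit)
```

```
2PNO posterior summary (1000 kept draws)
 item alpha_hat alpha_mcse beta_hat beta_mcse   ratio
    1    1.1192     0.0185  -0.1738    0.0073 -0.1553
    2    0.5223     0.0095  -0.9542    0.0070 -1.8269
    3    1.1655     0.0259  -0.9248    0.0152 -0.7934
    4    0.7693     0.0162  -1.1513    0.0116 -1.4966
    5    0.8823     0.0158   0.9891    0.0103  1.1210
    6    0.3128     0.0078   1.1403    0.0060  3.6454
    7    0.8439     0.0133  -0.3439    0.0068 -0.4075
    8    1.0574     0.0189  -1.1031    0.0149 -1.0432
    9    0.6179     0.0077   0.0179    0.0047  0.0290
   10    1.2586     0.0254   2.3040    0.0299  1.8307
traits: 500 persons, mean theta_hat 0.007, sd 0.845
```

Each row is one item: `alpha_hat` is the posterior-mean slope (how sharply
the item separates low from high traits), `beta_hat` the intercept, the
MCSE columns quantify chain-length uncertainty in those means, and `ratio`
= β̂/α̂ is the difficulty location (item 6 is the hardest above — its curve
crosses 50% at θ ≈ 3.6 — and item 10, with the largest α̂, is the most
discriminating).
Against the generating truth this run gives
`cor(alpha_hat, alpha_true) = 0.97` and `rmse(beta_hat) = 0.076`.

A blocked run, bit-identical to the serial one:

```r
cfg <- chain_config(2000, burn_in = 1000, seed = 7, prior_mode = "conjugate",
                    grid = block_grid(500, 10, r = 5, c = 2),
                    stream_mode = "serial-equivalent")
fit_blocked <- run_chain_blocked(sim$y, cfg)
identical(fit_blocked$alpha_draws, fit$alpha_draws)  # TRUE
```

## Command line

A thin wrapper (`exec/gibbs2pno`, or call `cli_main()` directly) exposes
four subcommands:

```sh
gibbs2pno simulate --n 500 --k 10 --seed 1 --out resp.csv
gibbs2pno fit --data resp.csv --iterations 2000 --burn-in 1000 \
              --prior-mode conjugate --out-dir samples
gibbs2pno summarize --samples samples --out-prefix posterior
gibbs2pno bench --n 200 --k 10 --iterations 200 --grid-shapes 1x1,2x2
```

`fit` writes a columnar samples store (CSV draws plus a JSON manifest) and
Table-style summary CSVs; `summarize` adds item-response-curve and
trait-density tables; `bench` times serial vs blocked runs and reports S
and E (wall-clock values are hardware-dependent).

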