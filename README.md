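# distnorm

Distribution-based normalization for expression data measured on different
platforms.

## The problem

Expression cohorts assembled over years — rare-disease studies especially —
end up profiled on several microarray generations. Each platform imprints its
own intensity distribution on the shared probesets: shifted means, inflated
variances, different skew. Classical normalizers align one or two moments
(z-score, average-difference scaling) or force a pooled empirical reference
(quantile normalization); none lets you say *which* distribution the merged
data should follow.

`distnorm` normalizes by matching whole distributions. For each data source
it fits a parametric probability density *f*(·) to the pooled intensity
histogram (polynomial, Fourier series, Gaussian, or any user-supplied form),
and maps every value *m* of a source onto the target distribution *g*(·) by
equating cumulative probabilities:

```
P_src(m) = ∫_{-∞}^{m} f(t) dt  =  ∫_{-∞}^{m'} g(t) dt  =  P_tgt(m')
```

so *m′* = *G*⁻¹(*F*(*m*)). The map is monotone: the rank order of values,
ties included, is exactly preserved — only the scale changes. The target can
be the largest source in the study or an analytic reference such as a normal
distribution.

The package also ships the comparator normalizers used in cross-platform
evaluations (per-sample z-score, average-difference scaling, quantile
normalization), the evaluation statistics (binned Kullback–Leibler
divergence, six-number summaries, MA-plot median/IQR), and a synthetic
multi-platform generator so the whole pipeline can be exercised without any
external data.

## Worked example

Simulate a four-platform cohort (shared probes, platform-specific location /
scale / skew), normalize everything onto the `U133Plus2`-like source, and
evaluate:

```r
library(distnorm)

sim <- simulate_platforms(1000, westmead_like_preset(seed = 1), seed = 1)
res <- dbnorm_normalize(sim$matrices, target = "U133Plus2")
normalization_report(sim$matrices$U133A, res$normalized$U133A,
                     sim$matrices$U133Plus2)
#> normalization_report
#>   KL vs target: 0.1401 before -> 0.003587 after
#>   MA median: -0.07091 -> 0.02666, IQR: 0.6904 -> 0.881
#>           Min. 1st Qu. Median   Mean 3rd Qu.    Max.
#> before  2.1491  5.1545 6.1217 6.3390  7.3201 14.3997
#> after  -0.1496  4.8112 6.3550 6.4007  7.9077 16.1562
#> target  0.0006  4.8293 6.3480 6.3992  7.8965 15.9962
```

The KL divergence between the `U133A`-like pool and the target drops by two
orders of magnitude (0.14 → 0.0036 nats), the six-number summary of the
normalized source now tracks the target's, and the MA-plot median log-ratio
against the target profile moves toward 0. Mapping between two analytic
Gaussians reproduces the closed-form affine law exactly:

```r
src <- make_analytic_model("gaussian", c(0, 1))
tgt <- make_analytic_model("gaussian", c(5, 2))
dbnorm_map(c(-1, 0, 1), src, tgt)$mapped_values
#> [1] 3 5 7        # m' = 5 + 2 m
```

## Command line

A thin CLI over the same functions lives at `inst/cli/distnorm.R`:

```sh
Rscript inst/cli/distnorm.R simulate --preset westmead-like --seed 17 --out-dir sim/
Rscript inst/cli/distnorm.R fit --input sim/U133A.tsv --family fourier --out src.json
Rscript inst/cli/distnorm.R transform --input sim/U133A.tsv \
    --source-model src.json --target-model tgt.json --out normalized.tsv
Rscript inst/cli/distnorm.R eval kl --a normalized.tsv --b sim/U133Plus2.tsv
```

Exit codes: 0 success, 2 validation error, 3 fit failure, 4 I/O error.
Matrices are plain TSV/CSV (probes in rows, samples in columns); fitted
models are JSON documents that round-trip exactly.

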