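# adnorm — adaptive normalization for IP-versus-Mock enrichment data

Immunoprecipitation (IP) enrichment assays — RIP-chip, ChIP, CLIP-style
experiments — compare an enriched sample against a **mock** control
purification to find the genes a protein specifically binds. On the log2
scale each measurement is modeled as

```
IP_ij   = Mock_i + T_i + c_j  + Z_ij      (T_i >= 0, zero for non-targets)
Mock_ij = Mock_i       + c'_j + Z_ij
```

with unknown additive per-replicate offsets `c_j`, `c'_j`. Conventional
median normalization assumes the median gene is unchanged between IP and
Mock — false for proteins that bind much of the transcriptome, where it
systematically understates target enrichment and caps the number of
callable targets. This package estimates the offsets **adaptively**: it
ranks the per-gene differences `Mock − IP`, treats the top-k genes (those
least enriched by the IP) as empirical background, aligns the background
medians, chooses k per replicate from where the ranked difference curve
becomes piecewise linear, and removes the ranking's selection bias using
leave-one-out Mock controls. Normalized data feed a moderated t statistic
with permutation-estimated FDR (or a plain one-sided Welch test) to call
targets.

Intended users: anyone analysing two-condition enrichment designs where an
unknown — possibly large — fraction of features is truly enriched.

## Worked example

Simulate the idealized experiment used throughout validation — 6,000 genes,
10% true targets drawn from Normal(3, 1) against Normal(0, 1) background,
3 IP + 3 Mock replicates, each replicate shifted by a hidden
Uniform(−2, 2) offset — then normalize and call targets:

```r
library(adnorm)

sim <- simulate_ip_experiment(simulation_spec(n_genes = 6000,
                                              target_fraction = 0.1,
                                              seed = 42))
res <- normalize_experiment(sim$matrix)
res
#> normalization_result (set-median)
#>        constant   k
#> IP_1    -1.0910 593
#> IP_2     1.6553 797
#> IP_3    -0.0380 500
#> Mock_1   0.1609 627
#> Mock_2  -0.0604 936
#> Mock_3  -0.1005 974
#> Mock-estimated selection bias: 1.9268 (IP scale 0.9428)

tr <- permutation_fdr(res$normalized, fdr_threshold = 0.05, seed = 42)
tr
#> test_result (sam-permutation): 96 gene(s) called at FDR 0.05
sum(sim$truth[tr$called] == "target")
#> [1] 96
```

Every `constant` is the additive correction applied to that replicate
(recovering the hidden offsets up to the shared background alignment), `k`
is the per-replicate background-set size read off the ranked difference
curve, and the reported selection bias is the leave-one-out Mock estimate
subtracted from all constants (scaled for IP replicates). Here all 96
calls at FDR 0.05 are true targets, and the normalized data align well:
background IP mean 0.111 against Mock center 0.001, target mean 3.091
against the simulated 3.

Diagnostics: `rank_plot()` shows the ranked `Mock − IP` curve with the
chosen k; `constant_vs_k_curve()` shows how the constant would move with k.
A command-line wrapper with `normalize`, `select-k`, `test`, `simulate`
and `bin-counts` subcommands is installed at
`system.file("cli/adnorm.R", package = "adnorm")`; `counts_to_logmatrix()`
adapts binned sequencing read counts.

See `vignettes/adnorm-methods.Rmd` for the model, the bias correction, the
k-selection rule, test calibration, and known limitations.

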