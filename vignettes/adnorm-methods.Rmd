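---
title: "Adaptive normalization of IP-versus-Mock enrichment data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive normalization of IP-versus-Mock enrichment data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

An immunoprecipitation (IP) enrichment experiment purifies a protein of
interest — say an RNA-binding protein — together with the nucleic acids bound
to it, and compares each gene's enrichment against a *mock* purification run
without the specific antibody or tag. On the log2 scale, the working model
for gene $i$ in replicate $j$ is

$$ \mathrm{IP}_{ij} = \mathrm{Mock}_i + T_i + c_j + Z_{ij}, \qquad
   \mathrm{Mock}_{ij} = \mathrm{Mock}_i + c'_j + Z_{ij}, $$

where $\mathrm{Mock}_i$ is the gene's non-specific background enrichment,
$T_i \ge 0$ is the true binding signal (zero for non-targets), $Z$ is
mean-zero noise, and $c_j$, $c'_j$ are unknown additive per-replicate
offsets — labelling efficiency, scanner gain, sequencing depth — that must be
removed before any between-condition test is meaningful.

Median or quantile normalization sets each replicate's median (or whole
distribution) equal, which silently assumes the median gene is *not* a
target. For factors that bind a large fraction of the transcriptome this
assumption fails and the estimated enrichment of true targets is dragged
down, bounding the number of targets that can ever be called. The
adaptive method implemented here instead anchors the normalization on the
genes that the data themselves indicate are background.

## The adaptive procedure

`normalize_experiment()` performs, for an experiment with $m \ge 2$ Mock
replicates:

1. **Mock model** (`build_mock_model()`). Each Mock replicate is
   median-centered (removing $c'_j$ exactly, since an additive offset moves
   the median by itself), the centered Mocks are averaged into
   $\overline{\mathrm{Mock}}$, and every leave-one-out average (the mean of
   the other $m-1$ centered Mocks) is formed.
2. **Difference profile** (`difference_profile()`). For each IP replicate,
   the per-gene differences $D_i = \overline{\mathrm{Mock}}_i -
   \mathrm{IP}_i$ are ranked in descending order. Genes at the top are the
   most enriched in the Mock relative to the IP — the least plausible
   targets, since $T \ge 0$ means true targets can only push $D$ down.
3. **Background set**. The top $k$ genes form $S_k$, with $k$ chosen per
   replicate by `select_k()` (below) unless fixed.
4. **Raw constant** (`normalization_constant()`). The default `set-median`
   estimator is
   $\hat c = \mathrm{median}_{S_k}(\overline{\mathrm{Mock}}) -
   \mathrm{median}_{S_k}(\mathrm{IP})$: after adding $\hat c$, the
   background set has the same median in the IP as in the average Mock.
   `set-mean` and `orderstat-mean` (the mean of the top-$k$ ranked
   differences) are provided because the averaging function applied to the
   ranked differences is a genuinely open choice; all variants agree exactly
   under a pure shift.
5. **Bias estimation via the Mocks.** Each centered Mock replicate is put
   through steps 2–4 against its leave-one-out average, *as if it were an
   IP*. A Mock contains no true signal, so its raw constant ought to be
   zero; its actual value measures the selection bias that taking the top
   $k$ of a noisy ranking injects into every constant (the expected mean of
   the top $k$ of $n$ draws of pure noise is positive).
6. **Bias correction.** The mean Mock constant $\bar b$ is subtracted from
   every constant. For the IP constants it is first scaled by
   $\rho = \sqrt{(1 + 1/m) / (1 + 1/(m-1))}$: the IP is compared against an
   average of $m$ Mocks (difference noise
   $\sigma\sqrt{1 + 1/m}$) while each Mock is compared against an average of
   $m-1$ (noise $\sigma\sqrt{1 + 1/(m-1)}$), and the selection bias of a
   top-$k$ functional is proportional to the standard deviation of the
   ranked quantity. Without $\rho$ the correction systematically
   over-corrects the IP side.

The normalized matrix holds $\mathrm{IP}_j + \hat c_j$ for IP replicates and
centered $\mathrm{Mock}_j + \hat c'_j$ for Mocks. Three properties anchor
the procedure, and each is exercised by the test suite:

* **Shift invariance (exact).** Adding any constant to one IP replicate, or
  a common constant to all Mocks, changes no normalized value: the constant
  is absorbed by $\hat c_j$ or by median centering. Verified to machine
  precision.
* **Unbiasedness without targets (stochastic).** When every gene is
  background, the corrected difference between mean IP and mean Mock
  constants recovers the true offset difference; the measured bias shrinks
  as the gene count grows (about $-0.03$, $-0.01$, $-0.002$ at 500, 2,000
  and 6,000 genes under the simulator's default noise).
* **Conservativeness with targets (stochastic, one-sided).** When targets
  are present they deplete the effective background pool, the IP's top-$k$
  reaches deeper into it, and the estimated offset difference *understates*
  the truth. Downstream testing therefore calls no more targets than
  normalizing with the true constants would — the method fails safe. At 50%
  targets the mean understatement is about $0.3$ log2 units.

The residual conservative tilt also appears, attenuated, at moderate target
fractions: at 10% targets the mean normalized background gap to the Mock
center is about $-0.04$ rather than $0$. It cannot be removed without
knowing which genes are targets, and its direction is the safe one.

## Choosing the background-set size k

The descending difference curve $D_{(r)}$ versus rank $r$ has a
characteristic shape: a curved head of extreme order statistics, a long
nearly linear stretch produced by the bulk of the background genes, and (if
targets exist) a falling tail on the right. `select_k()` operationalizes
"where the curve settles into its linear regime":

* A sliding window of `min_segment` ranks (default 500, the minimum
  knot separation assumed for genome-scale panels) is fit by least squares
  at every start position; window $R^2$ is computed in closed form from
  cumulative sums, so the scan is $O(n)$.
* The selected $k$ is the smallest candidate in `[k_min, k_max]`
  (defaults: `min_segment` and $0.9\,n$) such that **every** window starting
  within the next `min_segment` ranks reaches `r2_min` (default 0.995).
* If no candidate qualifies — rough data, tiny panels — the candidate whose
  worst window fits best is used, with a warning. Normalization remains
  valid for any $k$; the selection rule only standardizes the choice.

Numerical conventions: ties in the ranking are broken by input order
(stable radix sort), exactly constant windows count as perfectly linear
($R^2 := 1$, so a flat pure-shift profile selects the earliest candidate),
window $R^2$ is clamped to $[0,1]$, and the curve is globally centered
before the cumulative sums for conditioning. Both the selected $k$ and the
whole window-$R^2$ profile are scale- and shift-invariant. For panels with
fewer than `2 * min_segment` genes the window is scaled down to
$\lfloor n/4 \rfloor$ (floored at 20) with a warning — the 500-rank default
encodes a genome-scale assumption that small custom panels do not meet.

`rank_plot()` draws the ranked curve with the chosen $k$; on simulated data
true targets can be highlighted to check that the background set is clean
(under default simulator settings the top-$k$ set contains essentially no
targets, since targets sit about 3 noise-SDs below background on the
difference scale).

## Calling enriched genes

`sam_statistic()` implements a moderated two-class statistic
$d_i = (\bar x_{\mathrm{IP},i} - \bar x_{\mathrm{Mock},i}) / (s_i + s_0)$
with $s_i$ the pooled two-sample standard error and $s_0$ the median of all
$s_i$. The original SAM software chooses $s_0$ by minimizing the
coefficient of variation of $d$ across scatter quantiles and calls genes
through asymmetric sliding cutoffs; those refinements are deliberately not
reproduced — the moderated-$t$ structure is what the normalization
comparison needs, and `s0` is an explicit argument for anyone who wants a
different rule.

`permutation_fdr()` estimates, for each candidate one-sided threshold
(every positive observed $d$, in descending order), the expected number of
null exceedances as the **mean** count over balanced label permutations
(all $\binom{n_1+n_2}{n_1}$ distinct assignments are enumerated when few
enough, the observed assignment included; otherwise sampled with the seed).
The per-gene $q$ is the step-up minimum of estimated FDR over thresholds at
or below the gene's $d$. The mean — the convention of the original SAM
procedure — was chosen over the median after a direct calibration
experiment: with only 20 distinct 3-vs-3 assignments, the observed maximum
exceeds the *median* permutation maximum about half the time under a
complete null, so a median numerator calls false targets in roughly half of
null datasets, while the mean keeps the null call rate low. A hard floor
remains: with $B$ distinct assignments no estimated FDR at the top rank can
fall below about $1/B$, and whenever one split of a null dataset happens to
dominate nearly all relabelings, a calibrated test at FDR 0.2 will call a
gene or two. This granularity is intrinsic to 3-vs-3 designs, not to the
normalization; with 5-vs-5 replicates (252 assignments) the effect
disappears.

`welch_t_test()` provides the plain alternative: vectorized one-sided Welch
$t$ with Benjamini–Hochberg adjustment. Note its power floor: with 3
replicates per group the Welch degrees of freedom (~4) make
genome-wide-adjusted significance nearly unreachable even for 3-SD shifts;
the moderated permutation test is substantially more powerful there. The
two agree closely once the design is strong (e.g. 5-vs-5 replicates and
5-SD shifts), which is how the cross-method check in the test suite is
framed.

## The simulators, and what they do not show

`simulate_ip_experiment()` generates the idealized experiment used for all
validation: background values $\mathcal N(0, 1)$, target values
$\mathcal N(3, 1)$ for a chosen fraction of genes (defaults 6,000 genes,
10% targets, 3 IP + 3 Mock replicates), independently per gene and
replicate, plus per-replicate offsets drawn $\mathrm{Uniform}(-2, 2)$ so
that recovery is non-trivial. `simulate_mock_mock()` generates the
false-target control: all replicates drawn from one background process —
a shared per-gene level (SD 1) plus independent noise (SD 1), making
replicates correlate like biological replicates — randomly split into a
pseudo-IP and a Mock group, so every called gene is a false positive.

These simulators validate the estimator's statistical properties; they do
not emulate real-array pathologies — intensity-dependent (banana-shaped)
biases, saturation, batch structure, heavy-tailed spot noise, or
replicate-specific scale differences. Two consequences deserve emphasis.
First, passing the recovery tests says nothing about multiplicative or
intensity-dependent distortions, which this additive method does not model.
Second, on the synthetic mock-versus-mock null both adaptive and median
normalization are essentially unbiased, so the dramatic real-data contrast
in false-positive counts between the two methods — driven by real-array
artifacts interacting with the median assumption — is *not* reproduced in
this idealized setting; what remains observable is the permutation-test
granularity discussed above, equally for both normalizations.

`counts_to_logmatrix()` adapts sequencing data: bins with zero counts in
IP or Mock are removed rather than pseudocounted (a deliberate choice —
pseudocounts would inject an intensity-dependent additive distortion
exactly where the log transform is most sensitive), optional division by a
total-RNA reference accounts for sequencing bias, and the result is
log2-transformed.

## Parameters at a glance

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `estimator` | `set-median` | — | robust to stragglers inside $S_k$; matches "equalize the background medians" |
| `k` | `"auto"` | genes | per-replicate selection from the curve shape |
| `min_segment` | 500 | ranks | minimum linear-piece length; genome-scale assumption |
| `r2_min` | 0.995 | $[0,1]$ | window linearity threshold; downstream validity does not hinge on it |
| `k_max` | $0.9\,n$ | genes | keeps a tail of candidate targets out of the normalization set |
| `s0` | median of $s_i$ | log2 | moderation constant of the test statistic |
| `n_permutations` | 1000 | — | cap; small designs enumerate all assignments |
| `fdr_threshold` | 0.05 | $[0,1]$ | calling threshold |

## Validation problem sizes

The test suite validates at the simulators' native scale: 100 seeds of the
6,000-gene idealized experiment for background/target recovery, 200 seeds
at 50% targets for the one-sided conservativeness test (binomial $p <
0.01$), 100 seeds each of the median-normalization failure curve (target
fractions 0.1/0.3/0.5) and the mock-versus-mock control, with exact
brute-force oracles (window-wise `lm` fits, fully sorted top-$k$ means,
closed-form $t$) for the deterministic components. The entire suite runs
in well under a minute on one CPU because the window scan and the
statistic are closed-form vectorized.

## Known limitations

* Additive (log-scale) offsets only; multiplicative or intensity-dependent
  normalization is out of scope.
* Requires at least two Mock replicates; the bias estimate improves with
  more ($\rho \to 1$ as $m$ grows).
* Complete-case gene filtering on input; no imputation.
* The conservative tilt at high target fractions is a feature for error
  control but means enrichment magnitudes of very broad binders are
  slightly understated.
* 3-vs-3 permutation FDR has coarse granularity near its floor; prefer
  more replicates or the Welch option when replicates allow.
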