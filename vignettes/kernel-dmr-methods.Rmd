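---
title: "Methods: kernel-smoothed detection of differentially methylated regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-smoothed detection of differentially methylated regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the default parameters and
their rationale, the synthetic data generator, and the numerical choices
made in `kdmr`. It is a methods reference, not a tutorial; see the README
for a worked example.

## 1. Data model and preprocessing

Input is a matrix of methylation beta values, `b[i, j]` in the open
interval (0, 1) for probe `i` and sample `j`, plus a probe manifest with
chromosome and basepair position, sorted with strictly increasing
positions within each chromosome (`as_manifest()` enforces this).

Betas are bounded and heteroscedastic, so modelling happens on M-values,
`M = log2(b / (1 - b))` (`beta_to_m()`), which behave approximately like
unbounded, roughly homoscedastic intensities. Effect sizes are still
reported on the beta scale (`betafc`, the contrast applied to
coefficients of the beta-scale fit) because beta differences are directly
interpretable as methylation-fraction shifts.

`filter_probes()` applies standard array hygiene before analysis, with
each dropped probe attributed to the **first** matching rule in a fixed
order — detection quality, SNP proximity, cross-reactivity, sex
chromosomes:

* detection: a probe is dropped if its detection p-value exceeds 0.05 in
  *any* sample (a single bad sample invalidates the probe's row);
* SNP: dropped if an annotated SNP lies within 2 bp of the interrogated
  site with minor allele frequency above 0.05; probes with missing SNP
  annotation are retained;
* optionally, cross-reactive probes and sex-chromosome probes.

Filtering is idempotent: re-filtering a filtered dataset drops nothing.

## 2. Per-site moderated statistics

For each site, an ordinary least-squares fit of the M-values on a common
design matrix `X` (n samples, d columns) yields residual variance `s²_i`
with `d_res = n - d` degrees of freedom. Site-level variances are noisy
at typical sample sizes, so they are shrunk towards a global prior
estimated empirically from all sites. Writing
`e_i = log s²_i - digamma(d_res/2) + log(d_res/2)`, the prior df solves

```
trigamma(d0 / 2) = var(e) - trigamma(d_res / 2)
```

(by a Newton iteration on the trigamma function, `trigamma_inverse()`),
and `s0² = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The posterior
variance is the df-weighted blend

```
s̃²_i = (d0 · s0² + d_res · s²_i) / (d0 + d_res)
```

and the moderated t-statistic for contrast `c` is
`t_i = c'β̂_i / (s̃_i √(c'(X'X)⁻¹ c))` with `ν* = d0 + d_res` total df.
Limiting cases are exposed for diagnostics: `prior_df = 0` reproduces the
per-site OLS t, `prior_df = Inf` the fully pooled t. The implementation
is verified in the test suite against an independent formula-by-formula
oracle and against `limma::eBayes` when available.

Three per-site statistics `Y` with numerator df `μ` feed the smoother
(`site_statistic()`):

| option        | Y                          | μ       | use |
|---------------|----------------------------|---------|-----|
| `two_group` / `contrast` | t² (moderated)  | 1       | one-df group or contrast tests |
| `model_F`     | model F on `s̃²`           | d − 1   | omnibus multi-coefficient tests |
| `variability` | V / V̄                     | n − k   | differential variability; `V` is the per-site variance (pooled within blocks when a k-level block factor is supplied), so `mean(Y) = 1` exactly and `ν = ∞` |

## 3. Kernel smoothing and the Satterthwaite null

A single-site statistic is noisy; biologically meaningful methylation
changes extend over regions. `Y` is therefore smoothed along each
chromosome with an **unnormalised** Gaussian kernel
`K(Δx) = exp(-Δx² / (2σ²))`, so a site's own weight is always
`K(0) = 1` and an isolated site is left untouched rather than averaged
into nothing. The bandwidth is `σ = λ / C` with defaults `λ = 1000` bp —
a scale typical of CpG-island-sized methylation features — and `C = 2`,
giving `σ = 500` bp. Each site accumulates three running sums over
in-range neighbours: `S_KY = Σ K Y`, `S_K = Σ K`, `S_KK = Σ K²`.

Under the null each `Y` is approximately a chi-squared with `μ` df (scaled
by `ν*/(ν*−2)`, absorbed into the moment matching), and a positively
weighted sum of chi-squareds is well approximated by a scaled chi-squared.
Matching the first two moments (Satterthwaite) gives

```
S_KY ≈ a · χ²(b),   a = S_KK / (μ · S_K),   b = μ · S_K² / S_KK
```

Note `a · b = S_K`: the null mean of the smoothed statistic equals the
weight it accumulated, a conservation property the tests assert
everywhere. An isolated site has `S_K = S_KK = 1` and so `b = μ` exactly,
and `b` grows with local probe density — dense regions effectively borrow
df from their neighbours. Degrees of freedom are deliberately fractional;
no rounding is applied. P-values are
`P = Pr(χ²_b > S_KY / a)` via `pchisq(..., lower.tail = FALSE)`.

All p-values across the genome are corrected in a single
Benjamini–Hochberg family (`bh_adjust()`, a thin wrapper over
`stats::p.adjust(method = "BH")`) — per-chromosome correction would make
significance depend on arbitrary chromosome boundaries.

## 4. Region agglomeration

Sites with `Q` strictly below the threshold (default 0.05) are grouped
per chromosome into maximal runs in which consecutive significant sites
are at most `λ` apart — the same `λ` as the kernel scale, so the merging
distance and the smoothing support agree. A region spans from its first
to its last significant CpG with **no padding**; single-site regions are
allowed. Regions are ranked by minimum constituent `Q` (ascending), then
by CpG count (descending), then by coordinate. `filter_regions_by_betafc()`
keeps regions whose largest-magnitude constituent beta-scale effect
strictly exceeds a floor, removing statistically crisp but biologically
negligible calls.

`consecutive_positions()` replaces basepair coordinates with per-
chromosome ranks (times a unit), turning the genomic-scale kernel into a
k-nearest-neighbour-style smoother for designs where probe spacing, not
genomic distance, should define adjacency.

## 5. The synthetic data generator

`simulate_dataset()` produces a fully specified benchmark: a manifest of
promoter-like probe clusters plus scattered background probes, a beta
matrix for a two-group design, and a nucleotide-resolution truth table.

* **Manifest** (`make_manifest()`): clusters of 10–30 probes with
  intra-cluster gaps of `2 + Poisson(38)` bp, and background probes with
  exponential gaps of mean 8 kb, laid out over 22 chromosomes. Full scale
  is 15,000 clusters plus 185,000 background probes (≈ 485,000 total);
  the desk-scale preset (`desk_scale_config()`) uses 1,500 clusters of
  8–20 probes plus 29,000 background probes (≈ 50,000).
* **Betas** are drawn from mode-parameterised Beta distributions:
  `alpha = mode·(conc − 2) + 1`, `beta = (1 − mode)·(conc − 2) + 1`, so
  the mode is specified exactly and the concentration (default 50)
  controls spread. Background probes are bimodal — mode 0.03
  (unmethylated) or 0.93 (methylated) with probability one half each —
  the canonical two-mode shape of array methylation data.
* **Planted DMRs**: 2,162 clusters at full scale (200 at desk scale) are
  made differential, half hypermethylated and half hypomethylated in the
  treatment group, with the treatment mode offset from the control mode
  by **exactly 0.2** on the beta scale; the control mode is drawn
  uniformly so the shifted mode stays inside the clip bounds.
* **Final adjustment**: all betas are clipped into [0.01, 0.99], keeping
  the logit transform finite.

The defaults (20 samples, 10 vs 10) are the package's reference study
conditions; tests and examples use them unmodified.

What the simulator deliberately does **not** emulate: probe-type
chemistry differences and their intensity biases, batch or slide
effects, correlated biological variation between neighbouring probes
beyond the shared cluster mode, sex chromosomes, SNP-affected or
cross-reactive probes (the filter rules are tested on hand-built
fixtures instead), and realistic genome sizes. Results on it measure
the pipeline's statistical behaviour, not preprocessing robustness.

## 6. Evaluation harness

`nt_confusion()` scores calls against truth at nucleotide resolution —
true positives are bases covered by both call and truth (intervals are
unioned first, via `GenomicRanges::reduce`, so overlapping calls are not
double-counted). `titrate_thresholds()` takes up to 200 quantile-spaced
thresholds over the achieved score range; `pr_curve()` calls the pipeline
at each, orders the points by recall, drops points with undefined
precision, and integrates precision by the trapezoid rule **over the
achieved recall range only** — no extrapolation to recall 0 or 1.
`shuffle_intervals()` provides the matched null: called regions are
re-placed uniformly at random preserving widths and chromosome
assignment.

## 7. Numerical choices

* Kernel sums use a per-chromosome sliding-offset sweep over sorted
  positions with an 8σ truncation radius (weights below `e^{-32}` are
  discarded); the suite verifies agreement with a dense O(n²) oracle to
  1e−10 relative error.
* `S_KK` is floored at `eps · S_K²` before the Satterthwaite division to
  guard against degenerate all-zero-weight input.
* Thresholds are strict (`Q < q`, `|betafc| > floor`), so boundary values
  never change group membership between runs.
* BH is delegated to `stats::p.adjust`; region merging and kernel sums
  are validated against independent transitive-closure and dense oracles.

## 8. Open design decisions and limitations

* The scaled chi-squared null for `S_KY` is a moment approximation; its
  accuracy degrades for very small `ν*` (heavy-tailed t²). The suite
  bounds this empirically (Monte-Carlo moment checks, global-null
  pipeline calibration) but extreme small-sample designs deserve caution.
* Smoothing `t²` discards sign, so a region mixing hyper- and
  hypomethylated probes can be called as one; the per-site `betafc`
  column is the tool for dissecting such calls.
* `λ` couples two roles — kernel scale and merge gap. This is a
  deliberate simplification; decoupling them is possible via the
  `lambda` argument of `call_regions()` but not exposed in the pipeline.
* The defaults target 450K-style probe densities. Much denser platforms
  would concentrate `S_K` and may warrant smaller `λ`.
* P-values at agglomeration are per-site, not per-region; region-level
  error control is inherited from the site-level BH family.
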