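---
title: "Smart pooling: expander designs and l1 decoding"
author: "smartpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart pooling: expander designs and l1 decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartpool)
```

## The model

A pooled ("multiplex") expression experiment mixes `n` mRNA samples into
`m < n` pools according to a binary design matrix `Φ` and assays each pool
on one chip. For each gene, if `x` is its (unknown) vector of per-sample
linear-scale intensities and intensities mix additively, the chip readouts
are `y = Φx`: an underdetermined linear system, one per gene.

The system becomes solvable under a sparsity assumption: most genes sit
near a constant baseline across samples and deviate ("spike", up or down)
in only a few. Writing `x = c·1 + s` with `s` sparse, the decoder recovers
`x` as the minimum-l1-norm vector consistent with the measurements (basis
pursuit),

$$\hat z = \arg\min_z \|z\|_1 \quad \text{s.t.} \quad \Phi z = y,$$

solved as a linear program by splitting `z` into nonnegative positive and
negative parts. Recovery is guaranteed when `Φ` is the adjacency matrix of
a left-`d`-regular unbalanced `(2k, ε)` expander — every subset `X` of at
most `2k` samples reaches at least `(1 − ε)·d·|X|` distinct pools — in
which case the l1 decoding error is bounded by a design-dependent constant
times the l1 mass of `x` outside its `k` largest-magnitude entries (the
"sparsity tail"). Exactly `k`-sparse profiles therefore decode exactly;
approximately sparse profiles decode with an error proportional to their
deviation from sparsity, and measurement noise enters the same way.

Two assumptions carry all of this and both are testable in the package:
*linearity* of pooled measurements (the forward operator `pool_profile()`
is exactly linear; real assays approximate this) and *sparsity* of the
profiles about their median.

## Why decoding centers on the median baseline

Basis pursuit is sparsity about **zero**, but expression profiles are
sparse about their **baseline**. The distinction matters more than it may
seem. For any column-regular binary design, summing the measurement rows
gives `sum(y) = d · sum(z)` for every feasible `z`, so every *nonnegative*
feasible vector has the same l1 norm `sum(y)/d`: on a dense
baseline-plus-spike profile the LP optimum is massively non-unique, and a
vertex solver will return some `m`-sparse solution, not the true dense
profile.

The package therefore exposes baseline centering
(`decode_options(center_baseline = TRUE)`): the shared baseline `c` is
estimated as the lower median of the per-pool ratios `y_i / rowsum_i`
(pools untouched by any spike read exactly `c · rowsum_i`, and with `k·d`
perturbed pools out of `m` the median is exact whenever unperturbed pools
are in the majority), the centered system `Φz = y − c·Φ1` is decoded, and
`c` is added back. For noiseless 1-spike profiles on a certified design
this is exact, which is how the simulation harness attains an exact
recovery rate of 1. Centering is off by default in `decode_profile()` so
that the raw program matches the classic equality-constrained decoder;
`run_experiment()` enables it because the generator's sparsity is defined
about the median. Pools that receive no sample are excluded from the ratio
median (they carry no baseline information; their `y_i = 0` rows still
constrain the LP).

## Designs and their certification

`build_design(n, m, d, seed)` draws each column's pool set uniformly among
the `choose(m, d)` possibilities, resampling collisions, so column supports
are pairwise distinct; requests with `choose(m, d) < n` fail with the
counting bound. Distinctness alone already certifies `(2, 1/4)` expansion
at `d = 2` — any two distinct degree-2 supports cover at least 3 pools —
which is why a 12-pool, 15-sample, degree-2 design guarantees one spike.
The random construction was chosen over structured (coding-theoretic)
expanders for simplicity and seeded reproducibility; certification is
always explicit, by `verify_expansion()`'s exhaustive enumeration (with a
hard subset budget, default 1e6 — no silent sampling), never assumed from
the construction.

`design_for_guarantee(n, k, ε, d)` searches increasing `m`, drawing up to
`max_attempts` designs per size and returning the first certified
`(2k, ε)` expander. Small ε at `k ≥ 2` needs `m` well above `n` for random
designs (e.g. a `(4, 1/4)` certificate at `n = 10`, `d = 4` first appears
near `m = 32`), consistent with pooling's economy being asymptotic: the
`chips_needed()` rule `round(k·ln(n/k))` — natural log, round-to-nearest,
chosen to reproduce the worked value 23 at `(n, k) = (100, 10)` — is an
asymptotic noise-free lower bound, not the `m` of a constructible small
design.

The default certification slack is `ε = 1/4`: it is the smallest slack any
`d = 2` design with overlapping column pairs can achieve (a shared pool
gives `|N(X)|/(2·2) = 3/4` for that pair), and it suffices for the 1-spike
guarantee used throughout. It is configurable wherever it appears.

## The solver

No equality-constrained l1 solver ships with the environment-independent
dependencies this package allows itself, so the LP core is a dense
two-phase primal simplex written for the decoder's problem sizes (tens of
variables): Bland's smallest-index rule everywhere, because pooled
measurement vectors contain exact zeros and the resulting degenerate bases
would otherwise risk cycling; an all-artificial phase-1 basis with
leftover artificials driven out and redundant rows dropped, so
rank-deficient designs are handled; no big-M terms, which are numerically
fragile at microarray intensity scales (~1e4). Pivot tolerance is 1e-9;
`decode_options(solver_tolerance = 1e-8)` governs the post-hoc
feasibility check (`residual_l1` relative to `sum|y|`). Correctness is
cross-checked in the test suite against an independent exhaustive
support-enumeration oracle on small instances.

Ties among optimal vertices are accepted: the optimum *value* and the
residual are unique even when the argmin is not, and all guarantees are
asserted on values and errors. The `δ`-relaxed program
(`noise_tolerance > 0`) replaces `Φz = y` with `sum|Φz − y| ≤ δ` via a
split residual and one budget row; note the optimizer will spend the full
budget whenever that lowers the l1 norm, so `δ` should reflect the actual
noise scale. With `nonnegative = TRUE` and centering, the bound
`x = c + z ≥ 0` is enforced with per-coordinate slack rows; without
centering, nonnegativity plus equality constraints can be infeasible for
noisy measurements — the status is reported, never zero-filled.

## The synthetic-data generator

`simulate_profiles()` draws, per gene, a baseline `b ~ N(8, 2²)` in log2
units (resembling RMA-scale chip intensities), replicates it across
samples, and perturbs `k` uniformly chosen samples by ±3 log2 units
(`spike_log2_magnitude`, about an 8-fold change; sign is down with
probability `down_spike_fraction = 0.5`). Intensities are `2^value`, hence
strictly positive: down-spikes are bounded below by zero by construction.
`k` may be fixed or drawn per gene from a distribution over counts.
`add_measurement_noise()` multiplies each pooled measurement by `2^e`,
`e ~ N(0, noise_log2_sd²)` with default sd 0.25, inflated by
`low_intensity_noise_boost = 2` below 64 linear units — emulating the
decaying signal-to-noise of array assays near background. These defaults
are stand-ins chosen once to resemble typical chip data; no published
quantitative noise model for pooled hybridizations exists to calibrate
against, and all values are recorded in every report.

What the generator does *not* emulate: probe-level effects and
normalization artifacts, chip spatial structure, gene–gene correlation,
and the separate-normalization offsets seen when two real experiments are
preprocessed independently. Passing tests therefore demonstrate the
decoding mathematics under the stated data model, not performance on any
particular laboratory dataset.

## Evaluation conventions

* Exact recovery: relative l1 error below 1e-4 (solver-tolerance-driven;
  noiseless exact decodes land near 1e-13).
* Spike calls: deviation of `log2(x̂ + 1)` from the profile's median by at
  least 1 log2 unit (the +1 keeps zeros finite). This is a scoring
  convention, not a differential-expression test.
* Median centering uses the lower median for even sample counts — a
  deterministic tie rule.
* The error-bound constant `C` in `check_error_bound()` is not available
  in closed form for a given design; the acceptance suite calibrates it
  empirically as the maximum error/tail ratio over a fixed-seed batch of
  500 two-spike simulations and asserts the bound with a factor-2 margin
  on an independent batch.

## Problem sizes

The shipped tests certify the 12×15 degree-2 design exhaustively (120
subsets), decode all 30 signed single-spike profiles, enumerate all 180
signed two-spike profiles on the `(4, 1/4)`-certified design, run the
monotonicity sweeps with 200 genes per spike-count and noise level, and
use 2 × 500 simulations for bound calibration — sizes chosen so the whole
suite certifies every claim exhaustively where enumeration is feasible and
with stable Monte-Carlo averages where it is not, while remaining quick to
run routinely.

## Limitations

* The decoder is gene-independent; correlation-aware or group-sparse
  decoding is out of scope.
* Random search in `design_for_guarantee()` is practical for `k ≤ 2` at
  tool scale; deterministic expander constructions are not implemented.
* `verify_expansion()` is exponential in `k` by design (it is a
  certificate, not a heuristic); the subset budget makes the cost explicit.
* Real pooled experiments normalize each chip separately; the resulting
  scale offsets are visible as deviations from the 45° line when comparing
  synthetic to measured pools and are not modelled here.
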