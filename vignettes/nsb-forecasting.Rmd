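---
title: "Forecasting dissolved oxygen with a semi-naive Bayes difference model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting dissolved oxygen with a semi-naive Bayes difference model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsbforecast)
```

## The model

Dissolved-oxygen sensor series are continuous, diurnal and nonstationary,
but their first-order differences are approximately stationary and — at
the resolution a field sensor reports — take a modest number of distinct
values. `nsbforecast` exploits this: it rounds each difference to a fixed
precision, treats the rounded values as categorical symbols, and forecasts
the next symbol with a semi-naive Bayes classifier.

A sliding window of length $L$ over the symbol stream produces training
samples: attributes $x_1 \dots x_d$ (the first $d = L-1$ symbols) and class
$y$ (the last). A window of length $L$ slid with stride 1 over $Z$ symbols
yields $Z - L + 1$ samples; every consecutive window is used, none is
discarded. Classes whose relative frequency is not strictly above a
threshold $\gamma$ are filtered out before fitting, which suppresses
rare outlier categories without editing the raw series.

Scoring relaxes naive Bayes' independence assumption by letting every
attribute depend on one *super-parent* attribute and averaging over the
choice of super-parent:

$$P(y \mid \mathbf{x}) \;\propto\; \sum_{i=1}^{d} \hat P(y, x_i)
  \prod_{j=1}^{d} \hat P(x_j \mid y, x_i)$$

with Laplace-smoothed estimates

$$\hat P(y, x_i) = \frac{|D_{y,x_i}| + 1}{|D| + N A}, \qquad
  \hat P(x_j \mid y, x_i) = \frac{|D_{y,x_i,x_j}| + 1}{|D_{y,x_i}| + A}.$$

Two conventions deserve a note. First, the inner product runs over *all*
$j$, including $j = i$: classic AODE excludes the super-parent from its own
product, this model deliberately does not (the $j = i$ factor is a
class-and-value dependent constant, so rankings shift only through the
smoothing denominators). Second, every attribute position draws from the
one shared difference alphabet, so all per-position cardinalities are set
to the global alphabet size $A$; this makes both smoothed families sum
exactly to one over their support, a property the test suite asserts for
every fitted model.

The predicted difference is the maximum-posterior class, added to the
current *observed* level — walk-forward, one step ahead, never feeding a
prediction back in as input. Forecasting is honest in the other direction
too: the attribute window at each step contains only observed differences.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `L` | window length; $d = L-1$ attributes | 4 | three predecessors disambiguate cyclical phase; larger $L$ costs time and splits counts |
| `gamma` | minimum class frequency (strict `>`) | 0 / 0.01 | 0 keeps everything; ~0.01 removes sensor-glitch categories on noisy data |
| `decimals` | difference rounding precision | 2 | 0.01 mg/L, a typical DO sensor resolution |
| `split_fraction` | chronological train share | 0.9 | standard walk-forward protocol: first 90% train, last 10% test |

Rounding is half-to-even, and `-0` is folded into `+0` so the two are one
symbol. Differences are discretized but never clipped: a spike produces a
legitimately large symbol, and $\gamma$ — not preprocessing — decides
whether it participates as a class.

## Incremental updates

The model state is integer count tables (class counts, (class, position,
value) pair counts, (class, position, value, position, value) triple
counts). `nsb_update()` adds the counts of new samples to an existing
model and is *exactly* equivalent to refitting on the pooled data — the
test suite checks table-for-table identity on random splits. New symbols
extend the alphabet, which enlarges the smoothing denominators
retroactively for all classes, exactly as a refit would. Models serialize
to schema-versioned JSON with counts as integers and symbols as
fixed-precision decimal strings, so a save/load round trip is lossless.

## The synthetic generator

`generate_sinusoidal()` emulates what a DO sensor on a marine ranch
records, so the whole pipeline is testable without any data download:

* a diurnal sinusoid: mean 8 mg/L, amplitude 1 mg/L, period 288 samples
  (one day at 5-minute sampling) — typical summer pond/ranch dynamics;
* Gaussian innovations of sd 0.02 mg/L injected **on the difference
  scale** (a random-walk component), so first differences are Gaussian
  around the cycle's slope — mirroring the approximately normal difference
  histograms real DO series show;
* mean-reverting "mutation" spikes: with probability 0.002 per step a
  ±1.5 mg/L offset appears, holds for 6 steps (30 min) and reverts,
  leaving the data before and after in stable ranges;
* quantization of the emitted levels to the 0.01 mg/L sensor grid, as a
  real instrument reports. Quantization is also what makes the
  noise-free cyclical regime *exactly* learnable: predicted differences
  and observed levels live on the same grid, so a correct symbol
  prediction reconstructs the next level exactly.

With noise and spikes off, the difference symbols repeat with the
configured period, and a window of three predecessors (L = 4) identifies
the phase of a period-12 cycle unambiguously — the held-out forecast error
is then zero to floating tolerance (asserted at 1e−12; grid-aligned
doubles leave ~1e−15 arithmetic residue). A first-order Markov generator
over a small symbol set (`generate_markov_diffs()`) complements it as a
stochastic ground truth whose Bayes-optimal one-step accuracy is
computable from the transition matrix.

What the generator does **not** emulate: sensor drift and recalibration
steps, missing-data gaps, weather-driven multi-day trends, and
cross-parameter coupling (temperature, chlorophyll). Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
recovery of known structure, not field performance on any particular
ranch.

## Evaluation

`metrics_report()` computes MAE, RMSE, MAPE (a proportion; the CLI prints
both proportion and percent) and Willmott's index of agreement

$$WIA = 1 - \frac{\sum_i (O_i - P_i)^2}
  {\sum_i \left(|P_i - \bar O| + |O_i - \bar O|\right)^2} \in [0, 1],$$

which is 1 exactly when predictions match observations (identical constant
series are defined as a perfect match) and scale-free otherwise. MAPE
refuses zero observations rather than returning infinity.

`dm_test()` implements the Diebold–Mariano comparison of two forecasts
under absolute or absolute-percentage loss. For one-step forecasts the
loss differential is taken serially uncorrelated, so the long-run variance
is the plain sample variance (truncation lag 0) and the statistic is
referred to the standard normal, two-sided — the classic test at horizon
one. The Harvey–Leybourne–Newbold small-sample correction (factor
$\sqrt{(n-1)/n}$, $t_{n-1}$ reference) is available behind a flag and off
by default. Degenerate zero-variance differentials return statistic 0 with
p = 1 when the mean differential is also zero, otherwise ±Inf with p = 0.

## Numerical choices

* Per-super-parent products are accumulated in the log domain and
  exponentiated before the outer sum (the terms are *added*, so a pure
  log-domain evaluation is impossible); at the window lengths this model
  uses ($d \lesssim 50$) the exponentiated terms are far from underflow.
* Argmax ties (scores equal to within 1e−12 relative) break
  deterministically: larger training class frequency, then smaller
  absolute symbol value, then smaller signed value — a "prefer the
  common, prefer the calm" rule that makes runs byte-reproducible.
* Window symbols unseen in training keep the alphabet fixed and simply
  contribute zero counts; smoothing supplies their mass. If a probe
  window is entirely unseen, all classes tie and the frequency tie-break
  yields the modal class.
* Score normalization to a probability vector is a reporting convenience;
  the argmax is invariant to it, and raw log-domain scores are returned
  alongside.

## Design decisions that were genuinely open

* **Window count.** Stride-1 windowing of $Z$ symbols admits $Z - L + 1$
  windows; descriptions of the scheme sometimes state $Z - L$. Discarding
  one window would be arbitrary, so all $Z - L + 1$ are used.
* **What $\gamma$ filters.** Whole samples whose *label* is rare are
  dropped and the class set shrinks accordingly; rare values remain legal
  as attributes. Frequencies are measured once, on the operator's input —
  re-applying the filter to its own output may remove more, and the
  documented contract is the single pass.
* **Reconstruction alignment.** Each predicted difference is added to the
  observed level at the current moment (walk-forward), not chained onto
  previous predictions; `reconstruct()` also inverts differencing exactly
  from a scalar anchor.
* **Filtering scope.** Only training samples are filtered; the test
  stream is never edited.
* **Config files.** The CLI accepts YAML configuration files, with
  command-line flags taking precedence.

## Problem sizes used in the checks

The packaged checks run at deliberately modest sizes: 200 randomized toy
instances (≤ 8 samples, alphabet ≤ 4, L ≤ 4) for the brute-force scorer
cross-check; a 600-point period-12 cyclical series for exact learnability;
5,000-symbol Markov streams for accuracy recovery, with accuracy measured
on an independently generated 5,000-symbol stream so that binomial
measurement noise (≈ 0.7 points) is small against the 3-point acceptance
band; 500 replicates of length-100 error pairs for DM null calibration;
and a 10,000-point default-regime series for the end-to-end pipeline.

## Limitations

* The classifier is first-order in the *window* sense only: dependence
  beyond $L - 1$ lagged differences is invisible to it.
* Accuracy is count-driven; early in a deployment, with few samples per
  class, predictions degrade toward the smoothed prior.
* A difference alphabet that grows with noisier data dilutes counts;
  `decimals` and `gamma` jointly control that trade-off, and there is no
  automatic selection — `cmd_sweep()` exists precisely to map the
  $(L, \gamma)$ surface for a given series.
* Multi-step forecasts (recursively feeding predictions) are out of
  scope, as are multivariate series and seasonal/higher-order
  differencing.
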