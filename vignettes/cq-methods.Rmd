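---
title: "Competitive queuing of prepared action sequences: models, decoding and controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive queuing of prepared action sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqdecode)
```

## The scientific question

When a skilled actor prepares a memorized sequence of actions -- here, five
finger presses with trained inter-press intervals of 550, 650, 800, 983 and
1300 ms -- competitive-queuing (CQ) models hold that *all* upcoming actions
are activated in parallel before the first movement, with activation strength
graded by serial position. The most active item wins a winner-take-all
competition, is executed, and is self-inhibited, so a parallel plan unrolls
into serial behaviour. The rival associative-chaining view predicts instead
that only the first item is prepared, each action cueing the next.

The decoding signature of CQ in multichannel recordings is concrete: a
classifier trained to recognize the activity pattern preceding each press
should, when applied to the *preparation* period, report posterior
probabilities ordered by upcoming position -- stable over time, not ramping.
This package implements that analysis end to end on synthetic data with known
ground truth: a generator for multichannel epochs, the Gaussian-linear
decoder, the CQ distance statistic with its transfer regimes and confound
controls, a sensor searchlight, and the CQ network model itself.

## The CQ network model

`context_states()` builds a temporal context layer in one of three standard
forms: a decaying start signal, mixed start and end signals, or overlapping
Gaussian states of width `sigma_c` on a position axis (overlap between
positions $i$ and $j$ is $\exp(-(i-j)^2/4\sigma_c^2)$). `encode()` associates
context states with items by Hebbian outer products,
$W \mathrel{+}= s_t \otimes \mathrm{onehot}(\mathrm{item}_t)$; `recall()`
replays the context, adds i.i.d. Gaussian noise of SD $\sigma_n$ at the
choice layer, picks the argmax and self-inhibits it. Self-inhibition is
absolute by default (produced items leave the competition); a graded factor
is available via `cq_network(inhibition_factor = )`.

```{r model}
ctx <- context_states("overlapping_states", 5, list(sigma_c = 1))
net <- encode(cq_network(ctx, 5), c(2, 4, 1, 5, 3))
round(planning_activations(net, 1), 3)  # graded queue at recall onset
recall(net)$order                       # noiseless recall is exact
```

Under choice noise the model's errors are overwhelmingly *adjacent*
transpositions (`error_profile()` reports the distance histogram), and
flatter context overlap trades gradient separation for error rate -- the
model-level analogue of the empirical CQ-accuracy association.

## The synthetic data generator

`simulate_trial()` emits a channels-by-samples epoch at 1000 samples/s,
spanning 2.8 s before to 8.5 s after the go cue:

* **Preparation** (cue to go, duration uniform on 1.8--2.2 s): a *constant*
  superposition $\sum_k g_k p_k$ of the five press patterns with gradient
  $g$. The constant (non-ramping) profile is deliberate: the slope control
  below tests the ramping alternative, and the generator must realize the
  null it claims.
* **Production**: each press adds its pattern under a unit-amplitude Gaussian
  envelope (SD 50 ms). Any smooth unimodal envelope would serve; the
  Gaussian is analytically convenient for tests.
* **Patterns**: `make_pattern_basis()` draws three orthonormalized families
  -- finger identity, preceding target interval, ordinal position -- and
  composes press patterns with mixture weights, so the transfer analyses
  have a known factorization to recover.
* **Confounds and behaviour**: i.i.d. Gaussian sensor noise; optional
  spatially rank-1 AR(1) common drift; multiplicative timing noise;
  occasional adjacent transpositions of presses 2--5 (press 1 is common to
  all sequences and never moves).

### Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| channels | 64 | desk-scale stand-in for a whole-head array; configurable to 275 |
| `prep_gradient` | $0.3 \times 0.75^{0:4}$ | geometric queue, peak 0.3 of the production pulse; amplitude scales are not constrained by recordings, so this is a modelling choice |
| `noise_sd` | 1.0 | calibrated so preparation posteriors are *graded* (roughly 0.29 down to 0.12 across positions) rather than saturated, and production decoding is high but imperfect (~0.9) |
| `timing_noise_sd` | 0.2 | yields ~16% mean absolute temporal error, inside the empirically typical 10--33% range |
| `finger_swap_prob` | 0.02 | typical 2% incidence of finger-order errors |
| `pulse_sd` | 50 ms | a press-locked transient of ~±150 ms support |
| shrinkage `lambda` | 0.1 | with more channels than training rows per class the pooled covariance is singular; shrinkage toward the scaled identity is mandatory and exposed in the API |

The default sequence set (`default_sequences()`) fixes the first press's
finger and interval across all four sequences and *deranges* positions 2--5
between the two finger orders and between the two interval orders. The
derangement is what makes the factorial transfer logic identifiable: if some
finger kept its position across orders, finger and position codes would be
partially confounded. `random_sequence_set()` draws per-subject sets under
the same constraints.

## Decoding

Features are per-channel means over non-overlapping half-open 10-ms windows
(`extract_window_means()`; 5/20/50 ms supported). Training rows are the
windows *ending at* each press onset, `[onset - 10, onset)`, from
correct-finger trials only. The classifier (`fit_gaussian_linear()`) uses
per-class means, one pooled class-demeaned covariance with shrinkage
$(1-\lambda)S + \lambda \bar{s} I$, and uniform priors; posteriors are
computed in the log domain with log-sum-exp normalization. Argmax ties break
to the lowest press index. No baseline correction or filtering is applied.
`crossval_decode()` provides sequence-stratified k-fold validation so that
production-window accuracies are never computed on a trial's own model.
`smooth_trace()` (100-ms boxcar) exists for display only; every statistic is
computed on unsmoothed traces.

## The CQ distance and its reading of the aggregation

For each trial, each consecutive press pair $(k, k+1)$ contributes the
*median* over preparation windows (the final 1 s before go) of
$p_k - p_{k+1}$; the trial's $d$ is the mean of the pair medians, the session
aggregate the mean over trials. The phrase "single trial median averaged
across trials" admits a second reading -- a median over the pooled
pair-by-window differences -- which is available as
`cq_distance(aggregation = "pooled_median")`; the pair-median-then-mean
order is the default. The variant without press 1 (`presses_2_5`) exists
because the first press is shared by design across sequences.

Transfer regimes re-pair training and test sequences: `within` (same
sequence), `temporal` (same intervals, different fingers), `spatial` (same
fingers, different intervals), `positional` (both different). Each regime's
aggregate averages over all four ordered train/test pairs. With a pure
position code the positional-transfer $d$ matches the within $d$; with a
pure finger code, temporal transfer scrambles the queue for presses 2--5 and
$d$ collapses.

## Confound controls

* **Slopes** (`probability_slope()`): OLS slope of each press probability
  over the preparation window. Temporal proximity to the upcoming presses
  predicts positive slopes; a stable queue predicts zero.
* **Pattern similarity** (`pattern_similarity()`): channel-wise correlation
  of each training mean with every window, to show the pipeline's CQ is not
  a smooth autocorrelation artifact.
* **Drift-only data**: the `drift-only` preset generates *no* preparatory
  patterns but a strong slow rank-1 AR(1) drift; the pipeline must not
  manufacture CQ from it.
* **EMG**: the 4-channel generator pre-activates only the first press's
  muscle pattern. The muscle basis is a deterministic synthetic synergy
  geometry -- fingers 2--5 mutually orthogonal and equiangular to finger 1 --
  so presses 2--5 are exactly exchangeable and any graded ordering among
  them would be a pipeline artifact.

## Statistical units: trials versus subjects

A subtlety that the synthetic ground truth makes visible: within one
session, every trial of a sequence is decoded by the *same* fitted
classifier. The classifier's class-mean sampling error therefore induces a
small session-fixed bias in $d$ (order $10^{-3}$ under the null at 240
trials), which trial-level bootstrap CIs cannot see -- they treat a biased
mean as precisely estimated. Claims that an aggregate $d$ is zero (the
cq-off, drift-only and EMG controls) are therefore made across synthetic
subjects (`group_cq_study()`: independent sequence draws, bases and noise),
the same unit of replication used in group neuroimaging. The positive CQ-on
effect is large enough to show at both levels.

## Searchlight

`neighbors()` builds 3-channel searchlights (each channel plus its two
nearest layout neighbours, ties broken by channel id). `searchlight_cq()`
trains per-searchlight classifiers and probes a single 10-ms window starting
500 ms before go; per-channel values are medians across trials within
sequence, then means across sequences, then z-scored across channels
(population SD). `searchlight_accuracy()` maps 5-fold cross-validated
production decoding accuracy. `group_tmap()` runs a one-sided one-sample t
test across subjects per channel (directional CQ hypothesis), reports
zero-variance channels as infinite-t sentinels excluded from the
significance mask, and thresholds at an uncorrected 0.01 by default.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` run sessions of 240 trials (10
blocks x 6 repetitions x 4 sequences) at 64 channels -- the study-scale
condition -- for the CQ recovery, transfer-dissociation, drift and EMG
checks (groups of 6 synthetic subjects where the claim is a null), 10
replicate sessions for searchlight support recovery, 200 replicates of
16-subject null maps for the group error rate, and 10,000-trial Monte Carlo
runs for the network model. Unit tests use 16-channel, few-dozen-trial
sessions of the same generator.

## Known limitations

The generator is a statistical emulator, not a biophysical one: no sensor
geometry or forward fields, no spectral structure beyond the optional AR(1)
drift, no learning dynamics across training days, and preparation amplitude
scales are modelling choices. Passing recovery tests therefore shows the
*pipeline* is sound -- unbiased under its nulls, sensitive to planted
structure -- not that any particular real dataset satisfies the generator's
assumptions. Source-space analysis (beamforming, anatomical attribution) is
out of scope, as are repeated-measures ANOVA group models, which the
pairwise contrasts and simulation-based CIs here deliberately replace.
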