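---
title: "Detecting cross-regional assemblies and loop-like motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cross-regional assemblies and loop-like motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`assemblymotifs` infers coordinated multi-neuron activation patterns — cell
assemblies — from parallel spike trains recorded across brain areas, and
censuses them as directed functional-network motifs relative to a focal
area (the zona incerta, "ZI", by default). This vignette documents the
model, the statistical machinery, the synthetic benchmark that validates
it, and the design decisions that were genuinely open.

## The detection model

An assembly is operationalized as a pair or triplet of units whose
binarized, binned spike trains co-occur at some fixed lag far more often
than independence predicts.

**Coincidence statistic.** At resolution $\Delta$, unit trains are binned
into half-open bins $[t\Delta, (t+1)\Delta)$ and binarized. For a unit
pair the lagged coincidence profile is
$c(\ell) = \sum_t \min(\tilde x_A(t), \tilde x_B(t+\ell))$,
$\ell \in [-L, L]$: the number of bins in which a spike of one unit is
followed $\ell$ bins later by a spike of the other. The lag $\ell^*$
maximizing $c$ is selected (ties resolve to the smallest $|\ell|$,
negative before positive, so a symmetric profile is called synchronous
rather than arbitrarily directional).

**Null model.** Under independence, the expected number of coincidences at
any lag is $\sum_k T_k\, \hat p_{A,k}\, \hat p_{B,k}$, where the session's
bins are split into $n_\mathrm{chunks} = 5$ contiguous blocks and
$\hat p_{\cdot,k}$ are empirical bin-occupancy probabilities per block.
Chunking makes the test robust to slow firing-rate drift: a common rate
increase raises the expected count where it raises the observed one. The
total null count is modeled as Poisson (the Poisson tail slightly
dominates the exact binomial tail, a conservative choice), and the
upper-tail p-value for $c(\ell^*)$ is Bonferroni-multiplied by the
$2L + 1$ lags examined.

**Multiplicity.** The grid spans ten resolutions (10–100 ms; maximal
delay capped below 200 ms), so a 20-unit session runs 1900 pairwise tests.
We Holm-adjust across *all* (pair × resolution) tests of a run by default.
Adjusting within each resolution separately is also implemented
(`pair_correction = "holm-resolution"`), but only the global family
controls the probability of reporting *any* spurious assembly on fully
independent data at $\alpha$ — the property the calibration benchmark
measures. This is deliberately conservative; with the strong planted
effects that assembly analysis targets (hundreds of excess coincidences),
power is not the binding constraint.

**Agglomeration.** Each significant pair is collapsed into a single
pseudo-unit — the element-wise minimum of the two binarized trains after
aligning by $\ell^*$ — and tested against every remaining unit with the
same machinery; significant extensions become triplets whose lags compose
the pair lag with the extension lag. Agglomeration stops at order 3:
higher orders explode combinatorially and the motif taxonomy below only
needs triplets. Duplicate unit sets found at several resolutions (or from
the two parent pairs of one triplet) collapse to the minimal-p record,
which defines the assembly's optimal temporal resolution.

## Motif taxonomy and normalized probabilities

Pairs split into synchronous (lag 0) and directional (lag > 0) assemblies;
relative to the focal area a directional cross-area pair is "from" or
"to" it by whether the focal unit leads or trails. Triplets spanning two
areas are *loop-like* when the chain is strictly sequential (no two lags
equal) with flanking units in one area and the middle unit in the other:
ZI→X→ZI (`triplet_loop_focal`) or X→ZI→X (`triplet_loop_external`).
Everything else — a synchronous sub-activation, a chain like X→X→ZI, or
(defensively) a triplet spanning three areas — is non-loop. Because lags
are integers, "synchronous" is exact equality, with no tolerance.

Counts are comparable across areas only after normalizing by the number
of possible configurations: $|A||B|$ cross pairs, $\binom{|A|}{2}$
internal pairs, $\binom{|A|}{2}|B|$ loop-like A→B→A triples (hence the
factor 2 in the probability formulas). The Int-Ext index
$P_\mathrm{ext}/(P_\mathrm{ext}+P_\mathrm{int})$ summarizes external vs
internal coupling propensity; it is reported as undefined (`NaN`, with a
warning) when both probabilities are zero rather than silently 0. When an
area pair spans several sessions, probabilities pool as summed counts
over summed denominators — the mean of per-session ratios would let a
small session dominate.

**Asymmetry tests.** Direction (from vs to) is tested with an exact
binomial test at $p_0 = 0.5$; loop structure with $p_0 =
(|A|-1)/(|A|+|B|-2)$, the share of possible loop-like triples that are
A→B→A — with few focal units, ZI→X→ZI triples are rare by combinatorics
alone, and the test must not mistake that for biology. Tests are exact
and two-sided (the minimum-likelihood rule of `binom.test`; a
doubled-one-tail variant is available), because directionality claims
should not presuppose the direction. Area pairs with fewer than 10
qualifying assemblies are flagged `tested = FALSE`: at such counts even a
10–0 split barely clears conventional thresholds, so reporting a p-value
would suggest more evidence than exists. No correction is applied across
area-wise tests; consumers comparing many areas should adjust downstream.

**Coverage categories.** Per focal unit we count partner areas linked by
at least one pair assembly ($k$) out of $N$ available external areas.
"At least half" uses $2k \ge N$ — ties count as reaching half, matching
the plain reading of the phrase; the categories (none, internal-only,
less than half, at least half but not all, all) are mutually exclusive
and exhaustive by construction.

## The synthetic benchmark

Real multi-area recordings cannot ship with a package, and their true
assembly content is unknowable; every quantitative guarantee is therefore
stated on seeded synthetic sessions that emulate the relevant statistics
of such data: 900–1000 s sessions, two areas with 8–10 units each,
heterogeneous background rates drawn log-uniformly from 0.5–10 Hz, and
planted coordinated activations superimposed on (never replacing) the
background — matching the additive excess-coincidence logic of the
detector. Each planted activation gives each member unit one spike at
$t_\mathrm{event} + \mathrm{lag}\cdot\Delta + U(0, \mathrm{jitter})$ with
participation probability 0.9 and 350 activations per pattern — firmly
supra-threshold, as the benchmark checks recovery, not the detection
boundary. Default jitter is $\Delta/2$ so planted lags survive arbitrary
bin phase in expectation.

Four registered scenarios (`make_scenario()`) fix the study conditions:
`null_independent` (20 units, 1000 s, no structure), `pairs_easy` (twelve
planted pairs covering from/to/synchronous/internal patterns, including
the canonical 60 ms = 2 bins × 30 ms and 80 ms = 4 bins × 20 ms delays),
`loops_mixed` (both loop structures plus a non-loop triplet), and
`nonstationary` (independent units whose rates are jointly modulated
across five equal epochs by factors 0.5–1.5, emulating task-block state
changes). All randomness flows through explicit integer seeds; the caller's
RNG state is saved and restored, and the same seed reproduces a session
byte-for-byte.

What passing these benchmarks does *not* show: robustness to oscillatory
phase-locking (a distinct coordination mechanism, not simulated), to
bursting or refractory ISI structure (backgrounds are Poisson), to rate
modulation much faster than session/5 (the chunked null assumes
piecewise-stationarity on chunk scale), or recovery at marginal
signal-to-noise. Those remain the user's responsibility on real data —
the circular-shift control is the tool for that.

## Numerical and degenerate-input choices

- Bins are half-open, anchored at time 0; a spike exactly at the session
  duration is clipped into the final bin so binning conserves counts.
- Duplicate timestamps are legal (multi-unit bins); binarization happens
  at detection, not ingestion.
- A unit with no occupied bins at some resolution yields $p = 1$, never an
  error, so silent units cannot break a session run.
- The spike-count filter is strict (`> min_spikes`, default 100): a unit
  with exactly 100 spikes is excluded.
- Circular shifts are continuous-uniform on $[0, \mathrm{duration})$ —
  maximal decorrelation given only "random" shifts; shift $s$ then
  $\mathrm{duration} - s$ is the identity, which the tests exploit.
- Holm is used rather than Bonferroni across pairs: uniformly more
  powerful, identical family-wise guarantee.
- GraphML/DOT export goes through igraph; zero-probability edges are
  omitted rather than written with weight 0, so edge presence means
  observed coordination.

## Problem sizes

The shipped validation uses 200 independent-Poisson and 200
block-modulated sessions (20 units, 1000 s) for calibration — detection
probability is a per-run binary outcome, so 200 replicates bound the
Monte-Carlo error on a 5% rate at about ±1.5 percentage points — plus
single seeded runs of the planted scenarios for recovery, and 2000
binomial draws for the loop-test size check. A full-grid run on a 20-unit,
1000 s session takes well under a second on one core.

## Known limitations

This is a faithful-at-desk-scale assembly detector in the CAD family, not
a port of any specific released implementation: the agglomerative
min-coincidence scheme, chunked parametric null and lag/pair corrections
are as documented above, and each is configurable. Assemblies of order
greater than 3 are out of scope. Triplet p-values inherit the extension
test's null (pair pseudo-unit vs third unit), which conditions on the
pair being significant; triplet counts should be read as a census of
significant extensions, not as jointly corrected order-3 discoveries.
Pooled multi-session asymmetry tests use the pooled unit counts in the
combinatorial null, which is exact only when unit counts are similar
across sessions.
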