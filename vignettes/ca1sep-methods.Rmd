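---
title: "Methods: quantifying CA1 input-to-output pattern separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying CA1 input-to-output pattern separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1sep)
```

## The question and the model

Hippocampal area CA1 receives two excitatory feedforward streams: Schaffer
collaterals from CA3 and the perforant path from entorhinal cortex (EC).
During population gamma oscillations (~30–100 Hz), principal cells within a
~1 mm patch are synchronized tightly enough that one ~20 ms gamma cycle can
be treated as a discrete processing step: presynaptic cells either spike in
the window or they do not, and each CA1 cell either fires an action
potential in response or it does not. Inputs and outputs are therefore
binary population vectors, and the natural dissimilarity between two
patterns is the Hamming distance (HD) — the number of cells that differ.

`ca1sep` implements this input-to-output transformation as a reproducible
pipeline and asks the pattern-separation question: when two input patterns
differ by a given amount, how different are the two output patterns?

The model is deliberately feedforward and memoryless within a window:

* a patch of `n_post` identical CA1 cells, each with a fixed number of
  synapse slots per pathway (full scale: 4407 CA3 slots and 1918 EC slots
  per cell, `n_post = 23500`);
* a frozen random wiring: each cell's slots are bound to presynaptic cells
  drawn uniformly without replacement, so a presynaptic cell makes at most
  one contact with a given CA1 cell (`build_projection()`);
* a response model turning each cell's set of active slots into a spike
  decision (`respond()` / `population_response()`);
* inhibition enters only implicitly — the gamma reset (all cells start each
  window in the same state) and a firing threshold that absorbs the
  feedforward-inhibitory operating point.

Recurrent CA1–CA1 connections, spike timing within the window, plasticity
and across-window dynamics are all out of scope by construction.

## The pattern ensemble

All input patterns have an *exact* number `k` of active cells (full scale:
1540 of 28,009 CA3 cells, i.e. 5.50%; 3086 of 45,073 EC cells, i.e. 6.85%).
This fixed-count ensemble, not i.i.d. Bernoulli spiking, is what
`random_pattern()` samples, because the scientific design holds input drive
constant across patterns and varies only *which* cells spike.

Pairs at an exactly controlled HD are built by the shared-core scheme
(`pair_with_hd()`): the second pattern keeps a random subset of `k - d/2`
of the first pattern's active cells and recruits `d/2` random inactive
cells. Conditional on the first pattern, the partner is uniform over all
equal-count patterns at distance exactly `d`. Since the literature rarely
states its pairing scheme, this choice is ours; it is the maximum-entropy
construction consistent with the two constraints (equal counts, exact HD).
Pairs are fully independent of each other (pattern A is not reused across
pairs).

Two named pair designs cover the experiment:

* **distinct** pairs sit at the chance level: `distinct_hd()` returns the
  mean of the binomial HD law (below) rounded to the nearest even integer —
  2910 for CA3, 5750 for EC at full scale. At exactly this distance the two
  patterns share `k^2/n` active cells, the chance-expected overlap.
* **similar** pairs sit at 2% of the maximal achievable distance
  `max_hd(n, k) = min(2k, 2(n - k))`: 0.02 × 3080 = 61.6 → 62 for CA3 and
  0.02 × 6172 = 123.44 → 124 for EC.

Equal-count patterns are always an even HD apart, so fractional targets are
rounded to the nearest even integer with ties upward; this single rule
reproduces all four printed full-scale targets (62, 124, 2910, 5750).

## Hamming-distance theory: binomial and exact laws

If each of `n` cells spiked independently with probability `p` in each of
two patterns, the per-cell difference probability would be
`pr_hd = 2p(1 - p)` and `HD ~ Binomial(n, pr_hd)`, giving

* mean `n·pr_hd`, SD `sqrt(n·pr_hd·(1 - pr_hd))`,
* expected co-active cells `np - mean/2`.

`binomial_hd_stats()` evaluates these in two modes. The default `"exact"`
mode carries full precision. The `"printed"` mode first rounds `pr_hd` to
two decimals, reproducing the two-significant-digit arithmetic that yields
the familiar full-scale output-side numbers (`pr_hd = 0.24`, mean 5640,
SD 65, overlap 470 of 3290 spiking cells at 14% activity). The two modes
exist because published integer values mix both conventions; the CA3/EC
input-side means (2910, 5750) come from exact proportions, and their
printed integers match the nearest-even rounding used by `distinct_hd()`
(the exact means are 2910.65 and 5749.42, so no single nearest-integer rule
reproduces both printed values — the even-rounding of the pair design
does).

For the fixed-count ensemble the package also provides the *exact* law
(`exact_hd_distribution()`): the overlap between two independent uniform
`k`-subsets is hypergeometric, so

P(HD = 2j) = C(k, k−j)·C(n−k, j) / C(n, k).

Its mean, `2k(n−k)/n`, equals the binomial mean exactly. Its spread does
**not**: under exact counts the per-cell differences are negatively
correlated, and at sparse activity the exact law is far narrower (SD 17.4
versus 51.1 at `n = 28009, k = 1540`). The binomial law should therefore be
read as the independent-spiking *approximation* used for analytic
reference values, while the exact law describes what the sampler actually
produces; both are tested against brute-force enumeration and Monte Carlo.
One practical consequence: "distinct" pairs placed at the binomial mean are
also typical pairs of the fixed-count ensemble, since the two laws share
that mean.

`relative_sd_active()` covers the drive side of the same theory: with `s`
slots per cell at activity `p`, the SD of the active-slot *proportion* is
`sqrt(p(1-p)/s)` — 0.34% for the CA3 pathway and 0.58% for the EC pathway
at full scale, which is why per-cell drive is so tightly concentrated.

## Connectivity arithmetic

`presyn_count()` and `fanout_of()` implement the edge-counting identities
tying patch size, slots per cell, presynaptic population and fan-out
(23,500 × 1918 / 1000 = 45,073 EC cells; 23,500 × 4407 / 28,009 → 3697 CA1
targets per CA3 cell). `fanout_of()` reports the integer part — the number
of *complete* targets — which is the convention the printed full-scale
value follows (3697, not round(3697.54) = 3698). The printed CA3 population
size 28,009 is treated as a given parameter: it is not exactly derivable
from the stated "~20% of 18,000 mean targets" (which would give 3600
targets in the patch, not 3697), so the package exposes the arithmetic in
both directions and takes the printed constant at face value.

The default wiring samples each cell's presynaptic partners independently,
so per-presynaptic fan-out is random with the exact edge-count mean; a
`method = "regular"` variant enforces exactly equal fan-out (random
bipartite regular wiring) for sensitivity checks.

## The threshold surrogate and what it replaces

The reference implementation of this analysis drove each cell with a
1330-compartment biophysical CA1 model. That backend is out of scope here;
`ca1sep` defines the response-model *contract* (deterministic binary
decision per cell per window, monotone in excitatory input) and ships a
random-weight threshold surrogate: slot weights are drawn once
(default i.i.d. lognormal, meanlog 0, sdlog 0.5) and frozen, and a cell
spikes iff the summed weight of its active slots reaches `theta > 0`.

Heterogeneous weights are essential, not cosmetic: with equal weights all
cells with the same active-slot count would decide identically. The
lognormal default is the standard right-skewed description of excitatory
synaptic efficacies; constant and uniform options support sensitivity
analysis and exact test arithmetic. Feedforward inhibition is absorbed into
`theta` rather than modeled as negative weights, because its role at this
level of abstraction is only to set the operating point that calibration
re-establishes anyway.

Consequences to keep in mind when interpreting results:

* the published full-scale output numbers (distinct-input output HDs
  5688/5696; similar-input output HDs 2931 vs 4315; spike counts 3316 ± 52
  etc., available as `reference_output_hd()`) depend on dendritic
  morphology and nonlinearities the surrogate does not have. The package
  reproduces their *qualitative structure* — similar inputs give outputs
  far closer than distinct inputs; distinct inputs land at the chance
  level; output activity stays at the calibrated 14% — not their values;
* in particular the striking EC-versus-CA3 sensitivity asymmetry of the
  detailed model (similar EC inputs separated much more than similar CA3
  inputs) is a biophysical effect; the surrogate makes no claim about it.

## Calibration

The operating point is a 14% spiking probability per window (`p_target`),
the binary-code equivalent of a ~7 Hz peak rate over 20 ms cycles; it is a
configuration default, not a constant.

Calibration has two independent instruments:

* `sweep_activity()` + `fit_boltzmann()`: the input-output curve of API
  (action-potential initiation) probability versus activity level, fitted
  with the Boltzmann sigmoid `f(x) = A / (1 + exp((x_half - x)/slope))` by
  Levenberg–Marquardt least squares. The amplitude is fixed at `A = 1` by
  default (the response is a probability that saturates), with a
  free-amplitude option. `invert_for_target()` is the closed-form inverse,
  so the activity level achieving any target probability can be read off
  exactly. Fits refuse saturated (all-0 or all-1) sweeps rather than
  extrapolating. Sweep grids default to 11 points geometrically spanning
  0.4–2.5× the nominal activity, which brackets the transition in all
  shipped configurations;
* `calibrate_threshold()`: the surrogate's extra degree of freedom `theta`
  is set by bisection on the cached drive distribution of a fixed
  calibration pattern set (valid because the spiking fraction is monotone
  in `theta`), to tolerance ±0.005 by default. With discrete drives
  (constant weights) the achievable fractions are quantized; the routine
  then returns the closest attainable fraction and says so, rather than
  failing. Unreachable targets (e.g. near-1 targets when many cells
  receive no drive) raise an error immediately.

Because the two pathways are driven separately in all conditions — matching
the separate per-pathway calibration of the reference analysis — the
experiment calibrates one `theta` per pathway at that pathway's nominal
activity. Calibration transfer is tested: thresholds set on one pattern set
reproduce the target fraction within ±0.01–0.02 on held-out patterns.

## The four-condition experiment and the desk scale

`run_experiment()` executes {distinct, similar} × {CA3, EC}: per condition
it generates `n_pairs_per_condition` (default 20) independent input pairs
at the exact target HD, drives the calibrated model, and summarizes output
HDs against the analytic chance level at `p_target`
(`empirical_hd_summary()`). The `report()` table adds a separation ratio:
relative (fraction-of-maximal) output distance divided by relative input
distance, so values above 1 mean relative contrast was amplified.

The full-scale configuration (`make_full_scale_config()`) is analytic-only: its
execution would need the compartmental backend, so `run_experiment()`
refuses it and `analytic_reference()` serves the closed-form numbers.

The runnable default is the desk scale (`make_desk_config()`): 500 CA1
cells; a CA3-like pathway of 600 cells, 90 slots/cell, fan-out 75, at 5.5%
activity; an EC-like pathway of 1000 cells, 40 slots/cell, fan-out 20, at
6.85% activity. These sizes were chosen once to preserve the full-scale
structure — CA3 fan-out ≫ EC fan-out, more CA3 than EC slots per cell,
sparse 5–7% input activity, 14% output activity — while a complete run
(calibration, sweeps, Boltzmann fits, 80 pairs, reports) takes seconds on
one CPU. Tests use this scale, some with reduced pair counts (4–10) where
only structure, not precision, is asserted.

What desk-scale results do and do not show: they validate the pipeline's
statistical machinery (exact pair construction, calibration transfer,
chance-level behaviour of distinct pairs, similar ≪ distinct separation,
end-to-end determinism); they do not constrain the biophysics of real CA1
neurons, and absolute output HDs at desk scale have no full-scale
interpretation beyond their normalized ratios.

## Numerical conventions and degenerate cases

* Indices are 1-based in R objects; all on-disk formats (pattern files,
  edge lists) are 0-based, converted only at the I/O boundary, and each
  format documents this.
* Even rounding of target HDs: nearest even integer, ties upward.
* `fanout_of()` floors; `presyn_count()` rounds to nearest.
* `exact_hd_distribution()` works in log-binomial coefficients
  (`lchoose`), exact to 1e-12 normalization at all tested sizes.
* All generators accept a seed and restore the caller's RNG state; the
  experiment derives every stream (connectivity, weights, calibration,
  sweeps, each pair) from three named seeds, so runs are bit-reproducible
  and two runs with the same configuration write byte-identical artifact
  trees.
* Degenerate inputs fail loudly: odd or infeasible pair distances,
  saturated sweeps, unreachable calibration targets, dimension mismatches,
  partial results passed to `report()`.

## A worked desk-scale run

```{r, eval = FALSE}
cfg <- make_desk_config(seed = 1)
res <- run_experiment(cfg)
print(res)
plot(res)
analytic_reference(make_full_scale_config())$pathways
```

## Known limitations

* The surrogate's output-side numbers are not comparable to the detailed
  compartmental model's; only orderings and calibrated levels are.
* Joint CA3+EC drive is supported by the response contract but unvalidated
  against any reference; all shipped conditions drive one pathway.
* Spatially non-uniform CA3 target distributions along the septotemporal
  axis are not modeled; wiring is uniform.
* The binomial reference law overstates the spread of fixed-count input
  HDs (see above); analytic SD comparisons for *inputs* should use
  `exact_hd_distribution()`.
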