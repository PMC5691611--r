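---
title: "Feedback-controlled tolerance evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-controlled tolerance evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talesim)
library(dplyr)
```

`talesim` implements the computational half of a tolerance adaptive
laboratory evolution (TALE) experiment: the feedback controller that raises a
stressor concentration as a serially passaged microbial population gains
fitness, the growth-curve and mutation analyses applied downstream, and a
stochastic simulator that stands in for the wet-lab cultures so the whole
loop can be exercised and tested on a desk. This vignette records the models,
the tunable parameters and the design decisions, in the spirit of a methods
section.

## The serial-passage world

A TALE run is a sequence of batch cultures ("flasks"). Each flask starts from
a 1:100 transfer of the previous one (150 µL into 15 mL), grows at 37 °C in
minimal medium containing the stressor, and is passaged as soon as the
plate-reader OD600 reaches 0.3 — i.e. during exponential phase. Plate-reader
ODs relate to 1 cm benchtop ODs by a fixed ratio of 4.2
(`plate_to_benchtop()`).

### Dose-response

The simulator gives every lineage a *tolerance* `T`: the stressor
concentration at which its growth ceases. At concentration `C` a lineage
grows exponentially at

    r(C) = r_max * max(0, 1 - (C / T)^hill)

This is the simplest monotone family that matches the qualitative
observations the package models: full-speed growth without stressor, growth
that slows as the dose rises, and cultures that stall entirely above a
threshold. `hill = 1` (linear decline) is the default; larger exponents make
the shoulder sharper. Wild type has `T = ic50_wt` (default 3.0 % w/v,
matching the scale on which the packaged endpoint table lives, where runs
start at 1-2 % w/v and initial rates are 0.1-0.3 /h with `r_max = 0.7 /h`).

### Lineage-level bookkeeping

Cultures of 10^10 cells cannot be simulated per cell. Instead the population
is a list of lineages (tibble rows), each with a mutation set, a tolerance
and a cell count. Within a flask, growth is deterministic exponential;
stochasticity enters in three places:

* **mutation arrivals** — Poisson with mean `mu × (new divisions)` per
  lineage. Beneficial arrivals (`mu_b`) land in a uniformly drawn causal
  region and multiply tolerance by `1 + Exp(mean = effect_mean - 1)` — a
  shifted exponential with mean `effect_mean` (default 1.3), so most steps
  are modest and large jumps are rare, giving diminishing-returns stepwise
  trajectories. Neutral arrivals (`mu_n`) land in decoy regions and leave
  tolerance unchanged. Each arrival founds a child lineage that grows from
  its (division-weighted) arrival time to the end of the flask;
* **bottlenecks** — each lineage's transferred count is binomial with
  `p = dilution`, so a freshly arisen beneficial lineage of a few hundred
  cells genuinely risks extinction at the 1:100 passage;
* **OD measurement noise** — Gaussian with `od_noise_sd` (default 0.002
  plate units, a typical plate-reader read noise).

Defaults for the mutation supply are a deliberate choice of world. A passage
flask performs about 1.9 × 10^10 divisions; with `mu_b = 2e-11` that is ~0.4
candidate tolerance mutations per flask. This supply-limited regime
reproduces what real tolerance evolutions look like: fitness recovers in
steps, escalations sometimes outrun adaptation and crash the culture, and
endpoint isolates carry a handful of mutations (of the order of 5), not
hundreds. A supply of 1e-9, tried first, made adaptation outrun the
controller entirely (every run saturated the escalation cap with zero
crashes) and was rejected on realism grounds. `mu_n = 1e-8` represents the
genome-wide rate of all other called mutations; because a neutral mutation
is only observed if its lineage later happens to host a sweep, few
hitchhikers reach the sequenced isolates — also realistic.

`cells_per_od` (cells per mL per benchtop OD unit) has no measured value in
the study this package models; 1e9 is the standard E. coli figure and is a
config knob, so cumulative-cell-division magnitudes should be read as
order-of-magnitude quantities.

### Determinism

One root seed drives everything. `run_tale()` derives a per-flask child
stream by counter (`seed` linear-congruential step, kept below 2^31), so a
run is bit-reproducible and independent of evaluation order; for a
`sim_culture` the root defaults to the `sim_config` seed, making identical
configs give byte-identical runs.

## The controller

After every flask the controller (`next_concentration()`) applies one rule:

* **crash** (passage OD not reached within `crash_timeout_h`): revert to the
  last concentration at which growth succeeded, multiply the step by
  `step_reduction`, restart the population from the pre-crash snapshot (the
  frozen stock of the previous flask);
* **escalate**: if the last `window_flasks` fitted rates — all obtained at
  the current concentration — are each at least `rate_threshold`, raise the
  concentration by the current step for the *next* flask (never mid-flask);
* otherwise do nothing.

Defaults: passage OD 0.3, dilution 1/100, threshold 0.15 /h and step
0.75 % w/v (the operating points of the platform the package models). Three
parameters are under-specified at source and fixed here as documented
choices: the escalation window ("a defined period of time") is 3 flasks,
matching how that platform reports endpoint rates from the first/last 3
flasks of a population; a crash (growth "ceased") is 72 h without reaching
the passage OD; and the post-crash "smaller step change" is a halving
(`step_reduction = 0.5`), which keeps every retry strictly between the last
good and the crashed concentration.

Two closed forms pin the controller down in tests: with a window of 2 and a
culture that always grows, 10 flasks produce exactly 5 escalations
(final = start + 3.75 % w/v at the 0.75 step); with `rate_threshold = 0` the
controller escalates every `window_flasks` flasks, so the final
concentration is `start + floor(n / window) × step`.

## Growth analytics

* **Rate** — OLS of log OD on time (`fit_rate()`), restricted to ODs in
  `[0.01, 0.3]` plate units by default: above the read-noise floor, below
  the passage threshold, i.e. the exponential window. On exact exponentials
  the true rate is recovered to machine precision with zero SE. The slope SE
  is computed directly from the residuals (`summary.lm`'s perfect-fit
  warning would otherwise fire on the healthy base case).
* **Lag** — the printed tables report a lag time but never define one; here
  it is the time at which the fitted exponential intersects the first
  observed OD, `lag = (ln OD_0 - intercept) / slope`. Zero for growth that
  starts immediately; configurable by refitting with other windows.
* **Final OD** — maximum of a 3-point running-median smoothed series, robust
  to single-read spikes.
* **Calibration** — plate-scanner screens report green pixel values;
  `pixels_to_od()` maps them through a monotone piecewise-linear calibration
  with clamping (and a warning) outside the calibrated range.
* **Cumulative cell divisions** — each flask contributes
  `(od_end - od_start) × 4.2 × cells_per_od × volume_ml` divisions (every
  net new cell is one division; death and the subtracted inoculum are
  ignored). CCD is additive over flasks and serves as the evolutionary
  clock: a default 70-flask run accumulates ~1.3 × 10^12 divisions, the
  same order as the wet-lab experiments the fixtures transcribe.

On the rate fit's statistical calibration: with additive OD noise the
log-scale errors are heteroscedastic, and the plug-in SE from the regression
is mildly anti-conservative (on the package's reference noisy series,
plug-in SE ≈ 0.0035 vs a true sampling SD ≈ 0.0045). The acceptance test for
rate fitting therefore checks the estimator against the *closed-form* OLS
sampling SE implied by the noise model (delta method on the log scale),
under which the fitted rate is unbiased and 2-SE coverage is at its nominal
~95 %. Users who need honest intervals on noisy plate data should prefer
replicate spread (`clone_metrics()`'s RSDs) over single-fit SEs.

## Mutation analysis

Inputs are breseq-style per-isolate mutation tables (TSV or a minimal
GenomeDiff dialect) with the four-way type vocabulary SNP/DEL/INS/MOB;
malformed rows go to an attached error report, never silently dropped.

* **Region canonicalisation** — intergenic names `a/b` are sorted
  lexicographically, so the same region called against two reference
  orientations groups together. Idempotent.
* **Hypermutators** — isolates whose mutation count exceeds
  `multiplier × median` (default 4×, floored at 20) are flagged and excluded
  before convergence analysis; the floor keeps tight low-count cohorts
  intact. The real cohorts this mimics had non-hypermutators at 5 ± 4
  mutations and hypermutators at 39-267; the rule is a documented heuristic
  for what the original analysts did by inspection.
* **Key mutations** — a region is *key* when it shows recurrence: at least
  two unique alleles (distinct position/description/type), or mutations in
  isolates from at least two independent populations (two isolates from one
  population share ancestry and are not independent evidence). Regions seen
  in ≥ 2 strains are `combined`, recurrent single-strain regions
  `strain-specific`.
* **Allele identity across strains** — an identical deletion called against
  two reference genomes (different printed coordinates) is one allele; the
  packaged fixture carries a normalised `allele` token for exactly this
  case, and the same deletion still counts towards both strains' presence.
* **Locus grouping in the worked example** — the printed key-mutation table
  groups structural variants of the tqsA transporter (an in-frame ∆12 bp and
  a ∆3035 bp spanning pntA-pntB-tqsA) under the combined mdtJ/tqsA transport
  locus, and pairs the rph pseudogene insertion with the neighbouring
  pyrE/rph intergenic deletion. The fixture follows that grouping in its
  `region` column (keeping the printed gene label in `gene`); assigning each
  variant to its own gene instead would split the locus and inflate the
  combined count.

## Screening and clone selection

Replicate screens are summarised per isolate (`clone_metrics()`): means and
percent relative standard deviations (sample SD convention throughout, since
the source tables are consistent with no single convention). Genotypes are
clustered (`cluster_genotypes()`) by exact set equality
(genetically-identical) and single-linkage Jaccard ≥ 0.5
(genetically-similar; the threshold is this package's choice, no
quantitative definition exists at source). The cluster representative
(`select_best_clone()`) is chosen by fastest mean rate, then highest final
OD, then lowest rate RSD — but only when every member reproduces within the
20 % RSD gate on both rate and final OD; otherwise the RSD tie-break is
dropped. Ties break on the isolate label, so selection is a total order.

Condition summaries (`aggregate_condition()`, `summarize_conditions()`)
round half-away-from-zero at the printed precision for display while
computing fold increases on unrounded means. On the packaged endpoint table
this reproduces the printed MG1655 cells (5.7 ± 0.6 and 6.1 ± 0.3 % w/v) and
both per-stressor flask means (67 and 87); the two DH1 average cells are
inconsistent with any single rounding rule (5.05 printed as 5.0, 4.675 as
4.6) and are deliberately not asserted anywhere. The minimum fold increase
across the four conditions is 3.025 — the "threefold or greater" headline.

```{r table1}
summarize_conditions(ale_table1()) %>%
  select(strain, il, start_conc, mean_end, sd_end, fold_increase)
```

## What a green test establishes — and what it does not

The simulator emulates the *statistical structure* the downstream analyses
assume: exponential batches with stress-dependent rates, rare beneficial
arrivals that sweep through repeated bottlenecks, frequency-weighted isolate
sampling, causal signal against neutral decoys (5 causal vs 45 neutral
regions by default). End-to-end tests verify that under this world the
controller's final concentration exceeds its start, causal regions hit at
least twice independently are recovered as key, and at most one decoy region
is falsely key in ≥ 90 % of seeded runs.

It does **not** emulate: sequence-level mutation (alleles are labels, not
bases), clonal interference diagnostics beyond what lineage records trivially
permit, death or lag physiology inside a flask, media or temperature
effects, or the wet-lab endpoint numbers themselves (evolved rates, 8.5 or
11.9 % w/v cross-tolerance). Those live only in the packaged fixture tables,
and green tests about the simulator say nothing about them.

## Numerical notes

* Passage times solve `Σ n_i e^{r_i t} = target` by `uniroot` at 1e-9
  tolerance; a flask that cannot reach the target within the timeout is a
  crash with the series truncated at the timeout.
* Binomial bottlenecks and Poisson arrival counts switch to normal
  approximations above variance/mean 1e6 (counts there are doubles, far
  beyond integer-exact binomial sampling).
* Display rounding is half-away-from-zero with a 1e-9 epsilon to absorb
  binary representation error (24.2/4 must print as 6.1, not 6.0).
* `rsd()` is undefined for zero means and errors accordingly; single
  replicates yield `NA` RSDs and bypass the reproducibility gate.
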