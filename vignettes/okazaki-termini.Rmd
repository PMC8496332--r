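---
title: "Okazaki fragment termini, nick translation and the okterm simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Okazaki fragment termini, nick translation and the okterm simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okterm)
```

# The biology being modelled

Lagging-strand DNA is synthesised discontinuously.  In budding yeast each
Okazaki fragment is initiated by primase (a ~10-nt RNA primer), extended by
DNA polymerase α for 10–35 DNA nucleotides, and completed by Pol δ.  When
Pol δ runs into the 5′ end of the previously synthesised fragment, it
displaces 1–2 nucleotides as a flap that Fen1 cleaves; iterating this moves
the nick 5′→3′ (*nick translation*) until DNA ligase I seals it.  Nick
translation removes the RNA primer and part of the Pol α tract, and is
impeded by protein obstacles — nucleosomes and tightly bound transcription
factors (Abf1/Reb1/Rap1).

OK-seq experiments deplete nuclear ligase (anchor-away), so unligated
fragments accumulate and are sequenced.  Two facts shape the analysis:

1. The library chemistry requires a 5′ DNA phosphate, so only fragments
   whose RNA primer has already been removed are captured.
2. Unsealed nicks continue to nick-translate for as long as ligase is
   absent, so terminus positions depend on the depletion duration: brief
   depletions photograph near-native junctions; long depletions let them
   migrate into and around protein obstacles.

`okterm` implements both the analysis of such libraries and a mechanistic
simulator able to generate them under arbitrary depletion schedules.

# Analysis operations

**Coordinates.**  Everything is 0-based, half-open (BED).  The midpoint of
`[s, e)` is `floor((s + e − 1) / 2)`; for a 147-bp nucleosome footprint this
is the dyad base.  A `+` (Watson) fragment has its 5′ terminus at `start`
and 3′ terminus at `end − 1`; a `-` (Crick) fragment mirrors this.  Watson
fragments derive from leftward-moving forks and Crick fragments from
rightward forks, which is what makes strand ratios informative about fork
direction.

**OEM.**  `count_strand_windows()` assigns each fragment to the 10-kb
window left or right of an origin by its midpoint (midpoints exactly at the
origin fall right, by the half-open convention); midpoint assignment avoids
double-counting fragments that straddle the origin, and a 5′-end assignment
is available behind the `assign` argument.  `compute_oem()` evaluates
`W_L/(W_L+C_L) − W_R/(W_R+C_R)`; an empty window makes the metric
*undefined* and it is reported as `NA`, never as 0.

**Meta-profiles.**  `aggregate_ends()` counts, for every
(terminus, feature-midpoint) pair within the flank (default ±100 bp), the
offset `terminus − midpoint`, negating offsets of Crick fragments so that
negative offsets always mean "upstream in the direction of Okazaki-fragment
synthesis".  A terminus near several features counts toward each (nucleosome
repeats are shorter than twice the flank, so this matters; a
`nearest_only` option exists).  Features are used unoriented by default —
nucleosomes have no strand and TF-site orientation is not needed for the
questions here — with `orient_by_feature_strand` available.  Profiles are
then smoothed with a centred 5-bp moving average (`smooth_profile()`; the
window truncates at the grid edges) and divided by the median value within
±100 bp (`normalize_to_median()`), whose postcondition (median = 1) is
enforced; an all-zero window is an explicit error rather than a silent NaN.
"Smoothed to 5 bp" could alternatively be read as non-overlapping 5-bp
bins; the moving average was chosen because profiles are plotted per base
pair.  Normalisation follows smoothing.  `peak_location()` /
`trough_location()` break ties toward the smallest offset so that flat
profiles have a documented, deterministic answer.

**Pol α tracts.**  `tract_density()` expands retained-tract intervals to
per-base counts and applies the identical smoothing/normalisation, so
terminus and tract curves are directly comparable.  External
polymerase-usage data (single-base ribonucleotide positions mapped in a
Pol α steric-mutant background) can be supplied as BED6; the upstream
ribonucleotide calling is out of scope here.

# The simulator

## Model

Per cell and chromosome, each origin draws a firing time
`Normal(mean_time, time_sd)` and fires with its efficiency unless a fork
crosses it first (passive replication; an origin is silenced the instant it
is replicated).  Forks move at `fork_speed` (default 1500 bp/min);
converging forks stop where their arrival times agree, the meeting point
rounded toward the leftward-moving fork for reproducibility.

Along each fork, priming sites are laid at spacings
`Normal(165, 40)` bp (truncated at the minimal fragment size
`rna_primer_len + pol_alpha_min + 1`), each fragment carrying a 10-nt RNA
primer and a `Uniform{10..35}`-nt Pol α tract.  The junction between two
adjacent fragments starts at the downstream fragment's priming site and
advances in the synthesis direction by `Uniform{1..2}` nt per successful
cycle, with per-cycle success probability

`p_continue · exp(−penalty(x))`

evaluated at the base about to be removed.  The penalty is built by
`barrier_penalty()`: a triangular ramp from 0 at either footprint edge to
`nuc_kappa · score` at the dyad for nucleosomes, and a constant
`tf_kappa · score` across TF footprints.  The ramp makes the obstacle
progressively harder toward the dyad, so junctions accumulate upstream of
the dyad after few cycles and migrate toward it with more — the triangular
shape is a modelling choice (no quantitative barrier profile is known), the
simplest one with that property.

Junction life cycle (`cpp_run_junctions`, the Rcpp core): a
replication-coupled burst of cycles runs at birth (geometric stopping at
the first failed cycle).  Time then advances in 0.5-min ticks: while ligase
is present, a paused junction whose primer has been removed ligates with
probability `p_ligate` per tick and is frozen; every unligated junction
attempts `Poisson(post_nt_rate · tick)` further cycles per tick until
harvest.  Ligation requires primer removal because only an RNA-free nick is
ligatable — this is also why the sequenced library
(`harvest_library()`) is exactly the unligated, primer-removed fragments.
A junction never advances past the previous fragment's priming site, so
fragment bodies always tile the replicated interval exactly once.
Event-exact simulation of every cycle time was deliberately avoided: the
outputs of interest are profile-level, and Poisson-per-tick bookkeeping is
indistinguishable at that resolution.

Retained Pol α tracts are tracked for *all* fragments (ligated ones too):
polymerase-usage experiments see Pol α DNA regardless of ligation state.
The retained portion is the part of the tract the downstream-moving
junction has not yet overwritten.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `fork_speed` | 1500 bp/min | fork progression |
| `priming_spacing_mean/sd` | 165 / 40 bp | priming at the nucleosome repeat |
| `rna_primer_len` | 10 nt | RNA primer |
| `pol_alpha_min/max` | 10 / 35 nt | initiator-DNA tract bounds |
| `displace_min/max` | 1 / 2 nt | displacement per cycle before Fen1 cleavage |
| `p_continue` | 0.95 | per-cycle continuation in free DNA |
| `p_ligate` | 0.5 /tick | ligation at a ligatable pause |
| `nuc_kappa`, `tf_kappa` | 1.2, 4.0 | barrier strengths |
| `post_nt_rate` | 6 /min | cycles at persistent nicks |
| `tick` | 0.5 min | bookkeeping step |

Fragment geometry (165-bp repeat, 10-nt primer, 10–35-nt tracts, 1–2-nt
displacement steps) follows the established biochemistry.  The barrier
strengths and the post-replicative cycle rate have no measured values; they
are calibration placeholders, set once so that default conditions reproduce
the qualitative phenotype of ligase-depletion experiments — a 5-min
depletion peaks tens of bp upstream of the meta-dyad, a 60-min depletion
yields a roughly symmetrical distribution centred on the dyad, and TF-site
peaks grow with depletion duration.  With much stronger nucleosome
penalties the 60-min distribution stays upstream-peaked (junctions cannot
traverse the dyad on that timescale), which does not match the long-
depletion phenotype; κ≈1.2 with ~6 cycles/min is the weakest-assumption
regime that does.  They should not be read as measurements.

## RNG discipline

One root seed; per-cell substreams are derived by a counter
(`seed·69069 + cell·1000003 mod 2³¹−1`), so growing `n_cells` never
reshuffles earlier cells.  The C++ engine draws from R's RNG, making every
stage — including compiled code — reproducible from `set.seed()` /
`--seed` alone and byte-identical across runs.

# What the synthetic data does and does not show

The generator emulates: multi-origin stochastic firing with passive
replication, expanding fragment coverage around efficient origins early in
S phase, strand/fork-direction coupling, priming-spacing geometry,
primer-removal library selection, duration-dependent terminus migration,
S-phase-stationary processing, and Pol α tract erosion by nick translation.

It does **not** emulate: sequence composition or mappability, biased
priming relative to chromatin features (priming is uniform along the
fork), nucleosome re-formation kinetics behind the fork (maps are static),
the long-flap Dna2/Pif1 pathway, polymerase idling, leading-strand
synthesis, or read-level artefacts (fragments are emitted as exact
intervals).  Passing tests on synthetic data therefore validate the
*computational* pipeline and the *qualitative* mechanism, not quantitative
agreement with any real library.

One limitation deserves emphasis.  In the removal-only mechanism the
retained-Pol α density around a barrier develops a *maximum* just upstream
of the dyad (stalled junctions retain the tract immediately downstream of
themselves) flanked by two minima, and which flank is deeper is only weakly
determined; under long continuous depletion the trough usually, but not
always, falls downstream of the terminus peak.  When tracts are taken from
ligase-proficient (steady-state) simulations instead, the deepest
depletion sits in the fast-transit free DNA just upstream of the barrier —
upstream of the terminus peak.  A removal-only mechanism with uniform
priming therefore does not force the observed "trough slightly downstream
of the peak" geometry; position-dependent priming (deliberately not
modelled here) is a plausible missing ingredient, and this is exactly the
alternative interpretation that terminus-mapping experiments cannot, on
their own, exclude.

# Numerical and degenerate-input choices

* Strict parsing: malformed interval rows fail with line numbers; 1-based
  input is never silently coerced.
* Zero-length windows, empty feature sets, non-odd smoothing windows,
  out-of-genome features and impossible spacing truncations are errors, not
  warnings.
* Undefined OEMs propagate as `NA`.
* Peak/trough ties resolve toward the smallest offset; the
  converging-fork meeting point rounds toward the leftward fork; a
  nearest-feature distance tie goes to the feature earlier in position
  order.
* Jittered nucleosome placement redraws up to 100 times, then falls back
  deterministically to the midpoint of the feasible dyad window.

# Problem sizes used by the test and acceptance runs

Unit tests run on 40–60-kb single-chromosome genomes with ≤ 20 cells.  The
acceptance checks use the study-scale conditions: a 200-kb chromosome with
~1200 nucleosomes and 60–100 TF sites; 50 cells for the tiling invariant;
230 cells (≈ 2.7 × 10⁵ sequenced fragments) for strong-barrier position
recovery; 200 cells per arm for the duration and stationarity comparisons,
with ten 40-cell replicate pairs for the no-post-nick-translation
Kolmogorov–Smirnov check; and 150 cells for the Pol α comparison.  These
sizes give Monte-Carlo errors well inside the asserted margins while
keeping a full run to a few minutes on one CPU.
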