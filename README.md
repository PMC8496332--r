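# okterm

Analysis of Okazaki-fragment sequencing (OK-seq) data from DNA ligase I
depletion experiments, paired with a mechanistic stochastic simulator of
lagging-strand synthesis and barrier-limited nick translation in budding
yeast.

## The problem

Half of each eukaryotic genome is made as short Okazaki fragments.  Each
fragment starts with an RNA primer extended by ~10–35 nt of error-prone DNA
polymerase α DNA before Pol δ takes over; before ligation, the primer and
some Pol α DNA of the downstream neighbour are removed by iterative
strand-displacement/Fen1-cleavage cycles (*nick translation*).  When nuclear
DNA ligase I is depleted (anchor-away + rapamycin), unligated fragments
accumulate and can be sequenced, and their 5′/3′ termini report where nick
translation paused — typically at protein obstacles such as nucleosomes and
the general regulatory factors Abf1/Reb1/Rap1.  Because nicks left unsealed
keep nick-translating, the *duration* of ligase depletion moves the termini:
brief depletions capture near-native junctions upstream of nucleosome dyads,
long depletions let them migrate toward (and symmetrically around) the dyad.

`okterm` is for genomicists who want to (a) analyse fragment-interval data
from such experiments and (b) simulate the underlying mechanism to test
interpretations.  It provides:

* **Origin efficiency metric (OEM).**  For windows of `w` bp (default
  10 kb) left and right of an origin, with Watson/Crick fragment counts
  `W_L, C_L, W_R, C_R`:

  `OEM = W_L / (W_L + C_L) − W_R / (W_R + C_R)`

  Watson-strand fragments derive from leftward-moving forks and Crick-strand
  fragments from rightward forks, so a fully efficient origin scores +1.

* **Terminus meta-profiles.**  Strand-oriented aggregation of fragment 5′/3′
  ends around nucleosome dyads or TF-site midpoints, smoothed to 5 bp and
  normalised to the median density within ±100 bp of the midpoint; peak and
  shift statistics.

* **Pol α tract profiles.**  Per-base density of retained Pol α-synthesised
  DNA around the same features, normalised identically, with trough
  detection — the simulated analogue of polymerase-usage (HydEN-seq-style)
  comparisons.

* **A lagging-strand simulator.**  Stochastic origin firing with passive
  replication, fork progression, priming at nucleosome-repeat spacing,
  Pol α initiator tracts, replication-coupled and post-replicative nick
  translation through position-dependent barriers
  (`p_pass(x) = exp(−κ·w(x))`), ligation competing with nick translation,
  and configurable depletion/harvest schedules.  The sequenced library is
  the set of unligated fragments whose RNA primer has been removed, exactly
  as the sequencing chemistry selects.

Everything works on plain interval files (BED6/BEDPE, bedGraph, chrom
sizes), so real deduplicated OK-seq BEDPE data can replace simulator output
at any stage.

## Worked example

Simulate a 200-kb chromosome with a central efficient origin, a regular
nucleosome map and 80 TF-site barriers, under brief (10 min) versus long
(60 min) ligase depletion:

```r
library(okterm)

genome  <- make_toy_genome(1, 200000)
nucs    <- make_nucleosome_map(genome, seed = 1)
sites   <- make_tf_sites(genome, 80, min_gap = 800, seed = 2)
origins <- make_origins(genome, data.frame(chrom = "chr1", pos = 100000),
                        efficiencies = 1, mean_times = 10, time_sd = 2)

brief <- simulate_okseq(genome, origins,
                        sim_params(t_depletion_start = 50, t_harvest = 60),
                        n_cells = 100, nucleosomes = nucs, tf_sites = sites,
                        seed = 1)
brief
#> <ok_sim> 100 cells, 200 forks, 90728 fragments (19413 sequenceable), 80301 retained Pol alpha tracts
#>   ligase depleted at 50 min, harvested at 60 min

long <- simulate_okseq(genome, origins,
                       sim_params(t_depletion_start = 0, t_harvest = 60),
                       n_cells = 100, nucleosomes = nucs, tf_sites = sites,
                       seed = 1)

oem_table(harvest_library(long), origins)
#>   chrom   pos  W_L C_L W_R  C_R oem
#> 1  chr1 1e+05 6104   0   0 5971   1
```

All 6104 fragments left of the origin are Watson-strand and all 5971 on the
right are Crick-strand — the single origin fires in every cell and no
opposing fork exists, so the OEM is exactly 1.

```r
end_profile(harvest_library(brief), nucs, end_type = "five_prime")
#> <end_profile> five_prime, offsets -100..100 bp, 21679 (terminus, feature) pairs
#>   smoothed: 5 bp moving average
#>   normalised to median over ±100 bp
#>   peak at -40 bp (height 2.352)

p_long <- end_profile(harvest_library(long), nucs)
p_long
#> <end_profile> five_prime, offsets -100..100 bp, 88657 (terminus, feature) pairs
#>   ...
#>   peak at -1 bp (height 4.078)
```

After 10 minutes of depletion the 5′-end density peaks 40 bp *upstream* of
the meta-nucleosome dyad (normalised height 2.35); after 60 minutes the
persistent nicks have nick-translated onward and the peak sits essentially
on the dyad (−1 bp) with a near-symmetrical distribution — terminus
migration driven purely by ongoing strand-displacement synthesis at
unsealed nicks.  `plot(p_long)` draws the profile.

A command-line wrapper over the same functions is installed at
`system.file("cli", "okterm", package = "okterm")` with `fixtures`,
`simulate`, `oem`, `profile` and `polalpha` subcommands.

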