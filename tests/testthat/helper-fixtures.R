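## Shared builders for small, fast simulation fixtures.

toy_genome <- function(len = 50000) make_toy_genome(1, len)

## a single fully-efficient central origin
central_origin <- function(genome, mean_time = 5, time_sd = 1) {
  make_origins(genome,
               data.frame(chrom = names(genome)[1],
                          pos = floor(as.numeric(genome)[1] / 2)),
               efficiencies = 1, mean_times = mean_time, time_sd = time_sd)
}

## fast parameters: continuous depletion, short harvest
fast_params <- function(...) {
  sim_params(t_depletion_start = 0, t_harvest = 25, ...)
}

## small end-to-end simulation used by several tests
small_sim <- function(n_cells = 10, seed = 42, len = 50000, ...,
                      nucleosomes = NULL, tf_sites = NULL) {
  g <- make_toy_genome(1, len)
  simulate_okseq(g, central_origin(g), fast_params(...), n_cells = n_cells,
                 nucleosomes = nucleosomes, tf_sites = tf_sites, seed = seed)
}

## build an ok_fragments table inline
frags <- function(chrom, start, end, strand, name = NULL) {
  if (is.null(name)) name <- paste0("f", seq_along(start))
  as_fragments(data.frame(chrom = chrom, start = start, end = end,
                          name = name, score = 0, strand = strand,
                          stringsAsFactors = FALSE))
}

## point features (1-bp intervals) at given midpoints
point_features <- function(chrom, pos, strand = ".", score = 1) {
  ok_features(chrom, pos, pos + 1, name = paste0("x", seq_along(pos)),
              score = score, strand = strand)
}
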