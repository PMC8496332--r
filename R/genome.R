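#' Define a genome as a set of named chromosome lengths
#'
#' The analysis is purely positional, so a genome is just an ordered set of
#' chromosome names and lengths (base pairs).  All coordinates in the package
#' are 0-based, half-open (BED convention).
#'
#' @param lengths positive integer vector of chromosome lengths (bp).
#' @param names chromosome names; defaults to `chrI`, `chrII`, ... style
#'   `chr1..chrN` identifiers.  Must be unique.
#' @return An object of class `ok_genome`: a named numeric vector of lengths.
#' @examples
#' g <- ok_genome(c(chr1 = 100000))
#' chrom_lengths(g)
#' @export
ok_genome <- function(lengths, names = NULL) {
  if (length(lengths) < 1L) stop("a genome needs at least one chromosome")
  nm <- if (!is.null(names)) names else names(lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(lengths))
  lengths <- round(as.numeric(lengths))
  names(lengths) <- nm
  if (any(lengths < 1)) stop("chromosome lengths must be >= 1")
  if (anyDuplicated(names(lengths))) stop("chromosome names must be unique")
  structure(lengths, class = "ok_genome")
}

#' @export
print.ok_genome <- function(x, ...) {
  cat("<ok_genome> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @rdname ok_genome
#' @param genome an `ok_genome`.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(as.numeric(genome), names(genome))
}

.chrom_len <- function(genome, chrom) {
  i <- match(chrom, names(genome))
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  as.numeric(genome)[i]
}

#' Build a toy genome of equal-length chromosomes
#'
#' Convenience constructor for tests and simulations.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param length length of each chromosome in bp (>= 1000).
#' @return An `ok_genome`.
#' @examples
#' make_toy_genome(2, 50000)
#' @export
make_toy_genome <- function(n_chrom, length) {
  if (length(n_chrom) != 1L || is.na(n_chrom) || n_chrom < 1)
    stop("n_chrom must be a positive count")
  if (length(length) != 1L || is.na(length) || length < 1000)
    stop("chromosome length must be >= 1000 bp")
  ok_genome(rep(round(length), n_chrom))
}

## ---- feature sets -----------------------------------------------------------

#' Construct a validated set of genomic features
#'
#' A feature set is a BED6-shaped data frame: `chrom`, `start` (0-based,
#' inclusive), `end` (exclusive), `name`, `score` (used to carry barrier
#' strength or origin efficiency) and `strand` (`+`, `-` or `.`).  Records are
#' kept sorted by `(chrom, start)` and validated against the genome.
#'
#' @param chrom,start,end,name,score,strand feature columns (recycled where
#'   scalar).
#' @param genome optional `ok_genome` used to check bounds.
#' @return A data frame of class `ok_features`.
#' @export
ok_features <- function(chrom, start, end, name = ".", score = 0,
                        strand = ".", genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_features(df, genome)
}

validate_features <- function(df, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in% names(df)))
  if (nrow(df)) {
    if (any(df$start < 0)) stop("feature start < 0")
    if (any(df$start >= df$end)) stop("feature with start >= end")
    if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    if (any(df$score < 0)) stop("feature score (barrier strength) must be >= 0")
    if (!is.null(genome)) {
      if (any(df$end > .chrom_len(genome, df$chrom)))
        stop("feature extends beyond chromosome end")
    }
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("ok_features", "data.frame")
  df
}

#' Midpoints of features
#'
#' The midpoint of a 0-based half-open interval `[s, e)` is
#' `floor((s + e - 1) / 2)`, i.e. the dyad base for an odd-width nucleosome
#' footprint.
#'
#' @param features an `ok_features` data frame.
#' @return Integer vector of midpoint positions.
#' @export
feature_midpoints <- function(features) {
  floor((features$start + features$end - 1) / 2)
}

## ---- fixture generators -----------------------------------------------------

#' Generate a regularly spaced nucleosome dyad map
#'
#' Dyads are placed at multiples of `spacing` with optional Gaussian jitter.
#' Footprints (intervals of width `footprint` centred on the dyad) never
#' overlap: jittered positions violating this are redrawn up to 100 times and
#' then placed deterministically at the midpoint of the feasible window.
#'
#' @param genome an `ok_genome`.
#' @param spacing nucleosome repeat length in bp (default 165, the canonical
#'   budding-yeast value); must exceed `footprint`.
#' @param jitter_sd standard deviation (bp) of dyad jitter around the regular
#'   grid.
#' @param footprint nucleosomal DNA footprint width in bp (default 147).
#' @param strength barrier strength stored in the score column (dimensionless
#'   multiplier of the nucleosome barrier penalty).
#' @param seed integer seed; the map is deterministic given the seed.
#' @return An `ok_features` set of nucleosome footprints whose midpoints are
#'   the dyads.
#' @examples
#' g <- make_toy_genome(1, 2000)
#' feature_midpoints(make_nucleosome_map(g, spacing = 165, jitter_sd = 0))
#' @export
make_nucleosome_map <- function(genome, spacing = 165, jitter_sd = 0,
                                footprint = 147, strength = 1, seed = 1) {
  if (spacing <= footprint) stop("spacing must exceed the nucleosome footprint")
  if (footprint < 1) stop("footprint must be >= 1")
  set.seed(as.integer(seed))
  half_l <- floor(footprint / 2)
  half_r <- footprint - half_l        # interval = [dyad - half_l, dyad + half_r)
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    L <- as.numeric(genome)[ci]
    nominal <- seq(spacing, L, by = spacing)
    nominal <- nominal[nominal + half_r <= L & nominal - half_l >= 0]
    dyads <- numeric(0)
    prev_end <- -Inf
    for (k in seq_along(nominal)) {
      d <- NA_real_
      if (jitter_sd > 0) {
        for (try in 1:100) {
          cand <- round(nominal[k] + stats::rnorm(1, 0, jitter_sd))
          if (cand - half_l >= prev_end && cand - half_l >= 0 &&
              cand + half_r <= L) { d <- cand; break }
        }
      } else if (nominal[k] - half_l >= prev_end) d <- nominal[k]
      if (is.na(d)) {
        ## deterministic fallback: midpoint of the feasible dyad window
        lo <- max(prev_end + half_l, half_l)
        hi <- min(nominal[k] + floor(spacing / 2), L - half_r)
        if (lo > hi) next                # no room; skip this nucleosome
        d <- floor((lo + hi) / 2)
      }
      dyads <- c(dyads, d)
      prev_end <- d + half_r
    }
    if (length(dyads)) {
      out[[ci]] <- data.frame(chrom = names(genome)[ci], start = dyads - half_l,
                              end = dyads + half_r,
                              name = paste0("nuc_", names(genome)[ci], "_",
                                            seq_along(dyads)),
                              score = strength, strand = ".",
                              stringsAsFactors = FALSE)
    }
  }
  validate_features(do.call(rbind, out[!vapply(out, is.null, TRUE)]), genome)
}

#' Place transcription-factor binding sites at random non-overlapping positions
#'
#' Emulates a list of strong protein barriers (e.g. Abf1/Reb1/Rap1 sites).
#' Sites are drawn uniformly, rejecting candidates closer than `min_gap` to a
#' previously placed site.
#'
#' @inheritParams make_nucleosome_map
#' @param n_sites number of sites to place (>= 0).
#' @param footprint site footprint in bp (default 16).
#' @param min_gap minimum gap (bp) between site intervals.
#' @return An `ok_features` set of TF site footprints.
#' @export
make_tf_sites <- function(genome, n_sites, footprint = 16, strength = 1,
                          min_gap = 500, seed = 1) {
  if (n_sites < 0) stop("n_sites must be >= 0")
  set.seed(as.integer(seed))
  empty <- ok_features(character(0), numeric(0), numeric(0), character(0),
                       numeric(0), character(0))
  if (n_sites == 0) return(empty)
  half_l <- floor(footprint / 2)
  half_r <- footprint - half_l
  lens <- as.numeric(genome)
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  tries <- 0L
  max_tries <- 1000L * n_sites
  while (nrow(placed) < n_sites) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("genome too small to place ", n_sites, " sites with min_gap = ", min_gap)
    ci <- sample.int(length(lens), 1, prob = lens)
    L <- lens[ci]
    if (L < footprint) next
    d <- floor(stats::runif(1, half_l, L - half_r))
    s <- d - half_l; e <- d + half_r
    same <- placed[placed$chrom == names(genome)[ci], , drop = FALSE]
    if (nrow(same) && any(s - same$end < min_gap & same$start - e < min_gap)) next
    placed <- rbind(placed, data.frame(chrom = names(genome)[ci], start = s, end = e))
  }
  validate_features(data.frame(chrom = placed$chrom, start = placed$start,
                               end = placed$end,
                               name = paste0("tf_", seq_len(nrow(placed))),
                               score = strength, strand = ".",
                               stringsAsFactors = FALSE), genome)
}

#' Define replication origins with firing parameters
#'
#' Origins are point features carrying a firing efficiency (probability of
#' stochastic firing per cell, barring passive replication) and a firing-time
#' distribution (Normal with per-origin mean and common standard deviation,
#' minutes after release).
#'
#' @param genome an `ok_genome`.
#' @param positions data frame with columns `chrom` and `pos` (0-based bp).
#' @param efficiencies per-origin firing efficiency in \[0, 1\].
#' @param mean_times per-origin mean firing time (minutes).
#' @param time_sd standard deviation of firing time (minutes); scalar or
#'   per-origin.
#' @return An `ok_features` set with auxiliary columns `efficiency`,
#'   `mean_time` and `time_sd`; `score` mirrors the efficiency.
#' @examples
#' g <- make_toy_genome(1, 100000)
#' make_origins(g, data.frame(chrom = "chr1", pos = 50000), 1.0, 10)
#' @export
make_origins <- function(genome, positions, efficiencies, mean_times,
                         time_sd = 2) {
  n <- nrow(positions)
  if (length(efficiencies) != n || length(mean_times) != n)
    stop("positions, efficiencies and mean_times must have equal length")
  if (any(efficiencies < 0 | efficiencies > 1))
    stop("efficiencies must lie in [0, 1]")
  time_sd <- rep_len(time_sd, n)
  if (any(time_sd < 0)) stop("time_sd must be >= 0")
  if (any(positions$pos < 0 | positions$pos >= .chrom_len(genome, positions$chrom)))
    stop("origin position outside genome")
  df <- data.frame(chrom = as.character(positions$chrom),
                   start = as.numeric(positions$pos),
                   end = as.numeric(positions$pos) + 1,
                   name = paste0("ori_", seq_len(n)),
                   score = as.numeric(efficiencies), strand = ".",
                   efficiency = as.numeric(efficiencies),
                   mean_time = as.numeric(mean_times),
                   time_sd = as.numeric(time_sd),
                   stringsAsFactors = FALSE)
  validate_features(df, genome)
}

## ---- plain-text serialisation ----------------------------------------------

#' Read and write feature sets as BED6
#'
#' Tab-separated, no header, LF line endings.  Barrier strength (or origin
#' efficiency) travels in the score column.  Writing then reading a feature
#' set is lossless for the six BED columns.
#'
#' @param features an `ok_features` data frame.
#' @param path file path.
#' @return `write_bed` invisibly returns `path`; `read_bed` returns an
#'   `ok_features`.
#' @export
write_bed <- function(features, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(features)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", features$chrom,
                     as.integer(features$start), as.integer(features$end),
                     features$name, format_score(features$score), features$strand)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

format_score <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.6f", x)))
}

#' @rdname write_bed
#' @param genome optional `ok_genome` for bounds checking.
#' @export
read_bed <- function(path, genome = NULL) {
  if (file.size(path) == 0)
    return(ok_features(character(0), numeric(0), numeric(0), character(0),
                       numeric(0), character(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "character"),
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  validate_features(df, genome)
}

#' Read and write a genome as a chrom-sizes file
#'
#' Two tab-separated columns: chromosome name and length.
#'
#' @param genome an `ok_genome`.
#' @param path file path.
#' @export
write_chrom_sizes <- function(genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", names(genome), as.integer(genome)), con, sep = "\n")
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  ok_genome(df$length, df$chrom)
}
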