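#' Density profile of retained Pol alpha DNA around features
#'
#' Every base of every retained Pol alpha tract within `flank` of a feature
#' midpoint contributes one count at its oriented offset (offsets of
#' `-`-strand tracts are negated, as for terminus profiles).  The raw
#' per-base density is then smoothed and median-normalised identically to
#' terminus profiles, so the two kinds of curve are directly comparable.
#'
#' External polymerase-usage data (e.g. single-base ribonucleotide positions
#' from a Pol alpha steric mutant) can be supplied as a BED6 of 1-bp
#' intervals read with [read_fragments()].
#'
#' @param tracts an `ok_fragments`-shaped data frame of tract intervals
#'   (from [polalpha_tracts()] or a BED6 file).
#' @param features an `ok_features` set.
#' @param flank half-width of the profile in bp.
#' @param orient_by_strand negate offsets of `-`-strand tracts.
#' @param smooth moving-average window (bp); `NULL` to skip.
#' @param norm_range normalisation half-range (bp); `NULL` to return the raw
#'   per-base density (an all-zero raw profile is valid; normalising it is
#'   an error).
#' @return An `end_profile` with `end_type = "polalpha_tract"`.
#' @export
tract_density <- function(tracts, features, flank = 100,
                          orient_by_strand = TRUE, smooth = 5,
                          norm_range = 100) {
  if (flank < 1) stop("flank must be >= 1")
  if (is.null(features) || !nrow(features)) stop("empty feature set")
  ## expand intervals to per-base points (tracts are short: 0-35 nt)
  n <- nrow(tracts)
  if (n) {
    w <- tracts$end - tracts$start
    idx <- rep.int(seq_len(n), w)
    pts <- data.frame(chrom = tracts$chrom[idx],
                      pos = tracts$start[idx] + sequence(w) - 1,
                      strand = tracts$strand[idx], stringsAsFactors = FALSE)
  } else {
    pts <- data.frame(chrom = character(0), pos = numeric(0),
                      strand = character(0))
  }
  po <- pair_offsets(pts, features, flank)
  off <- po$offset
  if (orient_by_strand && length(off)) off <- ifelse(po$strand == "-", -off, off)
  count <- tabulate(off + flank + 1, nbins = 2 * flank + 1)
  p <- new_end_profile(-flank:flank, count, as.numeric(count),
                       "polalpha_tract", n_features = nrow(features),
                       n_ends = n)
  if (!is.null(smooth)) p <- smooth_profile(p, smooth)
  if (!is.null(norm_range)) p <- normalize_to_median(p, norm_range)
  p
}

#' Compare a terminus profile with a Pol alpha tract density
#'
#' Reports the terminus peak offset, the tract-density trough offset and
#' their difference `delta = trough - peak` (positive when the depletion of
#' Pol alpha DNA lies downstream of the terminus peak).
#'
#' @param terminus_profile an `end_profile` of fragment 5' ends.
#' @param density an `end_profile` from [tract_density()], same offset grid.
#' @return A list with `peak_offset`, `peak_height`, `trough_offset`,
#'   `trough_depth` and `delta` (bp).
#' @export
compare_polalpha <- function(terminus_profile, density) {
  if (!identical(terminus_profile$offset, density$offset))
    stop("mismatched offset grids")
  pk <- peak_location(terminus_profile)
  tr <- trough_location(density)
  list(peak_offset = pk$offset, peak_height = pk$height,
       trough_offset = tr$offset, trough_depth = tr$depth,
       delta = tr$offset - pk$offset)
}
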