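#' Terminus positions of Okazaki fragments
#'
#' For a `+` (Watson) fragment `[start, end)` the 5' terminus is `start` and
#' the 3' terminus `end - 1`; for a `-` (Crick) fragment the 5' terminus is
#' `end - 1` and the 3' terminus `start`.
#'
#' @param fragments an `ok_fragments` data frame.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @return A data frame with `chrom`, `pos` (0-based base position of the
#'   terminus) and `strand`.
#' @export
terminus_position <- function(fragments, end_type = c("five_prime",
                                                      "three_prime")) {
  end_type <- match.arg(end_type)
  five <- end_type == "five_prime"
  pos <- ifelse(fragments$strand == "+",
                if (five) fragments$start else fragments$end - 1,
                if (five) fragments$end - 1 else fragments$start)
  data.frame(chrom = fragments$chrom, pos = pos, strand = fragments$strand,
             stringsAsFactors = FALSE)
}

new_end_profile <- function(offsets, count, value, end_type, n_features,
                            n_ends, smooth_window = NULL, norm_range = NULL) {
  structure(list(offset = offsets, count = count, value = value,
                 end_type = end_type, n_features = n_features,
                 n_ends = n_ends, smooth_window = smooth_window,
                 norm_range = norm_range),
            class = "end_profile")
}

#' Aggregate fragment termini around aligned feature midpoints
#'
#' For every (terminus, feature-midpoint) pair closer than `flank`, the
#' offset `terminus - midpoint` is counted.  When orienting by fragment
#' strand (the default), offsets of `-`-strand fragments are negated so that
#' negative offsets always mean upstream in the direction of
#' Okazaki-fragment synthesis.  A terminus within the flank of several
#' features counts toward each (set `nearest_only = TRUE` to count only the
#' nearest).  Features may optionally be oriented by their own strand
#' instead.
#'
#' @param fragments an `ok_fragments` data frame.
#' @param features an `ok_features` set (e.g. nucleosome dyads or TF sites);
#'   alignment anchors are the feature midpoints.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @param flank half-width of the profile in bp (offsets `-flank..+flank`).
#' @param orient_by_fragment_strand negate offsets of `-`-strand fragments.
#' @param orient_by_feature_strand negate offsets at `-`-strand features
#'   (ignores fragment strand); only one orientation mode may be active.
#' @param nearest_only count each terminus toward its nearest feature only
#'   (distance ties go to the feature earlier in position order).
#' @return An `end_profile` holding raw counts per offset.
#' @export
aggregate_ends <- function(fragments, features,
                           end_type = c("five_prime", "three_prime"),
                           flank = 100, orient_by_fragment_strand = TRUE,
                           orient_by_feature_strand = FALSE,
                           nearest_only = FALSE) {
  end_type <- match.arg(end_type)
  if (flank < 1) stop("flank must be >= 1")
  if (is.null(features) || !nrow(features)) stop("empty feature set")
  if (orient_by_fragment_strand && orient_by_feature_strand)
    stop("choose a single orientation mode")
  term <- terminus_position(fragments, end_type)
  po <- pair_offsets(term, features, flank, nearest_only)
  off <- po$offset
  if (orient_by_fragment_strand && length(off)) {
    off <- ifelse(po$strand == "-", -off, off)
  } else if (orient_by_feature_strand && length(off)) {
    off <- ifelse(po$fstrand == "-", -off, off)
  }
  offsets <- -flank:flank
  count <- tabulate(off + flank + 1, nbins = 2 * flank + 1)
  new_end_profile(offsets, count, as.numeric(count), end_type,
                  n_features = nrow(features), n_ends = nrow(term))
}

## all (point, feature-midpoint) pairs with |offset| <= flank
pair_offsets <- function(points, features, flank, nearest_only = FALSE) {
  out_off <- vector("list", 0); out_str <- vector("list", 0)
  out_fstr <- vector("list", 0)
  mids_all <- feature_midpoints(features)
  for (ch in unique(points$chrom)) {
    sel <- features$chrom == ch
    if (!any(sel)) next
    mids <- mids_all[sel]
    fstr <- features$strand[sel]
    o <- order(mids); mids <- mids[o]; fstr <- fstr[o]
    p <- points[points$chrom == ch, , drop = FALSE]
    lo <- findInterval(p$pos - flank - 0.5, mids) + 1
    hi <- findInterval(p$pos + flank + 0.5, mids)
    n <- pmax(hi - lo + 1, 0)
    if (!sum(n)) next
    pi <- rep.int(seq_len(nrow(p)), n)
    fi <- sequence(n) + rep.int(lo - 1L, n)
    off <- p$pos[pi] - mids[fi]
    str <- p$strand[pi]
    fst <- fstr[fi]
    if (nearest_only && length(off)) {
      ord <- order(pi, abs(off))
      first <- !duplicated(pi[ord])
      keep <- logical(length(off)); keep[ord[first]] <- TRUE
      off <- off[keep]; str <- str[keep]; fst <- fst[keep]
    }
    out_off[[ch]] <- off; out_str[[ch]] <- str; out_fstr[[ch]] <- fst
  }
  list(offset = unlist(out_off, use.names = FALSE),
       strand = unlist(out_str, use.names = FALSE),
       fstrand = unlist(out_fstr, use.names = FALSE))
}

#' Smooth a profile with a centred moving average
#'
#' Width-`window` centred moving average; at the edges of the offset grid
#' the window truncates to the available offsets, so a constant profile is
#' unchanged everywhere.  `window = 1` is the identity.
#'
#' @param profile an `end_profile`.
#' @param window odd window width in bp (default 5).
#' @return The smoothed `end_profile`.
#' @export
smooth_profile <- function(profile, window = 5) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  v <- profile$value
  n <- length(v)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1, i - half); hi <- pmin(n, i + half)
  profile$value <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  profile$smooth_window <- window
  profile
}

#' Normalise a profile to its median over a central range
#'
#' Divides every value by the median of the values at offsets within
#' `[-range_bp, +range_bp]`.  After normalisation that median equals 1.
#' Normalisation of an already-normalised profile is the identity.
#'
#' @param profile an `end_profile` covering at least `[-range_bp, range_bp]`.
#' @param range_bp half-width (bp) of the normalisation window (default 100,
#'   i.e. the median end density in a 200-bp window around the sites).
#' @return The normalised `end_profile`.
#' @export
normalize_to_median <- function(profile, range_bp = 100) {
  if (min(profile$offset) > -range_bp || max(profile$offset) < range_bp)
    stop("profile does not cover the normalisation range")
  med <- stats::median(profile$value[abs(profile$offset) <= range_bp])
  if (med == 0) stop("median over the normalisation range is 0; ",
                     "profile too sparse to normalise")
  profile$value <- profile$value / med
  profile$norm_range <- range_bp
  profile
}

#' Locate the peak (or trough) of a profile
#'
#' Ties are broken toward the smallest offset.
#'
#' @param profile an `end_profile` (typically smoothed and normalised).
#' @return A list with `offset` (bp) and `height` (value at the peak).
#' @export
peak_location <- function(profile) {
  if (!length(profile$value)) stop("empty profile")
  i <- which.max(profile$value)
  list(offset = profile$offset[i], height = profile$value[i])
}

#' @rdname peak_location
#' @return `trough_location`: a list with `offset` and `depth`.
#' @export
trough_location <- function(profile) {
  if (!length(profile$value)) stop("empty profile")
  i <- which.min(profile$value)
  list(offset = profile$offset[i], depth = profile$value[i])
}

#' Shift between two profiles
#'
#' Positive values mean profile `b` peaks downstream of profile `a` (e.g.
#' terminus migration toward the dyad with longer ligase depletion).  Also
#' reports the difference of count-weighted mean offsets, which is more
#' robust than the argmax for noisy profiles.
#'
#' @param a,b `end_profile`s on the same offset grid.
#' @return A list with `peak_shift` (bp, `peak(b) - peak(a)`) and
#'   `mean_shift` (bp, difference of count-weighted mean offsets).
#' @export
profile_shift <- function(a, b) {
  if (!identical(a$offset, b$offset)) stop("mismatched offset grids")
  wmean <- function(p) {
    if (sum(p$count) == 0) return(NA_real_)
    sum(p$offset * p$count) / sum(p$count)
  }
  list(peak_shift = peak_location(b)$offset - peak_location(a)$offset,
       mean_shift = wmean(b) - wmean(a))
}

#' Count-weighted mean terminus offset of a profile
#'
#' @param profile an `end_profile`.
#' @return Mean offset in bp (using raw counts), `NA` if the profile is
#'   empty.
#' @export
mean_offset <- function(profile) {
  if (sum(profile$count) == 0) return(NA_real_)
  sum(profile$offset * profile$count) / sum(profile$count)
}

#' @export
print.end_profile <- function(x, ...) {
  cat("<end_profile> ", x$end_type, ", offsets ", min(x$offset), "..",
      max(x$offset), " bp, ", sum(x$count), " (terminus, feature) pairs\n",
      sep = "")
  if (!is.null(x$smooth_window))
    cat("  smoothed: ", x$smooth_window, " bp moving average\n", sep = "")
  if (!is.null(x$norm_range))
    cat("  normalised to median over ±", x$norm_range, " bp\n", sep = "")
  pk <- peak_location(x)
  cat("  peak at ", pk$offset, " bp (height ", format(pk$height, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.end_profile <- function(x, ...) {
  data.frame(offset = x$offset, count = x$count, value = x$value)
}

#' @export
plot.end_profile <- function(x, ..., xlab = "offset from feature midpoint (bp)",
                             ylab = NULL, type = "l") {
  if (is.null(ylab))
    ylab <- if (!is.null(x$norm_range)) "normalised end density" else "count"
  graphics::plot(x$offset, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Terminus meta-profile: aggregate, smooth and normalise in one call
#'
#' The standard presentation of terminus distributions: raw offset counts
#' around feature midpoints, smoothed to `smooth` bp and normalised to the
#' median value within `norm_range` bp of the midpoint.
#'
#' @inheritParams aggregate_ends
#' @param smooth moving-average window (bp); `NULL` to skip.
#' @param norm_range normalisation half-range (bp); `NULL` to skip.
#' @return An `end_profile`.
#' @export
end_profile <- function(fragments, features,
                        end_type = c("five_prime", "three_prime"),
                        flank = 100, smooth = 5, norm_range = 100,
                        orient_by_fragment_strand = TRUE,
                        orient_by_feature_strand = FALSE,
                        nearest_only = FALSE) {
  p <- aggregate_ends(fragments, features, end_type, flank,
                      orient_by_fragment_strand, orient_by_feature_strand,
                      nearest_only)
  if (!is.null(smooth)) p <- smooth_profile(p, smooth)
  if (!is.null(norm_range)) p <- normalize_to_median(p, norm_range)
  p
}

#' Write a profile as TSV
#'
#' Columns: offset, raw count, current (smoothed/normalised) value.
#'
#' @param profile an `end_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("offset\tcount\tvalue", con, sep = "\n")
  writeLines(sprintf("%d\t%s\t%s", profile$offset,
                     format_score(profile$count),
                     sprintf("%.8g", profile$value)), con, sep = "\n")
  invisible(path)
}
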