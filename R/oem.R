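#' Strand-specific fragment counts flanking an origin
#'
#' Counts Okazaki fragments by strand in windows of `window` bp immediately
#' left (`[pos - window, pos)`) and right (`[pos, pos + window)`) of an
#' origin.  A fragment is assigned by its midpoint `floor((start + end) / 2)`
#' (avoids double-counting fragments straddling the origin); set
#' `assign = "five_prime"` to assign by the 5' terminus instead.  A midpoint
#' exactly at `pos` falls in the right window (half-open convention).
#'
#' @param fragments an `ok_fragments` data frame.
#' @param origin a list or one-row data frame with `chrom` and `pos`.
#' @param window flank width in bp (default 10000).
#' @param assign `"midpoint"` (default) or `"five_prime"`.
#' @return A named numeric vector with elements `W_L`, `C_L`, `W_R`, `C_R`
#'   (Watson/Crick counts in the left/right windows).
#' @export
count_strand_windows <- function(fragments, origin, window = 10000,
                                 assign = c("midpoint", "five_prime")) {
  assign <- match.arg(assign)
  if (window <= 0) stop("window must be > 0")
  pos <- if (!is.null(origin$pos)) origin$pos else origin$start
  fr <- fragments[fragments$chrom == origin$chrom, , drop = FALSE]
  at <- if (assign == "midpoint") floor((fr$start + fr$end) / 2)
        else ifelse(fr$strand == "+", fr$start, fr$end - 1)
  left <- at >= pos - window & at < pos
  right <- at >= pos & at < pos + window
  c(W_L = sum(left & fr$strand == "+"), C_L = sum(left & fr$strand == "-"),
    W_R = sum(right & fr$strand == "+"), C_R = sum(right & fr$strand == "-"))
}

#' Origin efficiency metric
#'
#' `OEM = W_L / (W_L + C_L) - W_R / (W_R + C_R)`: the difference in the
#' Watson-strand fragment fraction between the windows left and right of the
#' origin.  Because Watson-strand fragments derive from leftward-moving
#' forks and Crick-strand fragments from rightward forks, a fully efficient
#' origin scores +1 (all-Watson on the left, all-Crick on the right).  If
#' either window is empty the metric is undefined and `NA` is returned
#' (never 0).
#'
#' @param counts a vector with elements `W_L`, `C_L`, `W_R`, `C_R` (from
#'   [count_strand_windows()]).
#' @return The OEM in \[-1, 1\], or `NA` when undefined.
#' @examples
#' compute_oem(c(W_L = 80, C_L = 20, W_R = 30, C_R = 70))  # 0.5
#' @export
compute_oem <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  dl <- counts[["W_L"]] + counts[["C_L"]]
  dr <- counts[["W_R"]] + counts[["C_R"]]
  if (dl == 0 || dr == 0) return(NA_real_)
  counts[["W_L"]] / dl - counts[["W_R"]] / dr
}

#' Origin efficiency metric for a table of origins
#'
#' @param fragments an `ok_fragments` data frame.
#' @param origins an `ok_features` set of origins (point features).
#' @param window flank width in bp.
#' @inheritParams count_strand_windows
#' @return A data frame with one row per origin, in the origins' order:
#'   `chrom`, `pos`, the four counts, and `oem` (`NA` where undefined).
#' @export
oem_table <- function(fragments, origins, window = 10000,
                      assign = c("midpoint", "five_prime")) {
  assign <- match.arg(assign)
  if (is.null(origins) || !nrow(origins)) stop("origins must be non-empty")
  rows <- lapply(seq_len(nrow(origins)), function(i) {
    cnt <- count_strand_windows(fragments,
                                list(chrom = origins$chrom[i],
                                     pos = origins$start[i]),
                                window = window, assign = assign)
    data.frame(chrom = origins$chrom[i], pos = origins$start[i],
               W_L = cnt[["W_L"]], C_L = cnt[["C_L"]], W_R = cnt[["W_R"]],
               C_R = cnt[["C_R"]], oem = compute_oem(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an OEM table as TSV
#'
#' @param tab output of [oem_table()].
#' @param path output path.
#' @export
write_oem_table <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("chrom", "pos", "W_L", "C_L", "W_R", "C_R", "oem"),
                   collapse = "\t"), con, sep = "\n")
  if (nrow(tab))
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%s", tab$chrom,
                       as.integer(tab$pos), tab$W_L, tab$C_L, tab$W_R,
                       tab$C_R, ifelse(is.na(tab$oem), "NA",
                                       sprintf("%.6g", tab$oem))),
               con, sep = "\n")
  invisible(path)
}
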