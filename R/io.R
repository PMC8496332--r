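#' Fragment sets
#'
#' An `ok_fragments` object is a data frame of stranded genomic intervals
#' (`chrom`, `start`, `end`, `name`, `score`, `strand`), 0-based half-open,
#' in canonical `(chrom, start, end, strand)` order.  Strand is mandatory:
#' `+` fragments are Watson-strand Okazaki fragments (from leftward-moving
#' forks), `-` fragments Crick-strand ones (rightward forks).
#'
#' @param df a data frame with at least `chrom`, `start`, `end`, `strand`.
#' @return An `ok_fragments` data frame.
#' @export
as_fragments <- function(df) {
  if (!all(c("chrom", "start", "end", "strand") %in% names(df)))
    stop("fragments need chrom, start, end and strand columns")
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("fragment with start >= end")
    if (any(df$start < 0)) stop("fragment start < 0")
    if (!all(df$strand %in% c("+", "-")))
      stop("fragment strand must be '+' or '-'")
  }
  canonical_order(df)
}

canonical_order <- function(df) {
  df <- df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ok_fragments", "data.frame")
  df
}

#' Read Okazaki fragments from BED6 or BEDPE
#'
#' Parsing is strict: 0-based half-open coordinates, `start < end`, strand in
#' `+`/`-`; malformed rows are reported with their line numbers.  For BEDPE,
#' both mates must map to the same chromosome; the fragment is the
#' outer-coordinate span `[min(start1, start2), max(end1, end2))` (paired-end
#' mates delimit the fragment) and its strand is the strand of mate 1, the
#' read anchored at the fragment's 5'-phosphate end.
#'
#' @param path input file (tab-separated, no header).
#' @param format `"bed6"` or `"bedpe"`.
#' @return An `ok_fragments` data frame.
#' @export
read_fragments <- function(path, format = c("bed6", "bedpe")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  empty <- as_fragments(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), name = character(0),
                                   score = numeric(0), strand = character(0)))
  if (file.size(path) == 0) return(empty)
  if (format == "bed6") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "numeric", "numeric",
                                           "character", "numeric", "character"),
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"))
    fail_rows(df$start >= df$end, "start >= end")
    fail_rows(df$start < 0, "negative start")
    fail_rows(!(df$strand %in% c("+", "-")), "unknown strand")
    return(canonical_order(df))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "character", "numeric", "character",
                                         "character"),
                          col.names = c("chrom1", "start1", "end1", "chrom2",
                                        "start2", "end2", "name", "score",
                                        "strand1", "strand2"))
  fail_rows(df$chrom1 != df$chrom2, "inter-chromosomal mate pair")
  fail_rows(df$start1 >= df$end1 | df$start2 >= df$end2, "mate start >= end")
  fail_rows(pmin(df$start1, df$start2) < 0, "negative start")
  fail_rows(!(df$strand1 %in% c("+", "-")), "unknown strand")
  canonical_order(data.frame(chrom = df$chrom1,
                             start = pmin(df$start1, df$start2),
                             end = pmax(df$end1, df$end2),
                             name = df$name, score = df$score,
                             strand = df$strand1, stringsAsFactors = FALSE))
}

fail_rows <- function(bad, what) {
  if (any(bad))
    stop("malformed row (", what, ") at line ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         if (sum(bad) > 5) " ..." else "", call. = FALSE)
}

#' Strand-specific per-base genome coverage
#'
#' Every fragment increments every base of its interval on its own strand's
#' track.  Coverage is conserved: the two tracks sum to the total fragment
#' length.
#'
#' @param fragments an `ok_fragments` data frame.
#' @param genome an `ok_genome`.
#' @return A list with elements `watson` and `crick`, each a `coverage_track`:
#'   a named list of per-chromosome numeric vectors.
#' @export
strand_coverage <- function(fragments, genome) {
  if (nrow(fragments)) {
    if (anyNA(match(fragments$chrom, names(genome))) ||
        any(fragments$end > .chrom_len(genome, fragments$chrom)) ||
        any(fragments$start < 0))
      stop("fragment outside genome bounds")
  }
  one_strand <- function(str) {
    tr <- lapply(seq_along(genome), function(ci) {
      L <- as.numeric(genome)[ci]
      fr <- fragments[fragments$strand == str &
                      fragments$chrom == names(genome)[ci], , drop = FALSE]
      if (!nrow(fr)) return(numeric(L))
      d <- tabulate(fr$start + 1, nbins = L + 1) -
        tabulate(fr$end + 1, nbins = L + 1)
      cumsum(d)[seq_len(L)]
    })
    names(tr) <- names(genome)
    structure(tr, class = "coverage_track")
  }
  list(watson = one_strand("+"), crick = one_strand("-"))
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal non-zero coverage are emitted run-length encoded; zero runs
#' are omitted.  Deterministic output with a single `track` header line.
#'
#' @param track a `coverage_track` (named list of per-chromosome vectors).
#' @param path output path.
#' @param strand_label name recorded in the track line.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, strand_label = "coverage") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", strand_label), con,
             sep = "\n")
  for (ch in names(track)) {
    r <- rle(track[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                         as.integer(ends[keep]), format_score(r$values[keep])),
                 con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome an `ok_genome` giving the vector lengths to expand into.
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  tr <- lapply(as.numeric(genome), numeric)
  names(tr) <- names(genome)
  if (length(lines)) {
    df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"))
    for (i in seq_len(nrow(df)))
      tr[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  structure(tr, class = "coverage_track")
}
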