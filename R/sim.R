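## Lagging-strand synthesis and maturation simulator.
##
## Internal coordinate system ("s-space"), per fork: s measures distance (bp)
## from the fork's origin-proximal end along the direction of fork movement,
## as half-open boundaries in [0, n].  Okazaki fragments are synthesized in
## the -s direction (toward the origin): for a leftward-moving fork this is
## rightward on the reference (Watson/+ fragments), mirrored for rightward
## forks (Crick/- fragments).  Priming tops q_1 < q_2 < ... are the 5'
## boundaries of successive fragments; the junction J_k between fragment k
## and the fragment primed after it starts at q_k and moves in -s as nick
## translation proceeds, bounded below by q_{k-1}.

#' Simulate origin firing and fork progression
#'
#' Per cell, each origin fires with its efficiency at a
#' Normal(`mean_time`, `time_sd`) firing time unless a fork from an
#' earlier-firing origin crosses its position first (passive replication).
#' Two forks per firing move at `fork_speed`; converging forks stop where
#' they meet (meeting point rounded toward the leftward-moving fork).
#'
#' @param genome an `ok_genome`.
#' @param origins an `ok_features` set from [make_origins()].
#' @param params a [sim_params()] object.
#' @param n_cells number of cells to simulate.
#' @param seed root seed; per-cell substreams are derived by a counter so
#'   earlier cells are unchanged when `n_cells` grows.
#' @return A data frame with one row per fork: `cell`, `chrom`, `origin`
#'   (position), `direction` (`L`/`R`), `start_time`, `end_time`, `start`,
#'   `end` (replicated genome interval at harvest) and `complete`.
#' @export
simulate_forks <- function(genome, origins, params, n_cells, seed = params$seed) {
  check_origins(genome, origins)
  out <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    set.seed(cell_seed(seed, cell))
    out[[cell]] <- forks_one_cell(genome, origins, params, cell)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_origins <- function(genome, origins) {
  if (is.null(origins) || !nrow(origins)) stop("at least one origin is required")
  for (ch in names(genome)) {
    eff <- origins$efficiency[origins$chrom == ch]
    if (!length(eff) || all(eff <= 0))
      stop("chromosome ", ch, " has no origin with efficiency > 0")
  }
  invisible(TRUE)
}

## one cell's fork set; assumes the RNG has been seeded by the caller
forks_one_cell <- function(genome, origins, params, cell) {
  v <- params$fork_speed
  rows <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    L <- as.numeric(genome)[ci]
    ori <- origins[origins$chrom == ch, , drop = FALSE]
    fire <- stats::runif(nrow(ori)) < ori$efficiency
    tf <- pmax(params$t_release,
               stats::rnorm(nrow(ori), ori$mean_time, ori$time_sd))
    ori <- ori[fire, , drop = FALSE]; tf <- tf[fire]
    if (!nrow(ori)) next                       # no firing: unreplicated cell
    ## passive replication: an origin is silenced if already replicated when
    ## its firing time comes
    o <- order(tf)
    keep_p <- numeric(0); keep_t <- numeric(0)
    for (k in o) {
      p <- ori$start[k]
      if (length(keep_p) && min(keep_t + abs(p - keep_p) / v) <= tf[k]) next
      keep_p <- c(keep_p, p); keep_t <- c(keep_t, tf[k])
    }
    ord <- order(keep_p)
    p <- keep_p[ord]; t <- keep_t[ord]
    m <- length(p)
    ## territory boundaries: converging forks meet where arrival times agree;
    ## round toward the leftward-moving fork (the right-hand origin's)
    b <- numeric(m + 1); b[1] <- 0; b[m + 1] <- L
    if (m > 1) {
      for (i in 1:(m - 1)) {
        mid <- (p[i] + p[i + 1]) / 2 + v * (t[i + 1] - t[i]) / 2
        b[i + 1] <- min(max(ceiling(mid), p[i] + 1), p[i + 1])
      }
    }
    mk <- function(i, dir) {
      full <- if (dir == "L") p[i] - b[i] else b[i + 1] - p[i]
      nrep <- max(0, min(full, floor((params$t_harvest - t[i]) * v)))
      gs <- if (dir == "L") p[i] - nrep else p[i]
      ge <- if (dir == "L") p[i] else p[i] + nrep
      data.frame(cell = cell, chrom = ch, origin = p[i], direction = dir,
                 start_time = t[i], end_time = t[i] + nrep / v,
                 start = gs, end = ge, complete = nrep == full,
                 stringsAsFactors = FALSE)
    }
    rows[[ci]] <- rbind(do.call(rbind, lapply(seq_len(m), mk, dir = "L")),
                        do.call(rbind, lapply(seq_len(m), mk, dir = "R")))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  res[order(res$chrom, res$origin, res$direction), , drop = FALSE]
}

#' Lay priming sites and Pol alpha tracts along one fork
#'
#' Successive priming-site spacings are Normal(`priming_spacing_mean`,
#' `priming_spacing_sd`) draws, rounded and truncated below at
#' `rna_primer_len + pol_alpha_min + 1`.  Each fragment carries an RNA primer
#' of `rna_primer_len` nt and a Pol alpha initiator-DNA tract of
#' Uniform\{`pol_alpha_min`..`pol_alpha_max`\} nt immediately 3' of the
#' primer.  Consumes the current RNG stream; seed beforehand for
#' reproducibility.
#'
#' @param fork one row of [simulate_forks()] output.
#' @param params a [sim_params()] object.
#' @return A data frame with one row per primed fragment: `q` (priming-top
#'   boundary in fork coordinates, distance from the origin-proximal end),
#'   `la` (tract length, nt), `priming_pos` (genome position of the 5'-most
#'   primer base) and `strand`.
#' @export
synthesize_fragments <- function(fork, params) {
  n <- fork$end - fork$start
  min_sp <- params$rna_primer_len + params$pol_alpha_min + 1
  mu <- params$priming_spacing_mean; sd <- params$priming_spacing_sd
  if (sd == 0 && mu < min_sp)
    stop("priming spacing below the minimum fragment size and sd = 0")
  if (sd > 0 && stats::pnorm(min_sp, mu, sd) > 0.999)
    stop("priming spacing truncation impossible with these parameters")
  qs <- numeric(0); tot <- 0
  while (tot < n) {
    k <- max(16L, ceiling((n - tot) / max(mu, min_sp)) + 8L)
    sp <- round(stats::rnorm(k, mu, sd))
    for (g in 1:100) {
      bad <- sp < min_sp
      if (!any(bad)) break
      sp[bad] <- round(stats::rnorm(sum(bad), mu, sd))
    }
    sp[sp < min_sp] <- min_sp
    qs <- c(qs, tot + cumsum(sp))
    tot <- qs[length(qs)]
  }
  qs <- qs[qs < n]
  m <- length(qs)
  la <- if (!m) integer(0)
  else if (params$pol_alpha_min == params$pol_alpha_max)
    rep.int(params$pol_alpha_min, m)
  else sample(params$pol_alpha_min:params$pol_alpha_max, m, replace = TRUE)
  left <- fork$direction == "L"
  pos <- if (left) fork$origin - qs else fork$origin + qs - 1
  data.frame(q = qs, la = la, priming_pos = pos,
             strand = if (left) "+" else "-", stringsAsFactors = FALSE)
}

#' Advance nick-translation junctions through a barrier profile
#'
#' Runs up to `n_cycles` displacement/cleavage cycles for each junction.
#' Each cycle advances the junction by Uniform\{`displace_min`..
#' `displace_max`\} nt in its synthesis direction with probability
#' `p_continue * exp(-penalty(x))`, `x` the base about to be removed; the
#' first failed cycle pauses the junction and ends the call.
#'
#' @param pos numeric vector of junction boundary positions (0-based genome
#'   boundary coordinates).
#' @param barrier_profile numeric per-base penalty vector for the chromosome
#'   (one element of [barrier_penalty()]); positions outside it are free DNA.
#' @param params a [sim_params()] object.
#' @param n_cycles maximum number of cycles (0 leaves positions unchanged).
#' @param dir +1 if the junction advances toward higher coordinates (Watson
#'   fragments / leftward forks), -1 otherwise; recycled.
#' @param bound furthest admissible boundary in the direction of advance
#'   (e.g. the downstream neighbour's priming top); recycled.
#' @return Numeric vector of new junction boundary positions.
#' @export
nick_translate <- function(pos, barrier_profile, params, n_cycles,
                           dir = 1L, bound = NULL) {
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  np <- length(pos)
  dir <- rep_len(as.integer(dir), np)
  if (is.null(bound)) bound <- ifelse(dir > 0, Inf, -Inf)
  bound <- rep_len(as.numeric(bound), np)
  cpp_nick_translate(as.numeric(pos), dir, bound, as.numeric(n_cycles),
                     as.numeric(barrier_profile), params$p_continue,
                     as.integer(params$displace_min),
                     as.integer(params$displace_max))
}

#' Simulate an Okazaki-fragment sequencing experiment
#'
#' Full pipeline: origin firing and fork progression, priming and Pol alpha
#' tract deposition, replication-coupled nick translation, ligation while
#' ligase is present (before `t_depletion_start`), continued nick translation
#' at persistent nicks until `t_harvest`, and bookkeeping of retained Pol
#' alpha tracts.
#'
#' @inheritParams simulate_forks
#' @param nucleosomes,tf_sites optional `ok_features` barrier sets.
#' @return An object of class `ok_sim`: a list with `fragments` (every
#'   fragment, ligated or not, with `ligated` and `primer_removed` flags),
#'   `tracts` (retained Pol alpha tract intervals of all fragments),
#'   `forks`, plus the inputs.  Use [harvest_library()] to extract the
#'   sequenceable library.
#' @export
simulate_okseq <- function(genome, origins, params = sim_params(),
                           n_cells = 100, nucleosomes = NULL, tf_sites = NULL,
                           seed = params$seed) {
  check_origins(genome, origins)
  pen <- barrier_penalty(genome, nucleosomes, tf_sites, params)
  frag_l <- vector("list", n_cells)
  tract_l <- vector("list", n_cells)
  fork_l <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    set.seed(cell_seed(seed, cell))
    forks <- forks_one_cell(genome, origins, params, cell)
    fork_l[[cell]] <- forks
    if (is.null(forks)) next
    prim <- vector("list", nrow(forks))
    for (fi in seq_len(nrow(forks))) {
      if (forks$end[fi] > forks$start[fi])
        prim[[fi]] <- synthesize_fragments(forks[fi, ], params)
    }
    jx <- build_junctions(forks, prim, params, names(genome))
    if (nrow(jx$junc)) {
      res <- cpp_run_junctions(jx$junc$cur0, jx$junc$dirg, jx$junc$bound,
                               jx$junc$prem, jx$junc$birth, jx$junc$chrom_idx,
                               unclass(pen)[names(genome)],
                               params$p_continue,
                               as.integer(params$displace_min),
                               as.integer(params$displace_max),
                               params$p_ligate, params$post_nt_rate,
                               params$t_depletion_start, params$t_harvest,
                               params$tick, params$nt_after_primer)
    } else res <- list(final = numeric(0), ligated = logical(0))
    asm <- assemble_cell(forks, prim, jx, res, params, cell)
    frag_l[[cell]] <- asm$fragments
    tract_l[[cell]] <- asm$tracts
  }
  fragments <- do.call(rbind, frag_l[!vapply(frag_l, is.null, TRUE)])
  tracts <- do.call(rbind, tract_l[!vapply(tract_l, is.null, TRUE)])
  forks <- do.call(rbind, fork_l[!vapply(fork_l, is.null, TRUE)])
  rownames(fragments) <- rownames(tracts) <- rownames(forks) <- NULL
  structure(list(fragments = fragments, tracts = tracts, forks = forks,
                 params = params, genome = genome, n_cells = n_cells,
                 seed = seed),
            class = "ok_sim")
}

## junction table for one cell, in genome boundary coordinates
build_junctions <- function(forks, prim, params, chrom_names) {
  rows <- vector("list", nrow(forks))
  for (fi in seq_len(nrow(forks))) {
    pr <- prim[[fi]]
    if (is.null(pr) || !nrow(pr)) next
    f <- forks[fi, ]
    n <- f$end - f$start
    q <- pr$q
    m <- length(q)
    qprev <- c(0, q[-m])
    qnext <- c(q[-1], n)
    left <- f$direction == "L"
    dirg <- if (left) 1L else -1L
    cur0 <- if (left) f$origin - q else f$origin + q
    bound <- if (left) f$origin - qprev else f$origin + qprev
    prem <- cur0 + dirg * params$rna_primer_len
    ## clamp primer-removal boundary into the fragment's own span
    prem <- if (left) pmin(prem, bound) else pmax(prem, bound)
    birth <- f$start_time + qnext / params$fork_speed
    rows[[fi]] <- data.frame(fork = fi, k = seq_len(m), cur0 = cur0,
                             dirg = dirg, bound = bound, prem = prem,
                             birth = birth,
                             chrom_idx = match(f$chrom, chrom_names),
                             stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  junc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fork = integer(0), k = integer(0), cur0 = numeric(0),
               dirg = integer(0), bound = numeric(0), prem = numeric(0),
               birth = numeric(0), chrom_idx = integer(0))
  list(junc = junc)
}

## fragments + retained tracts for one cell, from final junction positions
assemble_cell <- function(forks, prim, jx, res, params, cell) {
  junc <- jx$junc
  frag_rows <- vector("list", nrow(forks))
  tract_rows <- vector("list", nrow(forks))
  for (fi in seq_len(nrow(forks))) {
    f <- forks[fi, ]
    n <- f$end - f$start
    if (n <= 0) next
    pr <- prim[[fi]]
    left <- f$direction == "L"
    sel <- which(junc$fork == fi)
    if (length(sel)) {
      q <- pr$q; la <- pr$la; m <- length(q)
      Jg <- res$final[sel]
      sJ <- if (left) f$origin - Jg else Jg - f$origin
      lig <- res$ligated[sel]
    } else { q <- numeric(0); la <- integer(0); m <- 0L
             sJ <- numeric(0); lig <- logical(0) }
    B <- c(0, sJ, n)
    lo_s <- B[-length(B)]; hi_s <- B[-1]
    ligated <- c(lig, FALSE)
    prem_rm <- c(if (m) sJ <= q - params$rna_primer_len, FALSE)
    gs <- if (left) f$origin - hi_s else f$origin + lo_s
    ge <- if (left) f$origin - lo_s else f$origin + hi_s
    keep <- hi_s > lo_s
    if (any(keep)) {
      frag_rows[[fi]] <- data.frame(
        chrom = f$chrom, start = gs[keep], end = ge[keep],
        name = paste0("frag_c", cell, "_f", fi, "_", which(keep)),
        score = 0, strand = if (left) "+" else "-",
        cell = cell, fork = fi, ligated = ligated[keep],
        primer_removed = prem_rm[keep], stringsAsFactors = FALSE)
    }
    if (m) {
      qprev <- c(0, q[-m])
      t_lo <- pmax(q - params$rna_primer_len - la, qprev)
      t_hi <- pmin(q - params$rna_primer_len, sJ)
      tk <- t_hi > t_lo
      if (any(tk)) {
        tgs <- if (left) f$origin - t_hi[tk] else f$origin + t_lo[tk]
        tge <- if (left) f$origin - t_lo[tk] else f$origin + t_hi[tk]
        tract_rows[[fi]] <- data.frame(
          chrom = f$chrom, start = tgs, end = tge,
          name = paste0("tract_c", cell, "_f", fi, "_", which(tk)),
          score = 0, strand = if (left) "+" else "-", cell = cell,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(fragments = do.call(rbind, frag_rows[!vapply(frag_rows, is.null, TRUE)]),
       tracts = do.call(rbind, tract_rows[!vapply(tract_rows, is.null, TRUE)]))
}

#' @export
print.ok_sim <- function(x, ...) {
  lib <- sum(!x$fragments$ligated & x$fragments$primer_removed)
  cat("<ok_sim> ", x$n_cells, " cells, ", nrow(x$forks), " forks, ",
      nrow(x$fragments), " fragments (", lib, " sequenceable), ",
      nrow(x$tracts), " retained Pol alpha tracts\n", sep = "")
  cat("  ligase depleted at ", x$params$t_depletion_start,
      " min, harvested at ", x$params$t_harvest, " min\n", sep = "")
  invisible(x)
}

#' Extract the sequenceable Okazaki-fragment library from a simulation
#'
#' The sequencing chemistry only captures ligation-competent lagging-strand
#' intermediates: fragments that are unligated and whose RNA primer has been
#' removed by nick translation (a 5' DNA phosphate is required for adaptor
#' ligation).
#'
#' @param sim an `ok_sim` from [simulate_okseq()].
#' @return An `ok_fragments` data frame (see [read_fragments()]).
#' @export
harvest_library <- function(sim) {
  fr <- sim$fragments
  fr <- fr[!fr$ligated & fr$primer_removed, , drop = FALSE]
  as_fragments(fr[, c("chrom", "start", "end", "name", "score", "strand",
                      "cell")])
}

#' Retained Pol alpha tract intervals from a simulation
#'
#' All fragments contribute (ligated ones too): this emulates
#' polymerase-usage (HydEN-seq-style) data, which reports Pol alpha-derived
#' DNA genome-wide regardless of ligation state.
#'
#' @param sim an `ok_sim`.
#' @return An `ok_fragments`-shaped data frame of tract intervals.
#' @export
polalpha_tracts <- function(sim) {
  as_fragments(sim$tracts[, c("chrom", "start", "end", "name", "score",
                              "strand", "cell")])
}

#' Write a simulated library (and optional tract sidecar) to disk
#'
#' Fragments as BED6 or BEDPE; retained Pol alpha tracts as BED6.  Output is
#' sorted and deterministic.
#'
#' @param fragments an `ok_fragments` data frame.
#' @param path output path.
#' @param format `"bed6"` or `"bedpe"`.  BEDPE rows emit the two 75-bp mate
#'   intervals delimiting the fragment, mate 1 at the 5' end on the fragment
#'   strand, so the outer-coordinate span reconstructs the fragment.
#' @param read_len mate length used for BEDPE emission.
#' @return Invisibly, `path`.
#' @export
write_library <- function(fragments, path, format = c("bed6", "bedpe"),
                          read_len = 75) {
  format <- match.arg(format)
  fr <- canonical_order(fragments)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(fr)) {
    if (format == "bed6") {
      lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", fr$chrom,
                       as.integer(fr$start), as.integer(fr$end), fr$name,
                       format_score(fr$score), fr$strand)
    } else {
      e1 <- pmin(fr$start + read_len, fr$end)
      s2 <- pmax(fr$end - read_len, fr$start)
      lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                       fr$chrom, as.integer(fr$start), as.integer(e1),
                       fr$chrom, as.integer(s2), as.integer(fr$end),
                       fr$name, format_score(fr$score), fr$strand,
                       ifelse(fr$strand == "+", "-", "+"))
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
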