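#' Parameters of the lagging-strand maturation simulator
#'
#' Bundles every rate, length and probability the simulator uses.  Defaults
#' describe budding-yeast lagging-strand synthesis: forks at 1.5 kb/min,
#' priming at the nucleosome repeat (165 bp), a 10-nt RNA primer extended by
#' DNA polymerase alpha with 10-35 DNA nucleotides, and nick translation by
#' Pol delta/Fen1 that displaces 1-2 nt per cycle.
#'
#' @param fork_speed replication fork speed, bp/min.
#' @param priming_spacing_mean,priming_spacing_sd Normal parameters (bp) of
#'   the spacing between successive priming sites; draws are truncated below
#'   at `rna_primer_len + pol_alpha_min + 1`.
#' @param rna_primer_len RNA primer length, nt.
#' @param pol_alpha_min,pol_alpha_max bounds (nt) of the discrete-uniform
#'   Pol alpha initiator-DNA tract laid down 3' of the RNA primer.
#' @param displace_min,displace_max nucleotides displaced (then cleaved) per
#'   successful nick-translation cycle.
#' @param p_continue per-cycle probability of performing another
#'   displacement/cleavage cycle in barrier-free DNA.
#' @param p_ligate probability that a paused, ligatable (primer-removed) nick
#'   is sealed per time tick while ligase is present.
#' @param nuc_kappa,tf_kappa dimensionless barrier strengths for nucleosomes
#'   and TF sites: the pass probability at position `x` is
#'   `exp(-kappa * score * w(x))` with `w` the barrier weight profile.
#' @param post_nt_rate nick-translation cycles per minute attempted at
#'   persistent (unligated) nicks.
#' @param t_release release time (minutes); time 0 of the simulation clock.
#' @param t_depletion_start time (minutes) at which nuclear ligase is
#'   depleted; ligation only happens before this time.
#' @param t_harvest harvest time (minutes) at which fragments are collected.
#' @param tick bookkeeping time step (minutes) for ligation and
#'   post-replicative nick translation; within-tick cycle counts are Poisson.
#' @param nt_after_primer logical; if `FALSE`, nick translation stops as soon
#'   as the RNA primer has been removed (used to isolate the contribution of
#'   tract removal to Pol alpha profiles).
#' @param seed default root seed for simulations using these parameters.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(fork_speed = 1500,
                       priming_spacing_mean = 165, priming_spacing_sd = 40,
                       rna_primer_len = 10,
                       pol_alpha_min = 10, pol_alpha_max = 35,
                       displace_min = 1, displace_max = 2,
                       p_continue = 0.95, p_ligate = 0.5,
                       nuc_kappa = 1.2, tf_kappa = 4.0,
                       post_nt_rate = 6, t_release = 0,
                       t_depletion_start = 0, t_harvest = 60,
                       tick = 0.5, nt_after_primer = TRUE, seed = 1) {
  p <- list(fork_speed = fork_speed,
            priming_spacing_mean = priming_spacing_mean,
            priming_spacing_sd = priming_spacing_sd,
            rna_primer_len = rna_primer_len,
            pol_alpha_min = pol_alpha_min, pol_alpha_max = pol_alpha_max,
            displace_min = displace_min, displace_max = displace_max,
            p_continue = p_continue, p_ligate = p_ligate,
            nuc_kappa = nuc_kappa, tf_kappa = tf_kappa,
            post_nt_rate = post_nt_rate, t_release = t_release,
            t_depletion_start = t_depletion_start, t_harvest = t_harvest,
            tick = tick, nt_after_primer = isTRUE(nt_after_primer),
            seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  num <- p[setdiff(names(p), c("nt_after_primer", "seed"))]
  if (any(!vapply(num, is.numeric, TRUE)) || any(vapply(num, length, 1L) != 1L))
    stop("simulation parameters must be numeric scalars")
  if (p$p_continue < 0 || p$p_continue > 1) stop("p_continue must be in [0, 1]")
  if (p$p_ligate < 0 || p$p_ligate > 1) stop("p_ligate must be in [0, 1]")
  if (p$pol_alpha_min > p$pol_alpha_max) stop("pol_alpha_min > pol_alpha_max")
  if (p$displace_min > p$displace_max) stop("displace_min > displace_max")
  if (p$displace_min < 1) stop("displace_min must be >= 1")
  lens <- c("fork_speed", "priming_spacing_mean", "priming_spacing_sd",
            "rna_primer_len", "pol_alpha_min", "nuc_kappa", "tf_kappa",
            "post_nt_rate")
  if (any(unlist(p[lens]) < 0)) stop("lengths, rates and strengths must be >= 0")
  if (p$fork_speed <= 0) stop("fork_speed must be > 0")
  if (p$tick <= 0) stop("tick must be > 0")
  if (!(p$t_release <= p$t_depletion_start || p$t_depletion_start == 0) ||
      p$t_harvest < p$t_depletion_start || p$t_harvest < p$t_release)
    stop("times must satisfy t_release <= t_depletion_start <= t_harvest")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read or write simulator parameters as a flat key-value config file
#'
#' One `key = value` assignment per line (a flat TOML dialect); `#` starts a
#' comment.  Keys mirror [sim_params()] argument names exactly and values
#' round-trip bit-exactly through the R formatting used by
#' [write_sim_config()].
#'
#' @param path config file path.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad))
    stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  unknown <- setdiff(keys, names(formals(sim_params)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  parse1 <- function(v) {
    if (v %in% c("true", "false", "TRUE", "FALSE")) return(tolower(v) == "true")
    suppressWarnings(n <- as.numeric(v))
    if (is.na(n)) stop("non-numeric config value: ", v)
    n
  }
  do.call(sim_params, stats::setNames(lapply(vals, parse1), keys))
}

#' @rdname read_sim_config
#' @param params a `sim_params` object.
#' @export
write_sim_config <- function(params, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    format(v, digits = 17, scientific = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s = %s", names(params),
                     vapply(unclass(params), fmt, "")), con, sep = "\n")
  invisible(path)
}

## per-cell RNG substream: a counter-derived seed so earlier cells are stable
## when n_cells changes.
cell_seed <- function(seed, cell) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(cell) * 1000003) %% 2147483629)
}
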