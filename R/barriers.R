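#' Per-base barrier penalty profile
#'
#' Builds, for every chromosome, the penalty `c(x)` entering the per-cycle
#' pass probability of nick translation, `p_pass(x) = exp(-c(x))`.
#'
#' Nucleosomes contribute a triangular weight ramp: 0 at either footprint
#' edge rising linearly to 1 at the dyad, scaled by `nuc_kappa * score`.
#' This makes the obstacle progressively harder toward the dyad, so nicks
#' accumulate upstream of the dyad after few cycles and migrate toward it as
#' cycles accrue.  TF sites contribute a constant weight of 1 across their
#' footprint, scaled by `tf_kappa * score`.  Overlapping contributions add.
#'
#' @param genome an `ok_genome`.
#' @param nucleosomes,tf_sites optional `ok_features` sets; `score` holds the
#'   per-feature barrier strength multiplier.
#' @param params a [sim_params()] object supplying `nuc_kappa` and `tf_kappa`.
#' @return A list of per-chromosome numeric penalty vectors (class
#'   `barrier_penalty`), each of length equal to the chromosome.
#' @export
barrier_penalty <- function(genome, nucleosomes = NULL, tf_sites = NULL,
                            params = sim_params()) {
  pen <- lapply(as.numeric(genome), numeric)
  names(pen) <- names(genome)
  add_tri <- function(pen, feats, kappa) {
    if (is.null(feats) || !nrow(feats) || kappa == 0) return(pen)
    for (i in seq_len(nrow(feats))) {
      s <- feats$start[i]; e <- feats$end[i]
      m <- floor((s + e - 1) / 2)
      x <- s:(e - 1)
      half <- pmax(ifelse(x <= m, m - s, e - 1 - m), 1)
      w <- 1 - abs(x - m) / half
      pen[[feats$chrom[i]]][x + 1] <- pen[[feats$chrom[i]]][x + 1] +
        kappa * feats$score[i] * w
    }
    pen
  }
  add_flat <- function(pen, feats, kappa) {
    if (is.null(feats) || !nrow(feats) || kappa == 0) return(pen)
    for (i in seq_len(nrow(feats))) {
      idx <- (feats$start[i] + 1):feats$end[i]
      pen[[feats$chrom[i]]][idx] <- pen[[feats$chrom[i]]][idx] +
        kappa * feats$score[i]
    }
    pen
  }
  pen <- add_tri(pen, nucleosomes, params$nuc_kappa)
  pen <- add_flat(pen, tf_sites, params$tf_kappa)
  structure(pen, class = "barrier_penalty")
}
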