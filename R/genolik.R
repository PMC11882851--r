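# Forced genotyping: genotype likelihoods at every panel position, and hard
# calls for high-coverage data.
#
# The model is a symmetric single-parameter binomial error model: a read from
# a genotype-g individual shows the alternate allele with probability
# (g/2)(1-e) + (1-g/2)e. Per-site likelihoods are products over reads and are
# stored normalized to sum 1; the downstream HMM uses them as emission
# factors, which is invariant to per-site scaling.

#' Compute per-site genotype likelihoods from pileups
#'
#' Likelihoods are computed at every forced position, including zero-depth
#' sites, which get the uninformative triple (1/3, 1/3, 1/3).
#'
#' @param pileups a `pileup_set`.
#' @param error_rate per-read allele flip probability in `[0, 0.5)`.
#' @return an object of class `genotype_likelihoods` with `lik` (L x 3 matrix,
#'   rows summing to 1) and `depth` (integer vector).
#' @export
genotype_likelihoods <- function(pileups, error_rate = 0.005) {
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  }
  L <- pileups$n_sites
  depth <- tabulate(pileups$site, nbins = L)
  n_alt <- tabulate(pileups$site[pileups$allele == 1L], nbins = L)
  n_ref <- depth - n_alt
  p_alt <- c(error_rate, 0.5, 1 - error_rate)  # P(read = alt | g = 0, 1, 2)

  # log-likelihoods, guarding 0 * log(0) at error_rate = 0
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll <- vapply(p_alt, function(p) xlogy(n_alt, p) + xlogy(n_ref, 1 - p),
               numeric(L))
  ll <- matrix(ll, nrow = L, ncol = 3L)
  ll <- ll - apply(ll, 1L, max)
  lik <- exp(ll)
  lik <- lik / rowSums(lik)
  lik[depth == 0L, ] <- 1 / 3
  colnames(lik) <- c("L0", "L1", "L2")
  out <- list(lik = lik, depth = as.integer(depth))
  class(out) <- "genotype_likelihoods"
  out
}

#' Hard-call genotypes from likelihoods
#'
#' Per site, the maximum-likelihood genotype; sites with depth below
#' `min_depth` or an uninformative (uniform) triple are reported missing.
#' Intended for the high-coverage (15-30x) arm processed without imputation.
#'
#' @param lik a `genotype_likelihoods` object.
#' @param min_depth minimum read depth for a call (default 4).
#' @return integer vector in `{0, 1, 2}` with `NA` for missing sites.
#' @export
call_genotypes <- function(lik, min_depth = 4L) {
  g <- max.col(lik$lik, ties.method = "first") - 1L
  spread <- apply(lik$lik, 1L, function(r) max(r) - min(r))
  g[lik$depth < min_depth | spread < 1e-9] <- NA_integer_
  g
}
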