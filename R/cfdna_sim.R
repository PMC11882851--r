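# cfDNA pileup simulation: maternal/fetal read mixtures with origin-specific
# fragment-length distributions, plus length filtering and down-sampling.
#
# Pileups are per-site read lists; reads are independent across sites because
# at ~0.25x coverage with panel sites kilobases apart, a fragment essentially
# never spans two panel sites.

#' Mixture configuration for cfDNA pileup simulation
#'
#' @param coverage mean reads per site (Poisson).
#' @param fetal_fraction proportion of reads of fetal origin, in `[0, 1]`.
#' @param error_rate per-read allele flip probability, in `[0, 0.5)`.
#' @param maternal_length_mean fragment-length mode for maternal reads (bp).
#' @param fetal_length_mean fragment-length mode for fetal reads (bp);
#'   placentally derived cfDNA runs shorter than maternal cfDNA.
#' @param length_sd fragment-length standard deviation (bp).
#' @param length_bounds truncation interval for fragment lengths (bp).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return an object of class `mixture_config`.
#' @export
mixture_config <- function(coverage = 0.25,
                           fetal_fraction = 0,
                           error_rate = 0.005,
                           maternal_length_mean = 166,
                           fetal_length_mean = 143,
                           length_sd = 15,
                           length_bounds = c(50, 400),
                           seed = NULL) {
  mix <- list(coverage = coverage, fetal_fraction = fetal_fraction,
              error_rate = error_rate,
              maternal_length_mean = maternal_length_mean,
              fetal_length_mean = fetal_length_mean,
              length_sd = length_sd, length_bounds = length_bounds,
              seed = seed)
  class(mix) <- "mixture_config"
  validate_mixture_config(mix)
  mix
}

validate_mixture_config <- function(mix) {
  if (mix$coverage < 0) stop("coverage must be >= 0", call. = FALSE)
  if (mix$fetal_fraction < 0 || mix$fetal_fraction > 1) {
    stop("fetal_fraction must be in [0, 1]", call. = FALSE)
  }
  if (mix$error_rate < 0 || mix$error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  }
  b <- mix$length_bounds
  if (length(b) != 2L || any(b <= 0) || b[1] >= b[2]) {
    stop("length_bounds must be a positive interval (min < max)", call. = FALSE)
  }
  invisible(mix)
}

new_pileup_set <- function(site, allele, length, origin, n_sites) {
  p <- list(site = as.integer(site), allele = as.integer(allele),
            length = as.numeric(length), origin = as.integer(origin),
            n_sites = as.integer(n_sites))
  class(p) <- "pileup_set"
  p
}

#' @export
print.pileup_set <- function(x, ...) {
  cat(sprintf(
    "pileup_set: %d reads over %d sites (mean depth %.3f, fetal %.1f%%)\n",
    length(x$site), x$n_sites, length(x$site) / x$n_sites,
    100 * mean(x$origin == 1L)))
  invisible(x)
}

#' Simulate cfDNA pileups for a mother-fetus pair
#'
#' Per-site read counts are Poisson(`coverage`); each read is fetal with
#' probability `fetal_fraction`, otherwise maternal; its template allele is
#' drawn uniformly from the two haplotypes of the read's origin individual,
#' flipped with probability `error_rate`; fragment length is drawn from the
#' origin-specific truncated normal. The `origin` field is simulation truth
#' and must never be consumed by inference.
#'
#' @param pair a [sample_mother_fetus()] pair.
#' @param mix a [mixture_config()].
#' @param seed optional seed (default `mix$seed`).
#' @return a `pileup_set`.
#' @export
simulate_pileups <- function(pair, mix, seed = mix$seed) {
  validate_mixture_config(mix)
  L <- ncol(pair$mother_haps)
  with_seed(seed, {
    depth <- stats::rpois(L, mix$coverage)
    n <- sum(depth)
    if (n == 0L) return(new_pileup_set(integer(0), integer(0), numeric(0),
                                       integer(0), L))
    site <- rep.int(seq_len(L), depth)
    origin <- as.integer(stats::runif(n) < mix$fetal_fraction)
    hap <- sample.int(2L, n, replace = TRUE)
    allele <- integer(n)
    is_fet <- origin == 1L
    if (any(!is_fet)) {
      idx <- which(!is_fet)
      allele[idx] <- pair$mother_haps[cbind(hap[idx], site[idx])]
    }
    if (any(is_fet)) {
      idx <- which(is_fet)
      allele[idx] <- pair$fetus_haps[cbind(hap[idx], site[idx])]
    }
    flip <- stats::runif(n) < mix$error_rate
    allele[flip] <- 1L - allele[flip]
    len <- numeric(n)
    len[!is_fet] <- rtrunc_norm(sum(!is_fet), mix$maternal_length_mean,
                                mix$length_sd, mix$length_bounds[1],
                                mix$length_bounds[2])
    len[is_fet] <- rtrunc_norm(sum(is_fet), mix$fetal_length_mean,
                               mix$length_sd, mix$length_bounds[1],
                               mix$length_bounds[2])
    new_pileup_set(site, allele, len, origin, L)
  })
}

#' Filter pileup reads by minimum fragment length
#'
#' In-silico removal of short fragments, intended to deplete fetal reads
#' (which run ~23 bp shorter than maternal reads) before imputation. The site
#' list is unchanged; sites may become empty.
#'
#' @param pileups a `pileup_set`.
#' @param min_length keep reads with `fragment length >= min_length` (bp).
#' @return the filtered `pileup_set`.
#' @export
filter_by_length <- function(pileups, min_length) {
  stopifnot_scalar(min_length, "min_length")
  if (min_length < 0) stop("min_length must be >= 0", call. = FALSE)
  keep <- pileups$length >= min_length
  new_pileup_set(pileups$site[keep], pileups$allele[keep],
                 pileups$length[keep], pileups$origin[keep], pileups$n_sites)
}

#' Randomly down-sample pileup reads
#'
#' Each read is retained independently with probability `keep_fraction`,
#' emulating FASTQ down-sampling to a lower coverage.
#'
#' @param pileups a `pileup_set`.
#' @param keep_fraction retention probability in `[0, 1]`.
#' @param seed optional seed.
#' @return the down-sampled `pileup_set`.
#' @export
downsample_pileups <- function(pileups, keep_fraction, seed = NULL) {
  stopifnot_scalar(keep_fraction, "keep_fraction")
  if (keep_fraction < 0 || keep_fraction > 1) {
    stop("keep_fraction must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    keep <- stats::runif(length(pileups$site)) < keep_fraction
    new_pileup_set(pileups$site[keep], pileups$allele[keep],
                   pileups$length[keep], pileups$origin[keep],
                   pileups$n_sites)
  })
}

#' Write pileups to a tab-separated file
#'
#' @param pileups a `pileup_set`.
#' @param path output file.
#' @param include_origin include the simulation-truth origin column. Files
#'   destined for inference stages must omit it (the default).
#' @return invisibly `path`.
#' @export
write_pileups <- function(pileups, path, include_origin = FALSE) {
  df <- data.frame(site = pileups$site, allele = pileups$allele,
                   length = round(pileups$length, 1))
  if (include_origin) {
    df$origin <- c("maternal", "fetal")[pileups$origin + 1L]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pileups from a tab-separated file
#'
#' @param path file written by [write_pileups()].
#' @param n_sites number of forced sites (needed because trailing sites may
#'   have no reads).
#' @return a `pileup_set`; origin is `NA`-coded (0) when the file has no
#'   origin column.
#' @export
read_pileups <- function(path, n_sites) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  origin <- if ("origin" %in% names(df)) {
    as.integer(df$origin == "fetal")
  } else {
    rep(NA_integer_, nrow(df))
  }
  new_pileup_set(df$site, df$allele, df$length, origin, n_sites)
}
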