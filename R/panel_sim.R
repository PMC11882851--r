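# Reference haplotype panel and mother-fetus pair simulation.
#
# Haplotypes are built by a copying-mosaic process: after a set of i.i.d.
# founders, each new haplotype copies segments from previously generated
# haplotypes, switching template at a Poisson rate per centimorgan and
# miscopying alleles at a small per-site rate. This produces linkage
# disequilibrium that decays with genetic distance, which is all the
# downstream haplotype-copying imputation model needs to be learnable.

#' Simulation configuration for the haplotype panel
#'
#' @param n_panel_haplotypes number of phased haplotypes in the reference
#'   panel (must be >= 4).
#' @param n_sites number of candidate biallelic sites placed uniformly on the
#'   single pseudo-chromosome; sites failing `maf_floor` after simulation are
#'   dropped.
#' @param n_founders number of independent founder haplotypes seeding the
#'   copying-mosaic process.
#' @param region_length_bp length of the pseudo-chromosome in base pairs.
#' @param mosaic_switch_rate template switches per centimorgan for panel
#'   haplotypes.
#' @param mutation_rate per-site allele miscopy probability for panel
#'   haplotypes.
#' @param maf_floor minimum panel minor-allele frequency for a site to be
#'   retained.
#' @param map_cm_per_mb uniform genetic-map rate (centimorgans per megabase).
#' @param mother_switch_rate template switches per centimorgan used when a
#'   mother (or a paternal haplotype) is drawn as a mosaic of the panel.
#'   The default of one switch per 2 cM keeps study subjects closely related
#'   to the panel, so that imputation from high-coverage data is near perfect.
#' @param mother_mutation_rate per-site miscopy probability for subject
#'   haplotypes; kept very small for the same reason.
#' @param seed integer seed giving deterministic output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_panel_haplotypes = 200L,
                       n_sites = 5000L,
                       n_founders = 10L,
                       region_length_bp = 2e7,
                       mosaic_switch_rate = 1.0,
                       mutation_rate = 0.002,
                       maf_floor = 0.01,
                       map_cm_per_mb = 1.0,
                       mother_switch_rate = 0.5,
                       mother_mutation_rate = 1e-4,
                       seed = 1L) {
  cfg <- list(
    n_panel_haplotypes = as.integer(n_panel_haplotypes),
    n_sites = as.integer(n_sites),
    n_founders = as.integer(n_founders),
    region_length_bp = as.numeric(region_length_bp),
    mosaic_switch_rate = as.numeric(mosaic_switch_rate),
    mutation_rate = as.numeric(mutation_rate),
    maf_floor = as.numeric(maf_floor),
    map_cm_per_mb = as.numeric(map_cm_per_mb),
    mother_switch_rate = as.numeric(mother_switch_rate),
    mother_mutation_rate = as.numeric(mother_mutation_rate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_panel_haplotypes < 4L) {
    stop("n_panel_haplotypes must be >= 4", call. = FALSE)
  }
  if (cfg$n_founders < 2L || cfg$n_founders > cfg$n_panel_haplotypes) {
    stop("n_founders must be in [2, n_panel_haplotypes]", call. = FALSE)
  }
  rates <- c(cfg$mosaic_switch_rate, cfg$mutation_rate, cfg$maf_floor,
             cfg$map_cm_per_mb, cfg$mother_switch_rate,
             cfg$mother_mutation_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  if (cfg$mutation_rate >= 0.5 || cfg$mother_mutation_rate >= 0.5) {
    stop("miscopy rates must be < 0.5", call. = FALSE)
  }
  if (cfg$n_sites < 2L) stop("n_sites must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Fields mirror [sim_config()]; missing fields take the defaults.
#'
#' @param path file path to a YAML (or JSON, which YAML subsumes) mapping.
#' @return a `sim_config` object.
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}

# Copy one mosaic haplotype from the rows of `source` (matrix n_src x L).
# Template switches occur between adjacent sites with probability
# 1 - exp(-switch_rate * dcm); each copied allele flips with prob mut_rate.
mosaic_copy <- function(source, cm, switch_rate, mut_rate) {
  n_src <- nrow(source)
  L <- ncol(source)
  if (n_src == 1L) {
    seg_id <- rep(1L, L)
    templates <- 1L
  } else if (L == 1L) {
    seg_id <- 1L
    templates <- sample.int(n_src, 1L)
  } else {
    p_switch <- 1 - exp(-switch_rate * diff(cm))
    switches <- stats::runif(L - 1L) < p_switch
    seg_id <- cumsum(c(1L, as.integer(switches)))
    templates <- sample.int(n_src, seg_id[L], replace = TRUE)
  }
  hap <- source[cbind(templates[seg_id], seq_len(L))]
  if (mut_rate > 0) {
    flip <- stats::runif(L) < mut_rate
    hap[flip] <- 1L - hap[flip]
  }
  as.integer(hap)
}

#' Generate a reference haplotype panel
#'
#' Builds `n_panel_haplotypes` phased haplotypes over candidate sites placed
#' uniformly at random on a single pseudo-chromosome, using the copying-mosaic
#' process, then drops sites whose panel minor-allele frequency falls below
#' `maf_floor`.
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed overriding `config$seed`.
#' @return an object of class `haplotype_panel` with elements `haplotypes`
#'   (K x L 0/1 matrix), `positions` (1-based bp), `cm_positions`,
#'   `allele_freq`, `ref`, `alt`, `chrom`, `ids`.
#' @export
generate_panel <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    L <- config$n_sites
    K <- config$n_panel_haplotypes
    positions <- sort(sample.int(config$region_length_bp, L))
    cm <- positions * config$map_cm_per_mb / 1e6

    # founders: independent Bernoulli draws around a per-site base frequency
    base_freq <- stats::runif(L, 0.05, 0.95)
    H <- matrix(0L, nrow = K, ncol = L)
    for (h in seq_len(config$n_founders)) {
      H[h, ] <- as.integer(stats::runif(L) < base_freq)
    }
    for (h in seq.int(config$n_founders + 1L, K)) {
      H[h, ] <- mosaic_copy(H[seq_len(h - 1L), , drop = FALSE], cm,
                            config$mosaic_switch_rate, config$mutation_rate)
    }

    af <- colMeans(H)
    keep <- pmin(af, 1 - af) >= config$maf_floor
    if (sum(keep) < 2L) {
      stop("fewer than 2 sites passed the MAF floor filter (maf_floor = ",
           config$maf_floor, ")", call. = FALSE)
    }
    H <- H[, keep, drop = FALSE]
    positions <- positions[keep]
    cm <- cm[keep]
    af <- af[keep]
    L <- length(positions)

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    panel <- list(
      haplotypes = H,
      positions = positions,
      cm_positions = cm,
      allele_freq = af,
      ref = ref,
      alt = unname(alt),
      chrom = "1",
      ids = sprintf("snp%05d", seq_len(L)),
      config = config
    )
    class(panel) <- "haplotype_panel"
    panel
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes x %d sites, %.1f cM, mean MAF %.3f\n",
    nrow(x$haplotypes), ncol(x$haplotypes),
    diff(range(x$cm_positions)), mean(pmin(x$allele_freq, 1 - x$allele_freq))))
  invisible(x)
}

n_panel_sites <- function(panel) length(panel$positions)

#' Validate the invariants of a haplotype panel
#'
#' Checks the 0/1 allele coding, strictly increasing positions, non-decreasing
#' genetic map, the allele-frequency field against the haplotype matrix, and
#' the MAF floor. Called by tests and by the VCF reader.
#'
#' @param panel a `haplotype_panel`.
#' @param maf_floor floor to check against (default from the panel's config,
#'   0 if absent).
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_panel <- function(panel,
                           maf_floor = if (!is.null(panel$config))
                             panel$config$maf_floor else 0) {
  H <- panel$haplotypes
  if (!all(H %in% c(0L, 1L))) stop("haplotype entries must be 0/1")
  if (any(diff(panel$positions) <= 0)) stop("positions must strictly increase")
  if (any(diff(panel$cm_positions) < 0)) stop("cm_positions must be non-decreasing")
  if (max(abs(panel$allele_freq - colMeans(H))) > 1e-12) {
    stop("allele_freq does not match haplotype matrix column means")
  }
  if (any(pmin(panel$allele_freq, 1 - panel$allele_freq) < maf_floor - 1e-12)) {
    stop("a retained site violates the MAF floor")
  }
  invisible(TRUE)
}

# Recombine the mother's two haplotypes into one transmitted gamete.
# Crossover count is Poisson in the genetic map length (in Morgans).
recombine_haplotypes <- function(hap_a, hap_b, cm) {
  L <- length(hap_a)
  total_cm <- max(cm) - min(cm)
  n_cross <- stats::rpois(1L, total_cm / 100)
  start <- sample.int(2L, 1L)
  if (n_cross == 0L) {
    hap <- if (start == 1L) hap_a else hap_b
    return(list(hap = as.integer(hap), n_crossovers = 0L))
  }
  breaks <- sort(stats::runif(n_cross, min(cm), max(cm)))
  phase <- (start - 1L + findInterval(cm, breaks)) %% 2L  # 0 -> hap_a
  hap <- ifelse(phase == 0L, hap_a, hap_b)
  list(hap = as.integer(hap), n_crossovers = n_cross)
}

#' Draw a mother-fetus genotype pair related to the panel
#'
#' The mother's two haplotypes are low-switch-rate mosaics of the panel (so
#' she is related to, but not present in, the panel). The fetus carries one
#' recombinant of the mother's haplotypes (crossovers Poisson in the map
#' length) plus an independent panel-mosaic paternal haplotype.
#'
#' @param panel a `haplotype_panel`.
#' @param config the [sim_config()] providing mother mosaic rates.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return an object of class `mother_fetus_pair` with `mother_haps` and
#'   `fetus_haps` (2 x L matrices; fetus row 1 is the transmitted maternal
#'   haplotype, row 2 paternal), `mother_genotype`, `fetus_genotype`,
#'   `n_crossovers`.
#' @export
sample_mother_fetus <- function(panel, config = panel$config, seed = NULL) {
  if (n_panel_sites(panel) < 1L) stop("panel is empty", call. = FALSE)
  with_seed(seed, {
    cm <- panel$cm_positions
    H <- panel$haplotypes
    ma <- mosaic_copy(H, cm, config$mother_switch_rate,
                      config$mother_mutation_rate)
    mb <- mosaic_copy(H, cm, config$mother_switch_rate,
                      config$mother_mutation_rate)
    rec <- recombine_haplotypes(ma, mb, cm)
    pat <- mosaic_copy(H, cm, config$mother_switch_rate,
                       config$mother_mutation_rate)
    pair <- list(
      mother_haps = rbind(a = ma, b = mb),
      fetus_haps = rbind(transmitted = rec$hap, paternal = pat),
      mother_genotype = ma + mb,
      fetus_genotype = rec$hap + pat,
      n_crossovers = rec$n_crossovers
    )
    class(pair) <- "mother_fetus_pair"
    pair
  })
}

#' @export
print.mother_fetus_pair <- function(x, ...) {
  cat(sprintf(
    "mother_fetus_pair: %d sites, %d crossover(s) in transmitted haplotype\n",
    ncol(x$mother_haps), x$n_crossovers))
  invisible(x)
}

#' Validate Mendelian consistency of a mother-fetus pair
#'
#' @param pair a `mother_fetus_pair`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_pair <- function(pair) {
  if (!identical(as.integer(pair$mother_genotype),
                 as.integer(pair$mother_haps[1, ] + pair$mother_haps[2, ]))) {
    stop("mother genotype is not the sum of her haplotypes")
  }
  if (!identical(as.integer(pair$fetus_genotype),
                 as.integer(pair$fetus_haps[1, ] + pair$fetus_haps[2, ]))) {
    stop("fetus genotype is not the sum of its haplotypes")
  }
  tr <- pair$fetus_haps[1, ]
  ok <- tr == pair$mother_haps[1, ] | tr == pair$mother_haps[2, ]
  if (!all(ok)) stop("transmitted haplotype violates Mendelian consistency")
  invisible(TRUE)
}

#' Mean pairwise linkage disequilibrium (r-squared) by genetic distance
#'
#' Diagnostic used to confirm that simulated panels show LD decaying with
#' genetic distance. Samples site pairs and averages squared allele
#' correlation within the two distance classes.
#'
#' @param panel a `haplotype_panel`.
#' @param near_cm pairs closer than this count as "near".
#' @param far_cm pairs farther than this count as "far".
#' @param max_pairs pair sample size per class.
#' @param seed optional seed for pair sampling.
#' @return list with `r2_near` and `r2_far`.
#' @export
ld_decay_summary <- function(panel, near_cm = 0.1, far_cm = 5,
                             max_pairs = 2000L, seed = NULL) {
  with_seed(seed, {
    cm <- panel$cm_positions
    L <- length(cm)
    i <- sample.int(L, max_pairs * 4L, replace = TRUE)
    j <- sample.int(L, max_pairs * 4L, replace = TRUE)
    d <- abs(cm[i] - cm[j])
    ok <- i != j
    r2_of <- function(sel) {
      sel <- which(sel & ok)
      if (length(sel) > max_pairs) sel <- sel[seq_len(max_pairs)]
      vals <- vapply(sel, function(k) {
        a <- panel$haplotypes[, i[k]]
        b <- panel$haplotypes[, j[k]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
        stats::cor(a, b)^2
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }
    list(r2_near = r2_of(d < near_cm), r2_far = r2_of(d > far_cm))
  })
}
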