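# End-to-end studies: coverage down-sampling, maternal/fetal mixtures, and a
# prospective-cohort analog, with the evaluation statistics (Pearson
# correlation between PRS arms, fetal-fraction and panel-size stratification,
# and high-risk percentile misclassification).

#' Pearson correlation between two score vectors
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return sample Pearson correlation, `NA` when either vector has zero
#'   variance.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired scores", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Flag the ceil(q*n) highest-scoring samples; ties broken by stable sample
# order so the flagged count is exact.
flag_high_risk <- function(scores, q) {
  n <- length(scores)
  k <- ceiling(q * n)
  flagged <- logical(n)
  flagged[order(-scores, seq_len(n))[seq_len(k)]] <- TRUE
  flagged
}

#' High-risk misclassification rate between two PRS vectors
#'
#' Each vector independently flags its top `q` fraction of samples
#' (rank-based, `ceiling(q * n)` flags, ties broken by stable sample order)
#' as high genetic risk; the rate is the fraction of samples whose high-risk
#' label differs between the two vectors.
#'
#' @param ref_scores,alt_scores equal-length score vectors over the same
#'   samples.
#' @param q top-percentile cutoff in `(0, 0.5)` (default 0.05, the proposed
#'   high-risk cutoff of 5% of the population).
#' @return misclassification rate in `[0, 1]`.
#' @export
misclassification_rate <- function(ref_scores, alt_scores, q = 0.05) {
  if (length(ref_scores) != length(alt_scores)) {
    stop("score vectors differ in length", call. = FALSE)
  }
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)", call. = FALSE)
  n <- length(ref_scores)
  if (n * q < 1) stop("n * q < 1: cohort too small for cutoff q", call. = FALSE)
  mean(flag_high_risk(ref_scores, q) != flag_high_risk(alt_scores, q))
}

# One sample's low-coverage arm: pileups -> likelihoods -> imputation.
impute_arm_dosage <- function(pileups, panel, error_rate, params) {
  lik <- genotype_likelihoods(pileups, error_rate = error_rate)
  impute_dosages(lik, panel, params)$dosage
}

# One sample's high-coverage arm: pileups -> likelihoods -> hard calls
# (non-imputed), NA where missing.
hard_call_arm_dosage <- function(pileups, error_rate, min_depth = 4L) {
  lik <- genotype_likelihoods(pileups, error_rate = error_rate)
  as.numeric(call_genotypes(lik, min_depth = min_depth))
}

new_report <- function(type, seed, config, ...) {
  rep <- c(list(type = type, master_seed = seed, config = config), list(...))
  class(rep) <- "experiment_report"
  rep
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report (%s), master seed %d\n", x$type,
              x$master_seed))
  if (!is.null(x$correlations)) {
    print(x$correlations, row.names = FALSE)
  }
  if (!is.null(x$misclassification)) {
    cat(sprintf("mean misclassification at q = %.2f: %.4f\n",
                x$config$q, mean(x$misclassification$rate)))
  }
  invisible(x)
}

#' Coverage down-sampling experiment
#'
#' Simulates pure-maternal (fetal fraction 0) pileups for `n_subjects`
#' subjects at two low coverages (imputed) and one high coverage
#' (hard-called, non-imputed), computes PRS per arm, and reports the three
#' pairwise Pearson correlations pooled over `n_cohorts` replicate cohorts.
#'
#' @param panel optional pre-built `haplotype_panel`; generated from
#'   `config` when `NULL`.
#' @param scoring optional `scoring_panel`; default a synthetic 2,000-marker
#'   panel drawn from the sites.
#' @param n_subjects subjects per cohort (default 10).
#' @param n_cohorts replicate cohorts (default 20).
#' @param low_coverages the two imputed arms (default 0.2x and 1.0x).
#' @param high_coverage the hard-called reference arm (default 30x).
#' @param error_rate sequencing error rate.
#' @param params [hmm_params()] for imputation.
#' @param config [sim_config()] used when `panel` is `NULL`.
#' @param seed master seed; every stage seed derives from it.
#' @return an `experiment_report` with `scores` (long data.frame) and
#'   `correlations`.
#' @export
run_coverage_experiment <- function(panel = NULL, scoring = NULL,
                                    n_subjects = 10L, n_cohorts = 20L,
                                    low_coverages = c(0.2, 1.0),
                                    high_coverage = 30,
                                    error_rate = 0.005,
                                    params = hmm_params(),
                                    config = sim_config(),
                                    seed = 1L) {
  if (is.null(panel)) panel <- generate_panel(config, seed = derive_seed(seed, 1L))
  if (is.null(scoring)) {
    scoring <- make_scoring_panel(panel, min(2000L, n_panel_sites(panel)),
                                  seed = derive_seed(seed, 2L))
  }
  match <- match_markers(scoring, panel_sites(panel))
  arms <- make.unique(c(sprintf("imputed_%gx", low_coverages),
                        sprintf("hardcall_%gx", high_coverage)))
  rows <- vector("list", n_cohorts * n_subjects)
  k <- 0L
  for (co in seq_len(n_cohorts)) {
    for (su in seq_len(n_subjects)) {
      salt <- co * 1000L + su
      pair <- sample_mother_fetus(panel, config,
                                  seed = derive_seed(seed, salt))
      scores <- numeric(length(arms))
      for (a in seq_along(low_coverages)) {
        mix <- mixture_config(coverage = low_coverages[a], fetal_fraction = 0,
                              error_rate = error_rate)
        pu <- simulate_pileups(pair, mix, seed = derive_seed(seed, salt + a * 101L))
        d <- impute_arm_dosage(pu, panel, error_rate, params)
        scores[a] <- compute_prs(d, match)$score
      }
      mix_hi <- mixture_config(coverage = high_coverage, fetal_fraction = 0,
                               error_rate = error_rate)
      pu <- simulate_pileups(pair, mix_hi, seed = derive_seed(seed, salt + 997L))
      d <- hard_call_arm_dosage(pu, error_rate)
      scores[length(arms)] <- compute_prs(d, match)$score
      k <- k + 1L
      rows[[k]] <- data.frame(cohort = co, subject = su,
                              arm = arms, score = scores)
    }
  }
  scores_df <- do.call(rbind, rows)
  wide <- stats::reshape(scores_df, idvar = c("cohort", "subject"),
                         timevar = "arm", direction = "wide")
  cor_of <- function(a, b) pearson_cor(wide[[paste0("score.", a)]],
                                       wide[[paste0("score.", b)]])
  correlations <- data.frame(
    comparison = c(paste(arms[2], "vs", arms[3]),
                   paste(arms[1], "vs", arms[3]),
                   paste(arms[1], "vs", arms[2])),
    pearson = c(cor_of(arms[2], arms[3]), cor_of(arms[1], arms[3]),
                cor_of(arms[1], arms[2])))
  new_report("coverage", seed,
             list(n_subjects = n_subjects, n_cohorts = n_cohorts,
                  low_coverages = low_coverages,
                  high_coverage = high_coverage, error_rate = error_rate,
                  scoring_id = scoring$id),
             scores = scores_df, correlations = correlations)
}

#' Maternal/fetal mixture experiment
#'
#' Simulates 0.25x cfDNA pileups for a cohort of mother-fetus pairs at each
#' fetal fraction, with `n_replicates` independent pileup replicates per
#' condition; imputes and scores every replicate; and reports the Pearson
#' (and Spearman) correlation of each fetal-fraction arm's per-sample mean
#' PRS against the fetal-fraction-0 arm, plus bias/variability of per-sample
#' PRS deviations.
#'
#' @inheritParams run_coverage_experiment
#' @param n_pairs mother-fetus pairs in the cohort (default 40).
#' @param fetal_fractions conditions (default 0, 0.05, 0.10, 0.15).
#' @param n_replicates pileup replicates per pair per condition (default 7).
#' @param coverage cfDNA coverage (default 0.25x).
#' @param filter_min_length optional fragment-length floor (bp) applied to
#'   every pileup before imputation; `NULL` disables the filter.
#' @param length_sd fragment-length standard deviation passed to the
#'   simulator (0 makes the maternal/fetal distributions fully disjoint).
#' @return an `experiment_report` with `mean_scores` (pairs x conditions),
#'   `correlations` and `deviations`.
#' @export
run_mixture_experiment <- function(panel = NULL, scoring = NULL,
                                   n_pairs = 40L,
                                   fetal_fractions = c(0, 0.05, 0.10, 0.15),
                                   n_replicates = 7L,
                                   coverage = 0.25,
                                   error_rate = 0.005,
                                   filter_min_length = NULL,
                                   length_sd = 15,
                                   params = hmm_params(),
                                   config = sim_config(),
                                   seed = 1L) {
  if (is.null(panel)) panel <- generate_panel(config, seed = derive_seed(seed, 1L))
  if (is.null(scoring)) {
    scoring <- make_scoring_panel(panel, min(2000L, n_panel_sites(panel)),
                                  seed = derive_seed(seed, 2L))
  }
  match <- match_markers(scoring, panel_sites(panel))
  n_ff <- length(fetal_fractions)
  mean_scores <- matrix(NA_real_, nrow = n_pairs, ncol = n_ff,
                        dimnames = list(NULL, sprintf("ff%g", fetal_fractions)))
  for (p in seq_len(n_pairs)) {
    pair <- sample_mother_fetus(panel, config, seed = derive_seed(seed, p))
    for (f in seq_len(n_ff)) {
      reps <- numeric(n_replicates)
      for (r in seq_len(n_replicates)) {
        mix <- mixture_config(coverage = coverage,
                              fetal_fraction = fetal_fractions[f],
                              error_rate = error_rate,
                              length_sd = length_sd)
        pu <- simulate_pileups(pair, mix,
                               seed = derive_seed(seed, p * 571L + f * 7919L + r))
        if (!is.null(filter_min_length)) {
          pu <- filter_by_length(pu, filter_min_length)
        }
        d <- impute_arm_dosage(pu, panel, error_rate, params)
        reps[r] <- compute_prs(d, match)$score
      }
      mean_scores[p, f] <- mean(reps)
    }
  }
  ref <- mean_scores[, 1L]
  correlations <- data.frame(
    fetal_fraction = fetal_fractions,
    pearson = apply(mean_scores, 2L, function(s) pearson_cor(ref, s)),
    spearman = apply(mean_scores, 2L, function(s)
      stats::cor(ref, s, method = "spearman")))
  deviations <- data.frame(
    fetal_fraction = fetal_fractions,
    bias = colMeans(mean_scores - ref),
    sd = apply(mean_scores - ref, 2L, stats::sd))
  new_report("mixture", seed,
             list(n_pairs = n_pairs, fetal_fractions = fetal_fractions,
                  n_replicates = n_replicates, coverage = coverage,
                  error_rate = error_rate,
                  filter_min_length = filter_min_length,
                  length_sd = length_sd, scoring_id = scoring$id),
             mean_scores = mean_scores, correlations = correlations,
             deviations = deviations)
}

#' Prospective-cohort analog experiment
#'
#' Simulates a cohort of mother-fetus pairs with per-sample fetal fraction
#' drawn uniformly from `ff_range`. The cfDNA arm is a 0.25x mixture pileup,
#' imputed; the gDNA arm is pure-maternal 15x, hard-called (non-imputed).
#' PRS are computed against several scoring panels of different sizes.
#' Reports per-panel Pearson/Spearman correlations between arms, correlations
#' stratified by fetal fraction (low/high split at the cohort median), and
#' the high-risk misclassification rate at cutoff `q`.
#'
#' @inheritParams run_coverage_experiment
#' @param scorings list of `scoring_panel`s; default synthetic panels of
#'   50, 500, 2,000 and 5,000 markers (5,000 capped at the site count).
#' @param n_samples cohort size (default 450).
#' @param ff_range fetal-fraction range sampled per subject (default 3-20%).
#' @param cfdna_coverage cfDNA arm coverage (default 0.25x).
#' @param gdna_coverage gDNA arm coverage (default 15x).
#' @param q high-risk top-percentile cutoff (default 0.05).
#' @return an `experiment_report` with `scores`, `correlations`,
#'   `ff_stratified`, `misclassification` and `fetal_fractions`.
#' @export
run_cohort_experiment <- function(panel = NULL, scorings = NULL,
                                  n_samples = 450L,
                                  ff_range = c(0.03, 0.20),
                                  cfdna_coverage = 0.25,
                                  gdna_coverage = 15,
                                  error_rate = 0.005,
                                  q = 0.05,
                                  params = hmm_params(),
                                  config = sim_config(),
                                  seed = 1L) {
  if (is.null(panel)) panel <- generate_panel(config, seed = derive_seed(seed, 1L))
  if (is.null(scorings)) {
    sizes <- pmin(c(50L, 500L, 2000L, 5000L), n_panel_sites(panel))
    sizes <- unique(sizes)
    scorings <- lapply(seq_along(sizes), function(i)
      make_scoring_panel(panel, sizes[i], seed = derive_seed(seed, 100L + i)))
  }
  sites <- panel_sites(panel)
  matches <- lapply(scorings, match_markers, sites = sites)
  ff <- with_seed(derive_seed(seed, 3L),
                  stats::runif(n_samples, ff_range[1], ff_range[2]))
  n_panels <- length(scorings)
  cf_scores <- matrix(NA_real_, n_samples, n_panels)
  gd_scores <- matrix(NA_real_, n_samples, n_panels)
  for (s in seq_len(n_samples)) {
    pair <- sample_mother_fetus(panel, config, seed = derive_seed(seed, 10L + s))
    mix_cf <- mixture_config(coverage = cfdna_coverage, fetal_fraction = ff[s],
                             error_rate = error_rate)
    pu_cf <- simulate_pileups(pair, mix_cf, seed = derive_seed(seed, 50000L + s))
    d_cf <- impute_arm_dosage(pu_cf, panel, error_rate, params)
    mix_gd <- mixture_config(coverage = gdna_coverage, fetal_fraction = 0,
                             error_rate = error_rate)
    pu_gd <- simulate_pileups(pair, mix_gd, seed = derive_seed(seed, 100000L + s))
    d_gd <- hard_call_arm_dosage(pu_gd, error_rate)
    for (j in seq_len(n_panels)) {
      cf_scores[s, j] <- compute_prs(d_cf, matches[[j]])$score
      gd_scores[s, j] <- compute_prs(d_gd, matches[[j]])$score
    }
  }
  panel_ids <- vapply(scorings, `[[`, character(1), "id")
  panel_sizes <- vapply(scorings, `[[`, integer(1), "n_markers")
  correlations <- data.frame(
    panel_id = panel_ids, n_markers = panel_sizes,
    pearson = vapply(seq_len(n_panels), function(j)
      pearson_cor(gd_scores[, j], cf_scores[, j]), numeric(1)),
    spearman = vapply(seq_len(n_panels), function(j)
      stats::cor(gd_scores[, j], cf_scores[, j], method = "spearman"),
      numeric(1)))
  low <- ff <= stats::median(ff)
  ff_stratified <- do.call(rbind, lapply(seq_len(n_panels), function(j) {
    data.frame(panel_id = panel_ids[j], n_markers = panel_sizes[j],
               stratum = c("low_ff", "high_ff"),
               pearson = c(pearson_cor(gd_scores[low, j], cf_scores[low, j]),
                           pearson_cor(gd_scores[!low, j], cf_scores[!low, j])))
  }))
  misclassification <- data.frame(
    panel_id = panel_ids, n_markers = panel_sizes,
    rate = vapply(seq_len(n_panels), function(j)
      misclassification_rate(gd_scores[, j], cf_scores[, j], q), numeric(1)))
  new_report("cohort", seed,
             list(n_samples = n_samples, ff_range = ff_range,
                  cfdna_coverage = cfdna_coverage,
                  gdna_coverage = gdna_coverage, error_rate = error_rate,
                  q = q, panel_sizes = panel_sizes),
             scores = list(cfdna = cf_scores, gdna = gd_scores),
             fetal_fractions = ff,
             correlations = correlations,
             ff_stratified = ff_stratified,
             misclassification = misclassification)
}

#' Write an experiment report as TSV tables plus a JSON summary
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("correlations", "ff_stratified", "misclassification",
               "deviations")) {
    if (!is.null(report[[nm]]) && is.data.frame(report[[nm]])) {
      utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (is.data.frame(report$scores)) {
    utils::write.table(report$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(type = report$type, master_seed = report$master_seed,
                  config = report$config)
  if (!is.null(report$correlations)) summary$correlations <- report$correlations
  if (!is.null(report$misclassification)) {
    summary$misclassification <- report$misclassification
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
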