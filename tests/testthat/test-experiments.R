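test_that("pearson correlation handles identities and the worked example", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, x), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)
  expect_equal(round(pearson_cor(x, c(1, 2, 3, 5)), 4), 0.9827)
  expect_true(is.na(pearson_cor(x, rep(1, 4))))
  expect_error(pearson_cor(x, 1:3), "length")
})

test_that("misclassification counts flipped high-risk labels", {
  ref <- as.numeric(1:100)
  expect_equal(misclassification_rate(ref, ref, 0.05), 0)
  expect_equal(misclassification_rate(ref, 3 + 2 * ref, 0.05), 0)
  # swap the values of the top-5 and bottom-5 samples: 10 labels flip
  alt <- ref
  alt[96:100] <- ref[1:5]
  alt[1:5] <- ref[96:100]
  expect_equal(misclassification_rate(ref, alt, 0.05), 0.10)
  expect_error(misclassification_rate(ref, ref, 0.6), "q must")
  expect_error(misclassification_rate(1:5, 1:5, 0.05), "too small")
})

test_that("misclassification agrees with an independent label oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(20:50, 1)
    q <- runif(1, 0.05, 0.4)
    if (n * q < 1) next
    ref <- rnorm(n)
    alt <- ref + rnorm(n, sd = runif(1, 0, 2))
    expected <- mean(oracle_high_risk(ref, q) != oracle_high_risk(alt, q))
    expect_equal(misclassification_rate(ref, alt, q), expected)
  }
})

cfg_small <- tiny_config(seed = 61)

test_that("the noise-free limit of the coverage experiment gives unit
           correlations", {
  rep <- run_coverage_experiment(n_subjects = 6, n_cohorts = 2,
                                 low_coverages = c(30, 30),
                                 high_coverage = 30, error_rate = 0,
                                 params = tiny_params(copy_error = 1e-4),
                                 config = cfg_small, seed = 5)
  expect_true(all(rep$correlations$pearson > 0.9999))
})

test_that("experiments are reproducible from their master seed", {
  r1 <- run_coverage_experiment(n_subjects = 4, n_cohorts = 2,
                                params = tiny_params(), config = cfg_small,
                                seed = 9)
  r2 <- run_coverage_experiment(n_subjects = 4, n_cohorts = 2,
                                params = tiny_params(), config = cfg_small,
                                seed = 9)
  expect_identical(r1$correlations, r2$correlations)
  expect_identical(r1$scores, r2$scores)
})

test_that("PRS correlation degrades with fetal fraction and improves with
           coverage over replicate runs", {
  degr <- sapply(1:10, function(i) {
    rep <- run_mixture_experiment(n_pairs = 8, fetal_fractions = c(0, 0.15),
                                  n_replicates = 2, coverage = 0.3,
                                  params = tiny_params(),
                                  config = tiny_config(seed = 70 + i),
                                  seed = 300 + i)
    rep$correlations$pearson[2]
  })
  cover <- sapply(1:10, function(i) {
    rep <- run_coverage_experiment(n_subjects = 8, n_cohorts = 1,
                                   params = tiny_params(),
                                   config = tiny_config(seed = 70 + i),
                                   seed = 600 + i)
    rep$correlations$pearson
  })
  # FF = 0.15 arm correlates with the FF = 0 arm less than perfectly
  expect_lt(mean(degr), 1)
  # 1.0x tracks 30x better than 0.2x does, on average over runs
  expect_gt(mean(cover[1, ]), mean(cover[2, ]))
})

test_that("the fragment-length filter rescues the high-FF arm when the
           length distributions are disjoint", {
  diffs <- sapply(1:5, function(i) {
    base <- run_mixture_experiment(n_pairs = 8, fetal_fractions = c(0, 0.15),
                                   n_replicates = 2, length_sd = 0,
                                   coverage = 0.4, params = tiny_params(),
                                   config = tiny_config(seed = 80 + i),
                                   seed = 400 + i)
    filt <- run_mixture_experiment(n_pairs = 8, fetal_fractions = c(0, 0.15),
                                   n_replicates = 2, length_sd = 0,
                                   coverage = 0.4, filter_min_length = 150,
                                   params = tiny_params(),
                                   config = tiny_config(seed = 80 + i),
                                   seed = 400 + i)
    filt$correlations$pearson[2] - base$correlations$pearson[2]
  })
  expect_gt(mean(diffs), 0)
})

test_that("the cohort experiment stratifies by fetal fraction and panel size
           and reports misclassification", {
  rep <- run_cohort_experiment(n_samples = 30, q = 0.1,
                               params = tiny_params(), config = cfg_small,
                               seed = 15)
  n_panels <- nrow(rep$correlations)
  expect_gte(n_panels, 3L)
  expect_true(all(rep$correlations$pearson >= -1 &
                    rep$correlations$pearson <= 1))
  expect_true(all(rep$misclassification$rate >= 0 &
                    rep$misclassification$rate <= 1))
  expect_identical(nrow(rep$ff_stratified), 2L * n_panels)
  expect_length(rep$fetal_fractions, 30L)
  expect_true(all(rep$fetal_fractions >= 0.03 & rep$fetal_fractions <= 0.20))
  # deterministic re-computation of the misclassification from the report
  j <- which.max(rep$misclassification$n_markers)
  expect_equal(rep$misclassification$rate[j],
               misclassification_rate(rep$scores$gdna[, j],
                                      rep$scores$cfdna[, j], 0.1))
})

test_that("reports serialize to TSV tables plus a JSON summary", {
  rep <- run_mixture_experiment(n_pairs = 6, fetal_fractions = c(0, 0.1),
                                n_replicates = 1, params = tiny_params(),
                                config = cfg_small, seed = 21)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "correlations.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_identical(summ$type, "mixture")
  expect_identical(summ$master_seed, 21L)
})
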