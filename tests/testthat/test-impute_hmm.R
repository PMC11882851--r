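test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (case in 1:4) {
    K <- sample(2:3, 1)
    L <- sample(3:4, 1)
    alleles <- matrix(sample(0:1, K * L, replace = TRUE), K, L)
    cm <- cumsum(runif(L, 0.01, 2))
    lik <- matrix(rexp(L * 3), L, 3)
    lik <- lik / rowSums(lik)
    n_eff <- runif(1, 0.5, 10)
    mu <- runif(1, 1e-4, 0.05)
    fast <- niptprs:::.diploid_ls_posteriors(lik, alleles, cm, n_eff, mu, 0)
    slow <- oracle_diploid_posteriors(lik, alleles, cm, n_eff, mu)
    expect_equal(fast, slow, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("with no data the dosage reverts to twice the panel frequency", {
  cfg <- sim_config(n_panel_haplotypes = 200L, n_sites = 400L,
                    region_length_bp = 2e6, seed = 23)
  panel <- generate_panel(cfg)
  pu <- manual_pileups(integer(0), integer(0), n_panel_sites(panel))
  lik <- genotype_likelihoods(pu)
  d <- impute_dosages(lik, panel,
                      hmm_params(copy_error = 1e-6, subset_size = Inf))
  expect_lt(max(abs(d$dosage - 2 * panel$allele_freq)), 0.05)
})

test_that("an in-panel mother is recovered perfectly at high coverage", {
  cfg <- tiny_config(seed = 29)
  panel <- generate_panel(cfg)
  pair <- in_panel_pair(panel, 5L, 12L)
  pu <- simulate_pileups(pair, mixture_config(coverage = 30, error_rate = 0),
                         seed = 1)
  lik <- genotype_likelihoods(pu, error_rate = 0)
  d <- impute_dosages(lik, panel, hmm_params(copy_error = 1e-4,
                                             subset_size = Inf))
  expect_identical(d$hard_call, as.integer(pair$mother_genotype))
})

test_that("posterior genotype distributions are normalized", {
  cfg <- tiny_config(seed = 31)
  panel <- generate_panel(cfg)
  pair <- sample_mother_fetus(panel, cfg, seed = 2)
  pu <- simulate_pileups(pair, mixture_config(coverage = 0.25), seed = 3)
  d <- impute_dosages(genotype_likelihoods(pu), panel, tiny_params())
  expect_lt(max(abs(rowSums(d$posterior) - 1)), 1e-9)
  expect_true(all(d$dosage >= 0 & d$dosage <= 2))
})

test_that("dosages are invariant to permuting the copying set", {
  cfg <- tiny_config(seed = 37)
  panel <- generate_panel(cfg)
  pair <- sample_mother_fetus(panel, cfg, seed = 4)
  pu <- simulate_pileups(pair, mixture_config(coverage = 0.5), seed = 5)
  lik <- genotype_likelihoods(pu)
  d1 <- impute_dosages(lik, panel, hmm_params(subset_size = Inf))
  perm <- sample(nrow(panel$haplotypes))
  panel2 <- panel
  panel2$haplotypes <- panel$haplotypes[perm, , drop = FALSE]
  d2 <- impute_dosages(lik, panel2, hmm_params(subset_size = Inf))
  expect_equal(d1$dosage, d2$dosage, tolerance = 1e-9)
})

test_that("swapping the mother's haplotype labels leaves dosages unchanged", {
  cfg <- tiny_config(seed = 41)
  panel <- generate_panel(cfg)
  pair <- sample_mother_fetus(panel, cfg, seed = 6)
  swapped <- pair
  swapped$mother_haps <- pair$mother_haps[2:1, ]
  # the same physical reads, re-expressed against each labelling: a read of
  # haplotype h from `pair` is a read of haplotype 3 - h from `swapped`
  set.seed(7)
  n <- 600L
  site <- sample.int(ncol(pair$mother_haps), n, replace = TRUE)
  hap <- sample.int(2L, n, replace = TRUE)
  pu1 <- manual_pileups(site, pair$mother_haps[cbind(hap, site)],
                        ncol(pair$mother_haps))
  pu2 <- manual_pileups(site, swapped$mother_haps[cbind(3L - hap, site)],
                        ncol(pair$mother_haps))
  expect_identical(pu1$allele, pu2$allele)
  d1 <- impute_dosages(genotype_likelihoods(pu1), panel, tiny_params())
  d2 <- impute_dosages(genotype_likelihoods(pu2), panel, tiny_params())
  expect_identical(d1$dosage, d2$dosage)
})

test_that("imputation accuracy improves with coverage", {
  cfg <- tiny_config(seed = 43)
  panel <- generate_panel(cfg)
  r2 <- sapply(1:10, function(i) {
    pair <- sample_mother_fetus(panel, cfg, seed = 50 + i)
    sapply(c(0, 0.2, 1.0), function(cov) {
      pu <- simulate_pileups(pair, mixture_config(coverage = cov),
                             seed = 500 + i)
      d <- impute_dosages(genotype_likelihoods(pu), panel, tiny_params())
      posterior_r2(d, pair$mother_genotype)
    })
  })
  means <- rowMeans(r2, na.rm = TRUE)  # r2 at 0x is NA when dosage is flat
  m0 <- if (is.nan(means[1])) 0 else means[1]
  expect_gt(means[3], means[2])
  expect_gt(means[2], m0)
})

test_that("misaligned site lists fail loudly", {
  cfg <- tiny_config(seed = 47)
  panel <- generate_panel(cfg)
  pu <- manual_pileups(1L, 1L, n_sites = 10)
  lik <- genotype_likelihoods(pu)
  expect_error(impute_dosages(lik, panel), "align")
})

test_that("posterior_r2 behaves as a squared correlation", {
  truth <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L)
  expect_equal(posterior_r2(as.numeric(truth), truth), 1.0)
  expect_equal(posterior_r2(0.3 + 0.5 * truth, truth), 1.0)
  expect_true(is.na(posterior_r2(rep(1, 8), truth)))
  set.seed(1)
  x <- sample(rep(0:2, 200))
  y <- sample(rep(0:2, 200))
  expect_lt(posterior_r2(as.numeric(x), y), 0.05)
})
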