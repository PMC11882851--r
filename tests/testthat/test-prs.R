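scoring_file_text <- function(rows, header = TRUE) {
  c("#pgs_id=PGSTEST01",
    "#genome_build=GRCh38",
    if (header) "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    rows)
}

test_that("scoring files parse, count malformed rows, and flag missing columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(scoring_file_text(c("1\t100\tA\tC\t0.5",
                                 "1\t200\tG\tT\t-1.0",
                                 "1\t300\tC\tA\t2.0")), path)
  p <- load_scoring_file(path)
  expect_identical(p$id, "PGSTEST01")
  expect_identical(p$n_markers, 3L)
  expect_identical(p$n_skipped_rows, 0L)

  writeLines(scoring_file_text(c("1\t100\tA\tC\t0.5",
                                 "1\t200\tG\tT\tnot_a_number",
                                 "1\t300\tC\tA\t2.0",
                                 "1\t400\tT\tG\t1.0")), path)
  expect_message(p2 <- load_scoring_file(path), "skipped")
  expect_identical(p2$n_markers, 3L)
  expect_identical(p2$n_skipped_rows, 1L)

  writeLines(c("#pgs_id=X",
               "chr_name\tchr_position\teffect_allele\teffect_weight",
               "1\t100\tA\t0.5"), path)
  expect_error(load_scoring_file(path), "other_allele")
})

test_that("scoring panels round-trip through the catalog dialect", {
  cfg <- tiny_config(seed = 51)
  panel <- generate_panel(cfg)
  sp <- make_scoring_panel(panel, 50L, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_scoring_file(sp, path)
  back <- load_scoring_file(path)
  expect_identical(back$id, sp$id)
  expect_equal(back$markers$chr_position, sp$markers$chr_position)
  expect_equal(back$markers$effect_weight, sp$markers$effect_weight)
  expect_identical(back$markers$effect_allele, sp$markers$effect_allele)
})

test_that("marker matching resolves position, alleles and orientation", {
  sites <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      ref = c("A", "G", "C"), alt = c("C", "T", "A"),
                      af = c(0.1, 0.5, 0.9))
  markers <- data.frame(chr_name = "1",
                        chr_position = c(100L, 200L, 250L, 300L),
                        effect_allele = c("C", "G", "A", "T"),
                        other_allele = c("A", "T", "C", "G"),
                        effect_weight = c(1, 2, 3, 4))
  sp <- niptprs:::new_scoring_panel("X", markers)
  m <- match_markers(sp, sites)
  # marker 1: effect = alt -> direct; marker 2: effect = ref -> flipped;
  # marker 3: position absent; marker 4: allele pair mismatch
  expect_identical(m$site_idx, c(1L, 2L))
  expect_identical(m$flipped, c(FALSE, TRUE))
  expect_identical(attr(m, "n_unmatched"), 2L)
})

test_that("PRS matches hand arithmetic and is linear in the weights", {
  sites <- data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                      ref = c("A", "A", "A"), alt = c("C", "C", "C"),
                      af = c(0.5, 0.5, 0.5))
  markers <- data.frame(chr_name = "1", chr_position = c(10L, 20L, 30L),
                        effect_allele = "C", other_allele = "A",
                        effect_weight = c(0.5, -1.0, 2.0))
  sp <- niptprs:::new_scoring_panel("X", markers)
  m <- match_markers(sp, sites)
  res <- compute_prs(c(2, 1, 0), m)
  expect_equal(res$score, 0.0)   # (1.0 - 1.0 + 0) / 3
  expect_identical(res$M, 3L)

  sp0 <- sp
  sp0$markers$effect_weight <- 0
  expect_equal(compute_prs(c(2, 1, 0), match_markers(sp0, sites))$score, 0)

  sp2 <- sp
  sp2$markers$effect_weight <- 2 * sp$markers$effect_weight
  m2 <- match_markers(sp2, sites)
  d <- c(1.2, 0.4, 1.9)
  expect_equal(compute_prs(d, m2, M = 3)$score,
               2 * compute_prs(d, m, M = 3)$score)
})

test_that("flipped markers contribute through the complemented dosage", {
  sites <- data.frame(chrom = "1", pos = 10L, ref = "A", alt = "C", af = 0.5)
  markers <- data.frame(chr_name = "1", chr_position = 10L,
                        effect_allele = "A", other_allele = "C",
                        effect_weight = 1.0)
  m <- match_markers(niptprs:::new_scoring_panel("X", markers), sites)
  expect_equal(compute_prs(0.4, m)$score, 1.6)  # beta * (2 - d) / 1
})

test_that("missing-dosage policies drop or mean-impute as documented", {
  sites <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "C",
                      af = c(0.25, 0.5))
  markers <- data.frame(chr_name = "1", chr_position = c(10L, 20L),
                        effect_allele = "C", other_allele = "A",
                        effect_weight = c(1.0, 1.0))
  m <- match_markers(niptprs:::new_scoring_panel("X", markers), sites)
  d <- c(NA, 1.0)
  drop <- compute_prs(d, m, missing_policy = "drop")
  expect_equal(drop$score, 1.0)
  expect_identical(drop$M, 1L)
  imp <- compute_prs(d, m, missing_policy = "mean_impute", af = sites$af)
  expect_equal(imp$score, (2 * 0.25 + 1.0) / 2)
  expect_error(compute_prs(c(NA, NA), m), "missing")
})

test_that("cross-sample correlations are invariant to the M convention", {
  cfg <- tiny_config(seed = 53)
  panel <- generate_panel(cfg)
  sp <- make_scoring_panel(panel, 100L, seed = 2)
  m <- match_markers(sp, panel_sites(panel))
  set.seed(3)
  dosages <- matrix(runif(n_panel_sites(panel) * 12, 0, 2),
                    ncol = 12)
  per_avg <- compute_prs_cohort(dosages, m)               # M = marker count
  plain_sum <- compute_prs_cohort(dosages, m, M = 1)      # PLINK sum mode
  other <- rnorm(12)
  expect_equal(stats::cor(per_avg, other), stats::cor(plain_sum, other),
               tolerance = 1e-12)
  expect_equal(stats::cor(per_avg, plain_sum), 1, tolerance = 1e-12)
})

test_that("scores from dosages equal scores from truth when they coincide", {
  cfg <- tiny_config(seed = 59)
  panel <- generate_panel(cfg)
  pair <- sample_mother_fetus(panel, cfg, seed = 1)
  sp <- make_scoring_panel(panel, 80L, seed = 4)
  m <- match_markers(sp, panel_sites(panel))
  truth <- as.numeric(pair$mother_genotype)
  expect_equal(compute_prs(truth, m)$score, compute_prs(truth + 0, m)$score)
})

test_that("empty matches fail loudly", {
  sites <- data.frame(chrom = "1", pos = 10L, ref = "A", alt = "C", af = 0.5)
  markers <- data.frame(chr_name = "1", chr_position = 99L,
                        effect_allele = "C", other_allele = "A",
                        effect_weight = 1.0)
  m <- match_markers(niptprs:::new_scoring_panel("X", markers), sites)
  expect_error(compute_prs(1.0, m), "match")
})
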