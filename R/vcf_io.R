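# VCF interchange: phased panels and truth genotypes (GT), genotype
# likelihoods (GT + GL, log10-scaled), and imputed dosages (GT + DS).
# Writing is plain VCFv4.2 text; reading goes through vcfR.

vcf_header <- function(format_lines, sample_names, extra_info = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=niptprs",
    "##contig=<ID=1>",
    extra_info,
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

vcf_fixed_cols <- function(panel, info) {
  cbind(panel$chrom, panel$positions, panel$ids, panel$ref, panel$alt,
        ".", "PASS", info)
}

write_vcf_body <- function(path, header, fixed, format, geno_matrix) {
  body <- apply(cbind(fixed, format, geno_matrix), 1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a phased haplotype panel as VCF
#'
#' Haplotypes are paired into diploid samples with phased GT (`|`). The
#' genetic-map coordinate is stored in INFO as `CM=` alongside `AF=` so the
#' panel round-trips.
#'
#' @param panel a `haplotype_panel` with an even number of haplotypes.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_panel_vcf <- function(panel, path) {
  K <- nrow(panel$haplotypes)
  if (K %% 2L != 0L) stop("panel must have an even number of haplotypes to ",
                          "pair into diploid VCF samples", call. = FALSE)
  n_samp <- K %/% 2L
  gt <- matrix("", nrow = n_panel_sites(panel), ncol = n_samp)
  for (s in seq_len(n_samp)) {
    gt[, s] <- paste(panel$haplotypes[2L * s - 1L, ],
                     panel$haplotypes[2L * s, ], sep = "|")
  }
  header <- vcf_header(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    sprintf("PANEL%04d", seq_len(n_samp)),
    c('##INFO=<ID=AF,Number=1,Type=Float,Description="Panel alternate allele frequency">',
      '##INFO=<ID=CM,Number=1,Type=Float,Description="Genetic map position in centimorgans">'))
  info <- sprintf("AF=%.6f;CM=%.8f", panel$allele_freq, panel$cm_positions)
  write_vcf_body(path, header, vcf_fixed_cols(panel, info), "GT", gt)
}

#' Read a phased haplotype panel from VCF
#'
#' Expects phased GT fields; the genetic map is taken from the `CM` INFO key
#' when present, otherwise derived from positions at `map_cm_per_mb`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param map_cm_per_mb fallback uniform map rate.
#' @param maf_floor MAF floor recorded on the imported panel (sites are not
#'   re-filtered; supply the floor the panel was built with).
#' @return a `haplotype_panel`.
#' @export
read_panel_vcf <- function(path, map_cm_per_mb = 1.0, maf_floor = 0) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("|", gt, fixed = TRUE))) {
    stop("panel VCF must contain phased (|) genotypes", call. = FALSE)
  }
  a1 <- t(apply(gt, 1L, function(r) as.integer(sub("\\|.*", "", r))))
  a2 <- t(apply(gt, 1L, function(r) as.integer(sub(".*\\|", "", r))))
  L <- nrow(gt)
  K <- 2L * ncol(gt)
  H <- matrix(0L, nrow = K, ncol = L)
  H[seq(1L, K, by = 2L), ] <- t(a1)
  H[seq(2L, K, by = 2L), ] <- t(a2)
  pos <- as.integer(vcfR::getPOS(v))
  cm_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CM")))
  cm <- if (all(is.finite(cm_info))) cm_info else pos * map_cm_per_mb / 1e6
  panel <- list(
    haplotypes = H,
    positions = pos,
    cm_positions = cm,
    allele_freq = colMeans(H),
    ref = vcfR::getREF(v),
    alt = vcfR::getALT(v),
    chrom = vcfR::getCHROM(v)[1],
    ids = vcfR::getID(v),
    config = NULL
  )
  class(panel) <- "haplotype_panel"
  validate_panel(panel, maf_floor = maf_floor)
  panel
}

#' Write mother and fetus truth genotypes as a phased VCF
#'
#' Two samples, `MOTHER` (hap a | hap b) and `FETUS` (transmitted | paternal).
#'
#' @param pair a `mother_fetus_pair`.
#' @param panel the `haplotype_panel` providing site annotation.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pair_vcf <- function(pair, panel, path) {
  gt <- cbind(
    MOTHER = paste(pair$mother_haps[1, ], pair$mother_haps[2, ], sep = "|"),
    FETUS = paste(pair$fetus_haps[1, ], pair$fetus_haps[2, ], sep = "|"))
  header <- vcf_header(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    c("MOTHER", "FETUS"))
  write_vcf_body(path, header, vcf_fixed_cols(panel, "."), "GT", gt)
}

#' Write genotype likelihoods as VCF (GT + GL)
#'
#' GL is the log10-scaled genotype-likelihood triple for genotypes 0/0, 0/1,
#' 1/1 (VCF GL dialect, not phred-scaled PL); GT is the hard call from
#' [call_genotypes()], `./.` when missing.
#'
#' @param lik a `genotype_likelihoods` object.
#' @param panel the `haplotype_panel` providing site annotation.
#' @param path output file.
#' @param sample_name sample column name.
#' @param min_depth hard-call depth threshold passed to [call_genotypes()].
#' @return invisibly `path`.
#' @export
write_likelihood_vcf <- function(lik, panel, path, sample_name = "SAMPLE",
                                 min_depth = 4L) {
  g <- call_genotypes(lik, min_depth = min_depth)
  gt <- c("0/0", "0/1", "1/1")[g + 1L]
  gt[is.na(gt)] <- "./."
  gl <- apply(log10(pmax(lik$lik, 1e-300)), 1L, function(r)
    paste(sprintf("%.4f", r), collapse = ","))
  header <- vcf_header(
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Hard-called genotype">',
      '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10-scaled genotype likelihoods for 0/0,0/1,1/1">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    sample_name)
  geno <- paste(gt, gl, lik$depth, sep = ":")
  write_vcf_body(path, header, vcf_fixed_cols(panel, "."), "GT:GL:DP", geno)
}

#' Read genotype likelihoods from a VCF written by [write_likelihood_vcf()]
#'
#' @param path VCF file.
#' @return a `genotype_likelihoods` object (likelihoods renormalized to sum 1).
#' @export
read_likelihood_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gl <- vcfR::extract.gt(v, element = "GL")
  dp <- as.integer(vcfR::extract.gt(v, element = "DP"))
  lik <- t(vapply(gl[, 1L], function(x) 10^as.numeric(strsplit(x, ",")[[1]]),
                  numeric(3)))
  lik <- lik / rowSums(lik)
  dimnames(lik) <- list(NULL, c("L0", "L1", "L2"))
  out <- list(lik = lik, depth = dp)
  class(out) <- "genotype_likelihoods"
  out
}

#' Write imputed dosages as VCF (GT + DS)
#'
#' @param dosage a `dosage_result`.
#' @param panel the `haplotype_panel` providing site annotation.
#' @param path output file.
#' @param sample_name sample column name.
#' @return invisibly `path`.
#' @export
write_dosage_vcf <- function(dosage, panel, path, sample_name = "SAMPLE") {
  gt <- c("0/0", "0/1", "1/1")[dosage$hard_call + 1L]
  header <- vcf_header(
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Posterior-mode genotype">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected alternate allele dosage">'),
    sample_name)
  geno <- paste(gt, sprintf("%.4f", dosage$dosage), sep = ":")
  write_vcf_body(path, header, vcf_fixed_cols(panel, "."), "GT:DS", geno)
}

#' Read dosages from a VCF with a DS field
#'
#' @param path VCF file.
#' @return numeric dosage vector (first sample).
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as.numeric(vcfR::extract.gt(v, element = "DS")[, 1L])
}
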