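# Polygenic risk score computation: PGS Catalog scoring files, marker-to-site
# matching with effect-allele orientation, and the weighted-dosage score
#   PRS_j = sum_i beta_i * g_ij / M_j,
# where g_ij is the orientation-corrected dosage and M_j is a per-sample
# normalization scalar (default: the matched non-missing marker count, i.e.
# per-marker averaging).

required_scoring_cols <- c("chr_name", "chr_position", "effect_allele",
                           "other_allele", "effect_weight")

new_scoring_panel <- function(id, markers, n_skipped_rows = 0L) {
  p <- list(id = id, markers = markers, n_markers = nrow(markers),
            n_skipped_rows = as.integer(n_skipped_rows))
  class(p) <- "scoring_panel"
  p
}

#' @export
print.scoring_panel <- function(x, ...) {
  cat(sprintf("scoring_panel '%s': %d markers (%d malformed rows skipped)\n",
              x$id, x$n_markers, x$n_skipped_rows))
  invisible(x)
}

#' Load a PGS Catalog scoring file
#'
#' Parses the harmonized scoring-file text dialect: '#'-prefixed header lines
#' (of which `#pgs_id=` supplies the panel id when present), then a
#' tab-separated table whose columns must include `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele` and `effect_weight`. Unknown columns are
#' ignored; rows with a non-numeric weight or position are counted and
#' skipped.
#'
#' @param path file path.
#' @return an object of class `scoring_panel`.
#' @export
load_scoring_file <- function(path) {
  if (!file.exists(path)) stop("scoring file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  id <- sub("^#pgs_id=", "", grep("^#pgs_id=", hdr, value = TRUE)[1])
  if (is.na(id)) id <- basename(path)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, colClasses = "character")
  missing_cols <- setdiff(required_scoring_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("scoring file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(df$chr_position))
  w <- suppressWarnings(as.numeric(df$effect_weight))
  ok <- is.finite(pos) & is.finite(w) & nzchar(df$effect_allele) &
    nzchar(df$other_allele)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " malformed scoring row(s) skipped")
  }
  markers <- data.frame(
    chr_name = df$chr_name[ok],
    chr_position = as.integer(pos[ok]),
    effect_allele = df$effect_allele[ok],
    other_allele = df$other_allele[ok],
    effect_weight = w[ok],
    stringsAsFactors = FALSE
  )
  if (nrow(markers) < 1L) stop("scoring file has no valid markers", call. = FALSE)
  if (anyDuplicated(markers[c("chr_name", "chr_position")]) > 0) {
    stop("duplicated marker positions in scoring file", call. = FALSE)
  }
  new_scoring_panel(id, markers, n_skipped)
}

#' Write a scoring panel in the PGS Catalog text dialect
#'
#' @param scoring a `scoring_panel`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_scoring_file <- function(scoring, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#pgs_id=%s", scoring$id),
               sprintf("#variants_number=%d", scoring$n_markers)), con)
  utils::write.table(scoring$markers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Site table of a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
panel_sites <- function(panel) {
  data.frame(chrom = panel$chrom, pos = panel$positions, ref = panel$ref,
             alt = panel$alt, af = panel$allele_freq,
             stringsAsFactors = FALSE)
}

#' Draw a synthetic scoring panel from simulated sites
#'
#' Markers are a random draw of panel sites with weights ~ Normal(0, sd) and
#' the effect allele assigned to ref or alt uniformly at random, exercising
#' both marker orientations.
#'
#' @param panel a `haplotype_panel`.
#' @param n_markers marker count.
#' @param weight_sd standard deviation of effect weights.
#' @param id panel id string.
#' @param seed optional seed.
#' @return a `scoring_panel`.
#' @export
make_scoring_panel <- function(panel, n_markers, weight_sd = 0.1,
                               id = sprintf("SYN%06d", n_markers),
                               seed = NULL) {
  L <- n_panel_sites(panel)
  if (n_markers > L) stop("n_markers exceeds the number of panel sites",
                          call. = FALSE)
  with_seed(seed, {
    idx <- sort(sample.int(L, n_markers))
    eff_is_alt <- stats::runif(n_markers) < 0.5
    markers <- data.frame(
      chr_name = panel$chrom,
      chr_position = panel$positions[idx],
      effect_allele = ifelse(eff_is_alt, panel$alt[idx], panel$ref[idx]),
      other_allele = ifelse(eff_is_alt, panel$ref[idx], panel$alt[idx]),
      effect_weight = stats::rnorm(n_markers, 0, weight_sd),
      stringsAsFactors = FALSE
    )
    new_scoring_panel(id, markers)
  })
}

#' Match scoring-panel markers to panel sites
#'
#' A marker matches a site when chromosome, position and the unordered allele
#' pair agree. The orientation flag records whether the effect allele is the
#' site's alternate allele (dosage used directly) or its reference allele
#' (dosage d replaced by 2 - d). Unmatched markers are excluded and counted.
#'
#' @param scoring a `scoring_panel`.
#' @param sites a site table from [panel_sites()].
#' @return an object of class `marker_match`: data.frame with `marker_idx`,
#'   `site_idx`, `weight`, `flipped`, plus attribute `n_unmatched`.
#' @export
match_markers <- function(scoring, sites) {
  m <- scoring$markers
  key_m <- paste(m$chr_name, m$chr_position)
  key_s <- paste(sites$chrom, sites$pos)
  site_idx <- match(key_m, key_s)
  found <- !is.na(site_idx)
  si <- site_idx[found]
  direct <- m$effect_allele[found] == sites$alt[si] &
    m$other_allele[found] == sites$ref[si]
  flipped <- m$effect_allele[found] == sites$ref[si] &
    m$other_allele[found] == sites$alt[si]
  allele_ok <- direct | flipped
  keep <- which(found)[allele_ok]
  out <- data.frame(marker_idx = keep,
                    site_idx = si[allele_ok],
                    weight = m$effect_weight[keep],
                    flipped = flipped[allele_ok])
  attr(out, "n_unmatched") <- scoring$n_markers - nrow(out)
  class(out) <- c("marker_match", class(out))
  out
}

#' Compute a polygenic risk score from dosages
#'
#' `PRS = sum(beta * g) / M` over matched markers, with `g` the
#' orientation-corrected dosage. Markers with missing dosage are either
#' dropped from both the sum and `M` (default) or mean-imputed as
#' `2 * allele frequency` of the effect allele.
#'
#' @param dosages numeric dosage vector over panel sites (may contain `NA`),
#'   or a `dosage_result`.
#' @param match a [match_markers()] result.
#' @param missing_policy `"drop"` or `"mean_impute"`.
#' @param af per-site alternate-allele frequencies (required for
#'   `"mean_impute"`).
#' @param M optional fixed normalization scalar; default is the matched
#'   non-missing marker count.
#' @return an object of class `prs_result` with `score`, `M`, `n_matched`,
#'   `n_missing`.
#' @export
compute_prs <- function(dosages, match, missing_policy = c("drop", "mean_impute"),
                        af = NULL, M = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(dosages, "dosage_result")) dosages <- dosages$dosage
  if (nrow(match) == 0L) {
    stop("no scoring markers matched the dosage sites", call. = FALSE)
  }
  d <- dosages[match$site_idx]
  miss <- !is.finite(d)
  if (missing_policy == "mean_impute" && any(miss)) {
    if (is.null(af)) stop("mean_impute policy requires allele frequencies",
                          call. = FALSE)
    d[miss] <- 2 * af[match$site_idx[miss]]
    miss[] <- FALSE
  }
  g <- ifelse(match$flipped, 2 - d, d)
  used <- !miss
  if (!any(used)) stop("all matched markers have missing dosage", call. = FALSE)
  M_use <- if (is.null(M)) sum(used) else M
  res <- list(score = sum(match$weight[used] * g[used]) / M_use,
              M = M_use,
              n_matched = nrow(match),
              n_missing = sum(miss))
  class(res) <- "prs_result"
  res
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("prs_result: score %.5f (M = %g, %d markers, %d missing)\n",
              x$score, x$M, x$n_matched, x$n_missing))
  invisible(x)
}

#' Scores for a cohort of dosage vectors
#'
#' @param dosage_matrix L x n matrix of per-sample dosages over panel sites.
#' @param match a [match_markers()] result.
#' @param ... passed to [compute_prs()].
#' @return numeric vector of scores, one per column.
#' @export
compute_prs_cohort <- function(dosage_matrix, match, ...) {
  apply(dosage_matrix, 2L, function(d) compute_prs(d, match, ...)$score)
}
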