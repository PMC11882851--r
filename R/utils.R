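# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so that every stage of an experiment gets its
#' own reproducible stream. Result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param salt integer stage identifier.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, salt) {
  x <- (as.numeric(master) * 104729 + as.numeric(salt) * 7919 + 12345) %%
    2147483645
  as.integer(x) + 1L
}

# Run expr with a locally-set seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Truncated-normal sampler by inverse-CDF; sd = 0 degenerates to the
# (bound-clipped) mean, used by tests that need fully separated distributions.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
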