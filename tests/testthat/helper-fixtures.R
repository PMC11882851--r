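# Shared fixtures and independent oracles, built in code at test time.

# Small, fast simulation scale used by most unit tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_panel_haplotypes = 80L, n_sites = 600L, n_founders = 8L,
             region_length_bp = 4e6, seed = seed, ...)
}

tiny_params <- function(...) hmm_params(subset_size = 30L, ...)

# Build a pileup_set by hand (for exact-arithmetic likelihood tests).
manual_pileups <- function(site, allele, n_sites,
                           frag_length = rep(166, base::length(site)),
                           origin = rep(0L, base::length(site))) {
  niptprs:::new_pileup_set(site, allele, frag_length, origin, n_sites)
}

# Brute-force diploid haplotype-copying posterior by exhaustive enumeration
# over all (K^2)^L ordered-pair state paths. Independent of the package's
# forward-backward: transition and emission probabilities are multiplied out
# path by path.
oracle_diploid_posteriors <- function(lik, alleles, cm, n_eff, mu) {
  K <- nrow(alleles)
  L <- ncol(alleles)
  states <- expand.grid(h1 = seq_len(K), h2 = seq_len(K))
  S <- nrow(states)
  tmat <- function(r) (1 - r) * diag(K) + r / K
  Tcg <- rbind(c((1 - mu)^2, 2 * mu * (1 - mu), mu^2),
               c(mu * (1 - mu), (1 - mu)^2 + mu^2, mu * (1 - mu)),
               c(mu^2, 2 * mu * (1 - mu), (1 - mu)^2))
  # per-site per-state class and emission
  cls <- sapply(seq_len(L), function(s)
    alleles[states$h1, s] + alleles[states$h2, s])
  emis <- sapply(seq_len(L), function(s)
    as.numeric(Tcg[cls[, s] + 1L, ] %*% lik[s, ]))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  prob <- rep(1 / S, nrow(paths))
  for (s in seq_len(L)) {
    if (s > 1) {
      r <- 1 - exp(-n_eff * (cm[s] - cm[s - 1]) / K)
      P1 <- tmat(r)
      from <- paths[, s - 1]
      to <- paths[, s]
      prob <- prob * P1[cbind(states$h1[from], states$h1[to])] *
        P1[cbind(states$h2[from], states$h2[to])]
    }
    prob <- prob * emis[cbind(paths[, s], rep(s, nrow(paths)))]
  }
  prob <- prob / sum(prob)
  post <- matrix(0, L, 3)
  for (s in seq_len(L)) {
    w <- tapply(prob, cls[cbind(paths[, s], rep(s, nrow(paths)))], sum)
    wfull <- numeric(3)
    wfull[as.integer(names(w)) + 1L] <- w
    # per class c the conditional P(g | c, data_s), weighted by class mass
    pg <- sapply(0:2, function(g) {
      num <- lik[s, g + 1L] * Tcg[, g + 1L]
      den <- as.numeric(Tcg %*% lik[s, ])
      sum(wfull * num / den)
    })
    post[s, ] <- pg / sum(pg)
  }
  post
}

# Independent high-risk label oracle: top ceil(q*n) by score, stable ties.
oracle_high_risk <- function(scores, q) {
  k <- ceiling(q * length(scores))
  rank_first <- rank(-scores, ties.method = "first")
  rank_first <= k
}

# A mother-fetus pair whose haplotypes are exact copies of two panel rows
# (fully in-panel target, used for the perfect-recovery test).
in_panel_pair <- function(panel, i, j) {
  ma <- panel$haplotypes[i, ]
  mb <- panel$haplotypes[j, ]
  pair <- list(
    mother_haps = rbind(a = ma, b = mb),
    fetus_haps = rbind(transmitted = ma, paternal = mb),
    mother_genotype = ma + mb,
    fetus_genotype = ma + mb,
    n_crossovers = 0L
  )
  class(pair) <- "mother_fetus_pair"
  pair
}
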