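# Shared fixtures: small genotype matrices and simulation configs built in
# code at test time.

make_gm <- function(dosage, ploidy = NULL, provenance = "initial_diploid") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(ploidy)) ploidy <- rep(2L, nrow(dosage))
  names(ploidy) <- rownames(dosage)
  genotype_matrix(dosage, ploidy, provenance)
}

small_config <- function(...) {
  defaults <- list(n_clusters = 2L, sizes = c(25L, 25L), ploidy = c(2L, 2L),
                   F_k = c(0.2, 0.2), n_nuclear_sites = 200L,
                   n_cp_sites = 20L, n_populations = 6L, n_teams = 4L,
                   hybrids = list(), clones = list(n = 0L, error = 0),
                   cp_pool_size = 6L, split_cluster = NA, seed = 11L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(simulation_config, defaults)
}

## independent Weir-Cockerham (1984) oracle: literal component-by-component
## transcription of the estimator for two or more diploid groups, computed
## with explicit loops (used to cross-check the package implementation)
wc_theta_oracle <- function(dosage, groups) {
  labs <- sort(unique(groups))
  r <- length(labs)
  suma <- 0; sumabc <- 0
  for (l in seq_len(ncol(dosage))) {
    n_i <- p_i <- h_i <- numeric(r)
    for (t in seq_len(r)) {
      x <- dosage[groups == labs[t], l]
      x <- x[!is.na(x)]
      n_i[t] <- length(x)
      if (length(x)) {
        p_i[t] <- sum(x) / (2 * length(x))
        h_i[t] <- sum(x == 1) / length(x)
      }
    }
    if (any(n_i < 2)) next
    nbar <- sum(n_i) / r
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    suma <- suma + a
    sumabc <- sumabc + a + b + cc
  }
  suma / sumabc
}
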