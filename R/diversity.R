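#' Per-population diversity statistics (Ho, Hs, FIS)
#'
#' Per locus and population with n genotyped diploid individuals:
#' Ho = fraction heterozygous; gene diversity
#' Hs = n/(n-1) * (1 - sum_a p_a^2 - Ho/(2n)) (the small-sample-corrected
#' within-population gene diversity); FIS = 1 - Ho/Hs where Hs > 0. Loci
#' with fewer than 2 genotyped individuals in a population are skipped for
#' that population; per-population averages weight loci by data presence.
#'
#' @param G diploid-coded [genotype_matrix()].
#' @param populations named vector (sample id -> population).
#' @return a `diversity_table` list: `per_locus` (long data.frame), `summary`
#'   (per population: mean Ho, Hs, FIS over usable loci), `overall`.
#' @export
population_diversity <- function(G, populations) {
  if (!all(G$ploidy == 2))
    stop("population_diversity expects a diploid-coded matrix")
  dos <- G$dosage
  pops <- populations[rownames(dos)]
  per <- list()
  for (pop in sort(unique(pops))) {
    rows <- which(pops == pop)
    sub <- dos[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    ho <- colMeans(sub == 1, na.rm = TRUE)
    p <- colMeans(sub, na.rm = TRUE) / 2
    hs <- ifelse(n >= 2,
                 (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * n)),
                 NA_real_)
    fis <- ifelse(!is.na(hs) & hs > 0, 1 - ho / hs, NA_real_)
    usable <- n >= 2
    per[[pop]] <- data.frame(population = pop, locus = colnames(dos),
                             n = n, Ho = ifelse(usable, ho, NA),
                             Hs = hs, FIS = fis, stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, per)
  rownames(per_locus) <- NULL
  summ <- do.call(rbind, lapply(split(per_locus, per_locus$population),
    function(d) data.frame(population = d$population[1],
                           Ho = mean(d$Ho, na.rm = TRUE),
                           Hs = mean(d$Hs, na.rm = TRUE),
                           FIS = 1 - mean(d$Ho, na.rm = TRUE) /
                             mean(d$Hs, na.rm = TRUE),
                           n_loci = sum(!is.na(d$Hs)),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  overall <- data.frame(Ho = mean(per_locus$Ho, na.rm = TRUE),
                        Hs = mean(per_locus$Hs, na.rm = TRUE))
  overall$FIS <- 1 - overall$Ho / overall$Hs
  structure(list(per_locus = per_locus, summary = summ, overall = overall),
            class = "diversity_table")
}

## Weir & Cockerham (1984) per-locus variance components for one locus.
## freqs p_i, het freqs h_i, sizes n_i over r populations; returns (a, b, c).
wc_components <- function(p_i, h_i, n_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  if (r < 2 || nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham FST between groups
#'
#' Multi-locus theta per group pair as the ratio of sums of the Weir &
#' Cockerham (1984) variance components: theta = sum(a) / sum(a + b + c)
#' over loci. Small negative estimates are reported as computed (estimator
#' property), not truncated. Groups with fewer than 2 genotyped individuals
#' are excluded with a warning. Diploid-coded data only.
#'
#' @param G diploid-coded [genotype_matrix()].
#' @param groups named vector (sample id -> group label).
#' @return an `fst_matrix`: symmetric matrix of theta with zero diagonal.
#' @export
pairwise_fst <- function(G, groups) {
  dos <- G$dosage
  grp <- groups[rownames(dos)]
  labs <- sort(unique(stats::na.omit(grp)))
  sizes <- vapply(labs, function(g) sum(grp == g, na.rm = TRUE), 0L)
  small <- sizes < 2
  if (any(small)) {
    warning("excluding group(s) below minimum size: ",
            paste(labs[small], collapse = ", "))
    labs <- labs[!small]
  }
  if (length(labs) < 2) stop("need at least two groups")
  th <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      th[i, j] <- th[j, i] <- wc_theta_pair(dos, grp, labs[c(i, j)])
    }
  }
  structure(th, class = c("fst_matrix", "matrix"))
}

wc_theta_pair <- function(dos, grp, pair) {
  suma <- 0; sumall <- 0
  for (l in seq_len(ncol(dos))) {
    p_i <- numeric(2); h_i <- numeric(2); n_i <- numeric(2)
    for (t in 1:2) {
      x <- dos[grp == pair[t] & !is.na(grp), l]
      x <- x[!is.na(x)]
      n_i[t] <- length(x)
      if (n_i[t] > 0) {
        p_i[t] <- mean(x) / 2
        h_i[t] <- mean(x == 1)
      }
    }
    if (any(n_i < 2)) next
    comp <- wc_components(p_i, h_i, n_i)
    if (anyNA(comp)) next
    suma <- suma + comp["a"]
    sumall <- sumall + sum(comp)
  }
  if (sumall == 0) return(NA_real_)
  unname(suma / sumall)
}

#' Per-individual heterozygosity (method-of-moments F)
#'
#' For each sample over its non-missing loci: observed homozygote count
#' O(Hom); expected homozygote count E(Hom) = sum over loci of
#' (1 - 2 p (1 - p) * 2n/(2n - 1)) with p the overall sample frequency at
#' the locus and n the number of genotyped individuals there; and
#' F = (O(Hom) - E(Hom)) / (N - E(Hom)), N the number of loci used. This is
#' the usual per-individual inbreeding summary extracted from VCF data.
#'
#' @param G diploid-coded [genotype_matrix()].
#' @return data.frame: `id`, `O_hom`, `E_hom`, `N_loci`, `F`, `het_rate`.
#' @export
individual_heterozygosity <- function(G) {
  if (!all(G$ploidy == 2))
    stop("individual_heterozygosity expects a diploid-coded matrix")
  dos <- G$dosage
  nl <- colSums(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  ehom_l <- ifelse(nl >= 2, 1 - 2 * p * (1 - p) * (2 * nl) / (2 * nl - 1),
                   NA_real_)
  out <- data.frame(id = rownames(dos), O_hom = NA_real_, E_hom = NA_real_,
                    N_loci = NA_integer_, F = NA_real_, het_rate = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dos))) {
    ok <- !is.na(dos[i, ]) & !is.na(ehom_l)
    N <- sum(ok)
    if (!N) next
    ohom <- sum(dos[i, ok] != 1)
    ehom <- sum(ehom_l[ok])
    out$O_hom[i] <- ohom
    out$E_hom[i] <- ehom
    out$N_loci[i] <- N
    out$F[i] <- if (abs(N - ehom) > 1e-12) (ohom - ehom) / (N - ehom) else NA
    out$het_rate[i] <- 1 - ohom / N
  }
  out
}
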