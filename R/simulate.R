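#' Simulation configuration for mixed-ploidy SNP datasets
#'
#' Builds and validates the configuration driving [simulate_dataset()]. The
#' defaults emulate the sampling design of the shrub-birch study the package
#' is built around: five genetic clusters (two large diploid dwarf-birch
#' groups, a small hybrid group, one tetraploid cluster and a geographically
#' split northern cluster), targeted amplicon sequencing at a mean depth of
#' 24x, a pool of 20 chloroplast haplotypes partially shared across clusters,
#' clonal duplicates, and 29 sampling teams spread over populations nested
#' within clusters.
#'
#' @param n_clusters number of source clusters (K).
#' @param sizes integer vector of per-cluster sample counts.
#' @param ploidy integer vector in \{2,3,4,5\}, per-cluster ploidy.
#' @param F_k per-cluster divergence (Balding-Nichols F), each in (0,1).
#' @param n_nuclear_sites,n_cp_sites number of nuclear / chloroplast SNPs.
#' @param mean_depth mean sequencing depth (reads).
#' @param depth_dispersion negative-binomial size parameter for per-site
#'   depth; `Inf` gives fixed depth `mean_depth`.
#' @param read_overdispersion beta-binomial concentration for allele-specific
#'   read counts; `Inf` gives pure binomial reads.
#' @param sequencing_error per-read error rate pulling homozygote allelic
#'   ratios off 0 and 1.
#' @param missing_rate MCAR probability that a genotype cell is missing.
#' @param hybrids list of hybrid specs, each
#'   `list(clusters = <2 or 3 cluster indices>, admixture = <weights summing
#'   to 1>, n = <count>)`; hybrid samples are appended after the pure
#'   clusters.
#' @param clones `list(n = <count>, error = <per-locus dosage error rate>)`;
#'   clonal copies of randomly chosen parents, appended last.
#' @param cp_pool_size number of distinct chloroplast haplotypes in the pool.
#' @param cp_share_prob probability that a haplotype is shared by a second
#'   cluster (chloroplast capture).
#' @param n_teams number of sampling teams.
#' @param n_populations total number of populations (nested within clusters).
#' @param team_span_frac fraction of teams whose populations span >= 2
#'   clusters.
#' @param split_cluster index of the cluster split across the "Alaska" and
#'   "Europe" regions (NA for none); all other samples are labelled "Canada".
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_clusters = 5,
                              sizes = c(198, 109, 10, 127, 25),
                              ploidy = c(2, 2, 2, 4, 2),
                              F_k = c(0.15, 0.15, 0.2, 0.35, 0.4),
                              n_nuclear_sites = 1000,
                              n_cp_sites = 85,
                              mean_depth = 24,
                              depth_dispersion = 10,
                              read_overdispersion = 500,
                              sequencing_error = 0.005,
                              missing_rate = 0.03,
                              hybrids = list(
                                list(clusters = c(1, 2), admixture = c(0.5, 0.5), n = 10),
                                list(clusters = c(1, 2, 4), admixture = rep(1/3, 3), n = 14)
                              ),
                              clones = list(n = 10, error = 0.005),
                              cp_pool_size = 20,
                              cp_share_prob = 0.3,
                              n_teams = 29,
                              n_populations = 40,
                              team_span_frac = 0.4,
                              split_cluster = 5,
                              seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters), sizes = as.integer(sizes),
              ploidy = as.integer(ploidy), F_k = F_k,
              n_nuclear_sites = as.integer(n_nuclear_sites),
              n_cp_sites = as.integer(n_cp_sites), mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              read_overdispersion = read_overdispersion,
              sequencing_error = sequencing_error, missing_rate = missing_rate,
              hybrids = hybrids, clones = clones,
              cp_pool_size = as.integer(cp_pool_size),
              cp_share_prob = cp_share_prob, n_teams = as.integer(n_teams),
              n_populations = as.integer(n_populations),
              team_span_frac = team_span_frac, split_cluster = split_cluster,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  k <- cfg$n_clusters
  stopifnot(k >= 1,
            length(cfg$sizes) == k, all(cfg$sizes >= 0),
            length(cfg$ploidy) == k, all(cfg$ploidy %in% 2:5),
            length(cfg$F_k) == k, all(cfg$F_k > 0), all(cfg$F_k < 1),
            cfg$mean_depth > 0, cfg$n_nuclear_sites >= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$sequencing_error >= 0, cfg$sequencing_error < 0.5)
  for (h in cfg$hybrids) {
    if (any(h$clusters > k) || any(h$clusters < 1))
      stop("hybrid spec references unknown cluster")
    if (length(h$admixture) != length(h$clusters))
      stop("hybrid admixture vector length must match its cluster set")
    if (abs(sum(h$admixture) - 1) > 1e-8)
      stop("hybrid admixture vector must sum to 1")
  }
  invisible(cfg)
}

## run expr under a local, seeded RNG stream without disturbing the caller's
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate allele-specific read counts at heterozygous sites
#'
#' Draws per-site (ref, alt) read pairs for one individual of known ploidy.
#' Sites are heterozygous by construction: the alternate-allele dosage is
#' uniform on \{1, ..., ploidy - 1\}, so the expected allelic ratio at a site
#' is dosage/ploidy (0.5 for diploids; 1/3 and 2/3 for triploids; 0.25, 0.5,
#' 0.75 for tetraploids; 0.2, 0.4, 0.6, 0.8 for pentaploids). Total depth is
#' negative-binomial with mean `mean_depth` (fixed depth when
#' `depth_dispersion = Inf`); alternate counts are beta-binomial centred on
#' the dosage ratio, with `error` pulling ratios slightly toward 0.5.
#'
#' @param ploidy 2, 3, 4 or 5.
#' @param n_sites number of heterozygous sites.
#' @param mean_depth mean total depth per site.
#' @param overdispersion beta-binomial concentration (`Inf` = binomial).
#' @param error per-read sequencing error rate.
#' @param seed optional seed (local RNG stream).
#' @param depth_dispersion negative-binomial size (`Inf` = fixed depth).
#' @return data.frame with columns `ref`, `alt`, `depth`, `dosage`.
#' @export
simulate_allelic_depths <- function(ploidy, n_sites, mean_depth = 24,
                                    overdispersion = 500, error = 0.005,
                                    seed = NULL, depth_dispersion = 10) {
  if (!ploidy %in% 2:5) stop("ploidy must be in {2,3,4,5}")
  run <- function() {
    dosage <- sample(seq_len(ploidy - 1), n_sites, replace = TRUE)
    depth <- if (is.infinite(depth_dispersion)) rep(as.integer(mean_depth), n_sites)
             else stats::rnbinom(n_sites, mu = mean_depth, size = depth_dispersion)
    p <- dosage / ploidy
    pe <- p * (1 - error) + (1 - p) * error
    pp <- if (is.infinite(overdispersion)) pe
          else stats::rbeta(n_sites, pe * overdispersion, (1 - pe) * overdispersion)
    alt <- stats::rbinom(n_sites, depth, pp)
    data.frame(ref = depth - alt, alt = alt, depth = depth, dosage = dosage)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## beta-binomial read draw used for whole-matrix simulation
rbetabinom_mat <- function(depth, p, conc, error) {
  pe <- p * (1 - error) + (1 - p) * error
  pp <- if (is.infinite(conc)) pe
        else stats::rbeta(length(pe), pe * conc, (1 - pe) * conc)
  stats::rbinom(length(depth), depth, pp)
}

#' Simulate a mixed-ploidy multi-species SNP dataset with known truth
#'
#' Nuclear model: per-locus ancestral frequencies are uniform on
#' (0.05, 0.95); cluster frequencies follow the Balding-Nichols beta with
#' parameters (p(1-F)/F, (1-p)(1-F)/F); individual alternate dosages are
#' binomial in the ploidy with success probability equal to the
#' admixture-weighted cluster frequency; read depths are negative-binomial
#' and alternate read counts beta-binomial centred on dosage/ploidy.
#' Chloroplast haplotypes are drawn per cluster from a shared pool with
#' configurable cross-cluster sharing (chloroplast capture) and inherited
#' maternally by clones and hybrids. Clonal copies duplicate a parent's
#' genotypes with independent per-locus error. Deterministic given
#' `config$seed`.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return a `synthetic_dataset` list: `samples` (truth table), `ad`
#'   (nuclear [allele_depth_matrix]), `genotypes` (true nuclear dosages),
#'   `cp` (haploid chloroplast dosage matrix with NAs), `cluster_freqs`
#'   (true K x L allele frequencies), `cp_pool` (haplotype strings),
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  K <- cfg$n_clusters
  L <- cfg$n_nuclear_sites

  ## ---- truth table scaffolding -------------------------------------------
  n_pure <- sum(cfg$sizes)
  cluster_of <- rep(seq_len(K), cfg$sizes)
  ploidy_of <- cfg$ploidy[cluster_of]
  Qtruth <- matrix(0, n_pure, K)
  Qtruth[cbind(seq_len(n_pure), cluster_of)] <- 1

  for (h in cfg$hybrids) {
    q <- numeric(K); q[h$clusters] <- h$admixture
    Qtruth <- rbind(Qtruth, matrix(q, h$n, K, byrow = TRUE))
    cluster_of <- c(cluster_of, rep(NA_integer_, h$n))
    ## hybrid ploidy: ploidy of the first (maternal) parent cluster
    ploidy_of <- c(ploidy_of, rep(cfg$ploidy[h$clusters[1]], h$n))
  }
  n_main <- nrow(Qtruth)

  ## ---- nuclear frequencies and dosages -----------------------------------
  p_anc <- stats::runif(L, 0.05, 0.95)
  freqs <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    Fk <- cfg$F_k[k]
    freqs[k, ] <- stats::rbeta(L, p_anc * (1 - Fk) / Fk,
                               (1 - p_anc) * (1 - Fk) / Fk)
  }
  pi_mat <- Qtruth %*% freqs                       # n_main x L
  dosage <- matrix(stats::rbinom(n_main * L, rep(ploidy_of, L), pi_mat),
                   n_main, L)

  ## ---- clones -------------------------------------------------------------
  n_cl <- if (is.null(cfg$clones)) 0L else as.integer(cfg$clones$n)
  clone_of <- rep(NA_integer_, n_main)
  if (n_cl > 0) {
    parents <- sample(which(!is.na(cluster_of)), n_cl, replace = n_cl > n_main)
    err <- cfg$clones$error
    for (p in parents) {
      row <- dosage[p, ]
      if (err > 0) {
        flip <- stats::runif(L) < err
        ## per-locus error: redraw the dosage uniformly among valid values
        row[flip] <- vapply(which(flip), function(l)
          sample(0:ploidy_of[p], 1L), 0L)
      }
      dosage <- rbind(dosage, row)
      Qtruth <- rbind(Qtruth, Qtruth[p, ])
      cluster_of <- c(cluster_of, cluster_of[p])
      ploidy_of <- c(ploidy_of, ploidy_of[p])
      clone_of <- c(clone_of, p)
    }
  }
  n <- nrow(dosage)
  ids <- sprintf("S%03d", seq_len(n))
  rownames(dosage) <- ids

  ## ---- read depths --------------------------------------------------------
  depth <- matrix(
    if (is.infinite(cfg$depth_dispersion)) as.integer(cfg$mean_depth)
    else stats::rnbinom(n * L, mu = cfg$mean_depth, size = cfg$depth_dispersion),
    n, L)
  alt <- matrix(rbetabinom_mat(depth, dosage / ploidy_of,  # recycles by column
                               cfg$read_overdispersion, cfg$sequencing_error),
                n, L)
  miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
  depth[miss] <- 0L
  alt[miss] <- 0L

  sites <- data.frame(compartment = "nuclear", chrom = "chr1",
                      pos = seq_len(L) * 10L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  ad <- allele_depth_matrix(samples = ids, sites = sites,
                            depth = depth, alt_depth = alt)

  ## ---- chloroplast ---------------------------------------------------------
  ## haplotype pool on a random genealogy under infinite sites: each site
  ## mutates exactly once on one branch, so sites on the same branch carry
  ## identical presence patterns (the redundancy the informative-SNP
  ## collapse removes) and every pool haplotype is distinct
  n_pool <- min(cfg$cp_pool_size, cfg$n_cp_sites + 1L)
  hap_mat <- matrix(0L, n_pool, cfg$n_cp_sites)
  if (n_pool > 1) {
    branch_of <- c(2:n_pool,
                   sample(rep(2:n_pool, 2), cfg$n_cp_sites - (n_pool - 1L),
                          replace = TRUE))
    branch_of <- branch_of[sample.int(cfg$n_cp_sites)]
    for (j in 2:n_pool) {
      parent <- if (j == 2) 1L else sample.int(j - 1L, 1L)
      hap_mat[j, ] <- hap_mat[parent, ]
      flip <- branch_of == j
      hap_mat[j, flip] <- 1L - hap_mat[j, flip]
    }
  }
  pool <- apply(hap_mat, 1, paste, collapse = "")
  home <- sample(seq_len(K), n_pool, replace = TRUE)
  carriers <- lapply(seq_len(n_pool), function(h) {
    cl <- home[h]
    if (K > 1 && stats::runif(1) < cfg$cp_share_prob)
      cl <- c(cl, sample(setdiff(seq_len(K), cl), 1L))
    cl
  })
  hap_sets <- lapply(seq_len(K), function(k)
    which(vapply(carriers, function(cl) k %in% cl, TRUE)))
  ## every cluster needs at least one haplotype
  for (k in seq_len(K)) if (!length(hap_sets[[k]])) {
    h <- sample(seq_len(n_pool), 1L)
    carriers[[h]] <- union(carriers[[h]], k)
    hap_sets[[k]] <- union(hap_sets[[k]], h)
  }
  maternal <- ifelse(is.na(cluster_of),
                     vapply(seq_len(n), function(i) which.max(Qtruth[i, ]), 0L),
                     cluster_of)
  hap_of <- vapply(seq_len(n), function(i)
    if (!is.na(clone_of[i])) NA_integer_
    else sample(hap_sets[[maternal[i]]], 1L), 0L)
  hap_of[!is.na(clone_of)] <- hap_of[clone_of[!is.na(clone_of)]]
  cp <- hap_mat[hap_of, , drop = FALSE]
  ## organellar missingness is a per-sample dropout (failed amplicons), not
  ## per-cell noise: affected samples lose about half their cp sites
  dropout <- stats::runif(n) < cfg$missing_rate
  for (i in which(dropout))
    cp[i, stats::runif(cfg$n_cp_sites) < 0.5] <- NA_integer_
  rownames(cp) <- ids
  colnames(cp) <- sprintf("cp_%d", seq_len(cfg$n_cp_sites))

  ## ---- populations, teams, regions ----------------------------------------
  npop <- max(cfg$n_populations, K)
  pop_cluster <- rep(seq_len(K), length.out = npop)[order(rep(seq_len(K), length.out = npop))]
  ## allocate populations to clusters proportionally to cluster sizes
  alloc <- pmax(1L, round(npop * cfg$sizes / sum(cfg$sizes)))
  while (sum(alloc) > npop) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < npop) alloc[which.max(cfg$sizes)] <- alloc[which.max(cfg$sizes)] + 1L
  pop_cluster <- rep(seq_len(K), alloc)
  pop_ids <- sprintf("P%02d", seq_len(npop))

  pop_of <- vapply(seq_len(n), function(i) {
    cl <- maternal[i]
    sample(rep(which(pop_cluster == cl), 2L), 1L)
  }, 0L)
  pop_of[!is.na(clone_of)] <- pop_of[clone_of[!is.na(clone_of)]]

  ## teams own populations; the first n_span teams get two populations from
  ## different clusters, the rest stay within one cluster
  n_span <- if (K > 1) round(cfg$team_span_frac * cfg$n_teams) else 0L
  pop_team <- rep(NA_integer_, npop)
  for (tm in seq_len(n_span)) {
    open <- which(vapply(seq_len(K), function(k)
      any(is.na(pop_team[pop_cluster == k])), TRUE))
    if (length(open) < 2) break
    cls <- sample(open, 2L)       # two distinct clusters (length(open) >= 2)
    for (cl in cls) {
      cand <- which(pop_cluster == cl & is.na(pop_team))
      pop_team[sample(rep(cand, 2L), 1L)] <- tm
    }
  }
  ## remaining populations: deal cluster by cluster to the remaining teams
  tm_next <- n_span + 1L
  for (k in sample(seq_len(K))) {
    left <- which(pop_cluster == k & is.na(pop_team))
    while (length(left)) {
      tm <- if (tm_next <= cfg$n_teams) tm_next else
        sample(rep(seq_len(max(n_span, 1L)), 2L), 1L)  # wrap to span teams
      pop_team[left[1L]] <- tm
      left <- left[-1L]
      tm_next <- tm_next + 1L
    }
  }
  team_of <- pop_team[pop_of]

  region_of_pop <- rep("Canada", npop)
  if (!is.na(cfg$split_cluster) && cfg$split_cluster <= K) {
    sp <- which(pop_cluster == cfg$split_cluster)
    if (length(sp)) {
      half <- seq_len(ceiling(length(sp) / 2))
      region_of_pop[sp[half]] <- "Alaska"
      region_of_pop[sp[-half]] <- "Europe"
    }
  }

  species_names <- sprintf("cluster%d", seq_len(K))
  samples <- data.frame(
    id = ids,
    population = pop_ids[pop_of],
    team = sprintf("T%02d", team_of),
    region = region_of_pop[pop_of],
    true_cluster = ifelse(is.na(cluster_of), "hybrid", species_names[cluster_of]),
    true_ploidy = ploidy_of,
    clone_of = ifelse(is.na(clone_of), NA_character_, ids[clone_of]),
    cp_haplotype = hap_of,
    stringsAsFactors = FALSE)

  structure(list(samples = samples, ad = ad, genotypes = dosage, cp = cp,
                 cluster_freqs = freqs, Q_truth = Qtruth, cp_pool = pool,
                 cp_carriers = carriers, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic mixed-ploidy dataset: %d samples, %d nuclear sites, %d cp sites\n",
              nrow(x$samples), ncol(x$genotypes), ncol(x$cp)))
  print(table(x$samples$true_cluster, x$samples$true_ploidy))
  invisible(x)
}
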