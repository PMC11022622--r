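test_that("diversity statistics reproduce hand-derived cases", {
  ## 10 individuals all heterozygous at one locus:
  ## Ho = 1, Hs = (10/9)(1 - 0.5 - 0.05) = 0.5, FIS = 1 - 1/0.5 = -1
  G <- make_gm(matrix(1L, 10, 1))
  d <- population_diversity(G, stats::setNames(rep("p1", 10), rownames(G$dosage)))
  expect_equal(d$per_locus$Ho, 1)
  expect_equal(d$per_locus$Hs, 0.5)
  expect_equal(d$per_locus$FIS, -1)
  ## monomorphic locus: Ho = Hs = 0, FIS undefined
  G0 <- make_gm(matrix(0L, 10, 1))
  d0 <- population_diversity(G0, stats::setNames(rep("p1", 10), rownames(G0$dosage)))
  expect_equal(d0$per_locus$Ho, 0)
  expect_equal(d0$per_locus$Hs, 0)
  expect_true(is.na(d0$per_locus$FIS))
  ## non-diploid provenance is rejected
  G4 <- make_gm(matrix(1L, 4, 1), ploidy = rep(4L, 4))
  expect_error(population_diversity(G4, stats::setNames(rep("p", 4), rownames(G4$dosage))),
               "diploid")
})

test_that("a large panmictic population has FIS near zero", {
  set.seed(30)
  n <- 500; L <- 1000
  p <- runif(L, 0.1, 0.9)
  dos <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  G <- make_gm(dos)
  d <- population_diversity(G, stats::setNames(rep("pop", n), rownames(G$dosage)))
  expect_lt(abs(d$overall$FIS), 0.02)
  ## and Ho >= Hs implies FIS <= 0 on the summary scale
  expect_equal(sign(d$overall$FIS), sign(d$overall$Hs - d$overall$Ho) * 1)
})

test_that("pairwise FST behaves at the calibration endpoints", {
  set.seed(31)
  ## one panmictic pool split arbitrarily in two: theta ~ 0
  n <- 200; L <- 1000
  p <- runif(L, 0.1, 0.9)
  dos <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  G <- make_gm(dos)
  grp <- stats::setNames(rep(c("x", "y"), each = n / 2), rownames(G$dosage))
  fst <- pairwise_fst(G, grp)
  expect_lt(abs(fst["x", "y"]), 0.01)
  expect_equal(unname(diag(fst)), c(0, 0))
  ## fixed alternative alleles: theta = 1
  dfix <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  Gf <- make_gm(dfix)
  grpf <- stats::setNames(rep(c("x", "y"), each = 10), rownames(Gf$dosage))
  expect_equal(unname(pairwise_fst(Gf, grpf)["x", "y"]), 1)
})

test_that("package FST equals the brute-force Weir-Cockerham oracle exactly", {
  ## fixed printed toy table: 2 populations x 10 diploids x 6 loci
  dos <- rbind(
    c(0L, 1L, 2L, 1L, 0L, 1L), c(1L, 1L, 2L, 0L, 0L, 2L),
    c(0L, 2L, 1L, 1L, 1L, 1L), c(1L, 1L, 2L, 1L, 0L, 1L),
    c(0L, 1L, 1L, 2L, 0L, 0L), c(0L, 0L, 2L, 1L, 1L, 1L),
    c(1L, 1L, 1L, 1L, 0L, 2L), c(0L, 1L, 2L, 0L, 0L, 1L),
    c(0L, 2L, 2L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L, 0L, 1L),
    c(2L, 0L, 0L, 1L, 2L, 1L), c(2L, 1L, 0L, 2L, 1L, 0L),
    c(1L, 0L, 1L, 1L, 2L, 0L), c(2L, 0L, 0L, 1L, 2L, 1L),
    c(2L, 1L, 0L, 1L, 1L, 0L), c(1L, 0L, 0L, 2L, 2L, 1L),
    c(2L, 0L, 1L, 1L, 2L, 0L), c(2L, 1L, 0L, 1L, 1L, 0L),
    c(1L, 0L, 0L, 1L, 2L, 1L), c(2L, 0L, 0L, 2L, 2L, 0L))
  G <- make_gm(dos)
  grp <- stats::setNames(rep(c("pop1", "pop2"), each = 10), rownames(G$dosage))
  want <- wc_theta_oracle(dos, rep(c("pop1", "pop2"), each = 10))
  got <- pairwise_fst(G, grp)["pop1", "pop2"]
  expect_equal(got, want, tolerance = 1e-10)
  ## and with missing data sprinkled in
  set.seed(32)
  dos_na <- dos
  dos_na[sample(length(dos), 15)] <- NA
  Gna <- make_gm(dos_na)
  expect_equal(pairwise_fst(Gna, grp)["pop1", "pop2"],
               wc_theta_oracle(dos_na, rep(c("pop1", "pop2"), each = 10)),
               tolerance = 1e-10)
})

test_that("FST increases with the simulated divergence parameter", {
  thetas <- vapply(c(0.05, 0.2, 0.5), function(f) {
    sim <- simulate_dataset(small_config(sizes = c(50L, 50L),
                                         n_nuclear_sites = 800L,
                                         F_k = c(f, f), seed = 19L))
    G <- make_gm(sim$genotypes)
    grp <- stats::setNames(sim$samples$true_cluster, sim$samples$id)
    pairwise_fst(G, grp)["cluster1", "cluster2"]
  }, 0)
  expect_true(all(diff(thetas) > 0))
})

test_that("per-individual heterozygosity has the documented directions", {
  set.seed(33)
  n <- 30; L <- 200
  dos <- matrix(rbinom(n * L, 2, 0.5), n, L)
  dos[1, ] <- 1L                      # fully heterozygous
  dos[2, ] <- ifelse(rbinom(L, 1, 0.5) == 1, 2L, 0L)  # fully homozygous
  dos[3, ] <- dos[4, ] <- dos[5, ]    # identical pair
  G <- make_gm(dos)
  h <- individual_heterozygosity(G)
  expect_equal(h$O_hom[1], 0)
  expect_lt(h$F[1], 0)
  expect_gt(h$F[2], 0)
  expect_equal(h$F[3], h$F[4])
  expect_equal(h$het_rate[1], 1)
})

test_that("the tetraploid-like cluster shows elevated individual heterozygosity", {
  ## diploid-coded genotypes of a tetraploid cluster carry more heterozygotes
  sim <- simulate_dataset(small_config(
    n_clusters = 3L, sizes = c(40L, 40L, 40L), ploidy = c(2L, 2L, 4L),
    F_k = c(0.15, 0.15, 0.3), n_nuclear_sites = 500L, seed = 35L))
  G <- make_gm(code_diploid(sim$genotypes, sim$samples$true_ploidy))
  h <- individual_heterozygosity(G)
  grp <- sim$samples$true_cluster
  het4 <- mean(h$het_rate[grp == "cluster3"])
  het2 <- mean(h$het_rate[grp %in% c("cluster1", "cluster2")])
  expect_gt(het4, het2)
})
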