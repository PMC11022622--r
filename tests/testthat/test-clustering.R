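test_that("genotype PCA has the standard decomposition properties", {
  set.seed(20)
  dos <- matrix(sample(0:2, 40 * 100, replace = TRUE), 40, 100)
  dos[sample(length(dos), 200)] <- NA
  pca <- pca_genotypes(make_gm(dos))
  ## total variance equals the sum of the eigenvalues
  X <- dos
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  expect_equal(sum(pca$eigenvalues), sum(apply(X, 2, stats::var)))
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  ## duplicated samples land on identical scores
  dos2 <- rbind(dos[1, ], dos)
  pca2 <- pca_genotypes(make_gm(dos2))
  expect_equal(unname(pca2$scores[1, ]), unname(pca2$scores[2, ]))
  expect_error(pca_genotypes(make_gm(dos[1, , drop = FALSE])), "2 samples")
})

test_that("PC1 separates two diverged clusters almost perfectly", {
  sim <- simulate_dataset(small_config(sizes = c(40L, 40L), F_k = c(0.3, 0.3),
                                       n_nuclear_sites = 500L, seed = 17L))
  pca <- pca_genotypes(make_gm(sim$genotypes))
  pc1 <- pca$scores[, 1]
  grp <- sim$samples$true_cluster
  thr <- mean(c(mean(pc1[grp == "cluster1"]), mean(pc1[grp == "cluster2"])))
  side <- (pc1 > thr)
  acc <- max(mean(side == (grp == "cluster1")),
             mean(side == (grp == "cluster2")))
  expect_gte(acc, 0.99)
})

test_that("BIC scan recovers well-separated blobs and respects kmax", {
  set.seed(21)
  scores <- rbind(matrix(rnorm(30 * 20, 0), 30, 20),
                  matrix(rnorm(30 * 20, 6), 30, 20))
  scan <- kmeans_bic_scan(scores, kmax = 10, seed = 2)
  expect_equal(scan$selected_k, 2L)
  expect_true(all(scan$k <= 10))
  expect_true(all(is.finite(scan$bic)))
  ## force_k overrides the BIC argmin
  scan5 <- kmeans_bic_scan(scores, kmax = 10, seed = 2, force_k = 5)
  expect_equal(scan5$selected_k, 5L)
  expect_true(scan5$overridden)
  expect_error(kmeans_bic_scan(scores[1:3, ], kmax = 30), "kmax")
})

test_that("a-score is near zero under the null and positive for real groups", {
  set.seed(22)
  noise <- matrix(rnorm(80 * 20), 80, 20)
  rand_lab <- sample(rep(1:2, 40))
  a0 <- a_score(noise, rand_lab, n_pcs_grid = c(2, 5, 10), seed = 3)
  expect_true(all(abs(a0$a_scores) < 0.2))
  sep <- rbind(matrix(rnorm(40 * 20, 0), 40, 20),
               matrix(rnorm(40 * 20, 4), 40, 20))
  a1 <- a_score(sep, rep(1:2, each = 40), n_pcs_grid = c(2, 5, 10), seed = 3)
  expect_true(max(a1$a_scores, na.rm = TRUE) > 0.2)
  expect_true(a1$optimal_n_pcs %in% c(2, 5, 10))
  expect_error(a_score(noise, rep(1, 80)), "two groups")
})

test_that("DAPC memberships are proper and reassignment is accurate", {
  sim <- simulate_dataset(small_config(
    n_clusters = 5L, sizes = c(40L, 25L, 10L, 30L, 15L),
    ploidy = c(2L, 2L, 2L, 4L, 2L), F_k = c(0.15, 0.15, 0.2, 0.35, 0.4),
    n_nuclear_sites = 800L, seed = 23L))
  G <- make_gm(code_diploid(sim$genotypes, sim$samples$true_ploidy))
  pca <- pca_genotypes(G)
  truth <- factor(sim$samples$true_cluster)
  fit <- dapc_fit(pca$scores, truth, n_pcs = 40)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, nrow(pca$scores)))
  expect_true(all(diff(fit$percent_variance) <= 1e-8))
  expect_lte(sum(fit$percent_variance), 100 + 1e-8)
  expect_gte(mean(fit$assigned == as.character(truth)), 0.95)
  ## two groups give exactly one discriminant axis
  fit2 <- dapc_fit(pca$scores, truth == "cluster4", n_pcs = 10)
  expect_equal(ncol(fit2$coords), 1L)
})

test_that("EM admixture: K=1 closed form, monotone lnL, label symmetry", {
  sim <- simulate_dataset(small_config(seed = 25L, n_nuclear_sites = 300L))
  G <- make_gm(sim$genotypes)
  r1 <- admixture_em(G, K = 1)
  dos <- G$dosage
  p_pool <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  expect_equal(as.numeric(r1$F), unname(p_pool), tolerance = 1e-12)
  expect_true(all(r1$Q == 1))
  r2 <- admixture_em(G, K = 2, seed = 7, n_restarts = 2, max_iter = 200)
  expect_true(all(diff(r2$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(r2$Q)), rep(1, nrow(dos)))
  expect_true(all(r2$F >= 0 & r2$F <= 1))
  ## different seeds agree up to cluster relabelling (matched on F)
  r2b <- admixture_em(G, K = 2, seed = 8, n_restarts = 2, max_iter = 200)
  d_direct <- mean(abs(r2$F - r2b$F))
  d_swap <- mean(abs(r2$F - r2b$F[2:1, ]))
  perm <- if (d_swap < d_direct) 2:1 else 1:2
  expect_lt(mean(abs(r2$Q - r2b$Q[, perm])), 0.05)
})

test_that("EM admixture recovers simulated ancestry proportions", {
  sim <- simulate_dataset(small_config(
    sizes = c(50L, 50L), n_nuclear_sites = 1000L, seed = 26L,
    hybrids = list(list(clusters = c(1, 2), admixture = c(0.5, 0.5), n = 10L))))
  G <- make_gm(sim$genotypes)
  res <- admixture_em(G, K = 2, seed = 5, n_restarts = 3, max_iter = 300)
  Qt <- sim$Q_truth
  mae <- min(mean(abs(res$Q - Qt)), mean(abs(res$Q[, 2:1] - Qt)))
  expect_lt(mae, 0.1)
})

test_that("Evanno delta-K matches direct formula evaluation", {
  ## hand table: mean L(1..3) = (-100, -50, -45), sd(L(2)) = 2
  runs <- data.frame(K = rep(1:3, each = 2),
                     replicate = rep(1:2, 3),
                     lnP = c(-100, -100,
                             -50 + sqrt(2), -50 - sqrt(2),
                             -45, -45))
  dk <- evanno_delta_k(runs)
  expect_equal(dk$delta_K[dk$K == 2], 22.5, tolerance = 1e-9)
  expect_true(all(is.na(dk$delta_K[dk$K %in% c(1, 3)])))
  ## exactly linear mean L -> interior delta-K ~ 0
  set.seed(27)
  lin <- data.frame(K = rep(1:4, each = 3), replicate = rep(1:3, 4))
  lin$lnP <- -200 + 10 * lin$K
  expect_equal(evanno_delta_k(lin)$delta_K[2:3], c(NA_real_, NA_real_)) # sd 0
  ## randomized tables match an independent brute-force evaluation
  for (i in 1:5) {
    tab <- data.frame(K = rep(1:5, each = 4), replicate = rep(1:4, 5))
    tab$lnP <- rnorm(20, -500 + 30 * tab$K, 5)
    got <- evanno_delta_k(tab)
    for (k in 2:4) {
      l <- function(kk) tab$lnP[tab$K == kk]
      want <- mean(abs(l(k + 1) - 2 * l(k) + l(k - 1))) / stats::sd(l(k))
      expect_equal(got$delta_K[got$K == k], want, tolerance = 1e-12)
    }
  }
  expect_error(evanno_delta_k(data.frame(K = c(1, 3), replicate = 1,
                                         lnP = c(-1, -2))), "contiguous")
})

test_that("lineage assignment applies the Q threshold and geographic split", {
  Q <- rbind(a = c(0.8, 0.2), b = c(0.6, 0.4), c = c(0.95, 0.05),
             d = c(0.1, 0.9))
  lin <- assign_lineages(Q)
  expect_equal(unname(lin), c("cluster1", "admixed", "cluster1", "cluster2"))
  ## a cluster spanning Alaska and Europe splits into two lineages
  regions <- c(a = "Alaska", b = "Canada", c = "Europe", d = "Canada")
  lin2 <- assign_lineages(Q, regions = regions)
  expect_equal(unname(lin2[c("a", "c")]),
               c("cluster1_Alaska", "cluster1_Europe"))
  expect_equal(unname(lin2["d"]), "cluster2")
  expect_error(assign_lineages(rbind(c(0.5, 0.6))), "sum to 1")
})
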