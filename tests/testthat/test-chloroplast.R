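cp_gm <- function(dos) {
  dos <- as.matrix(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("s%02d", seq_len(nrow(dos)))
  genotype_matrix(dos, stats::setNames(rep(1L, nrow(dos)), rownames(dos)),
                  "chloroplast")
}

test_that("uniquely informative SNP selection collapses redundancy", {
  dos <- cbind(a = c(0L, 0L, 1L, 1L),
               b = c(0L, 0L, 1L, 1L),       # identical to a
               c = c(1L, 1L, 0L, 0L),       # complement of a
               d = c(0L, 1L, 0L, 1L))       # distinct partition
  keep <- informative_cp_snps(cp_gm(dos))
  expect_length(keep, 2L)
  expect_true(4 %in% keep)
  expect_length(intersect(keep, 1:3), 1L)   # a, b, c collapse to one site
  ## a site with 50% missing data is dropped at the default 10% cap
  dos2 <- cbind(dos, e = c(NA, NA, 0L, 1L))
  expect_identical(informative_cp_snps(cp_gm(dos2)), keep)
  ## among redundant sites the least-missing one is kept
  dos3 <- cbind(a = c(0L, NA, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L),
                b = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L))
  expect_equal(informative_cp_snps(cp_gm(dos3)), 2L)
  expect_error(informative_cp_snps(cp_gm(matrix(c(NA, 0L, NA, 1L), 2, 2))),
               "no chloroplast sites")
})

test_that("informative-site selection is idempotent", {
  set.seed(40)
  dos <- matrix(sample(c(0L, 1L, NA), 30 * 25, replace = TRUE,
                       prob = c(0.48, 0.48, 0.04)), 30, 25)
  G <- cp_gm(dos)
  k1 <- informative_cp_snps(G)
  G2 <- cp_gm(dos[, k1, drop = FALSE])
  k2 <- informative_cp_snps(G2)
  expect_equal(k1[k2], k1)                   # re-running keeps every site
  expect_length(k2, length(k1))
})

test_that("haplotypes concatenate retained sites with an all-or-nothing rule", {
  dos <- rbind(s1 = c(0L, 1L, 1L),
               s2 = c(0L, 1L, 1L),           # same string as s1
               s3 = c(0L, 1L, 0L),           # differs at site 3
               s4 = c(0L, NA, 1L))           # missing a retained site
  H <- cp_haplotypes(cp_gm(dos), 1:3)
  expect_equal(H$hap_id[1], H$hap_id[2])
  expect_false(H$hap_id[1] == H$hap_id[3])
  expect_true(is.na(H$haplotype[4]) && is.na(H$hap_id[4]))
  ## letters rank by frequency: the duplicated string gets "A"
  expect_equal(H$hap_id[1], "A")
  expect_equal(H$haplotype[1], "011")
  expect_error(cp_haplotypes(cp_gm(dos), integer(0)), "empty")
})

test_that("sharing report separates shared from endemic haplotypes", {
  dos <- rbind(s1 = c(0L, 0L), s2 = c(0L, 0L),   # hap X in cluster c1
               s3 = c(0L, 0L),                   # hap X in cluster c2: shared
               s4 = c(1L, 1L), s5 = c(1L, 1L),   # hap Y only in c2: endemic
               s6 = c(0L, NA))                   # no haplotype
  H <- cp_haplotypes(cp_gm(dos), 1:2)
  cl <- stats::setNames(c("c1", "c1", "c2", "c2", "c2", "c1"), rownames(dos))
  pop <- stats::setNames(rep(c("p1", "p2"), 3), rownames(dos))
  rep_out <- haplotype_summary(H, cl, pop)
  tab <- rep_out$haplotypes
  expect_true(tab$shared[tab$hap_id == "A"])     # X spans c1 and c2
  expect_false(tab$shared[tab$hap_id == "B"])
  expect_equal(sum(tab$abundance), 5L)           # all assigned samples
  expect_equal(rep_out$cluster_richness$richness[
    rep_out$cluster_richness$cluster == "c2"], 2L)
})

test_that("simulated cross-cluster sharing is recovered exactly", {
  cfg <- small_config(n_clusters = 3L, sizes = c(30L, 30L, 30L),
                      ploidy = c(2L, 2L, 2L), F_k = rep(0.2, 3),
                      cp_pool_size = 8L, cp_share_prob = 0.5,
                      missing_rate = 0, seed = 44L)
  sim <- simulate_dataset(cfg)
  G <- cp_gm(sim$cp)
  keep <- informative_cp_snps(G)
  H <- cp_haplotypes(G, keep)
  cl <- stats::setNames(sim$samples$true_cluster, sim$samples$id)
  out <- haplotype_summary(H, cl)
  ## truth: clusters actually carrying each simulated haplotype index
  true_carriers <- tapply(cl[sim$samples$id], sim$samples$cp_haplotype,
                          function(x) sort(unique(x)))
  ## haplotype strings are unique in the pool, so ids map 1:1 onto truth
  for (i in seq_len(nrow(out$haplotypes))) {
    samp <- H$id[!is.na(H$hap_id) & H$hap_id == out$haplotypes$hap_id[i]]
    pool_idx <- unique(sim$samples$cp_haplotype[match(samp, sim$samples$id)])
    expect_length(pool_idx, 1L)                # id maps to one true haplotype
    want <- true_carriers[[as.character(pool_idx)]]
    expect_equal(strsplit(out$haplotypes$clusters[i], ",")[[1]], want)
    expect_equal(out$haplotypes$shared[i], length(want) > 1)
  }
})
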