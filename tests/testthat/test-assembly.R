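test_that("sample missingness filter applies the dataset-specific caps", {
  set.seed(10)
  dos <- matrix(sample(0:2, 20 * 100, replace = TRUE), 20, 100)
  dos[1, 1:45] <- NA            # sample 1: 45% missing
  G <- make_gm(dos)
  f40 <- filter_samples_by_missingness(G, 0.40)
  expect_false("s01" %in% rownames(f40$dosage))
  expect_equal(attr(f40, "removed"), 1L)
  f50 <- filter_samples_by_missingness(G, 0.50)
  expect_true("s01" %in% rownames(f50$dosage))
  expect_error(filter_samples_by_missingness(make_gm(matrix(NA_integer_, 2, 4)), 0.4),
               "all samples")
})

test_that("locus filter enforces ploidy-aware MAF and missingness", {
  dos <- cbind(rep(0:1, 50),                   # MAF 0.25, complete
               c(rep(1L, 1), rep(0L, 99)),     # MAF 0.005 -> removed
               c(rep(NA, 35), sample(0:2, 65, replace = TRUE)),  # 35% missing
               rep(0L, 100))                   # monomorphic -> removed
  G <- make_gm(dos)
  out <- filter_loci(G)
  expect_equal(ncol(out$dosage), 1L)
  ## ploidy-aware frequency: tetraploids contribute 4 allele copies
  dos2 <- cbind(c(2L, 2L, 0L, 0L))
  G2 <- make_gm(dos2, ploidy = c(4L, 4L, 2L, 2L))
  out2 <- filter_loci(G2, maf_min = 0.3)
  ## freq = 4 / (4+4+2+2) = 1/3 -> passes at maf 0.3
  expect_equal(ncol(out2$dosage), 1L)
})

test_that("filters are idempotent", {
  set.seed(11)
  dos <- matrix(sample(c(0:2, NA), 30 * 200, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 30, 200)
  G <- make_gm(dos)
  once <- filter_loci(filter_samples_by_missingness(G, 0.4))
  twice <- filter_loci(filter_samples_by_missingness(once, 0.4))
  expect_identical(once$dosage, twice$dosage)
})

test_that("genetic distance is the summed dosage difference over shared loci", {
  dos <- rbind(a = c(0L, 2L, 1L, NA),
               b = c(0L, 2L, 1L, 0L),
               c = c(2L, 0L, NA, 2L))
  D <- genetic_distance_matrix(make_gm(dos))
  expect_equal(D["a", "b"], 0)               # identical on shared loci
  expect_equal(D["a", "c"], 4)               # |0-2| + |2-0|, locus 3/4 unshared
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  ## single locus, dosages 0 vs 2 -> distance 2
  D2 <- genetic_distance_matrix(make_gm(rbind(x = 0L, y = 2L)))
  expect_equal(D2["x", "y"], 2)
})

test_that("matrix-algebra distances equal the brute-force definition", {
  set.seed(12)
  dos <- matrix(sample(c(0:4, NA), 15 * 60, replace = TRUE), 15, 60)
  G <- make_gm(dos, ploidy = rep(4L, 15))
  D <- genetic_distance_matrix(G)
  brute <- matrix(0, 15, 15)
  for (i in 1:14) for (j in (i + 1):15) {
    ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
    brute[i, j] <- brute[j, i] <- sum(abs(dos[i, ok] - dos[j, ok]))
  }
  expect_equal(unname(unclass(D)), brute, ignore_attr = TRUE)
})

test_that("single-linkage clone detection follows chain closure", {
  D <- matrix(c(0, 300, 600,
                300, 0, 300,
                600, 300, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- detect_clones(D, 350)
  expect_length(cl$groups, 1L)               # chain a-b-c joins despite d(a,c)=600
  expect_setequal(cl$groups[[1]], c("a", "b", "c"))
  ## all pairs above threshold: every sample its own genet
  cl2 <- detect_clones(D, 100)
  expect_length(cl2$groups, 3L)
  ## representative has least missing data, ties to smallest id
  cl3 <- detect_clones(D, 350,
                       missing_fraction = c(a = 0.2, b = 0.05, c = 0.3))
  expect_equal(cl3$representative, "b")
})

test_that("injected clones are recovered exactly below the inter-genet distance", {
  cfg <- small_config(clones = list(n = 5L, error = 0), missing_rate = 0,
                      n_nuclear_sites = 400L, seed = 33L)
  sim <- simulate_dataset(cfg)
  G <- make_gm(sim$genotypes)
  D <- genetic_distance_matrix(G)
  ## minimum distance between distinct genets
  truth_pairs <- outer(sim$samples$id, sim$samples$id, function(x, y) {
    px <- ifelse(is.na(sim$samples$clone_of), sim$samples$id,
                 sim$samples$clone_of)[match(x, sim$samples$id)]
    py <- ifelse(is.na(sim$samples$clone_of), sim$samples$id,
                 sim$samples$clone_of)[match(y, sim$samples$id)]
    px == py
  })
  min_between <- min(D[!truth_pairs & upper.tri(D)])
  expect_gt(min_between, 0)
  cl <- detect_clones(D, min_between / 2)
  got <- unname(split(sim$samples$id, cl$assignment[sim$samples$id]))
  want <- unname(split(sim$samples$id,
                       ifelse(is.na(sim$samples$clone_of), sim$samples$id,
                              sim$samples$clone_of)))
  expect_setequal(lapply(got, sort), lapply(want, sort))
  ## threshold 0 groups exactly the zero-mismatch profiles
  cl0 <- detect_clones(D, 0)
  for (g in cl0$groups[lengths(cl0$groups) > 1])
    expect_true(all(D[g, g] == 0))
})

test_that("mixed-ploidy recoding maps every non-diploid call to tetraploid", {
  dos <- matrix(sample(0:2, 4 * 10, replace = TRUE), 4, 10,
                dimnames = list(c("d", "t3", "t4", "u"), NULL))
  G <- make_gm(dos, ploidy = rep(2L, 4))
  calls <- data.frame(id = c("d", "t3", "t4", "u"),
                      label = c("diploid", "triploid", "tetraploid", "unknown"))
  out <- recode_mixed_ploidy(G, calls)
  expect_equal(unname(out$ploidy), c(2L, 4L, 4L, 4L))
  expect_equal(out$provenance, "diploid_tetraploid")
  expect_error(recode_mixed_ploidy(G, calls[-1, ]), "missing ploidy call")
})
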