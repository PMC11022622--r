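test_that("allelic ratios respect the depth floor and boundaries", {
  sites <- data.frame(compartment = "nuclear", chrom = "chr1",
                      pos = 1:3, ref = "A", alt = "T")
  depth <- rbind(s1 = c(24L, 14L, 20L))
  alt <- rbind(s1 = c(12L, 4L, 20L))
  ad <- allele_depth_matrix("s1", sites, depth, alt)
  R <- allelic_ratios(ad)
  expect_equal(unname(R$ratio[1, 1]), 0.5)          # 12 of 24
  expect_true(is.na(R$ratio[1, 2]))         # depth 14 < 15 -> missing
  expect_equal(unname(R$ratio[1, 3]), 1.0)          # 20 of 20
  ## chloroplast sites are rejected
  sites$compartment <- "chloroplast"
  adc <- allele_depth_matrix("s1", sites, depth, alt)
  expect_error(allelic_ratios(adc), "nuclear")
})

test_that("reference-SNP selection applies depth, mode and central-mass rules", {
  set.seed(1)
  n <- 40
  mk_ad <- function(ratios, depth = 30L) {
    k <- length(ratios)
    sites <- data.frame(compartment = "nuclear", chrom = "chr1",
                        pos = seq_len(k), ref = "A", alt = "T")
    d <- matrix(depth, n, k)
    a <- round(sweep(d, 2, ratios, "*"))
    storage.mode(a) <- "integer"
    allele_depth_matrix(sprintf("p%02d", 1:n), sites, d, a)
  }
  ## site 1: clean 0.5; site 2: mode 0.70; site 3: mode 0.5 but wide spread
  sites <- data.frame(compartment = "nuclear", chrom = "chr1",
                      pos = 1:4, ref = "A", alt = "T")
  d <- matrix(30L, n, 4)
  a <- cbind(round(30 * rnorm(n, 0.5, 0.02)),
             round(30 * rnorm(n, 0.70, 0.02)),
             round(30 * c(rnorm(n / 2, 0.5, 0.01), runif(n / 2, 0.07, 0.35))),
             round(30 * rnorm(n, 0.5, 0.02)))
  d[, 4] <- 18L                                 # mean depth below 24
  a[, 4] <- round(18 * rnorm(n, 0.5, 0.02))
  storage.mode(a) <- "integer"
  ad <- allele_depth_matrix(sprintf("p%02d", 1:n), sites, d, a)
  R <- allelic_ratios(ad)
  keep <- select_reference_snps(R, sprintf("p%02d", 1:n))
  expect_true(1 %in% keep)                      # satisfies all criteria
  expect_false(2 %in% keep)                     # mode outside [0.45, 0.55]
  expect_false(3 %in% keep)                     # < 2/3 of mass in [0.4, 0.6]
  expect_false(4 %in% keep)                     # mean depth < 24
  expect_error(select_reference_snps(R, character(0)), "empty")
})

test_that("ratio density is a proper reflected KDE", {
  d <- ratio_density(rep(0.5, 100), bandwidth = 0.02)
  expect_equal(d$x[which.max(d$y)], 0.5, tolerance = 0.01)
  ## integrates to ~1 and is non-negative
  expect_equal(sum(d$y) * diff(d$x[1:2]), 1, tolerance = 1e-3)
  expect_true(all(d$y >= 0))
  ## too few sites -> NULL sentinel
  expect_null(ratio_density(rep(0.5, 10)))
})

test_that("peak templates classify canonical and uninterpretable patterns", {
  set.seed(2)
  mix <- function(centers, n = 3000, sd = 0.03)
    as.numeric(vapply(centers, function(m) rnorm(n / length(centers), m, sd),
                      numeric(n / length(centers))))
  lab_of <- function(r) classify_ploidy(ratio_density(r))$label
  expect_equal(lab_of(mix(0.5)), "diploid")
  expect_equal(lab_of(mix(c(0.33, 0.67))), "triploid")
  expect_equal(lab_of(mix(c(0.25, 0.5, 0.75))), "tetraploid")
  expect_equal(lab_of(mix(c(0.2, 0.4, 0.6, 0.8), sd = 0.025)), "pentaploid")
  ## peaks at 0.10/0.35/0.62/0.90 match no template
  expect_equal(lab_of(mix(c(0.10, 0.35, 0.62, 0.90))), "unknown")
  ## degenerate input
  expect_equal(classify_ploidy(NULL)$label, "unknown")
})

test_that("classification is invariant to mirrored ratios", {
  for (s in 1:8) {
    pl <- sample(2:4, 1)
    ad <- simulate_allelic_depths(pl, 1500, seed = 100 + s)
    r <- ad$alt / ad$depth
    a <- classify_sample_ploidy(r, ad$depth)
    b <- classify_sample_ploidy(1 - r, ad$depth)
    expect_equal(a$label, b$label)
  }
})

test_that("classification accuracy meets the working thresholds at 24x", {
  ## 200 individuals per ploidy, 2000 heterozygous reference-quality sites
  set.seed(3)
  n_ind <- 200
  acc <- function(pl, n_sites = 2000, depth = 24) {
    calls <- vapply(seq_len(n_ind), function(i) {
      ad <- simulate_allelic_depths(pl, n_sites, mean_depth = depth)
      classify_sample_ploidy(ad$alt / ad$depth, ad$depth)$label
    }, "")
    table(factor(calls, levels = c("diploid", "triploid", "tetraploid",
                                   "pentaploid", "unknown"))) / n_ind
  }
  a2 <- acc(2); a3 <- acc(3); a4 <- acc(4)
  expect_gte(a2[["diploid"]], 0.95)
  expect_gte(a3[["triploid"]], 0.85)
  expect_gte(a4[["tetraploid"]], 0.95)
  ## pentaploid profiles at 24x sit at the method's resolution limit: the
  ## 0.4/0.6 components merge, so calls split between pentaploid,
  ## tetraploid and unknown -- but essentially never diploid
  a5 <- acc(5)
  expect_lt(a5[["diploid"]], 0.05)
  expect_gte(a5[["pentaploid"]] + a5[["tetraploid"]] + a5[["unknown"]], 0.9)
})

test_that("lower depth weakly increases the unknown rate", {
  unknown_rate <- function(depth) {
    mean(vapply(1:60, function(i) {
      ad <- simulate_allelic_depths(4, 800, mean_depth = depth,
                                    seed = 500 + i)
      classify_sample_ploidy(ad$alt / ad$depth, ad$depth)$label
    }, "") == "unknown")
  }
  expect_gte(unknown_rate(10), unknown_rate(24))
})

test_that("pooled classification rescues unresolved groups", {
  ## individually sparse tetraploid profiles, pooled -> tetraploid
  set.seed(4)
  n <- 12; k <- 120
  sites <- data.frame(compartment = "nuclear", chrom = "chr1",
                      pos = seq_len(k), ref = "A", alt = "T")
  dep <- alt <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ad <- simulate_allelic_depths(4, k)
    dep[i, ] <- ad$depth
    alt[i, ] <- ad$alt
  }
  adm <- allele_depth_matrix(sprintf("u%02d", 1:n), sites, dep, alt)
  R <- allelic_ratios(adm)
  pc <- pooled_classification(R, sprintf("u%02d", 1:n))
  expect_equal(pc$label, "tetraploid")
  expect_error(pooled_classification(R, character(0)), "empty")
})
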