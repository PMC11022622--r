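#' Ploidy count table with percentages
#'
#' Tabulates ploidy calls over genets and reports counts and percentages of
#' the total (one decimal, as conventionally printed). The "putative"
#' categories hold samples resolved only by pooled classification.
#'
#' @param calls ploidy-call data.frame from [infer_ploidy()] (columns
#'   `label`, `putative`), restricted to the genets of interest.
#' @return data.frame: `category`, `n`, `percent`; attribute `total`.
#' @export
ploidy_count_table <- function(calls) {
  cat_of <- function(label, putative) {
    if (label == "diploid") if (putative) "putative_diploid" else "diploid"
    else if (label == "tetraploid")
      if (putative) "putative_tetraploid" else "tetraploid"
    else if (label == "unknown") "unknown"
    else "others"
  }
  cats <- mapply(cat_of, calls$label, calls$putative)
  lev <- c("diploid", "putative_diploid", "tetraploid", "putative_tetraploid",
           "others", "unknown")
  n <- table(factor(cats, levels = lev))
  out <- data.frame(category = lev, n = as.integer(n),
                    percent = round(100 * as.integer(n) / nrow(calls), 1),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(calls)
  out
}

#' Percentages of printed classification counts
#'
#' Arithmetic helper turning per-class counts into percentages of their
#' total, rounded to one decimal as printed in reports.
#'
#' @param counts named integer vector.
#' @return named numeric percentages.
#' @export
count_percentages <- function(counts) {
  round(100 * counts / sum(counts), 1)
}

#' Team-by-cluster cross-tabulation and summary
#'
#' Cross-tabulates sampling teams against genetic clusters and summarises:
#' the percentage of teams that collected at least one individual of each
#' cluster, and the percentage of teams whose collections fall outside a
#' given reference cluster set (e.g. outside the two common dwarf-birch
#' clusters).
#'
#' @param teams,clusters named vectors (sample id -> team / cluster label).
#' @param reference_clusters cluster labels counted as "expected"; teams
#'   with any individual outside the set are counted in
#'   `pct_teams_outside_reference`.
#' @return list: `crosstab` (teams x clusters counts), `n_teams`,
#'   `pct_teams_with_cluster` (named), `pct_teams_outside_reference`,
#'   `pct_teams_multi_cluster`.
#' @export
team_cluster_report <- function(teams, clusters, reference_clusters = NULL) {
  ids <- intersect(names(teams), names(clusters))
  ct <- table(team = teams[ids], cluster = clusters[ids])
  n_teams <- nrow(ct)
  with_cl <- apply(ct > 0, 2, sum)
  pct_with <- round(100 * with_cl / n_teams)
  multi <- sum(rowSums(ct > 0) >= 2)
  out <- list(crosstab = ct, n_teams = n_teams,
              pct_teams_with_cluster = pct_with,
              pct_teams_multi_cluster = round(100 * multi / n_teams))
  if (!is.null(reference_clusters)) {
    outside <- colnames(ct)[!colnames(ct) %in% reference_clusters]
    n_out <- sum(rowSums(ct[, outside, drop = FALSE] > 0) > 0)
    out$n_teams_outside_reference <- n_out
    out$pct_teams_outside_reference <- round(100 * n_out / n_teams)
  }
  out
}

#' Combine criteria into per-sample multicriteria records
#'
#' Applies the concordance rule: ploidy call and genetic-cluster assignment
#' are the necessary criteria — a final species-group label needs both
#' criteria present and consistent (the cluster's modal ploidy class);
#' morphology corroborates when available, and the chlorotype is recorded
#' but never decides (haplotype sharing across species strips it of
#' discriminatory power). Samples unassigned at the Q threshold whose top
#' two memberships come from different clusters are flagged putative
#' hybrids; three memberships of at least 0.2 flag putative trihybrids.
#'
#' @param ploidy_calls data.frame from [infer_ploidy()].
#' @param lineages named lineage labels from [assign_lineages()].
#' @param Q admixture membership matrix (for hybrid flags).
#' @param chlorotypes optional `haplotype_table`.
#' @param morphology optional data.frame `id`, `candidates` (comma string).
#' @return data.frame, one row per sample: criteria columns, `final_label`
#'   ("unresolved" when fewer than two criteria concur) and `rule_trace`.
#' @export
multicriteria_table <- function(ploidy_calls, lineages, Q,
                                chlorotypes = NULL, morphology = NULL) {
  ids <- ploidy_calls$id
  lin <- lineages[ids]
  ## modal non-diploid/diploid class per lineage defines its expected ploidy
  pl_class <- ifelse(ploidy_calls$label == "diploid", "diploid",
              ifelse(ploidy_calls$label %in% c("tetraploid", "triploid",
                                               "pentaploid"), "polyploid",
                     "unknown"))
  names(pl_class) <- ids
  modal <- tapply(pl_class[ids][pl_class != "unknown"],
                  lin[pl_class != "unknown"], function(x)
                    names(sort(table(x), decreasing = TRUE))[1])
  hyb <- vapply(ids, function(s) {
    q <- Q[s, ]
    if (max(q) >= 0.75) return("")
    if (sum(q >= 0.2) >= 3) return("putative trihybrid")
    if (sum(q >= 0.2) >= 2) return("putative hybrid")
    ""
  }, "")
  out <- data.frame(id = ids, ploidy = ploidy_calls$label,
                    putative_ploidy = ploidy_calls$putative,
                    lineage = unname(lin), hybrid_flag = unname(hyb),
                    stringsAsFactors = FALSE)
  out$chlorotype <- if (!is.null(chlorotypes))
    chlorotypes$hap_id[match(ids, chlorotypes$id)] else NA_character_
  out$morphology <- if (!is.null(morphology))
    morphology$candidates[match(ids, morphology$id)] else NA_character_
  final <- character(length(ids)); trace <- character(length(ids))
  for (i in seq_along(ids)) {
    l <- out$lineage[i]
    concur <- 0L; tr <- character(0)
    if (!is.na(l) && l != "admixed") {
      concur <- concur + 1L; tr <- c(tr, sprintf("cluster=%s", l))
      expected <- modal[[l]] %||% NA_character_
      if (pl_class[i] != "unknown" && !is.na(expected) &&
          pl_class[i] == expected) {
        concur <- concur + 1L; tr <- c(tr, sprintf("ploidy=%s", out$ploidy[i]))
      }
    }
    if (!is.na(out$morphology[i]) && nzchar(out$morphology[i]) && concur >= 1)
      tr <- c(tr, "morphology")
    if (concur >= 2) {
      final[i] <- l
    } else if (nzchar(out$hybrid_flag[i])) {
      final[i] <- out$hybrid_flag[i]
    } else final[i] <- "unresolved"
    trace[i] <- paste(tr, collapse = "+")
  }
  out$final_label <- final
  out$rule_trace <- trace
  out
}

#' Run the full multicriteria pipeline on a dataset
#'
#' Executes the analysis stages in study order on a synthetic (or read-in)
#' dataset: ploidy inference, assembly of the initial-diploid and
#' diploid-tetraploid datasets (filters + clone removal), DAPC clustering,
#' EM admixture with lineage assignment, diversity statistics, chloroplast
#' haplotypes, and the summary reports. Intermediate artifacts are written
#' under `outdir` as tab-separated files when `outdir` is given.
#'
#' @param sim a `synthetic_dataset` (or an equivalent list from
#'   [read_variant_table()] plus a sample table).
#' @param K number of admixture clusters (default: number of simulated
#'   clusters).
#' @param n_pcs PCs retained in the DAPC (default 50, capped).
#' @param outdir optional output directory.
#' @param seed RNG seed for the stochastic stages.
#' @param kmax maximal k scanned in the BIC step.
#' @param force_k optional k override for the DAPC grouping.
#' @param admix_restarts EM restarts.
#' @param clone_threshold_initial,clone_threshold_mixed clone-calling
#'   distances for the two datasets (350/300 at full marker scale; absolute
#'   counts, so scale them with the locus count).
#' @return list of stage results: `ploidy`, `initial`, `mixed`, `scan`,
#'   `dapc`, `admixture`, `lineages`, `diversity`, `fst`, `het`,
#'   `chlorotypes`, `cp_summary`, `multicriteria`, `team_report`,
#'   `ploidy_table`, `cluster_sizes`.
#' @export
run_pipeline <- function(sim, K = NULL, n_pcs = 50, outdir = NULL, seed = 1L,
                         kmax = 20, force_k = NULL, admix_restarts = 5,
                         clone_threshold_initial = 350,
                         clone_threshold_mixed = 300) {
  samples <- sim$samples
  K <- K %||% sim$config$n_clusters

  ## stage 1: the initial diploid dataset (all individuals coded diploid)
  ad_missing <- sim$ad$depth < 5
  Gdip <- genotype_matrix(code_diploid(sim$genotypes, samples$true_ploidy),
                          stats::setNames(rep(2L, nrow(samples)), samples$id),
                          "initial_diploid")
  Gdip$dosage[ad_missing] <- NA_integer_
  initial <- assemble_dataset(Gdip, max_missing_ind = 0.40,
                              clone_threshold = clone_threshold_initial)

  ## stage 2: preliminary clustering (PCA + k-means/BIC + DAPC) on genets
  pca <- pca_genotypes(initial$G)
  scan <- kmeans_bic_scan(pca$scores, kmax = min(kmax, nrow(pca$scores) - 1),
                          seed = seed, force_k = force_k)
  grp <- scan$assignments[[scan$selected_k]]
  np <- min(n_pcs, ncol(pca$scores), nrow(pca$scores) - scan$selected_k - 1)
  dapc <- dapc_fit(pca$scores, grp, n_pcs = np)
  genet_ids <- rownames(initial$G$dosage)
  dapc_groups <- stats::setNames(sprintf("dapc%d", grp), genet_ids)

  ## stage 3: ploidy, pooling unresolved samples by their genet's cluster
  genet_of <- stats::setNames(initial$clones$representative[
    initial$clones$assignment], names(initial$clones$assignment))
  rescue_groups <- dapc_groups[genet_of[samples$id]]
  names(rescue_groups) <- samples$id
  ploidy <- infer_ploidy(sim$ad, groups = rescue_groups)

  ## stage 4: the diploid-tetraploid dataset
  Gmix0 <- genotype_matrix(sim$genotypes,
                           stats::setNames(samples$true_ploidy, samples$id),
                           "diploid_tetraploid")
  Gmix0$dosage[ad_missing] <- NA_integer_
  Gmix0 <- recode_mixed_ploidy(Gmix0, ploidy)
  mixed <- assemble_dataset(Gmix0, max_missing_ind = 0.50,
                            clone_threshold = clone_threshold_mixed)

  ## stage 5: admixture and lineages on the mixed dataset
  adm <- admixture_em(mixed$G, K = K, seed = seed, n_restarts = admix_restarts)
  regions <- stats::setNames(samples$region, samples$id)
  lineages <- assign_lineages(adm$Q, regions = regions)

  ## stage 6: diversity on the initial diploid dataset
  pops <- stats::setNames(samples$population, samples$id)
  div <- population_diversity(initial$G, pops)
  fst <- pairwise_fst(initial$G, dapc_groups)
  het <- individual_heterozygosity(initial$G)

  ## stage 7: chloroplast
  cpG <- genotype_matrix(sim$cp[genet_ids, , drop = FALSE],
                         stats::setNames(rep(1L, length(genet_ids)), genet_ids),
                         "chloroplast")
  cp_sites <- informative_cp_snps(cpG)
  chloro <- cp_haplotypes(cpG, cp_sites)
  cp_sum <- haplotype_summary(chloro, dapc_groups, pops[genet_ids])

  ## stage 8: reports (on genets of the initial dataset)
  pl_genets <- ploidy[ploidy$id %in% genet_ids, ]
  ploidy_table <- ploidy_count_table(pl_genets)
  teams <- stats::setNames(samples$team, samples$id)
  two_largest <- names(sort(table(dapc_groups), decreasing = TRUE))[1:2]
  team_report <- team_cluster_report(teams[genet_ids], dapc_groups,
                                     reference_clusters = two_largest)
  multicrit <- multicriteria_table(pl_genets,
                                   lineages[genet_ids],
                                   adm$Q[genet_ids, , drop = FALSE],
                                   chlorotypes = chloro)
  cluster_sizes <- as.data.frame(table(cluster = dapc_groups))

  res <- list(ploidy = ploidy, initial = initial, mixed = mixed, scan = scan,
              dapc = dapc, admixture = adm, lineages = lineages,
              diversity = div, fst = fst, het = het, chlorotypes = chloro,
              cp_summary = cp_sum, multicriteria = multicrit,
              team_report = team_report, ploidy_table = ploidy_table,
              cluster_sizes = cluster_sizes)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(res$ploidy, "ploidy_calls.tsv")
  wt(res$ploidy_table, "ploidy_counts.tsv")
  wt(res$multicriteria, "multicriteria.tsv")
  wt(res$cluster_sizes, "cluster_sizes.tsv")
  wt(res$diversity$summary, "diversity_by_population.tsv")
  utils::write.table(unclass(res$fst), file.path(outdir, "fst_pairwise.tsv"),
                     sep = "\t", quote = FALSE)
  wt(res$chlorotypes, "chlorotypes.tsv")
  wt(res$cp_summary$haplotypes, "chlorotype_sharing.tsv")
  utils::write.table(res$team_report$crosstab,
                     file.path(outdir, "team_by_cluster.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(outdir)
}
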