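#!/usr/bin/env Rscript
# Nuclear diversity on the initial diploid dataset: per-population Ho, Hs
# and FIS, pairwise Weir-Cockerham FST between DAPC clusters and between
# admixture lineages, and per-individual heterozygosity.

source("analysis/00_config.R")

rd <- read_variant_table(vcf_path)
truth <- read_truth()
coords <- utils::read.delim(file.path(out_dir, "dapc_coords.tsv"),
                            stringsAsFactors = FALSE)
qtab <- utils::read.delim(file.path(out_dir, "admixture_q.tsv"),
                          stringsAsFactors = FALSE)

initial <- assemble_dataset(rd$nuclear, max_missing_ind = 0.40,
                            clone_threshold = clone_thr_initial)
pops <- stats::setNames(truth$population, truth$id)

div <- population_diversity(initial$G, pops)
wt(div$summary, "diversity_by_population.tsv")
message(sprintf("%d of %d populations have Ho >= Hs (negative FIS)",
                sum(div$summary$FIS <= 0, na.rm = TRUE),
                sum(!is.na(div$summary$FIS))))

dapc_groups <- stats::setNames(sprintf("dapc%d", coords$cluster), coords$id)
fst_c <- pairwise_fst(initial$G, dapc_groups)
wt(round(unclass(fst_c), 4), "fst_dapc_clusters.tsv", rn = TRUE)
message("pairwise FST between DAPC clusters:")
print(round(unclass(fst_c), 3))

lin <- stats::setNames(qtab$lineage, qtab$id)
lin <- lin[lin != "admixed"]
lin <- lin[names(lin) %in% rownames(initial$G$dosage)]
keep <- names(lin)
fst_l <- pairwise_fst(
  genotype_matrix(initial$G$dosage[keep, , drop = FALSE],
                  initial$G$ploidy[keep], "initial_diploid", initial$G$loci),
  lin)
wt(round(unclass(fst_l), 4), "fst_lineages.tsv", rn = TRUE)

het <- individual_heterozygosity(initial$G)
het$cluster <- dapc_groups[het$id]
wt(het, "individual_heterozygosity.tsv")
agg <- tapply(het$het_rate, het$cluster, mean, na.rm = TRUE)
message("mean individual heterozygosity by cluster:")
print(round(agg, 4))
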