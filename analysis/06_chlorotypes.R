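#!/usr/bin/env Rscript
# Chloroplast haplotypes: collapse the organellar SNPs to uniquely
# informative sites, concatenate them to per-sample chlorotypes, and report
# haplotype sharing across the nuclear DAPC clusters (chloroplast capture
# shows up as haplotypes carried by more than one cluster).

source("analysis/00_config.R")

rd <- read_variant_table(vcf_path)
truth <- read_truth()
coords <- utils::read.delim(file.path(out_dir, "dapc_coords.tsv"),
                            stringsAsFactors = FALSE)

cpG <- rd$chloroplast
keep <- informative_cp_snps(cpG)
message(ncol(cpG$dosage), " chloroplast SNPs -> ", length(keep),
        " uniquely informative after missingness and redundancy filters")

## restrict to the genets of the initial dataset, as for the nuclear stages
genets <- coords$id
cp_sub <- genotype_matrix(cpG$dosage[genets, , drop = FALSE],
                          cpG$ploidy[genets], "chloroplast", cpG$loci)
H <- cp_haplotypes(cp_sub, keep)
n_missing <- sum(is.na(H$hap_id))
message(length(unique(stats::na.omit(H$hap_id))), " distinct chlorotypes; ",
        n_missing, " individuals without haplotype (missing data)")

clusters <- stats::setNames(sprintf("dapc%d", coords$cluster), coords$id)
pops <- stats::setNames(truth$population, truth$id)[genets]
summ <- haplotype_summary(H, clusters, pops)

wt(H, "chlorotypes.tsv")
wt(summ$haplotypes, "chlorotype_sharing.tsv")
wt(summ$cluster_richness, "chlorotype_richness_by_cluster.tsv")
wt(summ$population_spectrum, "chlorotype_spectrum_by_population.tsv")
message(sum(summ$haplotypes$shared), " chlorotypes shared between clusters, ",
        sum(!summ$haplotypes$shared), " endemic to a single cluster")
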