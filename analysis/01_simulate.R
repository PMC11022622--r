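#!/usr/bin/env Rscript
# Build the synthetic study cohort and persist it as a VCF (GT:DP:AD, with
# nuclear and chloroplast contigs) plus a tab-separated truth table. All
# later scripts read these files, so the whole workflow also exercises the
# variant-file round trip.

source("analysis/00_config.R")

sim <- get_dataset()
print(sim)

write_vcf_dataset(sim, vcf_path)
utils::write.table(sim$samples, truth_path, sep = "\t", quote = FALSE,
                   row.names = FALSE)

tab <- table(sim$samples$true_cluster, sim$samples$true_ploidy)
message("cohort written: ", nrow(sim$samples), " samples (",
        sum(!is.na(sim$samples$clone_of)), " clonal ramets), ",
        ncol(sim$genotypes), " nuclear + ", ncol(sim$cp), " cp sites")
message("true cluster x ploidy composition:")
print(tab)
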