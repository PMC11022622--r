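#!/usr/bin/env Rscript
# Infer each individual's ploidy from the allelic-ratio density profiles:
# bootstrap a clear-diploid panel, select reference SNPs, classify every
# sample, and report the classification table with percentages.

source("analysis/00_config.R")

rd <- read_variant_table(vcf_path)
truth <- read_truth()

nuc_ad <- subset_compartment(rd$ad, "nuclear")
calls <- infer_ploidy(nuc_ad)

message(length(attr(calls, "panel")), " samples in the clear-diploid panel; ",
        length(attr(calls, "ref_sites")), " reference SNPs retained")

wt(calls, "ploidy_calls.tsv")
tab <- ploidy_count_table(calls)
wt(tab, "ploidy_counts.tsv")
print(tab)

conf <- table(call = calls$label,
              truth = truth$true_ploidy[match(calls$id, truth$id)])
message("calls vs simulated truth:")
print(conf)
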