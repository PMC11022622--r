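#!/usr/bin/env Rscript
# Assemble the two analysis datasets. The initial diploid dataset treats
# every individual as diploid (40% sample-missingness cap, MAF >= 0.01,
# <30% locus missingness, clone collapse). The diploid-tetraploid dataset
# recodes every non-diploid or ambiguous individual as tetraploid (50% cap,
# clone collapse at the lower threshold) and is exported in the four-row
# STRUCTURE coding.

source("analysis/00_config.R")

rd <- read_variant_table(vcf_path)
calls <- utils::read.delim(file.path(out_dir, "ploidy_calls.tsv"),
                           stringsAsFactors = FALSE)

initial <- assemble_dataset(rd$nuclear, max_missing_ind = 0.40,
                            clone_threshold = clone_thr_initial)
message("initial diploid dataset:")
print(initial$report)

## mixed dataset from the same variant file, recoded by the inferred ploidy
Gmix <- recode_mixed_ploidy(rd$nuclear, calls)
mixed <- assemble_dataset(Gmix, max_missing_ind = 0.50,
                          clone_threshold = clone_thr_mixed)
message("diploid-tetraploid dataset:")
print(mixed$report)

genets <- data.frame(id = rownames(initial$G$dosage))
wt(genets, "genets_initial.tsv")
wt(data.frame(id = rownames(mixed$G$dosage)), "genets_mixed.tsv")
wt(data.frame(metric = names(initial$report), initial = initial$report,
              mixed = mixed$report[names(initial$report)]),
   "assembly_report.tsv")

write_structure_file(mixed$G, file.path(data_dir, "mixed_ploidy.str"))
message("STRUCTURE input written: ", file.path(data_dir, "mixed_ploidy.str"))
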