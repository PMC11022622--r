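# Shared settings for the analysis scripts. The synthetic cohort mirrors the
# field study's structure at a tractable marker scale: five genetic clusters
# (two widespread diploid dwarf-birch groups, a small hybrid-derived group,
# one tetraploid cluster, one geographically split northern cluster), clones,
# di- and trihybrids, 29 sampling teams over 40 populations, mean depth 24x.
# At 1000 nuclear SNPs the published absolute clone-distance thresholds
# (350/300, calibrated on a ~5000-locus panel) scale to 70/60.

library(ploidypop)

an_seed <- 20260101L
data_dir <- "results/data"
out_dir <- "results"

an_config <- simulation_config(seed = an_seed)

clone_thr_initial <- round(350 * an_config$n_nuclear_sites / 5000)
clone_thr_mixed <- round(300 * an_config$n_nuclear_sites / 5000)

vcf_path <- file.path(data_dir, "cohort.vcf")
truth_path <- file.path(data_dir, "truth_samples.tsv")

dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## deterministic re-simulation: every script can rebuild the same dataset
get_dataset <- function() simulate_dataset(an_config)

read_truth <- function() utils::read.delim(truth_path, stringsAsFactors = FALSE)

wt <- function(x, f, rn = FALSE) {
  utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                     row.names = rn)
  message("wrote ", file.path(out_dir, f))
}
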