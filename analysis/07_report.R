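#!/usr/bin/env Rscript
# Multicriteria synthesis: combine ploidy, admixture lineage, chlorotype and
# (illustrative) leaf morphology into per-sample records, plus the
# team-by-cluster cross-tabulation.

source("analysis/00_config.R")

truth <- read_truth()
calls <- utils::read.delim(file.path(out_dir, "ploidy_calls.tsv"),
                           stringsAsFactors = FALSE)
coords <- utils::read.delim(file.path(out_dir, "dapc_coords.tsv"),
                            stringsAsFactors = FALSE)
qtab <- utils::read.delim(file.path(out_dir, "admixture_q.tsv"),
                          stringsAsFactors = FALSE)
chloro <- utils::read.delim(file.path(out_dir, "chlorotypes.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(haplotype = "character"))

Q <- as.matrix(qtab[grep("^X", names(qtab))])
rownames(Q) <- qtab$id
lineages <- stats::setNames(qtab$lineage, qtab$id)

genets <- coords$id
mc <- multicriteria_table(calls[calls$id %in% genets, ],
                          lineages, Q, chlorotypes = chloro)
wt(mc, "multicriteria.tsv")
message("final multicriteria labels:")
print(table(mc$final_label))

## team-by-cluster cross-tab over the genets
teams <- stats::setNames(truth$team, truth$id)
clusters <- stats::setNames(sprintf("dapc%d", coords$cluster), coords$id)
two_largest <- names(sort(table(clusters), decreasing = TRUE))[1:2]
tr <- team_cluster_report(teams[genets], clusters,
                          reference_clusters = two_largest)
utils::write.table(tr$crosstab, file.path(out_dir, "team_by_cluster.tsv"),
                   sep = "\t", quote = FALSE)
message(sprintf(paste0("%d teams; %d%% collected more than one cluster; ",
                       "%d%% strayed outside the two largest clusters"),
                tr$n_teams, tr$pct_teams_multi_cluster,
                tr$pct_teams_outside_reference))

## illustrative morphology matching for the four canonical leaf types
demo <- data.frame(
  blade = c("obovate-orbicular", "elliptic", "ovate", "orbiculate-reniform"),
  length_cm = c(2, 4, 4, 1), width_cm = c(2, 3, 3, 1),
  teeth = c("obtuse-rounded", "acute-obtuse-rounded", "long-sharp", "rounded"))
demo$candidates <- vapply(seq_len(nrow(demo)), function(i)
  paste(match_species(demo$blade[i], demo$length_cm[i], demo$width_cm[i],
                      demo$teeth[i]), collapse = "; "), "")
wt(demo, "morphology_demo.tsv")
print(demo[, c("blade", "teeth", "candidates")])
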