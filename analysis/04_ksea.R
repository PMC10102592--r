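#!/usr/bin/env Rscript
# Kinase-substrate enrichment analysis on the simulated study: per-subtype
# KSEA z-scores from the site-level screen output, significance filtering
# (p < 0.05, >= 3 substrates), kinome-group annotation, and the IDC/ILC
# kinome comparison. Three CMGC kinases were planted active in IDC tumors by
# 01_simulate.R; they should dominate the activated set.

suppressPackageStartupMessages(library(phosphopair))

ind_data <- "results/sim_data"
ind_diff <- "results/differential"
outdir <- "results/ksea"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ann <- read_kinase_substrates(file.path(ind_data, "kinase_substrates.tsv"),
                              organism_filter = "human")
gmap <- load_kinome_groups()

res <- lapply(c(IDC = "IDC", ILC = "ILC"), function(st) {
  d <- read.delim(file.path(ind_diff, paste0("site_differential_", st, ".tsv")))
  r <- ksea_scores(site_fc_for_ksea(d[!is.na(d$mean_fc), ]), ann)
  annotate_kinome_group(r, gmap)
})
for (st in names(res)) {
  write.table(res[[st]], file.path(outdir, paste0("ksea_", st, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- significant_kinases(res[[st]])
  message(sprintf("%s: %d kinases scored, %d significant (p < 0.05, m >= 3)",
                  st, nrow(res[[st]]), nrow(sig)))
  if (nrow(sig)) {
    act <- sig[sig$direction == "activated", ]
    message(sprintf("  activated: %s",
                    paste(sprintf("%s[%s, z=%.2f]", act$kinase,
                                  act$kinome_group, act$z), collapse = ", ")))
    tally <- kinome_group_tally(act)
    message("  activated-set group tally: ",
            paste(sprintf("%s=%d", tally$kinome_group, tally$n), collapse = ", "))
  }
  write.table(kinome_group_tally(res[[st]]),
              file.path(outdir, paste0("kinome_group_tally_", st, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cmp <- compare_subtype_kinomes(res$IDC, res$ILC)
message(sprintf("kinome comparison: %d common, %d IDC-only, %d ILC-only, %d sign flips",
                cmp$n_common, cmp$n_idc_only, cmp$n_ilc_only,
                nrow(cmp$direction_table)))
jsonlite::write_json(cmp[c("n_idc_only", "n_ilc_only", "n_common")],
                     file.path(outdir, "kinome_venn.json"),
                     auto_unbox = TRUE, digits = NA)
if (nrow(cmp$direction_table))
  write.table(cmp$direction_table, file.path(outdir, "direction_flips.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
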