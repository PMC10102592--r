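#!/usr/bin/env Rscript
# Generate the synthetic paired proteome/phosphoproteome study used by the
# downstream analysis scripts: 5 IDC + 5 ILC tumor/NAT pairs, 1,000 proteins
# (10% planted differential at FC 3.0), 2,000 phosphosites with three kinases
# planted active in IDC tumors. Everything is written in the same table
# dialects the package reads from real MaxQuant output.

suppressPackageStartupMessages(library(phosphopair))

outdir <- "results/sim_data"
seed <- 20230331L

# kinase names drawn from the bundled kinome map so group-level summaries in
# 04_ksea.R are meaningful; three CMGC kinases are planted active in IDC
groups <- load_kinome_groups()
kinases <- c("MAPK3", "CDK2", "GSK3B", "AURKB", "SGK1", "LATS1", "STK38",
             "PDPK1", "CHEK1", "CSNK1D", "MAP2K1", "SRC", "EGFR", "RAF1",
             "ATM", "PLK1", "MAPK13", "MAPK8", "PRKCA", "CAMK2A")
set.seed(seed)
pool <- simulate_kinase_substrates(n_kinases = length(kinases),
                                   substrates_per_kinase = 15,
                                   n_genes = 500, seed = seed)
pool$kinase <- kinases[as.integer(sub("KIN", "", pool$kinase))]

params <- sim_params(
  n_proteins = 1000, n_sites = 2000,
  planted_kinases = c(MAPK3 = 1.0, CDK2 = 0.8, GSK3B = 0.9),
  planted_kinase_subtype = "IDC",
  seed = seed)

paths <- write_fixture_bundle(outdir, params, pool)
message("Simulated study written to ", outdir, ":")
for (p in paths) message("  ", p)
message(sprintf("planted differential proteins: %d of %d",
                round(params$frac_differential * params$n_proteins),
                params$n_proteins))
message("planted active kinases (IDC tumors): ",
        paste(names(params$planted_kinases), collapse = ", "),
        " [groups: ",
        paste(groups$group[match(names(params$planted_kinases), groups$kinase)],
              collapse = ", "), "]")
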