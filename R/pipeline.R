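#' Assemble a full-run configuration
#'
#' Collects the input paths and every stage's thresholds in one validated
#' list, so no printed threshold is hard-coded at a call site. A config can
#' also be stored as JSON and loaded with [read_run_config()].
#'
#' @param protein_table,phospho_table,design,kinase_substrates paths to the
#'   four input tables.
#' @param kinome_groups optional path to a kinase-to-group TSV; `NULL` uses
#'   the bundled map.
#' @param outdir output directory for the report bundle.
#' @param normalization list: `enabled` (default `TRUE`), `method`
#'   (`"median"`/`"total"`).
#' @param screen a [screen_config()].
#' @param phospho list: `min_localization_prob`, `drop_flags`,
#'   `aggregate_method` (`"median"`/`"mean"`).
#' @param ksea a [ksea_config()].
#' @param organism_filter organism filter for the annotation table, or
#'   `NULL`.
#' @param intensity_prefix intensity column family in the MaxQuant-style
#'   inputs (`"Intensity"` or `"LFQ intensity"`).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(protein_table, phospho_table, design, kinase_substrates,
                       kinome_groups = NULL, outdir = "results",
                       normalization = list(enabled = TRUE, method = "median"),
                       screen = screen_config(),
                       phospho = list(min_localization_prob = 0.75,
                                      drop_flags = TRUE,
                                      aggregate_method = "median"),
                       ksea = ksea_config(),
                       organism_filter = NULL,
                       intensity_prefix = "Intensity",
                       seed = 1L) {
  for (p in c(protein_table, phospho_table, design, kinase_substrates, kinome_groups))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  list(protein_table = protein_table, phospho_table = phospho_table,
       design = design, kinase_substrates = kinase_substrates,
       kinome_groups = kinome_groups, outdir = outdir,
       normalization = normalization, screen = screen, phospho = phospho,
       ksea = ksea, organism_filter = organism_filter,
       intensity_prefix = intensity_prefix, seed = as.integer(seed))
}

#' Load a run configuration stored as JSON
#' @param path JSON file with the [run_config()] fields.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  if (!is.null(args$screen)) args$screen <- do.call(screen_config, args$screen)
  if (!is.null(args$ksea)) args$ksea <- do.call(ksea_config, args$ksea)
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# normalize a linear matrix per config; returns list(log2 = X, report = df)
normalize_stage <- function(X, norm_cfg) {
  Xl <- to_log2(X)
  if (isTRUE(norm_cfg$enabled)) {
    res <- global_normalize(Xl, method = norm_cfg$method %||% "median")
    list(log2 = res$matrix, report = res$report)
  } else {
    list(log2 = Xl,
         report = data.frame(sample = colnames(Xl$values), offset_log2 = 0,
                             n_features_used = colSums(!is.na(Xl$values))))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis end to end
#'
#' read -> normalize -> patient-coverage filter -> per-subtype differential
#' screen (protein and site level) -> protein-level phospho aggregation ->
#' quadrant and discordance integration -> KSEA per subtype -> subtype
#' kinome comparison. One TSV/JSON per stage is written under
#' `cfg$outdir`, plus `manifest.json` echoing the config, the seed and
#' per-stage row counts. Reruns with the same config are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  design <- read_design(cfg$design)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  counts <- list()

  ## proteins
  prot <- read_protein_table(cfg$protein_table, design, cfg$intensity_prefix)
  counts$proteins_read <- nrow(prot$values)
  norm <- normalize_stage(prot, cfg$normalization)
  write_tsv(norm$report, file.path(cfg$outdir, "protein_normalization.tsv"))
  prot_f <- patient_coverage_filter(norm$log2, design, cfg$screen)
  counts$proteins_high_coverage <- nrow(prot_f$values)
  prot_diff <- lapply(c(IDC = "IDC", ILC = "ILC"), function(st)
    differential_screen(prot_f, design, st, cfg$screen))
  for (st in names(prot_diff))
    write_tsv(prot_diff[[st]],
              file.path(cfg$outdir, paste0("protein_differential_", st, ".tsv")))
  counts$protein_calls_idc <- sum(prot_diff$IDC$call != "ns")
  counts$protein_calls_ilc <- sum(prot_diff$ILC$call != "ns")

  ## phosphosites
  sites <- read_phospho_table(cfg$phospho_table, design, cfg$intensity_prefix)
  counts$sites_read <- nrow(sites)
  sites_f <- filter_sites(sites,
                          min_localization_prob = cfg$phospho$min_localization_prob %||% 0.75,
                          drop_flags = cfg$phospho$drop_flags %||% TRUE)
  counts$sites_class1 <- nrow(sites_f)
  write_tsv(as.data.frame(sites_f), file.path(cfg$outdir, "sites_filtered.tsv"))
  write_tsv(multiplicity_summary(sites_f, design),
            file.path(cfg$outdir, "multiplicity_summary.tsv"))
  smat <- site_matrix(sites_f)
  snorm <- normalize_stage(smat, cfg$normalization)
  smat_f <- patient_coverage_filter(snorm$log2, design, cfg$screen)
  counts$sites_high_coverage <- nrow(smat_f$values)
  site_diff <- lapply(c(IDC = "IDC", ILC = "ILC"), function(st)
    differential_screen(smat_f, design, st, cfg$screen))
  for (st in names(site_diff))
    write_tsv(site_diff[[st]],
              file.path(cfg$outdir, paste0("site_differential_", st, ".tsv")))
  phos_agg <- lapply(site_diff, aggregate_protein_phospho_fc,
                     method = cfg$phospho$aggregate_method %||% "median")
  for (st in names(phos_agg))
    write_tsv(phos_agg[[st]],
              file.path(cfg$outdir, paste0("phosphoprotein_fc_", st, ".tsv")))

  ## integration
  common <- intersect(prot_diff$IDC$feature, prot_diff$ILC$feature)
  fci <- prot_diff$IDC$mean_fc[match(common, prot_diff$IDC$feature)]
  fcl <- prot_diff$ILC$mean_fc[match(common, prot_diff$ILC$feature)]
  called <- prot_diff$IDC$call[match(common, prot_diff$IDC$feature)] != "ns" |
    prot_diff$ILC$call[match(common, prot_diff$ILC$feature)] != "ns"
  ok <- called & !is.na(fci) & !is.na(fcl)
  quad <- data.frame(feature = common[ok], fc_idc = fci[ok], fc_ilc = fcl[ok],
                     quadrant = quadrant_classify(fci[ok], fcl[ok], cfg$screen),
                     stringsAsFactors = FALSE)
  write_tsv(quad, file.path(cfg$outdir, "quadrants.tsv"))

  diff_prot <- unique(unlist(lapply(prot_diff, function(d) d$feature[d$call != "ns"])))
  diff_phos <- unique(unlist(lapply(phos_agg, function(d) d$protein[d$any_called])))
  overlap <- overlap_diff_protein_phospho(diff_prot, diff_phos)
  both <- intersect(diff_prot, diff_phos)
  sig <- discordance_groups(
    both,
    prot_diff$IDC$mean_fc[match(both, prot_diff$IDC$feature)],
    prot_diff$ILC$mean_fc[match(both, prot_diff$ILC$feature)],
    phos_agg$IDC$mean_fc[match(both, phos_agg$IDC$protein)],
    phos_agg$ILC$mean_fc[match(both, phos_agg$ILC$protein)])
  write_tsv(sig, file.path(cfg$outdir, "discordance_groups.tsv"))

  ## KSEA
  ann <- read_kinase_substrates(cfg$kinase_substrates, cfg$organism_filter)
  counts$kinase_substrate_triples <- nrow(ann)
  gmap <- load_kinome_groups(cfg$kinome_groups)
  ksea <- lapply(site_diff, function(d) {
    res <- ksea_scores(site_fc_for_ksea(d[!is.na(d$mean_fc), , drop = FALSE]),
                       ann, cfg$ksea)
    annotate_kinome_group(res, gmap)
  })
  for (st in names(ksea))
    write_tsv(ksea[[st]], file.path(cfg$outdir, paste0("ksea_", st, ".tsv")))
  write_tsv(kinome_group_tally(ksea$IDC),
            file.path(cfg$outdir, "kinome_group_tally_IDC.tsv"))
  write_tsv(kinome_group_tally(ksea$ILC),
            file.path(cfg$outdir, "kinome_group_tally_ILC.tsv"))
  comp <- compare_subtype_kinomes(ksea$IDC, ksea$ILC)
  jsonlite::write_json(comp[c("n_idc_only", "n_ilc_only", "n_common")],
                       file.path(cfg$outdir, "kinome_venn.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$kinases_idc <- nrow(ksea$IDC)
  counts$kinases_ilc <- nrow(ksea$ILC)

  manifest <- list(package_version = as.character(utils::packageVersion("phosphopair")),
                   seed = cfg$seed, config = cfg[setdiff(names(cfg), "outdir")],
                   row_counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(design = design, protein_diff = prot_diff,
                 site_diff = site_diff, phospho_agg = phos_agg,
                 quadrants = quad, overlap = overlap, signatures = sig,
                 ksea = ksea, kinome_comparison = comp, manifest = manifest))
}

#' Summary report computed from the printed dual-layer fold-change table
#'
#' Recomputes, from printed values only: the cross-subtype quadrant counts
#' of the 13 proteins (one up in IDC but down in ILC; two down in IDC but
#' up in ILC), the count of proteins quantified in both layers (10), and
#' the discordance-group memberships under the inclusive-bound state rule
#' appropriate for 2-decimal printed fold changes.
#'
#' @return list with `quadrant_counts` (named integer vector),
#'   `n_dual_layer`, `groups` (the [discordance_groups()] table over the 10
#'   dual-layer proteins) and `g1_members`.
#' @export
table2_report <- function() {
  t2 <- load_table2_fixture()
  quad <- opposite_direction_counts(t2$prot_fc_idc, t2$prot_fc_ilc)
  dual <- t2[!is.na(t2$phos_fc_idc) & !is.na(t2$phos_fc_ilc), , drop = FALSE]
  groups <- discordance_groups(dual$protein_label,
                               dual$prot_fc_idc, dual$prot_fc_ilc,
                               dual$phos_fc_idc, dual$phos_fc_ilc,
                               inclusive = TRUE)
  list(quadrant_counts = quad,
       n_dual_layer = nrow(dual),
       groups = groups,
       g1_members = sort(groups$feature[groups$group == "G1"]))
}
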