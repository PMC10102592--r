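#' Simulation parameters for paired proteome/phosphoproteome data
#'
#' Defaults emulate the study design the pipeline targets: 5 tumor/NAT pairs
#' per subtype (IDC and ILC), log-normal abundances, a patient random effect
#' shared by the two members of a pair, per-sample scale biases,
#' intensity-dependent (missing-not-at-random) dropout, and planted
#' differential features at a fixed fold change.
#'
#' @param n_pairs_per_subtype tumor/NAT pairs per subtype.
#' @param n_proteins number of protein features.
#' @param n_sites number of phosphosites.
#' @param frac_differential fraction of proteins planted as differential.
#' @param planted_fc linear tumor/NAT fold change of planted features.
#' @param within_group_log2_sd residual log2 SD per measurement.
#' @param patient_log2_sd SD of the patient random effect (log2).
#' @param sample_scale_log2_sd SD of per-sample scale offsets (log2).
#' @param missing_rate overall expected fraction of missing cells.
#' @param mnar_strength logistic slope of dropout in standardized log2
#'   intensity; 0 gives missing-completely-at-random.
#' @param planted_kinases named numeric vector: log2 activity shift applied
#'   to each named kinase's substrate sites in tumor samples of
#'   `planted_kinase_subtype`.
#' @param planted_kinase_subtype subtype whose tumors carry the kinase
#'   shifts.
#' @param frac_low_localization fraction of sites drawn with localization
#'   probability at or below 0.75 (to exercise the class-I filter).
#' @param baseline_log2_mean,baseline_log2_sd distribution of feature
#'   baseline log2 abundances.
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_pairs_per_subtype = 5, n_proteins = 1000,
                       n_sites = 2000, frac_differential = 0.1,
                       planted_fc = 3.0, within_group_log2_sd = 0.5,
                       patient_log2_sd = 0.3, sample_scale_log2_sd = 0.25,
                       missing_rate = 0.10, mnar_strength = 1.0,
                       planted_kinases = numeric(0),
                       planted_kinase_subtype = "IDC",
                       frac_low_localization = 0.10,
                       baseline_log2_mean = 25, baseline_log2_sd = 2,
                       seed = 1L) {
  stopifnot(n_pairs_per_subtype >= 2, n_proteins >= 1, n_sites >= 1,
            frac_differential >= 0, frac_differential <= 1,
            planted_fc > 0, within_group_log2_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            frac_low_localization >= 0, frac_low_localization <= 1,
            planted_kinase_subtype %in% c("IDC", "ILC"))
  as.list(environment())
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv))
  set.seed(seed)
  code
}

# the 5+5 paired design the generators emulate
sim_design <- function(n_pairs_per_subtype) {
  pts <- sprintf("P%02d", seq_len(2 * n_pairs_per_subtype))
  subtype <- rep(c("IDC", "ILC"), each = n_pairs_per_subtype)
  paired_design(data.frame(
    sample = c(paste0(pts, "_T"), paste0(pts, "_N")),
    patient = c(pts, pts),
    tissue = rep(c("tumor", "NAT"), each = length(pts)),
    subtype = c(subtype, subtype), stringsAsFactors = FALSE))
}

# shared measurement model on the log2 scale; true_fc: features x patients
# (added to tumor samples only)
sim_log2_matrix <- function(features, design, true_fc_by_patient, p) {
  n_f <- length(features)
  baseline <- stats::rnorm(n_f, p$baseline_log2_mean, p$baseline_log2_sd)
  patients <- design_patients(design)
  u <- matrix(stats::rnorm(n_f * length(patients), 0, p$patient_log2_sd),
              n_f, length(patients), dimnames = list(features, patients))
  offset <- stats::rnorm(nrow(design), 0, p$sample_scale_log2_sd)
  names(offset) <- design$sample
  vals <- matrix(NA_real_, n_f, nrow(design),
                 dimnames = list(features, design$sample))
  for (i in seq_len(nrow(design))) {
    s <- design$sample[i]; pt <- design$patient[i]
    mu <- baseline + u[, pt] + offset[s]
    if (design$tissue[i] == "tumor") mu <- mu + true_fc_by_patient[, pt]
    vals[, i] <- mu + stats::rnorm(n_f, 0, p$within_group_log2_sd)
  }
  list(log2 = vals, sample_offset = offset)
}

# intensity-dependent dropout: logistic in standardized log2 intensity with
# slope -mnar_strength, intercept solved so the mean dropout matches the
# requested rate
apply_mnar_dropout <- function(log2_vals, missing_rate, mnar_strength) {
  if (missing_rate == 0) return(log2_vals)
  z <- (log2_vals - mean(log2_vals)) / stats::sd(log2_vals)
  a <- stats::uniroot(function(a) mean(stats::plogis(a - mnar_strength * z)) - missing_rate,
                      c(-50, 50))$root
  drop <- stats::runif(length(z)) < stats::plogis(a - mnar_strength * z)
  log2_vals[drop] <- NA_real_
  log2_vals
}

#' Simulate a paired tumor/NAT protein intensity dataset
#'
#' Draws log-normal baseline abundances, adds a per-(feature, patient)
#' random effect shared by both members of a pair, plants
#' `frac_differential` of features at `planted_fc` (random direction, the
#' same true effect in both subtypes), adds per-sample scale offsets and
#' residual noise, and applies intensity-dependent dropout. Deterministic
#' for a fixed seed.
#'
#' @param params a [sim_params()] list.
#' @return list with `matrix` (linear-scale `IntensityMatrix`), `design`
#'   (`PairedDesign`) and `truth` (list: `feature_log2fc` features x
#'   subtypes matrix, `differential` character vector of planted feature
#'   ids, `sample_offset` named per-sample log2 offsets).
#' @export
simulate_protein_dataset <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    design <- sim_design(p$n_pairs_per_subtype)
    features <- sprintf("PROT%04d", seq_len(p$n_proteins))
    n_diff <- round(p$frac_differential * p$n_proteins)
    diff_idx <- if (n_diff > 0) sample(p$n_proteins, n_diff) else integer(0)
    signs <- sample(c(-1, 1), n_diff, replace = TRUE)
    l2fc <- matrix(0, p$n_proteins, 2, dimnames = list(features, c("IDC", "ILC")))
    l2fc[diff_idx, "IDC"] <- signs * log2(p$planted_fc)
    l2fc[diff_idx, "ILC"] <- signs * log2(p$planted_fc)
    subtype_of <- design$subtype[match(design_patients(design), design$patient)]
    fc_by_patient <- l2fc[, subtype_of, drop = FALSE]
    colnames(fc_by_patient) <- design_patients(design)
    gen <- sim_log2_matrix(features, design, fc_by_patient, p)
    vals <- apply_mnar_dropout(gen$log2, p$missing_rate, p$mnar_strength)
    list(matrix = intensity_matrix(2^vals, "linear"), design = design,
         truth = list(feature_log2fc = l2fc,
                      differential = features[sort(diff_idx)],
                      sample_offset = gen$sample_offset))
  })
}

#' Simulate a random kinase-substrate annotation table
#'
#' Builds a pool of genes each carrying a few serine/threonine sites and
#' assigns every kinase a random substrate set from the pool; used to
#' exercise KSEA without external annotation downloads.
#'
#' @param n_kinases number of kinases (`KIN001`, ...).
#' @param substrates_per_kinase substrate sites per kinase.
#' @param n_genes size of the substrate gene pool.
#' @param sites_per_gene sites carried by each pool gene.
#' @param seed integer seed.
#' @return data.frame with columns `kinase`, `substrate`, `site`.
#' @export
simulate_kinase_substrates <- function(n_kinases = 20, substrates_per_kinase = 10,
                                       n_genes = 500, sites_per_gene = 4,
                                       seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    pool <- data.frame(
      substrate = rep(genes, each = sites_per_gene),
      site = paste0(sample(c("S", "T"), n_genes * sites_per_gene,
                           replace = TRUE, prob = c(0.8, 0.2)),
                    sample(5:999, n_genes * sites_per_gene, replace = TRUE)),
      stringsAsFactors = FALSE)
    pool <- pool[!duplicated(paste(pool$substrate, pool$site)), ]
    out <- do.call(rbind, lapply(seq_len(n_kinases), function(k) {
      idx <- sample(nrow(pool), substrates_per_kinase)
      data.frame(kinase = sprintf("KIN%03d", k), pool[idx, ],
                 stringsAsFactors = FALSE)
    }))
    out <- out[!duplicated(out), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a paired tumor/NAT phosphosite dataset
#'
#' The site universe is the unique (substrate gene, site) set of the
#' annotation table, padded with background sites up to `n_sites`.
#' Substrate sites of each planted kinase receive that kinase's log2 shift
#' in tumor samples of `planted_kinase_subtype`; background sites carry no
#' true effect. Localization probabilities are drawn so that
#' `frac_low_localization` of sites fall at or below the 0.75 class-I
#' cutoff; multiplicities are drawn from {1, 2, 3}.
#'
#' @param params a [sim_params()] list.
#' @param annotations kinase-substrate table covering every planted kinase.
#' @return list with `sites` (a `phospho_sites` data.frame), `design` and
#'   `truth` (list: `site_log2fc` named per-site true tumor/NAT log2 FC in
#'   the planted subtype, `planted_kinases`, `sample_offset`).
#' @export
simulate_phospho_dataset <- function(params = sim_params(),
                                     annotations = simulate_kinase_substrates()) {
  p <- params
  planted <- p$planted_kinases
  if (length(planted)) {
    missing_k <- setdiff(toupper(names(planted)), toupper(annotations$kinase))
    if (length(missing_k))
      stop("planted kinase(s) with no annotated substrates: ",
           paste(missing_k, collapse = ", "))
  }
  with_seed(p$seed + 1L, {
    design <- sim_design(p$n_pairs_per_subtype)
    uni <- unique(annotations[, c("substrate", "site")])
    n_extra <- max(0, p$n_sites - nrow(uni))
    if (n_extra > 0) {
      extra <- data.frame(
        substrate = sprintf("BGENE%04d", seq_len(n_extra)),
        site = paste0("S", sample(5:999, n_extra, replace = TRUE)),
        stringsAsFactors = FALSE)
      uni <- rbind(uni, extra)
    } else {
      uni <- uni[seq_len(p$n_sites), , drop = FALSE]
    }
    key <- paste(toupper(uni$substrate), uni$site, sep = "|")

    site_shift <- stats::setNames(rep(0, nrow(uni)), key)
    for (k in names(planted)) {
      rows <- toupper(annotations$kinase) == toupper(k)
      kk <- paste(toupper(annotations$substrate[rows]), annotations$site[rows], sep = "|")
      kk <- intersect(kk, names(site_shift))
      site_shift[kk] <- site_shift[kk] + planted[[k]]
    }

    n_s <- nrow(uni)
    residue <- substr(uni$site, 1, 1)
    position <- as.integer(sub("^[STY]", "", uni$site))
    mult <- sample(1:3, n_s, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    n_low <- round(p$frac_low_localization * n_s)
    loc <- stats::runif(n_s, 0.76, 1)
    if (n_low > 0) loc[sample(n_s, n_low)] <- stats::runif(n_low, 0, 0.75)

    patients <- design_patients(design)
    subtype_of <- design$subtype[match(patients, design$patient)]
    fc_by_patient <- outer(site_shift,
                           as.numeric(subtype_of == p$planted_kinase_subtype))
    colnames(fc_by_patient) <- patients
    ids <- paste(uni$substrate, uni$site, mult, sep = ":")
    gen <- sim_log2_matrix(ids, design, fc_by_patient,
                           within(p, baseline_log2_mean <- baseline_log2_mean - 2))
    vals <- apply_mnar_dropout(gen$log2, p$missing_rate, p$mnar_strength)

    sites <- data.frame(protein = uni$substrate, gene = uni$substrate,
                        residue = residue, position = position,
                        localization_prob = loc, multiplicity = mult,
                        reverse = FALSE, contaminant = FALSE,
                        stringsAsFactors = FALSE, check.names = FALSE)
    sites <- cbind(sites, as.data.frame(2^vals, check.names = FALSE))
    rownames(sites) <- NULL
    class(sites) <- c("phospho_sites", "data.frame")
    list(sites = sites, design = design,
         truth = list(site_log2fc = site_shift,
                      planted_kinases = planted,
                      sample_offset = gen$sample_offset))
  })
}

#' Write a ready-made synthetic fixture bundle
#'
#' Writes, in the exact dialects the readers consume: `design.tsv`, a
#' MaxQuant-style `protein_groups.tsv`, a MaxQuant-style
#' `phospho_sites.tsv`, `kinase_substrates.tsv` (PhosphoSitePlus dialect),
#' `kinome_groups.tsv` and `truth.json`. Re-running with the same
#' parameters reproduces the files byte for byte.
#'
#' @param outdir output directory (created if absent).
#' @param params a [sim_params()] list.
#' @param annotations kinase-substrate table used for the phospho dataset.
#' @return named character vector of the six file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir,
                                 params = sim_params(n_proteins = 60, n_sites = 80),
                                 annotations = simulate_kinase_substrates(
                                   n_kinases = 5, substrates_per_kinase = 6,
                                   n_genes = 30, seed = params$seed)) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("cannot create output directory ", outdir)
  prot <- simulate_protein_dataset(params)
  phos <- simulate_phospho_dataset(params, annotations)
  paths <- c(design = file.path(outdir, "design.tsv"),
             proteins = file.path(outdir, "protein_groups.tsv"),
             phospho = file.path(outdir, "phospho_sites.tsv"),
             kinase_substrates = file.path(outdir, "kinase_substrates.tsv"),
             kinome_groups = file.path(outdir, "kinome_groups.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_design(prot$design, paths["design"])
  write_protein_table(prot$matrix, paths["proteins"])
  write_phospho_table(phos$sites, paths["phospho"])
  utils::write.table(
    data.frame(GENE = annotations$kinase, SUB_GENE = annotations$substrate,
               SUB_MOD_RSD = annotations$site, KIN_ORGANISM = "human",
               SUB_ORGANISM = "human"),
    paths["kinase_substrates"], sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(system.file("extdata", "kinome_groups.tsv", package = "phosphopair",
                        mustWork = TRUE), paths["kinome_groups"], overwrite = TRUE)
  truth <- list(
    protein = list(feature_log2fc = as.data.frame(prot$truth$feature_log2fc),
                   differential = prot$truth$differential,
                   sample_offset = as.list(prot$truth$sample_offset)),
    phospho = list(site_log2fc = as.list(phos$truth$site_log2fc),
                   planted_kinases = as.list(phos$truth$planted_kinases)))
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
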