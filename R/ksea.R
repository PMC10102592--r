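#' KSEA configuration
#'
#' @param p_cutoff two-tailed p-value cutoff for significance (strict `<`).
#' @param min_substrates minimum quantified substrate sites per kinase.
#' @return a `ksea_config` list.
#' @export
ksea_config <- function(p_cutoff = 0.05, min_substrates = 3L) {
  stopifnot(p_cutoff > 0, p_cutoff < 1, min_substrates >= 1)
  list(p_cutoff = p_cutoff, min_substrates = as.integer(min_substrates))
}

#' Kinase-substrate enrichment analysis (KSEA) z-scores
#'
#' For each kinase with at least one quantified substrate site, the kinase
#' activity score is
#' \deqn{z = (\bar{s} - \bar{p}) \sqrt{m} / \delta}
#' where \eqn{\bar{s}} is the mean log2 fold change over the kinase's m
#' quantified substrate sites, and \eqn{\bar{p}} and \eqn{\delta} are the
#' mean and sample (n-1) standard deviation of log2 fold changes over ALL
#' quantified sites. The two-tailed p-value is the standard-normal tail of
#' z. Positive z reads as kinase activation in tumor relative to NAT.
#'
#' Sites contribute once per (gene, site) key: duplicate quantifications
#' (e.g. multiplicity classes of the same site) are collapsed by their mean
#' log2 FC before scoring, and duplicate annotation rows mapping a kinase to
#' the same site count once. Gene/site matching is case-insensitive on gene
#' symbols and exact on the site string (e.g. `"S473"`).
#'
#' @param site_fc data.frame with columns `gene`, `site` and `log2fc`
#'   (finite values only are used).
#' @param annotations kinase-substrate table from
#'   [read_kinase_substrates()] (columns `kinase`, `substrate`, `site`).
#' @param cfg a [ksea_config()].
#' @return data.frame sorted by decreasing z: `kinase`, `m`,
#'   `mean_substrate_log2fc`, `global_mean_log2fc`, `global_sd_log2fc`, `z`,
#'   `p`, `direction` (`"activated"`/`"inactivated"`), `significant`.
#' @export
ksea_scores <- function(site_fc, annotations, cfg = ksea_config()) {
  stopifnot(all(c("gene", "site", "log2fc") %in% names(site_fc)))
  if (nrow(annotations) == 0) stop("empty kinase-substrate annotation table")
  ok <- is.finite(site_fc$log2fc)
  key <- paste(toupper(site_fc$gene[ok]), site_fc$site[ok], sep = "|")
  fc <- tapply(site_fc$log2fc[ok], key, mean)
  if (length(fc) < 2) stop("need at least 2 quantified sites for KSEA")
  p_bar <- mean(fc)
  delta <- stats::sd(fc)
  if (delta == 0) stop("degenerate background: all site log2 fold changes identical")

  ann_key <- paste(toupper(annotations$substrate), annotations$site, sep = "|")
  ann <- data.frame(kinase = toupper(annotations$kinase), key = ann_key,
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann), , drop = FALSE]
  ann <- ann[ann$key %in% names(fc), , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(kinase = character(0), m = integer(0),
                      mean_substrate_log2fc = numeric(0),
                      global_mean_log2fc = numeric(0),
                      global_sd_log2fc = numeric(0), z = numeric(0),
                      p = numeric(0), direction = character(0),
                      significant = logical(0)))
  sub_fc <- split(unname(fc[ann$key]), ann$kinase)
  m <- vapply(sub_fc, length, integer(1))
  s_bar <- vapply(sub_fc, mean, numeric(1))
  z <- (s_bar - p_bar) * sqrt(m) / delta
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(kinase = names(sub_fc), m = m,
                    mean_substrate_log2fc = unname(s_bar),
                    global_mean_log2fc = p_bar, global_sd_log2fc = delta,
                    z = unname(z), p = unname(p),
                    direction = ifelse(z > 0, "activated", "inactivated"),
                    significant = unname(p < cfg$p_cutoff & m >= cfg$min_substrates),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter KSEA results to significant kinases
#'
#' Keeps kinases with p below `p_cutoff` and at least `min_substrates`
#' quantified substrate sites.
#'
#' @param results output of [ksea_scores()].
#' @param cfg a [ksea_config()].
#' @return the filtered data.frame.
#' @export
significant_kinases <- function(results, cfg = ksea_config()) {
  out <- results[results$p < cfg$p_cutoff & results$m >= cfg$min_substrates, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate KSEA results with kinome groups
#'
#' Joins kinases (upper-cased gene symbols) against a kinase-to-group map;
#' unmapped kinases get `"unknown"`.
#'
#' @param results output of [ksea_scores()].
#' @param group_map data.frame with columns `kinase`, `group` (see
#'   [load_kinome_groups()]).
#' @return `results` with a `kinome_group` column appended.
#' @export
annotate_kinome_group <- function(results, group_map = load_kinome_groups()) {
  idx <- match(toupper(results$kinase), toupper(group_map$kinase))
  results$kinome_group <- ifelse(is.na(idx), "unknown", group_map$group[idx])
  results
}

#' Tally kinases per kinome group
#' @param results a KSEA result table with a `kinome_group` column.
#' @return data.frame `kinome_group`, `n`, sorted by decreasing count.
#' @export
kinome_group_tally <- function(results) {
  tab <- table(results$kinome_group)
  if (length(tab) == 0)
    return(data.frame(kinome_group = character(0), n = integer(0)))
  out <- data.frame(kinome_group = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$kinome_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare kinase activity profiles between two subtypes
#'
#' Set arithmetic on the kinase identities of two KSEA result tables plus a
#' table of kinases whose z-scores have opposite signs in the two subtypes.
#'
#' @param results_idc,results_ilc KSEA result tables from [ksea_scores()].
#' @return list with `n_idc_only`, `n_ilc_only`, `n_common` and
#'   `direction_table` (data.frame `kinase`, `z_idc`, `z_ilc` for kinases
#'   scored in both subtypes with opposite signs).
#' @export
compare_subtype_kinomes <- function(results_idc, results_ilc) {
  a <- results_idc$kinase; b <- results_ilc$kinase
  common <- intersect(a, b)
  zi <- results_idc$z[match(common, a)]
  zl <- results_ilc$z[match(common, b)]
  flip <- sign(zi) * sign(zl) < 0
  list(n_idc_only = length(setdiff(a, b)),
       n_ilc_only = length(setdiff(b, a)),
       n_common = length(common),
       direction_table = data.frame(kinase = common[flip], z_idc = zi[flip],
                                    z_ilc = zl[flip], stringsAsFactors = FALSE))
}

#' Site-level subtype log2 fold changes in KSEA input form
#'
#' Bridges a site-level [differential_screen()] table to [ksea_scores()]:
#' parses site feature keys, attaches gene symbols, and returns the subtype
#' geometric-mean pair fold changes on the log2 scale.
#'
#' @param site_diff site-level screen table (features keyed
#'   `"<protein>:<site>:<mult>"`).
#' @param gene_of optional named character vector mapping protein ids to
#'   gene symbols; defaults to using the protein id itself.
#' @return data.frame with `gene`, `site`, `log2fc`.
#' @export
site_fc_for_ksea <- function(site_diff, gene_of = NULL) {
  meta <- parse_site_feature(site_diff$feature)
  gene <- if (is.null(gene_of)) meta$protein
    else ifelse(is.na(gene_of[meta$protein]), meta$protein, gene_of[meta$protein])
  data.frame(gene = unname(gene), site = meta$site,
             log2fc = log2(site_diff$mean_fc), stringsAsFactors = FALSE)
}
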