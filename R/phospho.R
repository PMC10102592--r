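#' Filter phosphosites on localization confidence and decoy flags
#'
#' Keeps class-I sites: localization probability strictly greater than the
#' cutoff (default 0.75) and, when `drop_flags` is set, neither
#' reverse-decoy nor contaminant flagged.
#'
#' @param sites a `phospho_sites` data.frame from [read_phospho_table()].
#' @param min_localization_prob strict lower bound on localization
#'   probability.
#' @param drop_flags drop reverse/contaminant rows (default `TRUE`).
#' @return the filtered `phospho_sites` data.frame.
#' @export
filter_sites <- function(sites, min_localization_prob = 0.75, drop_flags = TRUE) {
  stopifnot(min_localization_prob >= 0, min_localization_prob <= 1)
  keep <- sites$localization_prob > min_localization_prob
  if (drop_flags) keep <- keep & !sites$reverse & !sites$contaminant
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Site counts by multiplicity class per (subtype, tissue) stratum
#'
#' A site row counts toward a stratum when it has at least one present
#' intensity in a sample of that stratum. Multiplicity classes are 1, 2 and
#' >=3 phosphates on the carrier peptide.
#'
#' @param sites a filtered `phospho_sites` data.frame.
#' @param design a `PairedDesign`.
#' @return data.frame with one row per (subtype, tissue): class counts
#'   `mult_1`, `mult_2`, `mult_3plus`, `n_sites` (their sum) and
#'   `n_phosphoproteins` (distinct proteins observed in the stratum).
#' @export
multiplicity_summary <- function(sites, design) {
  vals <- phospho_intensities(sites)
  strata <- unique(design[, c("subtype", "tissue")])
  strata <- strata[order(strata$subtype, strata$tissue), ]
  res <- lapply(seq_len(nrow(strata)), function(i) {
    samp <- design$sample[design$subtype == strata$subtype[i] &
                            design$tissue == strata$tissue[i]]
    present <- if (nrow(sites) == 0) logical(0)
      else rowSums(!is.na(vals[, samp, drop = FALSE])) > 0
    cls <- pmin(sites$multiplicity[present], 3L)
    data.frame(subtype = strata$subtype[i], tissue = strata$tissue[i],
               mult_1 = sum(cls == 1), mult_2 = sum(cls == 2),
               mult_3plus = sum(cls == 3), n_sites = length(cls),
               n_phosphoproteins = length(unique(sites$protein[present])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Site key "PROT:S15:2" used to bridge site rows to the matrix machinery
#' @noRd
site_feature_id <- function(sites) {
  paste(sites$protein, paste0(sites$residue, sites$position),
        sites$multiplicity, sep = ":")
}

#' Convert a phospho site table to an intensity matrix
#'
#' Feature ids are `"<protein>:<residue><position>:<multiplicity>"`, e.g.
#' `"P1:S15:2"`, so sites flow through the same normalization and screening
#' machinery as proteins.
#'
#' @param sites a filtered `phospho_sites` data.frame.
#' @return an `IntensityMatrix` on the linear scale.
#' @export
site_matrix <- function(sites) {
  ids <- site_feature_id(sites)
  if (anyDuplicated(ids))
    stop("duplicate site feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- phospho_intensities(sites)
  rownames(vals) <- ids
  intensity_matrix(vals, "linear")
}

#' Parse site feature ids back to (protein, site, multiplicity)
#' @param feature_ids character vector of `"<protein>:<residue><pos>:<mult>"` keys
#' @return data.frame with `protein`, `site`, `multiplicity`
#' @export
parse_site_feature <- function(feature_ids) {
  parts <- strsplit(feature_ids, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) stop("malformed site feature id: ", feature_ids[which(bad)[1]])
  data.frame(protein = vapply(parts, `[`, character(1), 1),
             site = vapply(parts, `[`, character(1), 2),
             multiplicity = as.integer(vapply(parts, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Aggregate site-level screen results to protein-level phosphorylation FCs
#'
#' Per protein: fold change is the median of its sites' log2 mean fold
#' changes, exponentiated (the `"mean"` method averages instead); `best_p`
#' is the minimum site p-value; `n_sites` the number of contributing site
#' records; `any_called` whether any site received a non-`ns` call.
#' Proteins with no site carrying a finite mean FC are absent from the
#' output.
#'
#' @param site_diff a site-level data.frame from [differential_screen()] run
#'   on a [site_matrix()].
#' @param method `"median"` (default) or `"mean"` across site log2 FCs.
#' @return data.frame with `protein`, `mean_fc` (linear), `best_p`,
#'   `n_sites`, `any_called`.
#' @export
aggregate_protein_phospho_fc <- function(site_diff, method = c("median", "mean")) {
  method <- match.arg(method)
  meta <- parse_site_feature(site_diff$feature)
  ok <- !is.na(site_diff$mean_fc)
  sd_ok <- site_diff[ok, , drop = FALSE]
  prot <- meta$protein[ok]
  if (!length(prot))
    return(data.frame(protein = character(0), mean_fc = numeric(0),
                      best_p = numeric(0), n_sites = integer(0),
                      any_called = logical(0)))
  agg_fun <- if (method == "median") stats::median else mean
  l2 <- split(log2(sd_ok$mean_fc), prot)
  p <- split(sd_ok$welch_p, prot)
  calls <- split(sd_ok$call, prot)
  out <- data.frame(
    protein = names(l2),
    mean_fc = 2^vapply(l2, agg_fun, numeric(1)),
    best_p = vapply(p, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE),
                    numeric(1)),
    n_sites = vapply(l2, length, integer(1)),
    any_called = vapply(calls, function(x) any(x != "ns"), logical(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
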