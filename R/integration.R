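#' Cross-subtype quadrant classification of fold changes
#'
#' Places each feature's (IDC fold change, ILC fold change) pair into one of
#' five mutually exclusive regions: up in both subtypes, down in both,
#' discordant in either direction, or `other` (at least one FC between the
#' thresholds). Thresholds are strict, matching the screen.
#'
#' @param fc_idc,fc_ilc linear tumor/NAT fold changes (vectors, > 0).
#' @param cfg a [screen_config()] supplying `fc_up` and `fc_down`.
#' @return character vector in `{"both_up", "both_down", "idc_up_ilc_down",
#'   "idc_down_ilc_up", "other"}`.
#' @export
quadrant_classify <- function(fc_idc, fc_ilc, cfg = screen_config()) {
  if (any(is.na(fc_idc)) || any(is.na(fc_ilc)) ||
      any(fc_idc <= 0) || any(fc_ilc <= 0))
    stop("fold changes must be present and strictly positive")
  up_i <- fc_idc > cfg$fc_up; dn_i <- fc_idc < cfg$fc_down
  up_l <- fc_ilc > cfg$fc_up; dn_l <- fc_ilc < cfg$fc_down
  out <- rep("other", length(fc_idc))
  out[up_i & up_l] <- "both_up"
  out[dn_i & dn_l] <- "both_down"
  out[up_i & dn_l] <- "idc_up_ilc_down"
  out[dn_i & up_l] <- "idc_down_ilc_up"
  out
}

#' Count features discordant between subtypes
#'
#' @param fc_idc,fc_ilc linear fold changes per feature.
#' @param cfg a [screen_config()].
#' @return named integer vector `c(idc_up_ilc_down = ..., idc_down_ilc_up = ...)`.
#' @export
opposite_direction_counts <- function(fc_idc, fc_ilc, cfg = screen_config()) {
  q <- quadrant_classify(fc_idc, fc_ilc, cfg)
  c(idc_up_ilc_down = sum(q == "idc_up_ilc_down"),
    idc_down_ilc_up = sum(q == "idc_down_ilc_up"))
}

#' Overlap between differential proteins and differential phosphoproteins
#'
#' @param diff_proteins,diff_phosphoproteins character vectors of protein
#'   identifiers (same key space).
#' @return named integer vector `n_both`, `n_protein_only`, `n_phospho_only`.
#' @export
overlap_diff_protein_phospho <- function(diff_proteins, diff_phosphoproteins) {
  a <- unique(diff_proteins); b <- unique(diff_phosphoproteins)
  c(n_both = length(intersect(a, b)),
    n_protein_only = length(setdiff(a, b)),
    n_phospho_only = length(setdiff(b, a)))
}

#' Directional state of a fold change
#'
#' `up` / `down` / `maintained` against the 1.5 and 1/1.5 thresholds. For
#' printed (2-decimal rounded) fold changes use `inclusive = TRUE`: a table
#' that prints 0.67 means a value rounded to 1/1.5, so the bounds must be
#' inclusive to reproduce printed groupings. Full-precision pipeline values
#' use the strict bounds.
#'
#' @param fc linear fold changes.
#' @param inclusive inclusive (`>=`/`<=`) or strict (`>`/`<`) bounds.
#' @param fc_up,fc_down thresholds.
#' @return character vector in `{"up", "down", "maintained"}` (`NA` in, `NA` out).
#' @export
fc_state <- function(fc, inclusive = FALSE, fc_up = 1.5, fc_down = 1 / 1.5) {
  # printed tables round 1/1.5 to 0.67; compare against the same rounding
  if (inclusive) fc_down <- round(fc_down, 2)
  up <- if (inclusive) fc >= fc_up else fc > fc_up
  down <- if (inclusive) fc <= fc_down else fc < fc_down
  ifelse(is.na(fc), NA_character_,
         ifelse(up, "up", ifelse(down, "down", "maintained")))
}

#' Protein/phosphorylation discordance groups across subtypes
#'
#' Classifies each feature's 4-tuple of states (protein-IDC, protein-ILC,
#' phospho-IDC, phospho-ILC) into discordance groups:
#' \describe{
#'   \item{G1}{protein up in both subtypes, phosphorylation up in IDC but
#'     down in ILC.}
#'   \item{G2}{protein not down in either subtype, phosphorylation down in
#'     IDC and not down in ILC.}
#'   \item{G3}{protein maintained in IDC and up in ILC, phosphorylation down
#'     or maintained in IDC and maintained or up in ILC.}
#' }
#' G2 and G3 overlap on part of the state space; precedence is most-specific
#' first (G1, then G3, then G2), and the `matches` column lists every
#' pattern a feature satisfies so borderline tuples are visible rather than
#' silently resolved.
#'
#' @param feature character vector of identifiers.
#' @param prot_idc,prot_ilc,phos_idc,phos_ilc linear fold changes per layer
#'   and subtype (`NA` = not detected).
#' @param inclusive use inclusive state bounds (set for printed 2-dp
#'   fold-change tables).
#' @return data.frame: `feature`, the four `state_*` columns, `group`
#'   (`"G1"`, `"G2"`, `"G3"` or `"unassigned"`) and `matches` (comma-joined
#'   list of all matching patterns, `""` if none).
#' @export
discordance_groups <- function(feature, prot_idc, prot_ilc, phos_idc, phos_ilc,
                               inclusive = FALSE) {
  s_pi <- fc_state(prot_idc, inclusive)
  s_pl <- fc_state(prot_ilc, inclusive)
  s_hi <- fc_state(phos_idc, inclusive)
  s_hl <- fc_state(phos_ilc, inclusive)
  complete <- !is.na(s_pi) & !is.na(s_pl) & !is.na(s_hi) & !is.na(s_hl)
  g1 <- complete & s_pi == "up" & s_pl == "up" & s_hi == "up" & s_hl == "down"
  g2 <- complete & s_pi != "down" & s_pl != "down" & s_hi == "down" & s_hl != "down"
  g3 <- complete & s_pi == "maintained" & s_pl == "up" &
    s_hi %in% c("down", "maintained") & s_hl %in% c("maintained", "up")
  group <- rep("unassigned", length(feature))
  group[g2] <- "G2"
  group[g3] <- "G3"
  group[g1] <- "G1"
  matches <- mapply(function(a, b, c_) paste(c("G1", "G2", "G3")[c(a, b, c_)],
                                             collapse = ","),
                    g1, g2, g3)
  data.frame(feature = feature, state_prot_idc = s_pi, state_prot_ilc = s_pl,
             state_phos_idc = s_hi, state_phos_ilc = s_hl,
             group = group, matches = matches, stringsAsFactors = FALSE)
}
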