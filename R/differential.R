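#' Screening thresholds for the paired differential analysis
#'
#' Defaults are the screen used throughout: Welch p < 0.05, mean fold change
#' > 1.50 (up) or < 1/1.5 = 0.67 (down), and strictly more than 60% of
#' quantified patient pairs individually crossing the fold-change threshold
#' in the call's direction ("more than 3 pairs of the 5"). The same 60%
#' fraction, strict, governs the patient-coverage filter.
#'
#' @param p_threshold two-tailed Welch p-value cutoff (strict `<`).
#' @param fc_up linear fold-change threshold for up-calls (strict `>`).
#' @param fc_down linear fold-change threshold for down-calls (strict `<`);
#'   defaults to `1 / fc_up`, displayed as 0.67.
#' @param concordance_fraction fraction of present pairs that must cross the
#'   per-pair fold-change threshold in the call direction (strict `>`).
#' @param min_pair_coverage_fraction fraction of all design pairs a feature
#'   must be quantified in (tumor and NAT both present) to enter the screen
#'   (strict `>`).
#' @param mean_fc_method `"geometric"` (mean of log2 pair ratios,
#'   exponentiated) or `"arithmetic"`.
#' @return a `screen_config` list.
#' @export
screen_config <- function(p_threshold = 0.05, fc_up = 1.5, fc_down = 1 / fc_up,
                          concordance_fraction = 0.60,
                          min_pair_coverage_fraction = 0.60,
                          mean_fc_method = c("geometric", "arithmetic")) {
  stopifnot(p_threshold > 0, p_threshold < 1, fc_up > 1,
            fc_down > 0, fc_down < 1,
            concordance_fraction > 0, concordance_fraction < 1,
            min_pair_coverage_fraction > 0, min_pair_coverage_fraction < 1)
  list(p_threshold = p_threshold, fc_up = fc_up, fc_down = fc_down,
       concordance_fraction = concordance_fraction,
       min_pair_coverage_fraction = min_pair_coverage_fraction,
       mean_fc_method = match.arg(mean_fc_method))
}

#' Keep features quantified in enough patient pairs
#'
#' A feature survives when it is present (non-missing) in both the tumor and
#' the NAT sample of strictly more than `min_pair_coverage_fraction` of all
#' pairs in the design (e.g. 7+ of 10 pairs at the default 60%).
#'
#' @param X an `IntensityMatrix` (either scale).
#' @param design a `PairedDesign`.
#' @param cfg a [screen_config()].
#' @return the filtered `IntensityMatrix`.
#' @export
patient_coverage_filter <- function(X, design, cfg = screen_config()) {
  pr <- design_pairs(design)
  v <- X$values
  cover <- !is.na(v[, pr$tumor, drop = FALSE]) & !is.na(v[, pr$nat, drop = FALSE])
  keep <- rowSums(cover) > cfg$min_pair_coverage_fraction * length(pr$patients)
  X$values <- v[keep, , drop = FALSE]
  X
}

#' Per-patient tumor/NAT fold changes
#'
#' @param X an `IntensityMatrix` on the linear scale (normalized).
#' @param design a `PairedDesign`.
#' @param subtype `"IDC"` or `"ILC"`.
#' @return numeric matrix, features x patients, of linear tumor/NAT ratios;
#'   `NA` where either member of the pair is missing.
#' @export
pair_fold_changes <- function(X, design, subtype) {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "linear") stop("pair_fold_changes expects the linear scale")
  pr <- design_pairs(design, subtype)
  fc <- X$values[, pr$tumor, drop = FALSE] / X$values[, pr$nat, drop = FALSE]
  colnames(fc) <- pr$patients
  fc
}

#' Two-tailed Welch t-test, tumor group vs NAT group, per feature
#'
#' Vectorized over features: the Welch unequal-variance statistic with
#' Welch-Satterthwaite degrees of freedom, on log2 intensities, comparing
#' all tumor samples to all NAT samples of the given subtype (unpaired
#' form). Features with fewer than 2 present values in either group get
#' `NA` (not callable). Zero pooled variance with a zero mean difference
#' gives p = 1.
#'
#' @param X an `IntensityMatrix` on the log2 scale.
#' @param design a `PairedDesign`.
#' @param subtype `"IDC"` or `"ILC"`.
#' @return named numeric vector of two-tailed p-values, one per feature.
#' @export
welch_test <- function(X, design, subtype) {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "log2") stop("welch_test expects the log2 scale")
  d <- design[design$subtype == subtype, ]
  a <- X$values[, d$sample[d$tissue == "tumor"], drop = FALSE]
  b <- X$values[, d$sample[d$tissue == "NAT"], drop = FALSE]
  welch_two_sample(a, b)
}

# rowwise Welch test of two matrices (groups in columns); returns p-values
welch_two_sample <- function(a, b) {
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- row_var(a, ma); vb <- row_var(b, mb)
  se2 <- va / na_ + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # identical groups: t = 0/0; the mean difference is 0, so no evidence
  p[is.nan(t_stat) & abs(ma - mb) < .Machine$double.eps^0.5] <- 1
  p[na_ < 2 | nb < 2] <- NA_real_
  names(p) <- rownames(a)
  p
}

row_var <- function(m, mu) {
  n <- rowSums(!is.na(m))
  rowSums((m - mu)^2, na.rm = TRUE) / (n - 1)
}

#' Concordant-pair fractions
#'
#' For each feature, the fraction of present pair fold changes at or beyond
#' the per-pair threshold in each direction: `frac_up` counts pairs with
#' FC >= `fc_up`, `frac_down` pairs with FC <= `fc_down`, both over the
#' number of present (quantified) pairs.
#'
#' @param pair_fcs matrix of linear pair fold changes from
#'   [pair_fold_changes()].
#' @param cfg a [screen_config()].
#' @return data.frame with `frac_up`, `frac_down`, `n_pairs_present`;
#'   fractions are `NA` when no pair is present (feature not callable).
#' @export
concordance_fractions <- function(pair_fcs, cfg = screen_config()) {
  n_present <- rowSums(!is.na(pair_fcs))
  frac_up <- rowSums(pair_fcs >= cfg$fc_up, na.rm = TRUE) / n_present
  frac_down <- rowSums(pair_fcs <= cfg$fc_down, na.rm = TRUE) / n_present
  frac_up[n_present == 0] <- NA_real_
  frac_down[n_present == 0] <- NA_real_
  data.frame(frac_up = frac_up, frac_down = frac_down,
             n_pairs_present = n_present, row.names = rownames(pair_fcs))
}

#' Apply the three-criterion differential call
#'
#' `up` requires p < `p_threshold` AND mean FC > `fc_up` AND
#' `frac_up` > `concordance_fraction` (all strict); `down` is symmetric with
#' `fc_down` and `frac_down`; anything else — including features with a
#' missing p-value or undefined fractions — is `ns`.
#'
#' @param mean_fc vector of linear mean fold changes.
#' @param welch_p vector of two-tailed p-values.
#' @param frac_up,frac_down concordant-pair fractions.
#' @param cfg a [screen_config()].
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
call_differential <- function(mean_fc, welch_p, frac_up, frac_down,
                              cfg = screen_config()) {
  up <- !is.na(welch_p) & welch_p < cfg$p_threshold &
    !is.na(mean_fc) & mean_fc > cfg$fc_up &
    !is.na(frac_up) & frac_up > cfg$concordance_fraction
  down <- !is.na(welch_p) & welch_p < cfg$p_threshold &
    !is.na(mean_fc) & mean_fc < cfg$fc_down &
    !is.na(frac_down) & frac_down > cfg$concordance_fraction
  ifelse(up, "up", ifelse(down, "down", "ns"))
}

#' Run the full paired differential screen for one subtype
#'
#' Combines [pair_fold_changes()], the subtype mean fold change (geometric
#' by default), [welch_test()], [concordance_fractions()] and
#' [call_differential()] into one per-feature table. Input must already be
#' normalized; apply [patient_coverage_filter()] beforehand if desired.
#'
#' @param X an `IntensityMatrix` on the log2 scale (normalized).
#' @param design a `PairedDesign`.
#' @param subtype `"IDC"` or `"ILC"`.
#' @param cfg a [screen_config()].
#' @return data.frame with one row per feature: `feature`, `subtype`,
#'   `mean_fc` (linear), `welch_p`, `frac_up`, `frac_down`,
#'   `n_pairs_present`, `call`, plus one `fc_<patient>` column per pair.
#' @export
differential_screen <- function(X, design, subtype, cfg = screen_config()) {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "log2") stop("differential_screen expects the log2 scale")
  fc <- pair_fold_changes(to_linear(X), design, subtype)
  mean_fc <- if (cfg$mean_fc_method == "geometric")
    2^rowMeans(log2(fc), na.rm = TRUE)
  else rowMeans(fc, na.rm = TRUE)
  mean_fc[rowSums(!is.na(fc)) == 0] <- NA_real_
  p <- welch_test(X, design, subtype)
  cons <- concordance_fractions(fc, cfg)
  call <- call_differential(mean_fc, p, cons$frac_up, cons$frac_down, cfg)
  out <- data.frame(feature = rownames(X$values), subtype = subtype,
                    mean_fc = unname(mean_fc), welch_p = unname(p),
                    frac_up = cons$frac_up, frac_down = cons$frac_down,
                    n_pairs_present = cons$n_pairs_present,
                    call = call, stringsAsFactors = FALSE)
  fc_df <- as.data.frame(fc)
  names(fc_df) <- paste0("fc_", colnames(fc))
  rownames(out) <- NULL
  cbind(out, fc_df, row.names = NULL)
}
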