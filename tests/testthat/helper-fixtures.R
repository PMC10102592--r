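# In-code fixture builders shared across the suite. Everything is generated
# at test time; no binary fixtures.

toy_design <- function(n_per_subtype = 5) {
  pts <- sprintf("P%02d", seq_len(2 * n_per_subtype))
  paired_design(data.frame(
    sample = c(paste0(pts, "_T"), paste0(pts, "_N")),
    patient = c(pts, pts),
    tissue = rep(c("tumor", "NAT"), each = length(pts)),
    subtype = rep(rep(c("IDC", "ILC"), each = n_per_subtype), 2),
    stringsAsFactors = FALSE))
}

write_toy_design <- function(design = toy_design(), path = tempfile(fileext = ".tsv")) {
  write_design(design, path)
  path
}

# a small proteinGroups-dialect file; `grid` is features x samples (0 = MaxQuant
# missing), rownames may contain ";"-joined accession lists
write_toy_protein_file <- function(grid, design, path = tempfile(fileext = ".txt"),
                                   reverse = rep("", nrow(grid)),
                                   contaminant = rep("", nrow(grid))) {
  df <- data.frame(`Majority protein IDs` = rownames(grid),
                   Reverse = reverse, `Potential contaminant` = contaminant,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- grid
  colnames(vals) <- paste("Intensity", design$sample)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a Phospho(STY)Sites-dialect file from a list of site rows; each element of
# `sites` is list(protein, gene, aa, pos, prob, intensities = list(`1` = vec, ...))
write_toy_phospho_file <- function(sites, design, path = tempfile(fileext = ".txt")) {
  ns <- nrow(design)
  base <- data.frame(
    Protein = vapply(sites, `[[`, character(1), "protein"),
    `Gene names` = vapply(sites, function(s) s$gene %||% s$protein, character(1)),
    `Amino acid` = vapply(sites, `[[`, character(1), "aa"),
    Position = vapply(sites, function(s) as.character(s$pos), character(1)),
    `Localization prob` = vapply(sites, `[[`, numeric(1), "prob"),
    Reverse = vapply(sites, function(s) s$reverse %||% "", character(1)),
    `Potential contaminant` = vapply(sites, function(s) s$contaminant %||% "", character(1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (k in 1:3) {
    block <- t(vapply(sites, function(s) {
      v <- s$intensities[[as.character(k)]]
      if (is.null(v)) rep(0, ns) else v
    }, numeric(ns)))
    colnames(block) <- paste0("Intensity ", design$sample, "___", k)
    base <- cbind(base, as.data.frame(block, check.names = FALSE))
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small linear intensity matrix
toy_matrix <- function(design, n_features = 20, seed = 42) {
  set.seed(seed)
  v <- matrix(2^rnorm(n_features * nrow(design), 20, 1), n_features,
              dimnames = list(sprintf("F%03d", seq_len(n_features)), design$sample))
  intensity_matrix(v, "linear")
}
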