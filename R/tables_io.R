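#' Read a paired sample design table
#'
#' Reads a TSV/CSV with columns `sample`, `patient`, `tissue` (tumor/NAT) and
#' `subtype` (IDC/ILC) and validates the pairing invariant: every patient has
#' exactly one tumor and one NAT sample and one subtype.
#'
#' @param path path to the design file (tab- or comma-separated; the
#'   separator is sniffed from the header line).
#' @return A `PairedDesign` data.frame.
#' @export
read_design <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("no samples: design file is empty")
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0) stop("no samples in design file ", path)
  paired_design(d)
}

#' Write a design table as TSV
#' @param design a `PairedDesign`
#' @param path output path
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated proteinGroups-dialect table: intensity columns named
#' `"<prefix> <sample_id>"` (default prefix `"Intensity"`), optional `Reverse`
#' and `Potential contaminant` columns marked `"+"`. Decoy and contaminant
#' rows are dropped; intensity 0 becomes missing (`NA`), following the
#' MaxQuant convention that 0 means "not quantified". The feature id is the
#' first accession of the `Majority protein IDs` field.
#'
#' @param path path to the TSV.
#' @param design a `PairedDesign`; intensity columns are matched and ordered
#'   against its sample ids.
#' @param intensity_prefix column-family prefix, `"Intensity"` or
#'   `"LFQ intensity"`.
#' @return An `IntensityMatrix` on the linear scale.
#' @export
read_protein_table <- function(path, design, intensity_prefix = "Intensity") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- if ("Majority protein IDs" %in% names(tab)) "Majority protein IDs"
            else if ("Protein IDs" %in% names(tab)) "Protein IDs"
            else stop("no 'Majority protein IDs' or 'Protein IDs' column in ", path)
  wanted <- paste(intensity_prefix, design$sample)
  missing_cols <- wanted[!wanted %in% names(tab)]
  if (length(missing_cols))
    stop("no intensity column for design sample(s): ",
         paste(sub(paste0("^", intensity_prefix, " "), "", missing_cols), collapse = ", "))
  tab <- drop_flagged_rows(tab)
  ids <- vapply(strsplit(tab[[id_col]], ";", fixed = TRUE), `[`, character(1), 1)
  vals <- as.matrix(tab[, wanted, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[vals == 0] <- NA_real_
  rownames(vals) <- ids
  colnames(vals) <- design$sample
  intensity_matrix(vals, "linear")
}

# MaxQuant flag convention: "+" marks reverse-decoy / contaminant rows
drop_flagged_rows <- function(tab) {
  keep <- rep(TRUE, nrow(tab))
  for (col in c("Reverse", "Potential contaminant", "Contaminant"))
    if (col %in% names(tab)) keep <- keep & !(tab[[col]] %in% "+")
  tab[keep, , drop = FALSE]
}

#' Read a MaxQuant-style Phospho(STY)Sites table
#'
#' Parses the Phospho(STY)Sites dialect: per-sample, per-multiplicity
#' intensity columns `"Intensity <sample>___k"` (k = 1,2,3 phosphates on the
#' carrier peptide), plus `Localization prob`, `Amino acid`, `Position` and
#' protein/gene columns. Emits one row per (site, multiplicity) that has a
#' non-missing intensity in at least one sample. No localization-probability
#' filtering happens here; that is a separate stage ([filter_sites()]).
#'
#' @param path path to the TSV.
#' @param design a `PairedDesign`.
#' @param intensity_prefix intensity column-family prefix.
#' @return A `phospho_sites` data.frame: metadata columns `protein`, `gene`,
#'   `residue`, `position`, `localization_prob`, `multiplicity`, `reverse`,
#'   `contaminant`, followed by one intensity column per design sample
#'   (`NA` = missing).
#' @export
read_phospho_table <- function(path, design, intensity_prefix = "Intensity") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("Localization prob", "Amino acid", "Position"))
    if (!col %in% names(tab)) stop("missing mandatory column '", col, "' in ", path)
  prot_col <- intersect(c("Protein", "Proteins", "Leading proteins"), names(tab))[1]
  if (is.na(prot_col)) stop("no protein id column in ", path)
  gene_col <- intersect(c("Gene names", "Gene name"), names(tab))[1]

  pos_raw <- tab[["Position"]]
  pos <- suppressWarnings(as.integer(pos_raw))
  bad <- which(is.na(pos) | pos != suppressWarnings(as.numeric(pos_raw)))
  if (length(bad))
    stop("malformed position '", pos_raw[bad[1]], "' at row ", bad[1], " of ", path)

  mult_cols <- lapply(1:3, function(k) {
    cols <- paste0(intensity_prefix, " ", design$sample, "___", k)
    if (all(cols %in% names(tab))) cols else NULL
  })
  have_mult <- which(!vapply(mult_cols, is.null, logical(1)))
  if (!length(have_mult))
    stop("no '", intensity_prefix, " <sample>___k' columns matching the design in ", path)

  prot <- vapply(strsplit(as.character(tab[[prot_col]]), ";", fixed = TRUE), `[`, character(1), 1)
  gene <- if (!is.na(gene_col))
    vapply(strsplit(as.character(tab[[gene_col]]), ";", fixed = TRUE), `[`, character(1), 1)
  else prot

  out <- list()
  for (k in have_mult) {
    vals <- as.matrix(tab[, mult_cols[[k]], drop = FALSE])
    storage.mode(vals) <- "double"
    vals[vals == 0] <- NA_real_
    colnames(vals) <- design$sample
    any_present <- rowSums(!is.na(vals)) > 0
    if (!any(any_present)) next
    meta <- data.frame(
      protein = prot, gene = gene,
      residue = as.character(tab[["Amino acid"]]),
      position = pos,
      localization_prob = as.numeric(tab[["Localization prob"]]),
      multiplicity = k,
      reverse = if ("Reverse" %in% names(tab)) tab[["Reverse"]] %in% "+" else FALSE,
      contaminant = if ("Potential contaminant" %in% names(tab))
        tab[["Potential contaminant"]] %in% "+" else FALSE,
      stringsAsFactors = FALSE, check.names = FALSE)
    out[[k]] <- cbind(meta, as.data.frame(vals, check.names = FALSE))[any_present, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  key <- paste(res$protein, res$position, res$multiplicity)
  if (anyDuplicated(key))
    stop("duplicate (protein, position, multiplicity) rows in ", path)
  class(res) <- c("phospho_sites", "data.frame")
  res
}

#' Metadata column names of a phospho site table
#' @noRd
phospho_meta_cols <- function() {
  c("protein", "gene", "residue", "position", "localization_prob",
    "multiplicity", "reverse", "contaminant")
}

#' Sample intensity sub-matrix of a phospho site table
#' @param sites a `phospho_sites` data.frame
#' @return numeric matrix, one row per site row, `NA` = missing
#' @export
phospho_intensities <- function(sites) {
  cols <- setdiff(names(sites), phospho_meta_cols())
  m <- as.matrix(as.data.frame(sites)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Read a kinase-substrate annotation table
#'
#' PhosphoSitePlus Kinase_Substrate_Dataset dialect: mandatory columns
#' `GENE` or `KINASE`, `SUB_GENE`, `SUB_MOD_RSD` (site string such as
#' `"S473"`); optional `KIN_ORGANISM` / `SUB_ORGANISM` for organism
#' filtering. Duplicate (kinase, substrate, site) triples are removed.
#'
#' @param path path to the TSV.
#' @param organism_filter if given (e.g. `"human"`), keep only rows where
#'   both organism columns match it (case-insensitive).
#' @return data.frame with columns `kinase`, `substrate`, `site`.
#' @export
read_kinase_substrates <- function(path, organism_filter = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  kin_col <- intersect(c("GENE", "KINASE"), names(tab))[1]
  if (is.na(kin_col)) stop("missing mandatory column 'GENE' (or 'KINASE')")
  for (col in c("SUB_GENE", "SUB_MOD_RSD"))
    if (!col %in% names(tab)) stop("missing mandatory column '", col, "'")
  if (!is.null(organism_filter)) {
    for (col in c("KIN_ORGANISM", "SUB_ORGANISM"))
      if (col %in% names(tab))
        tab <- tab[tolower(tab[[col]]) == tolower(organism_filter), , drop = FALSE]
  }
  out <- data.frame(kinase = as.character(tab[[kin_col]]),
                    substrate = as.character(tab[["SUB_GENE"]]),
                    site = as.character(tab[["SUB_MOD_RSD"]]),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an intensity matrix as TSV
#'
#' One `feature` column then one column per sample; missing cells written as
#' `NA` (never 0, so the MaxQuant zero convention cannot re-enter through a
#' round trip).
#'
#' @param X an `IntensityMatrix`
#' @param path output path
#' @export
write_intensity_tsv <- function(X, path) {
  df <- data.frame(feature = rownames(X$values), X$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity matrix written by [write_intensity_tsv()]
#' @param path TSV path
#' @param scale scale of the stored values
#' @return an `IntensityMatrix`
#' @export
read_intensity_tsv <- function(path, scale = "linear") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$feature
  intensity_matrix(vals, scale)
}

#' The printed 13-protein dual-layer fold-change fixture
#'
#' Thirteen proteins with printed tumor/NAT fold changes for protein
#' expression and (where detected) phosphorylation, per subtype (IDC, ILC).
#' `NA` phospho values correspond to "ND" (not detected) in the source table;
#' exactly three proteins have ND phosphorylation.
#'
#' @return data.frame with columns `protein_label`, `prot_fc_idc`,
#'   `prot_fc_ilc`, `phos_fc_idc`, `phos_fc_ilc`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2.csv", package = "phosphopair", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 13)
  df
}

#' Bundled kinase to kinome-group map
#'
#' Two-column TSV mapping kinase gene symbols to the ten sequence-based
#' kinome groups (AGC, CAMK, CK1, CMGC, STE, TK, TKL, RGC, Atypical, Other).
#' The bundled map covers common exemplars; it is a fixture, not a complete
#' kinome classification.
#'
#' @param path optional path to a user-supplied two-column TSV
#'   (`kinase`, `group`); defaults to the bundled map.
#' @return data.frame with columns `kinase`, `group`.
#' @export
load_kinome_groups <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinome_groups.tsv", package = "phosphopair",
                        mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("kinase", "group") %in% names(df)))
    stop("kinome group map needs columns 'kinase' and 'group'")
  df$kinase <- toupper(df$kinase)
  df
}

#' Write a phospho site table in the Phospho(STY)Sites dialect
#'
#' Inverse of [read_phospho_table()]: rows sharing a (protein, position) site
#' are collapsed to one output row with `___k` multiplicity-suffixed
#' intensity columns; missing cells are written as 0 per the MaxQuant
#' convention.
#'
#' @param sites a `phospho_sites` data.frame
#' @param path output path
#' @param intensity_prefix intensity column-family prefix
#' @export
write_phospho_table <- function(sites, path, intensity_prefix = "Intensity") {
  samp <- setdiff(names(sites), phospho_meta_cols())
  key <- paste(sites$protein, sites$position, sep = "\r")
  first <- !duplicated(key)
  base <- data.frame(
    `Protein` = sites$protein[first],
    `Gene names` = sites$gene[first],
    `Amino acid` = sites$residue[first],
    `Position` = sites$position[first],
    `Localization prob` = sites$localization_prob[first],
    `Reverse` = ifelse(sites$reverse[first], "+", ""),
    `Potential contaminant` = ifelse(sites$contaminant[first], "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  row_of <- match(key, key[first])
  for (k in sort(unique(sites$multiplicity))) {
    block <- matrix(0, nrow(base), length(samp),
                    dimnames = list(NULL, paste0(intensity_prefix, " ", samp, "___", k)))
    sel <- sites$multiplicity == k
    vals <- phospho_intensities(sites[sel, , drop = FALSE])
    vals[is.na(vals)] <- 0
    block[row_of[sel], ] <- vals
    base <- cbind(base, as.data.frame(block, check.names = FALSE))
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an intensity matrix in the proteinGroups dialect
#'
#' Inverse of [read_protein_table()]: feature ids go to
#' `Majority protein IDs`, missing cells are written as 0 per the MaxQuant
#' convention, and empty `Reverse` / `Potential contaminant` columns are
#' emitted.
#'
#' @param X an `IntensityMatrix` on the linear scale.
#' @param path output path.
#' @param intensity_prefix intensity column-family prefix.
#' @export
write_protein_table <- function(X, path, intensity_prefix = "Intensity") {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "linear") stop("write_protein_table expects the linear scale")
  vals <- X$values
  vals[is.na(vals)] <- 0
  colnames(vals) <- paste(intensity_prefix, colnames(vals))
  df <- data.frame(`Majority protein IDs` = rownames(X$values),
                   Reverse = "", `Potential contaminant` = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
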