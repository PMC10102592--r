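#' Intensity matrix container
#'
#' A features x samples matrix of non-negative abundances with explicit
#' missingness (`NA`), carrying its scale state so linear/log2 confusion is
#' impossible downstream. Missing is always `NA`, never 0: MaxQuant writes 0
#' for "not quantified", and the readers convert at parse time.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing.
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `IntensityMatrix`: a list with elements
#'   `values` and `scale`.
#' @export
intensity_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in intensity matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in intensity matrix")
  present <- values[!is.na(values)]
  if (any(!is.finite(present)))
    stop("present values must be finite")
  if (scale == "linear" && any(present < 0))
    stop("linear intensities must be non-negative")
  structure(list(values = values, scale = scale), class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("IntensityMatrix: %d features x %d samples [%s scale], %.1f%% missing\n",
              nrow(v), ncol(v), x$scale, 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

#' Construct and validate a paired sample design
#'
#' @param samples data.frame with columns `sample`, `patient`, `tissue`
#'   (`"tumor"`/`"NAT"`) and `subtype` (`"IDC"`/`"ILC"`).
#' @return A validated `PairedDesign` data.frame. Every patient must
#'   contribute exactly one tumor and one NAT sample and carry a single
#'   subtype label.
#' @export
paired_design <- function(samples) {
  req <- c("sample", "patient", "tissue", "subtype")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  d <- as.data.frame(samples)[, req]
  for (col in req) d[[col]] <- as.character(d[[col]])
  if (nrow(d) == 0) stop("no samples in design")
  if (anyDuplicated(d$sample))
    stop("duplicate sample ids: ", paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  bad_tissue <- setdiff(unique(d$tissue), c("tumor", "NAT"))
  if (length(bad_tissue)) stop("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "))
  bad_sub <- setdiff(unique(d$subtype), c("IDC", "ILC"))
  if (length(bad_sub)) stop("unknown subtype label(s): ", paste(bad_sub, collapse = ", "))
  for (p in unique(d$patient)) {
    rows <- d[d$patient == p, ]
    if (sum(rows$tissue == "tumor") != 1 || sum(rows$tissue == "NAT") != 1)
      stop("patient ", p, " must have exactly one tumor and one NAT sample")
    if (length(unique(rows$subtype)) != 1)
      stop("patient ", p, " has inconsistent subtype labels")
  }
  class(d) <- c("PairedDesign", "data.frame")
  d
}

#' Patients of a design, optionally restricted to one subtype
#' @param design a `PairedDesign`
#' @param subtype optional `"IDC"` or `"ILC"`
#' @return character vector of patient ids
#' @export
design_patients <- function(design, subtype = NULL) {
  d <- design
  if (!is.null(subtype)) d <- d[d$subtype == subtype, ]
  unique(d$patient)
}

#' Sample id for a (patient, tissue) pair
#' @noRd
design_sample <- function(design, patient, tissue) {
  s <- design$sample[design$patient == patient & design$tissue == tissue]
  if (length(s) != 1) stop("design lookup failed for patient ", patient)
  s
}

# tumor/NAT sample id vectors, aligned by patient, for a subtype (or all)
design_pairs <- function(design, subtype = NULL) {
  pts <- design_patients(design, subtype)
  list(patients = pts,
       tumor = vapply(pts, function(p) design_sample(design, p, "tumor"), character(1)),
       nat   = vapply(pts, function(p) design_sample(design, p, "NAT"), character(1)))
}
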