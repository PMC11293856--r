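# Compositional preprocessing: occurrence filter, multiplicative zero
# imputation, centred log-ratio transform.

#' Filter taxa by occurrence
#'
#' Keeps taxa observed (raw abundance > 0) in at least `minOccurrence`
#' samples; the sample set and the order of retained taxa are unchanged.
#' The marine-plankton default of 10 out of 80 samples motivates the
#' default.
#'
#' @param x an [AdmExperiment-class]
#' @param minOccurrence positive integer, at most the number of samples
#' @return the filtered [AdmExperiment-class]
#' @examples
#' ae <- AdmExperiment(matrix(c(1, 2, 0, 0, 3, 0), nrow = 2))
#' dim(filterByOccurrence(ae, 1))
#' @export
filterByOccurrence <- function(x, minOccurrence = 10L) {
  stopifnot(is(x, "AdmExperiment"))
  minOccurrence <- as.integer(minOccurrence)
  if (minOccurrence < 1L) stop("minOccurrence must be a positive integer")
  if (minOccurrence > ncol(x))
    stop("minOccurrence (", minOccurrence, ") exceeds the number of samples (",
         ncol(x), ")")
  occ <- rowSums(abundances(x) > 0)
  keep <- occ >= minOccurrence
  if (!any(keep))
    stop("no taxon reaches an occurrence of ", minOccurrence, " samples; ",
         "all ", nrow(x), " taxa would be removed")
  x[keep, ]
}

#' Impute zeros by multiplicative replacement
#'
#' Every zero entry is replaced by the global minimum non-zero value of the
#' table multiplied by `factor` (default 0.65), forcing the imputed value
#' below the observed minimum; non-zero entries are untouched. The factor
#' and the minimum used are recorded in `metadata()` for provenance.
#' Idempotent: a strictly positive table passes through unchanged.
#'
#' @param x an [AdmExperiment-class] with at least one non-zero entry
#' @param factor real in (0, 1)
#' @return the [AdmExperiment-class] with an added `"imputed"` assay
#' @examples
#' ae <- AdmExperiment(matrix(c(0, 4, 2, 8), nrow = 2))
#' SummarizedExperiment::assay(imputeZeros(ae), "imputed")
#' @export
imputeZeros <- function(x, factor = 0.65) {
  stopifnot(is(x, "AdmExperiment"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor >= 1)
    stop("factor must be a single real in (0, 1)")
  a <- abundances(x)
  nz <- a[a > 0]
  if (!length(nz)) stop("cannot impute an all-zero table")
  minNonZero <- min(nz)
  imp <- a
  imp[imp == 0] <- minNonZero * factor
  SummarizedExperiment::assay(x, "imputed") <- imp
  S4Vectors::metadata(x)$imputeFactor <- factor
  S4Vectors::metadata(x)$imputeMinNonZero <- minNonZero
  validObject(x)
  x
}

#' Centred log-ratio transform
#'
#' For each sample i (column), `clr[j, i] = log(x[j, i]) - mean_j
#' log(x[., i])` using the natural logarithm, so each sample's CLR values
#' sum to zero (closure). Requires strictly positive input: run
#' [imputeZeros()] first (the `"imputed"` assay is used when present).
#'
#' @param x an [AdmExperiment-class]
#' @return the [AdmExperiment-class] with an added `"clr"` assay
#' @export
clrTransform <- function(x) {
  stopifnot(is(x, "AdmExperiment"))
  src <- if ("imputed" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "imputed") else abundances(x)
  if (any(src <= 0))
    stop("abundances must be strictly positive for CLR; ",
         "impute zeros first with imputeZeros()")
  lg <- log(src)
  clr <- sweep(lg, 2L, colMeans(lg), "-")
  SummarizedExperiment::assay(x, "clr") <- clr
  validObject(x)
  x
}
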