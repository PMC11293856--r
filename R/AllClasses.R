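#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats var cor quantile kmeans lm coef predict runif rnorm sd
#'   setNames complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' AdmExperiment: compositional abundance data with sample metadata
#'
#' `AdmExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and is the entry
#' container of the package. The `"abundance"` assay holds raw non-negative
#' relative abundances (taxa as rows, samples as columns); `colData()`
#' carries the per-sample metadata used downstream (`latitude`, `longitude`,
#' `depth`, `month`, `size_fraction`). [imputeZeros()] adds an `"imputed"`
#' assay and [clrTransform()] a `"clr"` assay; presence/absence is always
#' defined on the raw `"abundance"` assay, because imputation makes every
#' entry positive and would otherwise destroy occurrence information.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class]; no
#'   additional slots, the class exists to attach validity and methods.
#'
#' @seealso [AdmExperiment()] the constructor, [clrTransform()],
#'   [allPairsRho()]
#' @export
setClass("AdmExperiment", contains = "SummarizedExperiment")

setValidity("AdmExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "abundance values must be finite")
    else if (any(a < 0))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if ("clr" %in% SummarizedExperiment::assayNames(object)) {
    cl <- SummarizedExperiment::assay(object, "clr")
    if (any(!is.finite(cl)))
      msg <- c(msg, "clr assay contains non-finite entries")
    else if (nrow(cl) > 0 && max(abs(colSums(cl))) > 1e-9)
      msg <- c(msg, "clr assay columns (samples) must sum to 0 (closure)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AdmExperiment from a sample x taxon abundance matrix
#'
#' @param abundance numeric matrix of non-negative abundances. Orientation
#'   is auto-resolved from `sampleMeta` row names when possible; with no
#'   metadata, rows are taken as samples (the on-disk TSV convention) unless
#'   `samplesAsRows = FALSE`.
#' @param sampleMeta `data.frame` keyed by sample id (row names or a
#'   `sample_id` column) with columns such as `latitude`, `longitude`,
#'   `depth`, `month`, `size_fraction`. Optional.
#' @param samplesAsRows logical; does `abundance` have samples as rows?
#' @return an [AdmExperiment-class] with taxa as rows and samples as columns.
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 3, 5), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB", "taxC")))
#' ae <- AdmExperiment(m)
#' dim(ae)  # 3 taxa x 2 samples
#' @export
AdmExperiment <- function(abundance, sampleMeta = NULL, samplesAsRows = TRUE) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- if (samplesAsRows)
      paste0("sample", seq_len(nrow(abundance))) else
      paste0("taxon", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- if (samplesAsRows)
      paste0("taxon", seq_len(ncol(abundance))) else
      paste0("sample", seq_len(ncol(abundance)))
  if (!is.null(sampleMeta)) {
    sampleMeta <- as.data.frame(sampleMeta)
    if (is.null(rownames(sampleMeta)) || all(rownames(sampleMeta) == seq_len(nrow(sampleMeta)))) {
      if ("sample_id" %in% names(sampleMeta)) {
        rownames(sampleMeta) <- sampleMeta$sample_id
        sampleMeta$sample_id <- NULL
      }
    }
    ids <- rownames(sampleMeta)
    if (all(rownames(abundance) %in% ids)) samplesAsRows <- TRUE
    else if (all(colnames(abundance) %in% ids)) samplesAsRows <- FALSE
  }
  if (samplesAsRows) abundance <- t(abundance)
  cd <- if (is.null(sampleMeta)) S4Vectors::DataFrame(row.names = colnames(abundance))
        else S4Vectors::DataFrame(sampleMeta[colnames(abundance), , drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  new("AdmExperiment", se)
}

#' AssociationSet: all-pairs proportionality results
#'
#' Holds the proportionality metric rho = 1 - var(mj - mk) /
#' (var(mj) + var(mk)) for every unordered taxon pair of a CLR matrix,
#' optionally with bootstrap-FDR significance thresholds applied. Pairs for
#' which both CLR vectors are constant (rho undefined) are excluded and
#' listed in `dropped`.
#'
#' @slot pairs data.frame with columns `taxon_j`, `taxon_k` (j < k in taxon
#'   order), `rho`, and after [callSignificance()] also `significant`
#'   (logical) and `sign` (`"positive"`/`"negative"`/`NA`).
#' @slot thresholds numeric `c(t_neg, t_pos)` or `NA` before calling.
#' @slot fdrLevel numeric FDR level the thresholds were derived at, or `NA`.
#' @slot nSamples integer number of samples rho was computed over.
#' @slot dropped character, taxon pairs excluded as constant ("j|k").
#' @export
setClass("AssociationSet",
  representation(pairs = "data.frame", thresholds = "numeric",
                 fdrLevel = "numeric", nSamples = "integer",
                 dropped = "character"),
  prototype(thresholds = c(t_neg = NA_real_, t_pos = NA_real_),
            fdrLevel = NA_real_, nSamples = 0L, dropped = character()))

setValidity("AssociationSet", function(object) {
  p <- object@pairs
  msg <- character()
  need <- c("taxon_j", "taxon_k", "rho")
  if (!all(need %in% names(p)))
    msg <- c(msg, "pairs must have columns taxon_j, taxon_k, rho")
  else {
    if (nrow(p) && max(abs(p$rho)) > 1 + 1e-9)
      msg <- c(msg, "|rho| must be <= 1")
    if (anyDuplicated(paste(p$taxon_j, p$taxon_k, sep = "|")))
      msg <- c(msg, "duplicate pairs")
    if ("significant" %in% names(p) && !all(is.na(object@thresholds))) {
      want <- p$rho >= object@thresholds[["t_pos"]] |
              p$rho <= object@thresholds[["t_neg"]]
      if (!identical(as.logical(want), as.logical(p$significant)))
        msg <- c(msg, "significance flags inconsistent with thresholds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AlphaMatrix: per-sample local contributions of one association
#'
#' The alpha decomposition of a pair's rho: `alpha[i]` is the squared
#' deviation of the per-sample CLR difference from its mean, normalized by
#' the summed squared deviations of the two taxa, so that
#' `1 - sum(alpha) == rho` exactly (to numerical tolerance). Each alpha is
#' therefore non-negative.
#'
#' @slot pair character(2), the taxon ids.
#' @slot alpha numeric vector, one non-negative value per sample.
#' @slot sampleIds character aligned to `alpha`.
#' @export
setClass("AlphaMatrix",
  representation(pair = "character", alpha = "numeric",
                 sampleIds = "character"))

setValidity("AlphaMatrix", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must have length 2")
  if (length(object@alpha) != length(object@sampleIds))
    msg <- c(msg, "alpha and sampleIds lengths differ")
  if (any(!is.finite(object@alpha))) msg <- c(msg, "alpha must be finite")
  else if (length(object@alpha) && min(object@alpha) < -1e-12)
    msg <- c(msg, "alpha components must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EnvTable: per-sample environmental predictors
#'
#' @slot sampleIds character sample ids.
#' @slot features numeric matrix (samples x predictors), no missing values.
#' @slot featureNames character predictor names; defaults follow the marine
#'   use case: temperature (degC), salinity (PSU), nitrate and silicate
#'   (umol kg-1).
#' @export
setClass("EnvTable",
  representation(sampleIds = "character", features = "matrix",
                 featureNames = "character"))

setValidity("EnvTable", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@sampleIds))
    msg <- c(msg, "feature rows must match sampleIds")
  if (ncol(object@features) != length(object@featureNames))
    msg <- c(msg, "feature columns must match featureNames")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "featureNames must be unique")
  if (anyNA(object@features) || any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite (no missing values)")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvTable
#'
#' @param features numeric matrix or data.frame, samples x predictors.
#' @param sampleIds character; defaults to the row names of `features`.
#' @return an [EnvTable-class]
#' @export
EnvTable <- function(features, sampleIds = rownames(features)) {
  features <- as.matrix(features)
  if (is.null(sampleIds)) sampleIds <- as.character(seq_len(nrow(features)))
  rownames(features) <- sampleIds
  new("EnvTable", sampleIds = as.character(sampleIds), features = features,
      featureNames = colnames(features))
}

#' CooccurrenceStates: the three per-sample states of a pair
#'
#' `copresence` (both raw abundances > 0), `coabsence` (both 0), `exclusion`
#' (exactly one present).
#'
#' @slot pair character(2).
#' @slot states factor over samples with levels
#'   `copresence`, `coabsence`, `exclusion`.
#' @slot sampleIds character aligned to states.
#' @export
setClass("CooccurrenceStates",
  representation(pair = "character", states = "factor",
                 sampleIds = "character"))

setValidity("CooccurrenceStates", function(object) {
  msg <- character()
  if (!identical(levels(object@states),
                 c("copresence", "coabsence", "exclusion")))
    msg <- c(msg, "states levels must be copresence, coabsence, exclusion")
  if (length(object@states) != length(object@sampleIds))
    msg <- c(msg, "states and sampleIds lengths differ")
  if (length(msg)) msg else TRUE
})

#' AdmModel: a fitted association distribution model
#'
#' Either a cADM (three-state co-occurrence classifier) or an rADM (alpha
#' regressor) for one association pair, with its cross-validated
#' performance, training feature ranges (used for projection masking) and
#' the training sample count needed for rho* reconstruction.
#'
#' @slot pair character(2).
#' @slot variant `"cADM"` or `"rADM"`.
#' @slot learner `"random_forest"`, `"gradient_boosting"`, `"svm"` or
#'   `"memorize"` (an exact-interpolation diagnostic learner).
#' @slot predictors character feature names, in training order.
#' @slot fit list: opaque engine payload.
#' @slot performance named numeric: `balanced_accuracy` (cADM) or `r2`
#'   (rADM), estimated by cross-validation on the training data only.
#' @slot trainingRanges numeric matrix 2 x p (rows `q2.5`, `q97.5`) of
#'   per-feature training quantiles.
#' @slot nTrain integer number of training samples.
#' @slot trainingRho numeric; the observed rho of the pair (rADM) or NA.
#' @slot seed integer seed the fit was performed under.
#' @export
setClass("AdmModel",
  representation(pair = "character", variant = "character",
                 learner = "character", predictors = "character",
                 fit = "list", performance = "numeric",
                 trainingRanges = "matrix", nTrain = "integer",
                 trainingRho = "numeric", seed = "integer"))

setValidity("AdmModel", function(object) {
  msg <- character()
  if (!object@variant %in% c("cADM", "rADM"))
    msg <- c(msg, "variant must be 'cADM' or 'rADM'")
  if (!object@learner %in% c("random_forest", "gradient_boosting", "svm",
                             "memorize"))
    msg <- c(msg, "unknown learner")
  if (ncol(object@trainingRanges) != length(object@predictors))
    msg <- c(msg, "trainingRanges columns must match predictors")
  if (length(msg)) msg else TRUE
})

#' FeatureImportance: permutation feature importance of an AdmModel
#'
#' Mean drop in model performance when one predictor column is permuted;
#' may be negative for useless features.
#'
#' @slot pair character(2).
#' @slot importance named numeric, one value per predictor.
#' @slot nRepeats integer permutations per feature.
#' @slot seed integer.
#' @export
setClass("FeatureImportance",
  representation(pair = "character", importance = "numeric",
                 nRepeats = "integer", seed = "integer"))

#' GridField: environmental values on lat/lon cells at one time point
#'
#' @slot cells data.frame with `lat` in \[-90, 90\] and `lon` normalized to
#'   \[-180, 180).
#' @slot features numeric matrix (cells x predictors).
#' @slot timeLabel character, e.g. `"present"`, `"2015"`.
#' @slot validMask logical per cell; predictions are made on valid cells
#'   only.
#' @export
setClass("GridField",
  representation(cells = "data.frame", features = "matrix",
                 timeLabel = "character", validMask = "logical"))

setValidity("GridField", function(object) {
  msg <- character()
  if (!all(c("lat", "lon") %in% names(object@cells)))
    msg <- c(msg, "cells must have lat and lon columns")
  else {
    if (nrow(object@cells) != nrow(object@features))
      msg <- c(msg, "cells and features row counts differ")
    if (length(object@validMask) != nrow(object@cells))
      msg <- c(msg, "validMask length must match cells")
    if (nrow(object@cells)) {
      if (anyDuplicated(paste(object@cells$lat, object@cells$lon)))
        msg <- c(msg, "cell coordinates must be unique")
      if (any(object@cells$lat < -90 | object@cells$lat > 90))
        msg <- c(msg, "lat must lie in [-90, 90]")
      if (any(object@cells$lon < -180 | object@cells$lon >= 180))
        msg <- c(msg, "lon must be normalized to [-180, 180)")
      if (any(object@validMask & !stats::complete.cases(object@features)))
        msg <- c(msg, "features must be finite on valid cells")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridField
#'
#' @param cells data.frame with columns `lat`, `lon` (longitudes are
#'   normalized to \[-180, 180)).
#' @param features numeric matrix/data.frame of predictors per cell.
#' @param timeLabel character time label.
#' @param validMask logical per cell; defaults to rows with finite features.
#' @return a [GridField-class]
#' @export
GridField <- function(cells, features, timeLabel = "present",
                      validMask = NULL) {
  cells <- as.data.frame(cells)
  cells$lon <- normalizeLongitude(cells$lon)
  features <- as.matrix(features)
  if (is.null(validMask)) validMask <- stats::complete.cases(features)
  new("GridField", cells = cells[, c("lat", "lon")], features = features,
      timeLabel = as.character(timeLabel), validMask = as.logical(validMask))
}

#' Normalize longitudes to \[-180, 180)
#' @param lon numeric degrees
#' @return numeric
#' @examples normalizeLongitude(359.5)  # -0.5
#' @export
normalizeLongitude <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' ProjectionResult: an AdmModel evaluated over a grid
#'
#' @slot pair character(2).
#' @slot variant `"cADM"` or `"rADM"`.
#' @slot timeLabel character.
#' @slot cellIndex integer indices of the valid grid cells predicted.
#' @slot states factor predictions (cADM) or zero-length.
#' @slot alphaStar numeric predictions (rADM) or zero-length.
#' @slot copresenceProportion numeric; fraction of valid cells predicted
#'   copresent (cADM), `NA` when no valid cells.
#' @slot rhoStarGlobal numeric; `1 - (nTrain/G) * sum(alphaStar)` (rADM).
#' @slot rhoStarByRegion named numeric, same reconstruction per region.
#' @export
setClass("ProjectionResult",
  representation(pair = "character", variant = "character",
                 timeLabel = "character", cellIndex = "integer",
                 states = "factor", alphaStar = "numeric",
                 copresenceProportion = "numeric", rhoStarGlobal = "numeric",
                 rhoStarByRegion = "numeric"),
  prototype(copresenceProportion = NA_real_, rhoStarGlobal = NA_real_,
            rhoStarByRegion = setNames(numeric(), character())))

#' ClusterResult: biogeographic signature clustering
#'
#' @slot associationIds character.
#' @slot labels integer cluster label per association, in `1..chosenK`.
#' @slot silhouetteByK named numeric, mean silhouette per scanned k.
#' @slot chosenK integer, the k maximizing mean silhouette.
#' @slot centers matrix of the chosen fit's centroids.
#' @slot seed integer.
#' @export
setClass("ClusterResult",
  representation(associationIds = "character", labels = "integer",
                 silhouetteByK = "numeric", chosenK = "integer",
                 centers = "matrix", seed = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@associationIds))
    msg <- c(msg, "labels must align with associationIds")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@chosenK))
    msg <- c(msg, "labels must lie in 1..chosenK")
  k <- names(object@silhouetteByK)[which.max(object@silhouetteByK)]
  if (length(k) && as.integer(k) != object@chosenK)
    msg <- c(msg, "chosenK must maximize silhouette")
  if (length(msg)) msg else TRUE
})

#' AssociationGraph: a weighted graph of significant associations
#'
#' Nodes are taxa, edges are association pairs weighted by reconstructed
#' global rho*.
#'
#' @slot graph an igraph object (undirected, no self loops).
#' @slot cluster character cluster label the graph belongs to.
#' @export
setClass("AssociationGraph",
  representation(graph = "ANY", cluster = "character"))

setValidity("AssociationGraph", function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::any_loop(g)) msg <- c(msg, "self loops are not allowed")
    w <- igraph::E(g)$weight
    if (!is.null(w) && any(!is.finite(w)))
      msg <- c(msg, "edge weights must be finite")
  }
  if (length(msg)) msg else TRUE
})
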