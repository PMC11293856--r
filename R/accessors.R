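# Accessors and show() methods. Slot access stays internal; user code goes
# through these.

#' @rdname AdmExperiment
#' @param object,x an object of the documented class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AdmExperiment
#' @export
setMethod("abundances", "AdmExperiment", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname AdmExperiment
#' @export
setGeneric("clrValues", function(x) standardGeneric("clrValues"))

#' @rdname AdmExperiment
#' @export
setMethod("clrValues", "AdmExperiment", function(x) {
  if (!"clr" %in% SummarizedExperiment::assayNames(x))
    stop("no 'clr' assay: run imputeZeros() then clrTransform() first")
  SummarizedExperiment::assay(x, "clr")
})

#' @rdname AdmExperiment
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' Presence/absence on the raw (pre-imputation) abundances
#' @rdname AdmExperiment
#' @export
setMethod("presenceMatrix", "AdmExperiment", function(x)
  abundances(x) > 0)

#' @rdname AdmExperiment
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname AdmExperiment
#' @export
setMethod("taxonIds", "AdmExperiment", function(x) rownames(x))

#' @rdname AdmExperiment
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AdmExperiment
#' @export
setMethod("sampleIds", "AdmExperiment", function(x) colnames(x))

#' @rdname AdmExperiment
#' @export
setMethod("sampleIds", "EnvTable", function(x) x@sampleIds)

#' @rdname AdmExperiment
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname AdmExperiment
#' @export
setMethod("sampleData", "AdmExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "AdmExperiment", function(object) {
  cat("AdmExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  md <- S4Vectors::metadata(object)
  if (!is.null(md$imputeFactor))
    cat("  zeros imputed with factor", md$imputeFactor, "\n")
})

#' @rdname AssociationSet
#' @param x an AssociationSet
#' @export
setGeneric("associationPairs", function(x) standardGeneric("associationPairs"))

#' Pair table of an AssociationSet
#' @rdname AssociationSet
#' @export
setMethod("associationPairs", "AssociationSet", function(x) x@pairs)

#' @rdname AssociationSet
#' @export
setGeneric("rhoValues", function(x) standardGeneric("rhoValues"))

#' @rdname AssociationSet
#' @export
setMethod("rhoValues", "AssociationSet", function(x)
  setNames(x@pairs$rho, paste(x@pairs$taxon_j, x@pairs$taxon_k, sep = "|")))

#' @rdname AssociationSet
#' @export
setGeneric("rhoThresholds", function(x) standardGeneric("rhoThresholds"))

#' @rdname AssociationSet
#' @export
setMethod("rhoThresholds", "AssociationSet", function(x) x@thresholds)

#' Significant pairs of an AssociationSet
#'
#' @param x an [AssociationSet-class] with thresholds applied
#' @param sign `"any"`, `"positive"` or `"negative"`
#' @return data.frame of significant pairs
#' @export
significantPairs <- function(x, sign = c("any", "positive", "negative")) {
  sign <- match.arg(sign)
  p <- x@pairs
  if (!"significant" %in% names(p))
    stop("no significance calls: run callSignificance() first")
  p <- p[p$significant, , drop = FALSE]
  if (sign != "any") p <- p[p$sign == sign, , drop = FALSE]
  p
}

setMethod("show", "AssociationSet", function(object) {
  cat("AssociationSet:", nrow(object@pairs), "pairs over",
      object@nSamples, "samples\n")
  if (!all(is.na(object@thresholds)))
    cat(sprintf("  thresholds: t_neg = %.3g, t_pos = %.3g (FDR %.3g); %d significant\n",
                object@thresholds[["t_neg"]], object@thresholds[["t_pos"]],
                object@fdrLevel, sum(object@pairs$significant)))
  if (length(object@dropped))
    cat("  dropped constant pairs:", length(object@dropped), "\n")
})

#' @rdname AlphaMatrix
#' @param x an AlphaMatrix
#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))

#' Per-sample alpha values
#' @rdname AlphaMatrix
#' @export
setMethod("alphaValues", "AlphaMatrix", function(x)
  setNames(x@alpha, x@sampleIds))

setMethod("show", "AlphaMatrix", function(object) {
  cat(sprintf("AlphaMatrix: %s | %s over %d samples; rho = 1 - sum(alpha) = %.6g\n",
              object@pair[1], object@pair[2], length(object@alpha),
              1 - sum(object@alpha)))
})

#' @rdname EnvTable
#' @param x an EnvTable
#' @export
setGeneric("envFeatures", function(x) standardGeneric("envFeatures"))

#' Feature matrix of an EnvTable
#' @rdname EnvTable
#' @export
setMethod("envFeatures", "EnvTable", function(x) x@features)

#' @rdname EnvTable
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname EnvTable
#' @export
setMethod("featureNames", "EnvTable", function(x) x@featureNames)

#' @rdname EnvTable
#' @export
setMethod("featureNames", "GridField", function(x) colnames(x@features))

setMethod("show", "EnvTable", function(object) {
  cat("EnvTable:", length(object@sampleIds), "samples x",
      length(object@featureNames), "predictors (",
      paste(object@featureNames, collapse = ", "), ")\n")
})

#' @rdname CooccurrenceStates
#' @param x a CooccurrenceStates
#' @export
setGeneric("stateVector", function(x) standardGeneric("stateVector"))

#' The per-sample state factor
#' @rdname CooccurrenceStates
#' @export
setMethod("stateVector", "CooccurrenceStates", function(x)
  setNames(x@states, x@sampleIds))

setMethod("show", "CooccurrenceStates", function(object) {
  cat(sprintf("CooccurrenceStates: %s | %s\n", object@pair[1], object@pair[2]))
  print(table(object@states))
})

#' @rdname AdmModel
#' @param x an AdmModel
#' @export
setGeneric("modelPerformance", function(x) standardGeneric("modelPerformance"))

#' Cross-validated performance of an AdmModel
#' @rdname AdmModel
#' @export
setMethod("modelPerformance", "AdmModel", function(x) x@performance)

#' @rdname AdmModel
#' @export
setGeneric("trainingRanges", function(x) standardGeneric("trainingRanges"))

#' @rdname AdmModel
#' @export
setMethod("trainingRanges", "AdmModel", function(x) x@trainingRanges)

#' @rdname AdmModel
#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))

#' @rdname AdmModel
#' @export
setMethod("modelVariant", "AdmModel", function(x) x@variant)

setMethod("show", "AdmModel", function(object) {
  cat(sprintf("%s [%s] %s | %s: %s = %.4g (CV), n = %d\n",
              object@variant, object@learner, object@pair[1], object@pair[2],
              names(object@performance)[1], object@performance[1],
              object@nTrain))
})

setMethod("show", "FeatureImportance", function(object) {
  cat(sprintf("FeatureImportance (%s | %s, %d repeats):\n",
              object@pair[1], object@pair[2], object@nRepeats))
  print(round(object@importance, 6))
})

#' @rdname FeatureImportance
#' @param x a FeatureImportance
#' @export
setGeneric("importanceValues", function(x) standardGeneric("importanceValues"))

#' Per-feature importance values
#' @rdname FeatureImportance
#' @export
setMethod("importanceValues", "FeatureImportance", function(x) x@importance)

#' @rdname GridField
#' @param x a GridField
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))

#' Cell coordinate table
#' @rdname GridField
#' @export
setMethod("gridCells", "GridField", function(x) x@cells)

#' @rdname GridField
#' @export
setGeneric("gridFeatures", function(x) standardGeneric("gridFeatures"))

#' @rdname GridField
#' @export
setMethod("gridFeatures", "GridField", function(x) x@features)

#' @rdname GridField
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname GridField
#' @export
setMethod("validMask", "GridField", function(x) x@validMask)

#' @rdname GridField
#' @export
setGeneric("timeLabel", function(x) standardGeneric("timeLabel"))

#' @rdname GridField
#' @export
setMethod("timeLabel", "GridField", function(x) x@timeLabel)

#' @rdname GridField
#' @export
setMethod("timeLabel", "ProjectionResult", function(x) x@timeLabel)

setMethod("show", "GridField", function(object) {
  cat(sprintf("GridField '%s': %d cells (%d valid), predictors: %s\n",
              object@timeLabel, nrow(object@cells), sum(object@validMask),
              paste(colnames(object@features), collapse = ", ")))
})

#' @rdname ProjectionResult
#' @param x a ProjectionResult
#' @export
setGeneric("copresenceProportion",
           function(x) standardGeneric("copresenceProportion"))

#' Fraction of valid cells predicted co-present (cADM)
#' @rdname ProjectionResult
#' @export
setMethod("copresenceProportion", "ProjectionResult", function(x)
  x@copresenceProportion)

#' @rdname ProjectionResult
#' @export
setGeneric("rhoStar", function(x) standardGeneric("rhoStar"))

#' Reconstructed global rho* (rADM); raw value, clip at reporting time only
#' @rdname ProjectionResult
#' @export
setMethod("rhoStar", "ProjectionResult", function(x) x@rhoStarGlobal)

#' @rdname ProjectionResult
#' @export
setGeneric("rhoStarByRegion", function(x) standardGeneric("rhoStarByRegion"))

#' @rdname ProjectionResult
#' @export
setMethod("rhoStarByRegion", "ProjectionResult", function(x)
  x@rhoStarByRegion)

#' @rdname ProjectionResult
#' @export
setGeneric("predictedStates", function(x) standardGeneric("predictedStates"))

#' @rdname ProjectionResult
#' @export
setMethod("predictedStates", "ProjectionResult", function(x) x@states)

#' @rdname ProjectionResult
#' @export
setGeneric("predictedAlpha", function(x) standardGeneric("predictedAlpha"))

#' @rdname ProjectionResult
#' @export
setMethod("predictedAlpha", "ProjectionResult", function(x) x@alphaStar)

setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf("ProjectionResult %s '%s' (%s | %s): %d cells",
              object@variant, object@timeLabel, object@pair[1],
              object@pair[2], length(object@cellIndex)))
  if (object@variant == "cADM")
    cat(sprintf("; copresence proportion = %.3f\n",
                object@copresenceProportion))
  else cat(sprintf("; rho* = %.4g\n", object@rhoStarGlobal))
})

#' @rdname ClusterResult
#' @param x a ClusterResult
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Cluster label per association
#' @rdname ClusterResult
#' @export
setMethod("clusterLabels", "ClusterResult", function(x)
  setNames(x@labels, x@associationIds))

#' @rdname ClusterResult
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname ClusterResult
#' @export
setMethod("chosenK", "ClusterResult", function(x) x@chosenK)

#' @rdname ClusterResult
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))

#' @rdname ClusterResult
#' @export
setMethod("silhouetteByK", "ClusterResult", function(x) x@silhouetteByK)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d associations, chosen k = %d (mean silhouette %.3f)\n",
              length(object@labels), object@chosenK,
              max(object@silhouetteByK)))
  print(table(cluster = object@labels))
})

#' @rdname AssociationGraph
#' @param x an AssociationGraph
#' @export
setGeneric("graphOf", function(x) standardGeneric("graphOf"))

#' The underlying igraph object
#' @rdname AssociationGraph
#' @export
setMethod("graphOf", "AssociationGraph", function(x) x@graph)

setMethod("show", "AssociationGraph", function(object) {
  cat(sprintf("AssociationGraph [%s]: %d taxa, %d associations\n",
              object@cluster, igraph::vcount(object@graph),
              igraph::ecount(object@graph)))
})
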