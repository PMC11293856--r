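# Biogeographic signature clustering of stacked co-occurrence projections
# and association-graph topology per cluster.

#' Stack co-presence indicators of many projections
#'
#' Builds the associations x valid-cells 0/1 matrix used for signature
#' clustering: entry 1 iff the projection predicts `copresence` in that
#' cell. All projections must come from the same masked grid (same valid
#' cell index).
#'
#' @param projections list of cADM [ProjectionResult-class] objects
#' @return integer matrix with one row per association (named "j|k")
#' @export
stackCopresence <- function(projections) {
  if (!length(projections)) stop("no projections supplied")
  idx <- projections[[1L]]@cellIndex
  rows <- lapply(projections, function(p) {
    if (p@variant != "cADM") stop("stackCopresence needs cADM projections")
    if (!identical(p@cellIndex, idx))
      stop("projections were made on different grids/masks")
    as.integer(p@states == "copresence")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(projections, function(p)
    paste(p@pair, collapse = "|"), character(1))
  colnames(out) <- paste0("cell", idx)
  out
}

#' Cluster association signatures with k-means and silhouette selection
#'
#' Runs k-means (10 restarts, Euclidean distance on the raw stacked 0/1
#' matrix) for each k in `kRange` and picks the k with the highest mean
#' silhouette width; exact silhouette ties resolve to the smaller k. For
#' large inputs the silhouette is evaluated on a seeded subsample of at
#' most `silhouetteMaxRows` rows. Deterministic for a fixed seed.
#'
#' @param stacked matrix from [stackCopresence()] (associations x cells)
#' @param kRange integer vector of cluster counts to scan (default 2:15)
#' @param seed integer
#' @param nstart k-means restarts per k (default 10)
#' @param silhouetteMaxRows subsample cap for silhouette evaluation
#' @return a [ClusterResult-class]
#' @export
clusterSignatures <- function(stacked, kRange = 2:15, seed = 1L,
                              nstart = 10L, silhouetteMaxRows = 5000L) {
  stacked <- as.matrix(stacked)
  n <- nrow(stacked)
  kRange <- sort(unique(as.integer(kRange)))
  if (n < max(kRange) + 1L)
    stop("need at least max(kRange) + 1 associations (have ", n, ")")
  if (nrow(unique(stacked)) < 2L)
    stop("all signatures identical: silhouette (and clustering) undefined")
  sub <- seq_len(n)
  if (n > silhouetteMaxRows)
    sub <- withSeed(seed, sort(sample.int(n, silhouetteMaxRows)))
  dsub <- stats::dist(stacked[sub, , drop = FALSE])
  sil <- setNames(rep(NA_real_, length(kRange)), kRange)
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    fit <- withSeed(seed + k, tryCatch(
      suppressWarnings(stats::kmeans(stacked, centers = k, nstart = nstart,
                                     iter.max = 100L)),
      error = function(e) NULL))
    if (is.null(fit)) next
    fits[[i]] <- fit
    lab <- fit$cluster[sub]
    if (length(unique(lab)) < 2L) next
    sw <- cluster::silhouette(lab, dsub)
    sil[i] <- mean(sw[, "sil_width"])
  }
  if (all(is.na(sil)))
    stop("k-means failed for every k in the scanned range")
  best <- which.max(sil)   # ties: first, i.e. smallest k
  fit <- fits[[best]]
  new("ClusterResult", associationIds = rownames(stacked),
      labels = as.integer(fit$cluster), silhouetteByK = sil,
      chosenK = kRange[best], centers = fit$centers,
      seed = as.integer(seed))
}

#' Build the weighted association graph of a cluster
#'
#' Nodes are taxa, undirected edges are association pairs weighted by the
#' reconstructed global rho*. Pairs must be unique; self loops are
#' impossible by construction of pairs but rejected defensively.
#'
#' @param associations data.frame with columns `taxon_j`, `taxon_k` and
#'   `rho_star` (used as edge weight)
#' @param cluster label of the cluster the graph describes
#' @return an [AssociationGraph-class]
#' @export
buildGraph <- function(associations, cluster = "all") {
  associations <- as.data.frame(associations)
  need <- c("taxon_j", "taxon_k", "rho_star")
  if (!all(need %in% names(associations)))
    stop("associations must have columns taxon_j, taxon_k, rho_star")
  if (nrow(associations)) {
    key <- paste(pmin(associations$taxon_j, associations$taxon_k),
                 pmax(associations$taxon_j, associations$taxon_k),
                 sep = "|")
    if (anyDuplicated(key)) stop("duplicate association pair(s)")
    if (any(associations$taxon_j == associations$taxon_k))
      stop("self association (taxon paired with itself)")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = associations$taxon_j, to = associations$taxon_k,
               weight = associations$rho_star), directed = FALSE)
  new("AssociationGraph", graph = g, cluster = as.character(cluster))
}

#' Edge betweenness centrality
#'
#' For each edge, the sum over node pairs of the fraction of shortest
#' paths passing through it, on the unweighted shortest-path structure
#' (association weights do not define a distance, so they are ignored for
#' path finding — the stock behaviour of common centrality routines). With
#' `normalized = TRUE` (default) values are divided by the n(n-1)/2 node
#' pairs.
#'
#' @param graph an [AssociationGraph-class]
#' @param normalized divide by the number of node pairs?
#' @return named numeric, one value per edge ("a|b")
#' @export
edgeBetweennessCentrality <- function(graph, normalized = TRUE) {
  stopifnot(is(graph, "AssociationGraph"))
  g <- graphOf(graph)
  if (igraph::ecount(g) == 0L)
    return(setNames(numeric(), character()))
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  if (normalized) {
    n <- igraph::vcount(g)
    eb <- eb / (n * (n - 1) / 2)
  }
  ends <- igraph::ends(g, igraph::E(g))
  setNames(eb, paste(ends[, 1L], ends[, 2L], sep = "|"))
}

#' Edge-per-node ratio (the non-standard "edge density")
#'
#' Number of edges divided by number of nodes. This is the ratio used in
#' the association-biogeography literature this package follows; it is NOT
#' the conventional graph density, which [graphDensity()] exposes
#' separately to avoid confusion.
#'
#' @param graph an [AssociationGraph-class] with at least one node
#' @return numeric
#' @export
edgeNodeRatio <- function(graph) {
  stopifnot(is(graph, "AssociationGraph"))
  g <- graphOf(graph)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  igraph::ecount(g) / igraph::vcount(g)
}

#' Conventional graph density 2E / (N(N-1))
#'
#' @param graph an [AssociationGraph-class]
#' @return numeric
#' @export
graphDensity <- function(graph) {
  stopifnot(is(graph, "AssociationGraph"))
  igraph::edge_density(graphOf(graph))
}

#' Min-max normalize a topology metric across clusters
#'
#' Rescales per-cluster metric values to \[0, 1\] and reports the spread,
#' `(max - min) / max * 100`, alongside — the percentage by which the true
#' maximum exceeds the true minimum. All-equal values map to all zeros
#' with spread 0 (documented convention).
#'
#' @param values named numeric, one value per cluster (>= 2 clusters)
#' @return list with `normalized` (named numeric in \[0, 1\]) and
#'   `spread_percent`
#' @examples
#' normalizeClusterMetrics(c(A = 2, B = 4))
#' @export
normalizeClusterMetrics <- function(values) {
  if (length(values) < 2L) stop("need at least 2 clusters")
  if (any(!is.finite(values))) stop("values must be finite")
  lo <- min(values); hi <- max(values)
  if (hi == lo)
    return(list(normalized = setNames(rep(0, length(values)), names(values)),
                spread_percent = 0))
  list(normalized = (values - lo) / (hi - lo),
       spread_percent = (hi - lo) / hi * 100)
}
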