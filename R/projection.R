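# Sample-to-grid environment mapping, observed-range masking, and spatial
# projection of cADMs/rADMs with rho* reconstruction.

#' Map samples to gridded environmental values
#'
#' Each sample takes the features of the exactly matching grid cell when
#' one is valid; otherwise the mean of all valid cells within `radius`
#' degrees (a per-axis degree box: at 1-degree resolution the difference
#' from a great-circle disc is negligible and the box keeps the rule
#' transparent). Samples with no valid cell in range are flagged in the
#' rejection report rather than silently dropped. With a per-month grid
#' list, each sample uses the grid of its sampling month.
#'
#' @param sampleMeta data.frame with row names = sample ids and columns
#'   `latitude`, `longitude` (degrees) and, when `grids` is a per-month
#'   list, `month` (1-12)
#' @param grids a [GridField-class] or a list of them named by month
#' @param radius search radius in degrees (default 2)
#' @return an [EnvTable-class] for the resolvable samples, with attribute
#'   `rejected` (character ids of unresolvable samples)
#' @export
mapSamplesToGrid <- function(sampleMeta, grids, radius = 2) {
  sampleMeta <- as.data.frame(sampleMeta)
  if (!all(c("latitude", "longitude") %in% names(sampleMeta)))
    stop("sampleMeta needs latitude and longitude columns")
  byMonth <- !is(grids, "GridField")
  if (byMonth && !"month" %in% names(sampleMeta))
    stop("per-month grids supplied but sampleMeta has no month column")
  ids <- rownames(sampleMeta)
  pickGrid <- function(i) {
    if (!byMonth) return(grids)
    g <- grids[[as.character(sampleMeta$month[i])]]
    if (is.null(g)) stop("no grid for month ", sampleMeta$month[i])
    g
  }
  g0 <- if (byMonth) grids[[1L]] else grids
  p <- ncol(gridFeatures(g0))
  feats <- matrix(NA_real_, nrow = nrow(sampleMeta), ncol = p,
                  dimnames = list(ids, featureNames(g0)))
  for (i in seq_len(nrow(sampleMeta))) {
    g <- pickGrid(i)
    cells <- gridCells(g)
    valid <- validMask(g)
    lat <- sampleMeta$latitude[i]
    lon <- normalizeLongitude(sampleMeta$longitude[i])
    exact <- which(valid & abs(cells$lat - lat) < 1e-6 &
                   abs(normalizeLongitude(cells$lon - lon)) < 1e-6)
    if (length(exact)) {
      feats[i, ] <- gridFeatures(g)[exact[1L], ]
    } else {
      near <- which(valid & abs(cells$lat - lat) <= radius &
                    abs(normalizeLongitude(cells$lon - lon)) <= radius)
      if (length(near))
        feats[i, ] <- colMeans(gridFeatures(g)[near, , drop = FALSE])
    }
  }
  ok <- stats::complete.cases(feats)
  env <- EnvTable(feats[ok, , drop = FALSE], sampleIds = ids[ok])
  attr(env, "rejected") <- ids[!ok]
  env
}

#' Mask a grid to the observed feature range
#'
#' Marks a cell valid only when EVERY feature lies within the
#' \[`qLo`, `qHi`\] percentiles of the corresponding observed (sample)
#' feature values — the no-extrapolation rule: cells outside the observed
#' environmental envelope get no prediction at all. Returns a new grid;
#' the input is untouched.
#'
#' @param grid a [GridField-class]
#' @param observed an [EnvTable-class] of the training samples
#' @param qLo,qHi percentile bounds (defaults 2.5 and 97.5)
#' @return a [GridField-class] with an updated `validMask`
#' @export
maskToObservedRange <- function(grid, observed, qLo = 2.5, qHi = 97.5) {
  stopifnot(is(grid, "GridField"), is(observed, "EnvTable"))
  fn <- featureNames(grid)
  if (!all(featureNames(observed) %in% fn) ||
      !all(fn %in% featureNames(observed)))
    stop("feature names of grid and observed table must match")
  obs <- envFeatures(observed)[, fn, drop = FALSE]
  # the 0/100 limits mean "no bound", not "observed min/max"
  lo <- if (qLo <= 0) rep(-Inf, length(fn)) else
    apply(obs, 2L, stats::quantile, probs = qLo / 100, names = FALSE)
  hi <- if (qHi >= 100) rep(Inf, length(fn)) else
    apply(obs, 2L, stats::quantile, probs = qHi / 100, names = FALSE)
  gf <- gridFeatures(grid)
  inside <- rep(TRUE, nrow(gf))
  for (jf in seq_along(fn))
    inside <- inside & gf[, jf] >= lo[jf] & gf[, jf] <= hi[jf]
  inside[is.na(inside)] <- FALSE
  mask <- validMask(grid) & inside
  if (!any(mask))
    warning("no grid cell falls inside the observed feature range; ",
            "projections on this grid will be empty")
  new("GridField", cells = gridCells(grid), features = gf,
      timeLabel = timeLabel(grid), validMask = mask)
}

#' Project a cADM over a grid
#'
#' Predicts the co-occurrence state in every valid cell and reports the
#' co-presence proportion (#cells predicted copresent / #valid cells). An
#' empty valid set yields an empty result with proportion `NA` (missing,
#' not 0). A pure function of (model, grid).
#'
#' @param model an [AdmModel-class] with `variant = "cADM"`
#' @param grid a (masked) [GridField-class]
#' @return a [ProjectionResult-class]
#' @export
projectCadm <- function(model, grid) {
  stopifnot(is(model, "AdmModel"), is(grid, "GridField"))
  if (model@variant != "cADM") stop("model is not a cADM")
  checkGridPredictors(model, grid)
  idx <- which(validMask(grid))
  if (!length(idx))
    return(new("ProjectionResult", pair = model@pair, variant = "cADM",
               timeLabel = timeLabel(grid), cellIndex = integer(),
               states = factor(character(), levels = STATE_LEVELS),
               alphaStar = numeric()))
  pred <- predictAdm(model, gridFeatures(grid)[idx, , drop = FALSE])
  states <- factor(as.character(pred), levels = STATE_LEVELS)
  new("ProjectionResult", pair = model@pair, variant = "cADM",
      timeLabel = timeLabel(grid), cellIndex = idx, states = states,
      alphaStar = numeric(),
      copresenceProportion = mean(states == "copresence"))
}

#' Project an rADM over a grid and reconstruct rho*
#'
#' Predicts alpha* in every valid cell and reconstructs the projected
#' association strength. The training identity `rho = 1 - sum(alpha)` runs
#' over the n training samples, while a projection sums over G grid cells,
#' so the sum is rescaled: `rho* = 1 - (nTrain / G) * sum(alpha*)`. A grid
#' whose cells replicate the training samples then reproduces the training
#' rho exactly (to model error). Regional rho* uses the same formula over
#' each region's cells, making `1 - rho*` proportional to the region's
#' mean alpha*.
#'
#' @param model an [AdmModel-class] with `variant = "rADM"`
#' @param grid a (masked) [GridField-class]
#' @param regions optional region assignment from [assignRegions()]
#' @param nTrain training sample count; defaults to the model's own
#' @return a [ProjectionResult-class]
#' @export
projectRadm <- function(model, grid, regions = NULL, nTrain = model@nTrain) {
  stopifnot(is(model, "AdmModel"), is(grid, "GridField"))
  if (model@variant != "rADM") stop("model is not an rADM")
  checkGridPredictors(model, grid)
  idx <- which(validMask(grid))
  if (!length(idx))
    return(new("ProjectionResult", pair = model@pair, variant = "rADM",
               timeLabel = timeLabel(grid), cellIndex = integer(),
               states = factor(character(), levels = STATE_LEVELS),
               alphaStar = numeric()))
  alphaStar <- predictAdm(model, gridFeatures(grid)[idx, , drop = FALSE])
  G <- length(idx)
  rhoGlobal <- 1 - (nTrain / G) * sum(alphaStar)
  byRegion <- setNames(numeric(), character())
  if (!is.null(regions)) {
    byRegion <- vapply(regions, function(cellIdx) {
      here <- match(intersect(cellIdx, idx), idx)
      if (!length(here)) return(NA_real_)
      1 - (nTrain / length(here)) * sum(alphaStar[here])
    }, numeric(1))
  }
  new("ProjectionResult", pair = model@pair, variant = "rADM",
      timeLabel = timeLabel(grid), cellIndex = idx,
      states = factor(character(), levels = STATE_LEVELS),
      alphaStar = as.numeric(alphaStar), rhoStarGlobal = rhoGlobal,
      rhoStarByRegion = byRegion)
}

checkGridPredictors <- function(model, grid) {
  if (!all(model@predictors %in% featureNames(grid)))
    stop("grid lacks predictors: ",
         paste(setdiff(model@predictors, featureNames(grid)),
               collapse = ", "))
  invisible(TRUE)
}

#' Assign grid cells to named rectangular regions
#'
#' Regions are named lat/lon rectangles `c(latMin, latMax, lonMin, lonMax)`
#' (longitudes in \[-180, 180)). Each valid cell may fall in at most one
#' region; overlapping specs are rejected. Unassigned cells are allowed.
#'
#' @param grid a [GridField-class]
#' @param regionSpec named list of numeric(4) rectangles
#' @return named list mapping region to integer cell indices
#' @export
assignRegions <- function(grid, regionSpec) {
  stopifnot(is(grid, "GridField"))
  if (!length(regionSpec) || is.null(names(regionSpec)))
    stop("regionSpec must be a non-empty named list of rectangles")
  cells <- gridCells(grid)
  valid <- which(validMask(grid))
  hit <- matrix(FALSE, nrow = nrow(cells), ncol = length(regionSpec))
  for (r in seq_along(regionSpec)) {
    box <- regionSpec[[r]]
    if (length(box) != 4L)
      stop("region '", names(regionSpec)[r],
           "' must be c(latMin, latMax, lonMin, lonMax)")
    hit[, r] <- cells$lat >= box[1L] & cells$lat <= box[2L] &
                cells$lon >= box[3L] & cells$lon <= box[4L]
  }
  over <- valid[rowSums(hit[valid, , drop = FALSE]) > 1L]
  if (length(over))
    stop("regions overlap on ", length(over),
         " valid cell(s); supply disjoint rectangles")
  out <- lapply(seq_along(regionSpec), function(r)
    intersect(which(hit[, r]), valid))
  names(out) <- names(regionSpec)
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty))
    message("region(s) with zero valid cells: ",
            paste(empty, collapse = ", "))
  out
}
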