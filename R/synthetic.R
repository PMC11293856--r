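# Synthetic world generator: environmental gradients, compositional
# abundance tables with planted associations, and future climate grids.
# Everything is a pure function of (spec, seed).

#' Specification for the synthetic world
#'
#' Defaults define the package's standard study conditions: 80 samples,
#' 50 taxa, 20 planted positive and 5 planted negative pairs, a
#' latitudinal temperature gradient, nitrate anticorrelated with
#' temperature at a target Pearson of about -0.9, near-constant salinity,
#' Gaussian thermal niches per taxon, and structural zeros where the niche
#' response falls below a cutoff (so co-occurrence carries environmental
#' signal, not random dropout).
#'
#' @param nSamples,nTaxa sample and taxon counts
#' @param nPositivePairs,nNegativePairs planted association counts (pairs
#'   are mutually disjoint)
#' @param tempEquator,tempLapse temperature at the equator (degC) and its
#'   decline per degree of |latitude|
#' @param tempNoise sampling noise sd on temperature (degC)
#' @param nutrientAnticorrelation target Pearson between temperature and
#'   nitrate (negative)
#' @param nitrateMean,nitrateSd,silicateMean,silicateSd nutrient scales
#'   (umol kg-1)
#' @param salinityMean,salinityNoise salinity scale (PSU); near-constant
#' @param coupling latent-factor coupling strength of planted pairs (log
#'   scale)
#' @param strengthGradient amplitude (log scale) of the environmentally
#'   driven decoupling of planted pairs: members drift apart away from
#'   their thermal optimum, so association strength (and alpha) varies
#'   along the temperature gradient
#' @param nicheBreadthRange range of thermal niche breadths (degC)
#' @param abundanceNoise log-abundance noise sd
#' @param zeroCutoff niche-suitability cutoff below which the taxon is
#'   structurally absent
#' @param closure close each sample to relative abundances summing to 1?
#' @return a list with class `"AdmSimSpec"`
#' @export
admSimSpec <- function(nSamples = 80L, nTaxa = 50L, nPositivePairs = 20L,
                       nNegativePairs = 5L, tempEquator = 28,
                       tempLapse = 0.28, tempNoise = 1,
                       nutrientAnticorrelation = -0.9, nitrateMean = 12,
                       nitrateSd = 5, silicateMean = 18, silicateSd = 6,
                       salinityMean = 35, salinityNoise = 0.3,
                       coupling = 2, strengthGradient = 1.5,
                       nicheBreadthRange = c(2.5, 5.5),
                       abundanceNoise = 0.4, zeroCutoff = 0.1,
                       closure = TRUE) {
  if (2L * (nPositivePairs + nNegativePairs) > nTaxa)
    stop("not enough taxa for disjoint planted pairs")
  if (nutrientAnticorrelation >= 0 || nutrientAnticorrelation < -1)
    stop("nutrientAnticorrelation must lie in [-1, 0)")
  structure(list(
    nSamples = as.integer(nSamples), nTaxa = as.integer(nTaxa),
    nPositivePairs = as.integer(nPositivePairs),
    nNegativePairs = as.integer(nNegativePairs),
    tempEquator = tempEquator, tempLapse = tempLapse, tempNoise = tempNoise,
    nutrientAnticorrelation = nutrientAnticorrelation,
    nitrateMean = nitrateMean, nitrateSd = nitrateSd,
    silicateMean = silicateMean, silicateSd = silicateSd,
    salinityMean = salinityMean, salinityNoise = salinityNoise,
    coupling = coupling, strengthGradient = strengthGradient,
    nicheBreadthRange = nicheBreadthRange,
    abundanceNoise = abundanceNoise, zeroCutoff = zeroCutoff,
    closure = closure), class = "AdmSimSpec")
}

# environmental fields from latitudes: temperature declines with |lat|,
# nitrate/silicate anticorrelate with temperature, salinity ~ constant
envFromLatitude <- function(spec, lat, noiseScale = 1) {
  n <- length(lat)
  temp <- spec$tempEquator - spec$tempLapse * abs(lat) +
    rnorm(n, sd = spec$tempNoise * noiseScale)
  r <- spec$nutrientAnticorrelation
  mix <- function(r) {
    z <- rnorm(n)
    ts <- if (sd(temp) > 0) (temp - mean(temp)) / sd(temp) else temp * 0
    r * ts + sqrt(1 - r^2) * z
  }
  nitrate <- pmax(0.01, spec$nitrateMean + spec$nitrateSd * mix(r))
  silicate <- pmax(0.01, spec$silicateMean + spec$silicateSd * mix(0.8 * r))
  salinity <- spec$salinityMean + rnorm(n, sd = spec$salinityNoise)
  cbind(temperature = temp, salinity = salinity, nitrate = nitrate,
        silicate = silicate)
}

#' Generate synthetic per-sample environment and metadata
#'
#' Draws sample locations, months and size fractions, then environmental
#' predictors from the spec's gradient model: temperature strictly
#' decreasing with |latitude| (plus noise), nitrate and silicate
#' anticorrelated with temperature at the spec'd strength, salinity
#' near-constant.
#'
#' @param spec an [admSimSpec()] list
#' @param seed integer
#' @return list with `env` (an [EnvTable-class]) and `meta` (data.frame of
#'   latitude, longitude, depth, month, size_fraction keyed by sample id)
#' @export
simulateEnv <- function(spec = admSimSpec(), seed = 1L) {
  withSeed(seed, {
    n <- spec$nSamples
    ids <- sprintf("sample%03d", seq_len(n))
    meta <- data.frame(
      latitude = runif(n, -65, 65),
      longitude = runif(n, -180, 180),
      depth = 10,
      month = sample.int(12L, n, replace = TRUE),
      size_fraction = sample(c("0.22-3", "0.8-2000", "20-180"), n,
                             replace = TRUE),
      row.names = ids)
    feats <- envFromLatitude(spec, meta$latitude)
    rownames(feats) <- ids
    list(env = EnvTable(feats, sampleIds = ids), meta = meta)
  })
}

#' Generate a synthetic abundance table with planted associations
#'
#' Per-taxon log-abundance follows a Gaussian thermal niche response plus
#' noise; members of a planted positive pair share the same niche and a
#' latent factor added to both (opposite signs for negative pairs), so
#' their CLR abundances co-vary strongly. Structural zeros arise where the
#' niche suitability falls below `zeroCutoff`, giving the three
#' co-occurrence states environmental structure. Optionally closed to
#' relative abundances (rows summing to 1).
#'
#' @param spec an [admSimSpec()] list
#' @param envSim output of [simulateEnv()] (or a compatible list)
#' @param seed integer
#' @return list with `experiment` (an [AdmExperiment-class]) and `truth`
#'   (data.frame of planted pairs: taxon_j, taxon_k, sign)
#' @export
simulateAbundances <- function(spec = admSimSpec(), envSim = NULL,
                               seed = 1L) {
  if (is.null(envSim)) envSim <- simulateEnv(spec, seed = seed)
  temp <- envFeatures(envSim$env)[, "temperature"]
  ids <- sampleIds(envSim$env)
  n <- length(temp); m <- spec$nTaxa
  withSeed(seed + 1L, {
    taxa <- sprintf("taxon%03d", seq_len(m))
    nPlanted <- spec$nPositivePairs + spec$nNegativePairs
    pairIdx <- matrix(seq_len(2L * nPlanted), ncol = 2L, byrow = TRUE)
    optimum <- runif(m, min(temp), max(temp))
    breadth <- runif(m, spec$nicheBreadthRange[1L], spec$nicheBreadthRange[2L])
    signs <- rep(c(1, -1), c(spec$nPositivePairs, spec$nNegativePairs))
    if (nPlanted) for (r in seq_len(nPlanted)) {
      j <- pairIdx[r, 1L]; k <- pairIdx[r, 2L]
      breadth[k] <- breadth[j]
      if (signs[r] > 0)
        optimum[k] <- optimum[j]    # shared niche keeps co-presence aligned
      else                          # mirrored niche: exclusion-prone pair
        optimum[k] <- min(temp) + max(temp) - optimum[j]
    }
    suit <- exp(-outer(temp, optimum, "-")^2 / (2 * rep(breadth^2, each = n)))
    dim(suit) <- c(n, m)
    logAb <- 2 + 3 * suit + matrix(rnorm(n * m, sd = spec$abundanceNoise),
                                   n, m)
    if (nPlanted) for (r in seq_len(nPlanted)) {
      u <- rnorm(n)
      j <- pairIdx[r, 1L]; k <- pairIdx[r, 2L]
      logAb[, j] <- logAb[, j] + spec$coupling * u
      if (signs[r] > 0) {
        # fully coupled log-abundances: the member k tracks j exactly up
        # to an environmentally driven decoupling term, so association
        # strength (and alpha) varies along the temperature gradient
        logAb[, k] <- logAb[, j] + spec$strengthGradient * (1 - suit[, j])
      } else {
        logAb[, k] <- logAb[, k] - spec$coupling * u
      }
    }
    ab <- exp(logAb) * (suit >= spec$zeroCutoff)
    if (spec$closure) {
      rs <- rowSums(ab)
      if (any(rs == 0)) rs[rs == 0] <- 1
      ab <- ab / rs
    }
    dimnames(ab) <- list(ids, taxa)
    truth <- if (nPlanted)
      data.frame(taxon_j = taxa[pairIdx[, 1L]], taxon_k = taxa[pairIdx[, 2L]],
                 sign = ifelse(signs > 0, "positive", "negative"),
                 stringsAsFactors = FALSE)
      else data.frame(taxon_j = character(), taxon_k = character(),
                      sign = character())
    list(experiment = AdmExperiment(ab, sampleMeta = envSim$meta),
         truth = truth)
  })
}

#' Generate a synthetic present-day environmental grid
#'
#' A regular lat/lon grid whose features follow the same gradient model as
#' the samples (optionally with reduced noise).
#'
#' @param spec an [admSimSpec()] list
#' @param latStep,lonStep grid resolution in degrees
#' @param latRange,lonRange extents
#' @param seed integer
#' @param noiseScale multiplier on the spec's noise terms (0 = smooth)
#' @return a [GridField-class] labelled `"present"`
#' @export
simulateGrid <- function(spec = admSimSpec(), latStep = 2, lonStep = 10,
                         latRange = c(-65, 65), lonRange = c(-175, 175),
                         seed = 1L, noiseScale = 1) {
  cells <- expand.grid(lat = seq(latRange[1L], latRange[2L], by = latStep),
                       lon = seq(lonRange[1L], lonRange[2L], by = lonStep))
  feats <- withSeed(seed + 2L,
                    envFromLatitude(spec, cells$lat, noiseScale = noiseScale))
  GridField(cells, feats, timeLabel = "present")
}

#' Generate future climate grids with monotone trends
#'
#' For each requested year, warms the base grid's temperature by
#' `warmingPerDecade` per decade since the first year and shrinks nitrate
#' (and silicate at half the rate) by `nutrientDeclinePerDecade`
#' multiplicatively; salinity is left unchanged, mirroring a
#' medium-emissions scenario in which it shows no clear trend. Optional
#' cell-level noise; with zero noise the fields are exact and mean nitrate
#' is non-increasing in time.
#'
#' @param baseGrid a [GridField-class]
#' @param years integer vector, strictly increasing; default the ten
#'   canonical time points 2015, 2020, 2030, ..., 2100
#' @param warmingPerDecade degC per decade (default 0.3)
#' @param nutrientDeclinePerDecade fractional decline per decade (default
#'   0.05)
#' @param noiseSd cell-level noise sd added to temperature and nutrients
#' @param seed integer
#' @return named list of [GridField-class], one per year
#' @export
simulateFutureGrids <- function(baseGrid, years = c(2015, seq(2020, 2100, 10)),
                                warmingPerDecade = 0.3,
                                nutrientDeclinePerDecade = 0.05,
                                noiseSd = 0, seed = 1L) {
  stopifnot(is(baseGrid, "GridField"))
  if (is.unsorted(years, strictly = TRUE)) stop("years must be increasing")
  f0 <- gridFeatures(baseGrid)
  out <- withSeed(seed + 3L, lapply(years, function(y) {
    decades <- (y - years[1L]) / 10
    f <- f0
    f[, "temperature"] <- f[, "temperature"] + warmingPerDecade * decades
    f[, "nitrate"] <- f[, "nitrate"] *
      (1 - nutrientDeclinePerDecade)^decades
    f[, "silicate"] <- f[, "silicate"] *
      (1 - nutrientDeclinePerDecade / 2)^decades
    if (noiseSd > 0) {
      nc <- nrow(f)
      for (v in c("temperature", "nitrate", "silicate"))
        f[, v] <- pmax(if (v == "temperature") -Inf else 0.01,
                       f[, v] + rnorm(nc, sd = noiseSd))
    }
    GridField(gridCells(baseGrid), f, timeLabel = as.character(y),
              validMask = validMask(baseGrid))
  }))
  setNames(out, as.character(years))
}
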