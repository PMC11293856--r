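# Plain-text readers/writers (TSV; NetCDF via ncdf4 when available),
# run configuration, and the staged pipeline.

fmtNum <- function(x) sprintf("%.15g", x)  # >= 12 significant digits

writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- fmtNum(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance TSV (+ optional sample metadata) into an AdmExperiment
#'
#' The table format: first column `sample_id`, remaining columns one taxon
#' each; the metadata TSV is keyed by `sample_id` and carries latitude,
#' longitude, depth, month, size_fraction. Ragged rows, duplicate ids and
#' negative values are rejected with the offending location named.
#'
#' @param path abundance TSV path
#' @param metaPath optional metadata TSV path
#' @return an [AdmExperiment-class]
#' @export
readAbundanceTsv <- function(path, metaPath = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": line(s) ",
         paste(head(which(nf != nf[1L]), 5), collapse = ", "))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected sample_id plus taxon columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(tab)[-1L]))
    stop("duplicate taxon ids in header")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(mode(vals) <- "numeric")  # NAs caught just below
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at row ", bad[1L] + 1L, " (sample ",
         ids[bad[1L]], "), column ", colnames(vals)[bad[2L]])
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at row ", bad[1L] + 1L, " (sample ",
         ids[bad[1L]], "), column ", colnames(vals)[bad[2L]])
  }
  rownames(vals) <- ids
  meta <- NULL
  if (!is.null(metaPath)) {
    meta <- read.delim(metaPath, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta))
      stop("metadata file needs a sample_id column")
    rownames(meta) <- meta$sample_id
    meta$sample_id <- NULL
    missing <- setdiff(ids, rownames(meta))
    if (length(missing))
      stop("metadata missing for sample(s): ",
           paste(head(missing, 5), collapse = ", "))
    meta <- meta[ids, , drop = FALSE]
  }
  AdmExperiment(vals, sampleMeta = meta, samplesAsRows = TRUE)
}

#' Write an AdmExperiment's raw abundances (and metadata) as TSV
#'
#' @param x an [AdmExperiment-class]
#' @param path abundance TSV path (samples as rows)
#' @param metaPath optional metadata TSV path
#' @return `path`, invisibly
#' @export
writeAbundanceTsv <- function(x, path, metaPath = NULL) {
  stopifnot(is(x, "AdmExperiment"))
  df <- data.frame(sample_id = sampleIds(x), t(abundances(x)),
                   check.names = FALSE)
  writeTsv(df, path)
  if (!is.null(metaPath)) {
    md <- sampleData(x)
    writeTsv(data.frame(sample_id = rownames(md), md, check.names = FALSE),
             metaPath)
  }
  invisible(path)
}

#' Read a grid from TSV
#'
#' Columns `lat`, `lon` then one column per predictor; longitudes are
#' normalized to \[-180, 180).
#'
#' @param path TSV path
#' @param timeLabel label for the grid's time point
#' @return a [GridField-class]
#' @export
readGridTsv <- function(path, timeLabel = "present") {
  tab <- read.delim(path, check.names = FALSE)
  if (!all(c("lat", "lon") %in% names(tab)))
    stop("grid TSV needs lat and lon columns; found: ",
         paste(names(tab), collapse = ", "))
  feats <- as.matrix(tab[, setdiff(names(tab), c("lat", "lon")),
                         drop = FALSE])
  if (!ncol(feats)) stop("grid TSV has no predictor columns")
  GridField(tab[, c("lat", "lon")], feats, timeLabel = timeLabel)
}

#' Write a grid as TSV
#'
#' @param grid a [GridField-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGridTsv <- function(grid, path) {
  stopifnot(is(grid, "GridField"))
  writeTsv(data.frame(gridCells(grid), gridFeatures(grid),
                      check.names = FALSE), path)
}

#' Read a grid from NetCDF
#'
#' Expects dimensions `lat` and `lon` and one variable per predictor.
#' Requires the ncdf4 package.
#'
#' @param path NetCDF path
#' @param timeLabel label for the grid's time point
#' @return a [GridField-class]
#' @export
readGridNc <- function(path, timeLabel = "present") {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading NetCDF grids requires the ncdf4 package; ",
         "use the TSV dialect otherwise")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  vars <- setdiff(names(nc$var), c("lat", "lon"))
  if (!length(vars))
    stop("no predictor variables found; available: ",
         paste(names(nc$var), collapse = ", "))
  cells <- expand.grid(lon = lon, lat = lat)[, c("lat", "lon")]
  feats <- vapply(vars, function(v)
    as.numeric(ncdf4::ncvar_get(nc, v)), numeric(nrow(cells)))
  colnames(feats) <- vars
  GridField(cells, feats, timeLabel = timeLabel)
}

#' Write a grid as NetCDF
#'
#' Cells are rasterized onto the unique sorted latitudes/longitudes;
#' absent combinations become missing values. Requires ncdf4.
#'
#' @param grid a [GridField-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGridNc <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("writing NetCDF grids requires the ncdf4 package")
  stopifnot(is(grid, "GridField"))
  cells <- gridCells(grid)
  lats <- sort(unique(cells$lat)); lons <- sort(unique(cells$lon))
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  feats <- gridFeatures(grid)
  vars <- lapply(colnames(feats), function(v)
    ncdf4::ncvar_def(v, "", list(dimLon, dimLat), missval = NA_real_,
                     prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  li <- match(cells$lon, lons); la <- match(cells$lat, lats)
  for (j in seq_len(ncol(feats))) {
    raster <- matrix(NA_real_, nrow = length(lons), ncol = length(lats))
    raster[cbind(li, la)] <- feats[, j]
    ncdf4::ncvar_put(nc, vars[[j]], raster)
  }
  invisible(path)
}

#' Write an AlphaMatrix as TSV (one row per sample)
#'
#' @param x an [AlphaMatrix-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAlphaTsv <- function(x, path) {
  stopifnot(is(x, "AlphaMatrix"))
  writeTsv(data.frame(sample_id = x@sampleIds,
                      taxon_j = x@pair[1L], taxon_k = x@pair[2L],
                      alpha = x@alpha), path)
}

#' Write an AssociationSet as TSV
#'
#' @param x an [AssociationSet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAssociationTsv <- function(x, path) {
  stopifnot(is(x, "AssociationSet"))
  writeTsv(x@pairs, path)
}

# ---- configuration ----------------------------------------------------

#' Default run configuration
#'
#' Every default traces to the package's standard study conditions:
#' occurrence >= 10 samples, zero imputation factor 0.65, FDR level 0.01,
#' quantile mask 2.5-97.5, k scan 2-15, neutral band fraction 0.10,
#' persistence threshold 0.30 co-presence at every time point.
#'
#' @param ... overrides of the defaults
#' @return a named list with class `"AdmConfig"`
#' @export
admConfig <- function(...) {
  cfg <- list(
    min_occurrence = 10L, impute_factor = 0.65, fdr_level = 0.01,
    n_boot = 50L, learner = "random_forest", cv_folds = 5L,
    mask_q_lo = 2.5, mask_q_hi = 97.5, k_min = 2L, k_max = 15L,
    band_fraction = 0.10, min_copresence = 0.30, seed = 1L,
    max_models = 30L, perf_floor_cadm = 0.5, perf_floor_radm = 0,
    years = c(2015, seq(2020, 2100, 10)))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, over), class = "AdmConfig")
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; keys as in [admConfig()]
#' @return an `"AdmConfig"` list
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(admConfig, vals)
}

#' Write a run configuration as YAML
#'
#' @param config an [admConfig()] list
#' @param path output path
#' @return `path`, invisibly
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- staged pipeline --------------------------------------------------

manifestPath <- function(runDir, stage)
  file.path(runDir, paste0("manifest_", stage, ".yaml"))

writeManifest <- function(runDir, stage, params, outputs, counts = list()) {
  mf <- list(stage = stage, params = params,
             outputs = as.list(tools::md5sum(file.path(runDir, outputs))),
             counts = counts)
  names(mf$outputs) <- outputs
  yaml::write_yaml(mf, manifestPath(runDir, stage))
  invisible(mf)
}

stageDone <- function(runDir, stage) {
  mp <- manifestPath(runDir, stage)
  if (!file.exists(mp)) return(FALSE)
  mf <- yaml::read_yaml(mp)
  outs <- names(mf$outputs)
  hashes <- tools::md5sum(file.path(runDir, outs))
  all(!is.na(hashes)) && all(hashes == unlist(mf$outputs))
}

#' Generate the synthetic world into a run directory
#'
#' Writes abundance, metadata, per-sample environment, present and future
#' grids, and the planted ground truth as TSV, plus a stage manifest.
#'
#' @param config an [admConfig()] list
#' @param runDir output directory (created if needed)
#' @param spec an [admSimSpec()] (defaults to the standard conditions)
#' @return `runDir`, invisibly
#' @export
stageSynth <- function(config, runDir, spec = admSimSpec()) {
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  envSim <- simulateEnv(spec, seed = seed)
  world <- simulateAbundances(spec, envSim, seed = seed)
  grid <- simulateGrid(spec, seed = seed)
  future <- simulateFutureGrids(grid, years = config$years, seed = seed)
  writeAbundanceTsv(world$experiment, file.path(runDir, "abundance.tsv"),
                    file.path(runDir, "metadata.tsv"))
  writeTsv(data.frame(sample_id = sampleIds(envSim$env),
                      envFeatures(envSim$env), check.names = FALSE),
           file.path(runDir, "env.tsv"))
  writeGridTsv(grid, file.path(runDir, "grid_present.tsv"))
  for (y in names(future))
    writeGridTsv(future[[y]], file.path(runDir, paste0("grid_", y, ".tsv")))
  writeTsv(world$truth, file.path(runDir, "truth.tsv"))
  outs <- c("abundance.tsv", "metadata.tsv", "env.tsv", "grid_present.tsv",
            paste0("grid_", names(future), ".tsv"), "truth.tsv")
  writeManifest(runDir, "synth", list(seed = seed), outs,
                list(samples = spec$nSamples, taxa = spec$nTaxa))
  invisible(runDir)
}

readEnvTsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  EnvTable(as.matrix(tab[, -1L, drop = FALSE]),
           sampleIds = as.character(tab[[1L]]))
}

#' Association stage: filter, impute, CLR, all-pairs rho, FDR thresholds
#'
#' @param config an [admConfig()] list
#' @param runDir run directory holding `abundance.tsv` (+ metadata)
#' @return the significant [AssociationSet-class], invisibly
#' @export
stageAssociate <- function(config, runDir) {
  ae <- readAbundanceTsv(file.path(runDir, "abundance.tsv"),
                         file.path(runDir, "metadata.tsv"))
  ae <- filterByOccurrence(ae, config$min_occurrence)
  ae <- clrTransform(imputeZeros(ae, config$impute_factor))
  aset <- allPairsRho(ae)
  thr <- bootstrapFdrThresholds(ae, nBoot = config$n_boot,
                                fdrLevel = config$fdr_level,
                                seed = config$seed)
  aset <- callSignificance(aset, thr, fdrLevel = config$fdr_level)
  writeAssociationTsv(aset, file.path(runDir, "associations.tsv"))
  yaml::write_yaml(list(t_neg = thr[["t_neg"]], t_pos = thr[["t_pos"]]),
                   file.path(runDir, "thresholds.yaml"))
  saveRDS(ae, file.path(runDir, "experiment.rds"))
  writeManifest(runDir, "associate",
                list(seed = config$seed, fdr_level = config$fdr_level,
                     n_boot = config$n_boot,
                     min_occurrence = config$min_occurrence,
                     impute_factor = config$impute_factor),
                c("associations.tsv", "thresholds.yaml"),
                list(pairs = nrow(aset@pairs),
                     significant = sum(aset@pairs$significant)))
  invisible(aset)
}

#' Fit stage: cADM + rADM per retained positive association
#'
#' Keeps models for significant positive pairs (the variant with superior
#' predictive performance in this framework) whose cross-validated score
#' clears the configured floor, capped at `max_models` pairs by descending
#' rho.
#'
#' @param config an [admConfig()] list
#' @param runDir run directory after [stageAssociate()]
#' @return named list of `list(cadm =, radm =)` per pair, invisibly
#' @export
stageFit <- function(config, runDir) {
  ae <- readRDS(file.path(runDir, "experiment.rds"))
  assoc <- read.delim(file.path(runDir, "associations.tsv"))
  env <- readEnvTsv(file.path(runDir, "env.tsv"))
  sig <- assoc[assoc$significant & assoc$sign == "positive", , drop = FALSE]
  sig <- sig[order(-sig$rho), , drop = FALSE]
  sig <- head(sig, config$max_models)
  clr <- clrValues(ae)
  models <- list()
  for (i in seq_len(nrow(sig))) {
    pair <- c(sig$taxon_j[i], sig$taxon_k[i])
    states <- discretizeStates(ae, pair)
    cadm <- tryCatch(fitCadm(states, env, learner = config$learner,
                             seed = config$seed, cvFolds = config$cv_folds),
                     error = function(e) NULL)
    alpha <- alphaDecompose(clr[pair[1L], ], clr[pair[2L], ], pair = pair,
                            sampleIds = sampleIds(ae))
    radm <- fitRadm(alpha, env, learner = config$learner,
                    seed = config$seed, cvFolds = config$cv_folds)
    okC <- !is.null(cadm) &&
      isTRUE(cadm@performance[[1L]] >= config$perf_floor_cadm)
    okR <- isTRUE(radm@performance[[1L]] >= config$perf_floor_radm)
    if (okC && okR)
      models[[paste(pair, collapse = "|")]] <-
        list(cadm = cadm, radm = radm, states = states, alpha = alpha)
  }
  if (!length(models))
    stop("no association model cleared the performance floor")
  saveRDS(models, file.path(runDir, "models.rds"))
  writeTsv(data.frame(
    association_id = names(models),
    cadm_balanced_accuracy = vapply(models, function(m)
      m$cadm@performance[[1L]], numeric(1)),
    radm_r2 = vapply(models, function(m) m$radm@performance[[1L]],
                     numeric(1)),
    rho = vapply(models, function(m) m$radm@trainingRho, numeric(1))),
    file.path(runDir, "models.tsv"))
  writeManifest(runDir, "fit",
                list(seed = config$seed, learner = config$learner,
                     cv_folds = config$cv_folds),
                "models.tsv", list(models = length(models)))
  invisible(models)
}

#' Projection stage: mask grids and project all models over all years
#'
#' @param config an [admConfig()] list
#' @param runDir run directory after [stageFit()]
#' @return list of per-year projection lists, invisibly
#' @export
stageProject <- function(config, runDir) {
  models <- readRDS(file.path(runDir, "models.rds"))
  env <- readEnvTsv(file.path(runDir, "env.tsv"))
  gridFiles <- c(present = "grid_present.tsv",
                 setNames(paste0("grid_", config$years, ".tsv"),
                          config$years))
  gridFiles <- gridFiles[file.exists(file.path(runDir, gridFiles))]
  proj <- list()
  rows <- list()
  for (lab in names(gridFiles)) {
    grid <- readGridTsv(file.path(runDir, gridFiles[[lab]]),
                        timeLabel = lab)
    grid <- maskToObservedRange(grid, env, config$mask_q_lo,
                                config$mask_q_hi)
    proj[[lab]] <- lapply(models, function(m)
      list(cadm = projectCadm(m$cadm, grid),
           radm = projectRadm(m$radm, grid)))
    rows[[lab]] <- data.frame(
      association_id = names(models), time = lab,
      copresence = vapply(proj[[lab]], function(p)
        copresenceProportion(p$cadm), numeric(1)),
      rho_star = vapply(proj[[lab]], function(p) rhoStar(p$radm),
                        numeric(1)))
  }
  saveRDS(proj, file.path(runDir, "projections.rds"))
  writeTsv(do.call(rbind, rows), file.path(runDir, "projections.tsv"))
  writeManifest(runDir, "project",
                list(mask_q_lo = config$mask_q_lo,
                     mask_q_hi = config$mask_q_hi),
                "projections.tsv",
                list(time_points = length(proj),
                     models = length(models)))
  invisible(proj)
}

#' Cluster stage: k-means signatures of present-day cADM projections
#'
#' @param config an [admConfig()] list
#' @param runDir run directory after [stageProject()]
#' @return a [ClusterResult-class], invisibly
#' @export
stageCluster <- function(config, runDir) {
  proj <- readRDS(file.path(runDir, "projections.rds"))
  present <- proj[["present"]]
  stacked <- stackCopresence(lapply(present, `[[`, "cadm"))
  kMax <- min(config$k_max, nrow(stacked) - 1L)
  res <- clusterSignatures(stacked, kRange = config$k_min:kMax,
                           seed = config$seed)
  writeTsv(data.frame(association_id = res@associationIds,
                      cluster = res@labels),
           file.path(runDir, "clusters.tsv"))
  writeManifest(runDir, "cluster",
                list(seed = config$seed, k_min = config$k_min,
                     k_max = kMax),
                "clusters.tsv", list(chosen_k = res@chosenK))
  invisible(res)
}

#' Response stage: persistence filter, slopes and response groups
#'
#' @param config an [admConfig()] list
#' @param runDir run directory after [stageCluster()]
#' @return the classification data.frame, invisibly
#' @export
stageRespond <- function(config, runDir) {
  tab <- read.delim(file.path(runDir, "projections.tsv"))
  tab <- tab[tab$time != "present", , drop = FALSE]
  tab$year <- as.numeric(tab$time)
  tr <- tab[, c("association_id", "year", "copresence", "rho_star")]
  kept <- filterPersistent(tr, config$min_copresence)
  if (!nrow(kept)) stop("no association is persistently co-present")
  cls <- classifyResponse(fitSlopes(kept),
                          bandFraction = config$band_fraction)
  writeTsv(cls, file.path(runDir, "responses.tsv"))
  clusters <- read.delim(file.path(runDir, "clusters.tsv"))
  labs <- setNames(clusters$cluster, clusters$association_id)
  ct <- summarizeGroups(cls, labs[cls$association_id])
  writeTsv(as.data.frame(ct), file.path(runDir, "response_groups.tsv"))
  writeManifest(runDir, "respond",
                list(band_fraction = config$band_fraction,
                     min_copresence = config$min_copresence),
                c("responses.tsv", "response_groups.tsv"),
                list(classified = nrow(cls)))
  invisible(cls)
}

#' Run the full pipeline into a directory
#'
#' Executes synth (optional) -> associate -> fit -> project -> cluster ->
#' respond. Each stage writes a manifest with parameter values and output
#' md5 hashes; on re-run, a stage whose manifest matches its outputs is
#' skipped (`resume = TRUE`), so a corrupted intermediate is detected and
#' recomputed. The resolved configuration is archived beside the outputs.
#'
#' @param config an [admConfig()] list
#' @param runDir output directory
#' @param synthetic generate the synthetic world first?
#' @param spec an [admSimSpec()] when `synthetic`
#' @param resume skip stages whose manifests validate?
#' @return `runDir`, invisibly
#' @export
runPipeline <- function(config = admConfig(), runDir, synthetic = TRUE,
                        spec = admSimSpec(), resume = TRUE) {
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(runDir, "config.yaml"))
  stages <- list(
    synth = function() stageSynth(config, runDir, spec),
    associate = function() stageAssociate(config, runDir),
    fit = function() stageFit(config, runDir),
    project = function() stageProject(config, runDir),
    cluster = function() stageCluster(config, runDir),
    respond = function() stageRespond(config, runDir))
  if (!synthetic) stages$synth <- NULL
  for (nm in names(stages)) {
    if (resume && stageDone(runDir, nm)) {
      message("stage ", nm, ": up to date, skipping")
      next
    }
    message("stage ", nm, " ...")
    tryCatch(stages[[nm]](), error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", runDir, ")", call. = FALSE))
  }
  invisible(runDir)
}
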