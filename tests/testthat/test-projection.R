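test_that("samples take exact-cell values or box means within the radius", {
  grid <- GridField(data.frame(lat = c(10, 10, 12), lon = c(20, 22, 20)),
                    cbind(temperature = c(10, 12, 20), salinity = 35,
                          nitrate = 5, silicate = 8))
  # exact match
  meta <- data.frame(latitude = 10, longitude = 20, row.names = "sA")
  env <- mapSamplesToGrid(meta, grid, radius = 2)
  expect_equal(unname(envFeatures(env)["sA", "temperature"]), 10)
  # adjacent to the two lat-10 cells only (lat 12 outside radius 1.4)
  meta2 <- data.frame(latitude = 10.5, longitude = 21, row.names = "sB")
  env2 <- mapSamplesToGrid(meta2, grid, radius = 1.4)
  expect_equal(unname(envFeatures(env2)["sB", "temperature"]), 11)
  # out of range: rejected, not dropped silently
  meta3 <- data.frame(latitude = -60, longitude = 100, row.names = "sC")
  env3 <- mapSamplesToGrid(meta3, grid, radius = 2)
  expect_equal(attr(env3, "rejected"), "sC")
  expect_equal(length(sampleIds(env3)), 0L)
})

test_that("grid mapping matches a brute-force search oracle", {
  grid <- smallGrid()
  cells <- gridCells(grid)
  feats <- gridFeatures(grid)
  set.seed(21)
  meta <- data.frame(latitude = runif(100, -70, 70),
                     longitude = runif(100, -180, 180),
                     row.names = paste0("s", 1:100))
  env <- mapSamplesToGrid(meta, grid, radius = 4)
  for (id in rownames(meta)) {
    dlat <- abs(cells$lat - meta[id, "latitude"])
    dlon <- abs(((cells$lon - meta[id, "longitude"] + 180) %% 360) - 180)
    exact <- which(dlat < 1e-6 & dlon < 1e-6)
    near <- which(dlat <= 4 & dlon <= 4)
    want <- if (length(exact)) feats[exact[1], "temperature"]
            else if (length(near)) mean(feats[near, "temperature"])
            else NA_real_
    if (is.na(want)) expect_true(id %in% attr(env, "rejected"))
    else expect_equal(unname(envFeatures(env)[id, "temperature"]),
                      unname(want))
  }
})

test_that("range masking keeps cells inside all observed percentiles", {
  grid <- smallGrid()
  set.seed(22)
  n <- 200
  obs <- EnvTable(cbind(temperature = runif(n, 5, 25),
                        salinity = rnorm(n, 35, 0.2),
                        nitrate = runif(n, 1, 15),
                        silicate = runif(n, 2, 20)),
                  sampleIds = paste0("s", seq_len(n)))
  masked <- maskToObservedRange(grid, obs)
  # percentile oracle
  f <- gridFeatures(grid)
  keep <- rep(TRUE, nrow(f))
  for (v in colnames(f)) {
    lo <- quantile(envFeatures(obs)[, v], 0.025)
    hi <- quantile(envFeatures(obs)[, v], 0.975)
    keep <- keep & f[, v] >= lo & f[, v] <= hi
  }
  expect_equal(validMask(masked), unname(keep) & validMask(grid))
  # q 0..100 keeps every finite cell; widening never shrinks the set
  all100 <- maskToObservedRange(grid, obs, 0, 100)
  expect_equal(validMask(all100), validMask(grid))
  expect_true(all(validMask(masked) <= validMask(all100)))
  # a feature shifted out of range empties the mask
  f2 <- f; f2[, "temperature"] <- f2[, "temperature"] + 1000
  grid2 <- GridField(gridCells(grid), f2)
  expect_warning(empty <- maskToObservedRange(grid2, obs), "empty|no grid")
  expect_equal(sum(validMask(empty)), 0L)
  # the input grid is untouched (a new mask is returned)
  expect_true(any(validMask(grid)))
})

# a memorizing cADM whose states are a pure threshold on temperature
thresholdCadm <- function(grid) {
  f <- gridFeatures(grid)[validMask(grid), , drop = FALSE]
  st <- factor(ifelse(f[, "temperature"] > 15, "copresence", "coabsence"),
               levels = c("copresence", "coabsence", "exclusion"))
  states <- new("CooccurrenceStates", pair = c("a", "b"), states = st,
                sampleIds = paste0("g", seq_len(nrow(f))))
  env <- EnvTable(f, sampleIds = paste0("g", seq_len(nrow(f))))
  fitCadm(states, env, learner = "memorize", seed = 1, cvFolds = 2)
}

test_that("cADM projection reports the copresence proportion exactly", {
  grid <- smallGrid()
  m <- thresholdCadm(grid)
  pr <- projectCadm(m, grid)
  f <- gridFeatures(grid)[validMask(grid), ]
  expect_equal(copresenceProportion(pr), mean(f[, "temperature"] > 15))
  # deterministic: identical maps on re-run
  pr2 <- projectCadm(m, grid)
  expect_identical(predictedStates(pr2), predictedStates(pr))
  # empty grid: proportion is missing, not zero
  gEmpty <- GridField(gridCells(grid), gridFeatures(grid),
                      validMask = rep(FALSE, nrow(gridCells(grid))))
  prE <- projectCadm(m, gEmpty)
  expect_true(is.na(copresenceProportion(prE)))
  expect_length(predictedStates(prE), 0L)
})

test_that("rADM round trip on training cells recovers training rho", {
  grid <- smallGrid()
  f <- gridFeatures(grid)[validMask(grid), , drop = FALSE]
  ids <- paste0("g", seq_len(nrow(f)))
  env <- EnvTable(f, sampleIds = ids)
  set.seed(23)
  alpha <- alphaFromVector(abs(rnorm(nrow(f), 0.01, 0.004)), ids)
  m <- fitRadm(alpha, env, learner = "memorize", seed = 1, cvFolds = 2)
  pr <- projectRadm(m, grid)
  # grid cells replicate the training rows, so rho* = training rho
  expect_equal(rhoStar(pr), m@trainingRho, tolerance = 1e-9)
  # all-zero alpha* reconstructs rho* = 1
  zero <- suppressWarnings(
    fitRadm(alphaFromVector(rep(0, nrow(f)), ids), env,
            learner = "memorize", seed = 1, cvFolds = 2))
  expect_equal(rhoStar(projectRadm(zero, grid)), 1)
})

test_that("regional rho* is consistent and additive over a partition", {
  grid <- smallGrid()
  f <- gridFeatures(grid)[validMask(grid), , drop = FALSE]
  ids <- paste0("g", seq_len(nrow(f)))
  env <- EnvTable(f, sampleIds = ids)
  set.seed(24)
  alpha <- alphaFromVector(abs(rnorm(nrow(f), 0.02, 0.01)), ids)
  m <- fitRadm(alpha, env, learner = "memorize", seed = 1, cvFolds = 2)
  whole <- assignRegions(grid, list(all = c(-90, 90, -180, 179.999)))
  pr <- projectRadm(m, grid, regions = whole)
  expect_equal(unname(rhoStarByRegion(pr)[["all"]]), rhoStar(pr),
               tolerance = 1e-9)
  halves <- assignRegions(grid, list(south = c(-90, -0.5, -180, 179.999),
                                     north = c(-0.4, 90, -180, 179.999)))
  pr2 <- projectRadm(m, grid, regions = halves)
  w <- lengths(halves)[c("south", "north")]
  lhs <- sum(w * (1 - rhoStarByRegion(pr2)[c("south", "north")])) / sum(w)
  expect_equal(lhs, 1 - rhoStar(pr2), tolerance = 1e-9)
})

test_that("region assignment partitions cells like brute-force point-in-box", {
  grid <- smallGrid()
  spec <- list(south = c(-90, -1, -180, 179.999),
               north = c(1, 90, -180, 179.999))
  reg <- assignRegions(grid, spec)
  cells <- gridCells(grid)
  for (nm in names(spec)) {
    box <- spec[[nm]]
    want <- which(validMask(grid) & cells$lat >= box[1] &
                  cells$lat <= box[2] & cells$lon >= box[3] &
                  cells$lon <= box[4])
    expect_equal(reg[[nm]], want)
  }
  # overlapping boxes are rejected
  expect_error(assignRegions(grid, list(a = c(-90, 10, -180, 179),
                                        b = c(0, 90, -180, 179))),
               "overlap")
  # degenerate zero-area region: zero cells, reported
  expect_message(z <- assignRegions(grid, list(line = c(0.2, 0.2, 5, 5))),
                 "zero valid cells")
  expect_length(z$line, 0L)
})

test_that("projection refuses a grid with mismatched predictors", {
  grid <- smallGrid()
  m <- thresholdCadm(grid)
  bad <- GridField(gridCells(grid),
                   gridFeatures(grid)[, c("salinity", "nitrate")])
  expect_error(projectCadm(m, bad), "lacks predictors")
})
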