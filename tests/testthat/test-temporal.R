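makeTrajectory <- function(id, years, cop, rho) {
  data.frame(association_id = id, year = years, copresence = cop,
             rho_star = rho)
}

test_that("persistence filter needs the threshold at every time point", {
  yrs <- c(2015, 2050, 2100)
  tr <- rbind(makeTrajectory("keep", yrs, c(0.4, 0.35, 0.31), 0.5),
              makeTrajectory("drop", yrs, c(0.4, 0.29, 0.5), 0.5))
  kept <- filterPersistent(tr, 0.30)
  expect_equal(unique(kept$association_id), "keep")
  # brute-force recount over 100 random trajectories
  set.seed(80)
  ids <- sprintf("a%03d", 1:100)
  big <- do.call(rbind, lapply(ids, function(id)
    makeTrajectory(id, yrs, runif(3, 0.1, 0.6), runif(3))))
  kept2 <- filterPersistent(big, 0.30)
  want <- ids[vapply(ids, function(id)
    all(big$copresence[big$association_id == id] >= 0.30), logical(1))]
  expect_equal(sort(unique(kept2$association_id)), sort(want))
})

test_that("slope fitting is exact on lines and degrades gracefully", {
  yrs <- c(2015, seq(2020, 2100, 10))
  lin <- 0.5 + 0.1 * (yrs - 2015) / 85    # exactly linear in year
  tr <- makeTrajectory("lin", yrs, lin, 1.1 - lin)
  s <- fitSlopes(tr)
  expect_equal(s$slope_c, 0.1 / 85)
  expect_equal(s$r2_c, 1)
  expect_equal(s$slope_r, -0.1 / 85)
  expect_equal(s$pearson_r, -1)
  # constant series: slope 0, diagnostics missing
  cons <- makeTrajectory("const", yrs, rep(0.4, 10), rep(0.5, 10))
  s2 <- fitSlopes(cons)
  expect_equal(s2$slope_c, 0)
  expect_true(is.na(s2$pearson_c) && is.na(s2$r2_c))
  expect_error(fitSlopes(makeTrajectory("x", rep(2015, 3), 1:3 / 10, 1:3 / 10)),
               "duplicate|constant")
  expect_error(fitSlopes(makeTrajectory("x", c(2015, 2020), c(0.1, 0.2),
                                        c(0.1, 0.2))), "fewer than 3")
})

test_that("noisy planted slopes are recovered within 3 standard errors", {
  yrs <- seq(2010, 2100, 10)
  set.seed(81)
  for (i in 1:10) {
    noise <- rnorm(10, sd = 0.01)
    tr <- makeTrajectory("p", yrs, 0.3 + 0.002 * (yrs - 2010) + noise,
                         rep(0.5, 10))
    s <- fitSlopes(tr)
    se <- summary(lm(I(0.3 + 0.002 * (yrs - 2010) + noise) ~ yrs))$
      coefficients["yrs", "Std. Error"]
    expect_lt(abs(s$slope_c - 0.002), 3 * se)
  }
})

test_that("the five response groups follow the band rule", {
  slopes <- data.frame(association_id = c("x", "y", "z"),
                       slope_c = c(0.01, -0.01, 0.0001),
                       slope_r = c(0.01, -0.01, 0.0001))
  cls <- classifyResponse(slopes, bandFraction = 0.10)
  expect_equal(as.character(cls$group), c("pp", "mm", "neutral"))
  expect_equal(cls$group_label, c("(+c)(+r)", "(-c)(-r)", "neutral"))
  # band 0: only exact zeros are neutral
  z <- data.frame(association_id = c("a", "b"),
                  slope_c = c(0, 1e-9), slope_r = c(0, -1e-9))
  c0 <- classifyResponse(z, bandFraction = 0)
  expect_equal(as.character(c0$group), c("neutral", "pm"))
  # band 1: everything neutral
  c1 <- classifyResponse(slopes, bandFraction = 1)
  expect_true(all(c1$group == "neutral"))
  # mixed case keeps the raw signs
  mix <- data.frame(association_id = c("big", "small"),
                    slope_c = c(1, 0.01), slope_r = c(1, -1))
  cm <- classifyResponse(mix, bandFraction = 0.10)
  expect_equal(as.character(cm$group), c("pp", "pm"))
})

test_that("classification is order- and scale-invariant and exhaustive", {
  set.seed(82)
  slopes <- data.frame(association_id = sprintf("a%02d", 1:40),
                       slope_c = rnorm(40, sd = 1e-3),
                       slope_r = rnorm(40, sd = 1e-2))
  c1 <- classifyResponse(slopes)
  perm <- sample(40)
  c2 <- classifyResponse(slopes[perm, ])
  expect_equal(as.character(c2$group[order(perm)]), as.character(c1$group))
  scaled <- slopes
  scaled$slope_r <- scaled$slope_r * 1000
  c3 <- classifyResponse(scaled)
  expect_equal(as.character(c3$group), as.character(c1$group))
  expect_false(anyNA(c1$group))          # exhaustive, disjoint by factor
  # quantile band mode marks the central mass neutral-capable
  cq <- classifyResponse(slopes, bandFraction = 0.2, bandMode = "quantile")
  expect_true(all(levels(cq$group) ==
                  c("pp", "pm", "mp", "mm", "neutral")))
})

test_that("planted trend patterns classify correctly, also under noise", {
  yrs <- c(2015, seq(2020, 2100, 10))
  patterns <- list(pp = c(1, 1), pm = c(1, -1), mp = c(-1, 1),
                   mm = c(-1, -1), neutral = c(0, 0))
  build <- function(noiseSd, seed) {
    set.seed(seed)
    do.call(rbind, lapply(names(patterns), function(g) {
      s <- patterns[[g]]
      makeTrajectory(g, yrs,
                     0.5 + s[1] * 0.002 * (yrs - 2015) + rnorm(10, sd = noiseSd),
                     0.5 + s[2] * 0.003 * (yrs - 2015) + rnorm(10, sd = noiseSd))
    }))
  }
  cls0 <- classifyResponse(fitSlopes(build(0, 1)))
  expect_equal(as.character(cls0$group[match(names(patterns),
                                             cls0$association_id)]),
               names(patterns))
  hits <- 0L
  for (s in 1:30) {
    cls <- classifyResponse(fitSlopes(build(0.01, 100 + s)))
    hits <- hits + sum(as.character(cls$group) == cls$association_id)
  }
  expect_gte(hits / (30 * 5), 0.9)
})

test_that("group-by-cluster contingency matches hand counts", {
  cls <- data.frame(association_id = c("a", "b", "c", "d", "e"),
                    group = factor(c("pp", "pp", "mm", "neutral", "mp"),
                                   levels = c("pp", "pm", "mp", "mm",
                                              "neutral")))
  labs <- c(a = 1, b = 2, c = 1, d = 1, e = 2)
  ct <- summarizeGroups(cls, labs)
  expect_equal(ct["pp", "1"], 1L)
  expect_equal(ct["pp", "2"], 1L)
  expect_equal(ct["mm", "1"], 1L)
  expect_equal(sum(ct), 5L)
  expect_equal(as.vector(rowSums(ct)),
               as.vector(table(cls$group)[rownames(ct)]))
  expect_error(summarizeGroups(cls, labs[1:2]), "missing")
  empty <- summarizeGroups(cls[0, ], labs)
  expect_equal(sum(empty), 0L)
})
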