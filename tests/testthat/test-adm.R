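test_that("states are discretized from raw presence/absence", {
  m <- rbind(s1 = c(a = 2, b = 3), s2 = c(0, 0), s3 = c(0, 5), s4 = c(4, 0))
  ae <- AdmExperiment(m)
  st <- stateVector(discretizeStates(ae, c("a", "b")))
  expect_equal(as.character(st),
               c("copresence", "coabsence", "exclusion", "exclusion"))
  expect_error(discretizeStates(ae, c("a", "zz")), "unknown taxa")
  # imputation must not change the states (presence is pre-imputation)
  st2 <- stateVector(discretizeStates(imputeZeros(ae), c("a", "b")))
  expect_equal(st2, st)
})

test_that("cADM learns a temperature-separable labelling", {
  env <- gradientEnv(120, seed = 1)
  temp <- envFeatures(env)[, "temperature"]
  states <- statesFromFactor(separableStates(temp), sampleIds(env))
  m <- fitCadm(states, env, seed = 3, cvFolds = 5)
  expect_s4_class(m, "AdmModel")
  expect_gte(modelPerformance(m)[["balanced_accuracy"]], 0.95)
  # training ranges cover the 2.5/97.5 quantiles of the features
  expect_equal(trainingRanges(m)["q2.5", "temperature"],
               unname(quantile(temp, 0.025)))
  # determinism
  m2 <- fitCadm(states, env, seed = 3, cvFolds = 5)
  expect_identical(modelPerformance(m2), modelPerformance(m))
})

test_that("cADM on random labels scores near chance; one state errors", {
  env <- gradientEnv(90, seed = 2)
  set.seed(4)
  lab <- factor(sample(c("copresence", "coabsence", "exclusion"), 90,
                       replace = TRUE),
                levels = c("copresence", "coabsence", "exclusion"))
  m <- fitCadm(statesFromFactor(lab, sampleIds(env)), env, seed = 1)
  expect_lt(abs(modelPerformance(m)[["balanced_accuracy"]] - 1 / 3), 0.15)
  allSame <- statesFromFactor(factor(rep("copresence", 90),
    levels = c("copresence", "coabsence", "exclusion")), sampleIds(env))
  expect_error(fitCadm(allSame, env), "degenerate")
})

test_that("cADM class probabilities sum to one per sample", {
  env <- gradientEnv(80, seed = 5)
  states <- statesFromFactor(
    separableStates(envFeatures(env)[, "temperature"]), sampleIds(env))
  m <- fitCadm(states, env, seed = 1)
  pr <- predictAdm(m, envFeatures(env), type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 80), tolerance = 1e-9)
})

test_that("rADM recovers a smooth functional dependence on temperature", {
  env <- gradientEnv(150, seed = 6)
  temp <- envFeatures(env)[, "temperature"]
  alpha <- alphaFromVector(0.04 * plogis((temp - 15) / 4), sampleIds(env))
  m <- fitRadm(alpha, env, seed = 2)
  expect_gte(modelPerformance(m)[["r2"]], 0.9)
  expect_equal(m@trainingRho, 1 - sum(alphaValues(alpha)))
  m2 <- fitRadm(alpha, env, seed = 2)
  expect_identical(modelPerformance(m2), modelPerformance(m))
})

test_that("rADM on noise scores near zero R2; constant alpha warns", {
  env <- gradientEnv(100, seed = 7)
  set.seed(8)
  alpha <- alphaFromVector(abs(rnorm(100, 0.01, 0.005)), sampleIds(env))
  m <- fitRadm(alpha, env, seed = 1)
  expect_lte(modelPerformance(m)[["r2"]], 0.1)
  const <- alphaFromVector(rep(0.01, 100), sampleIds(env))
  expect_warning(mc <- fitRadm(const, env, seed = 1), "constant alpha")
  expect_true(is.na(modelPerformance(mc)[["r2"]]))
  expect_equal(unname(predictAdm(mc, envFeatures(env))[1:5]),
               rep(0.01, 5), tolerance = 1e-6)
})

test_that("learner comparison ranks deterministically, best first", {
  env <- gradientEnv(100, seed = 9)
  temp <- envFeatures(env)[, "temperature"]
  states <- statesFromFactor(separableStates(temp), sampleIds(env))
  ranked <- compareLearners(states, env,
                            learners = c("random_forest", "svm"),
                            seed = 1, cvFolds = 5)
  perf <- vapply(ranked, function(m) modelPerformance(m)[[1]], numeric(1))
  expect_true(all(diff(perf) <= 0))
  single <- compareLearners(states, env, learners = "svm", seed = 1)
  expect_length(single, 1L)
  dup <- compareLearners(states, env,
                         learners = c("random_forest", "random_forest"),
                         seed = 1)
  expect_equal(names(dup), c("random_forest", "random_forest"))
  expect_identical(modelPerformance(dup[[1]]), modelPerformance(dup[[2]]))
})

test_that("tree ensembles beat the SVM on interaction-rich states", {
  env <- gradientEnv(150, seed = 10)
  f <- envFeatures(env)
  # co-presence set by a sharp interaction of temperature and nitrate
  lab <- ifelse((f[, "temperature"] > 15) != (f[, "nitrate"] > 10),
                "copresence",
                ifelse(f[, "silicate"] > 15, "coabsence", "exclusion"))
  states <- statesFromFactor(factor(lab,
    levels = c("copresence", "coabsence", "exclusion")), sampleIds(env))
  ranked <- compareLearners(states, env, seed = 2, cvFolds = 5)
  expect_true(which(names(ranked) == "svm") >
              min(which(names(ranked) %in%
                        c("random_forest", "gradient_boosting"))))
})

test_that("permutation importance finds the planted driver", {
  env <- gradientEnv(120, seed = 11)
  temp <- envFeatures(env)[, "temperature"]
  alpha <- alphaFromVector(0.03 * plogis((temp - 15) / 3), sampleIds(env))
  m <- fitRadm(alpha, env, seed = 1)
  fi <- permutationImportance(m, env, alpha, nRepeats = 10, seed = 5)
  imp <- importanceValues(fi)
  expect_equal(names(which.max(imp)), "temperature")
  expect_true(all(abs(imp[setdiff(names(imp), "temperature")]) < 0.15))
  fi2 <- permutationImportance(m, env, alpha, nRepeats = 10, seed = 5)
  expect_identical(importanceValues(fi2), imp)
  expect_error(permutationImportance(m, env, alpha, nRepeats = 0), ">= 1")
})

test_that("permuting a constant feature has exactly zero importance", {
  env <- gradientEnv(80, seed = 12)
  f <- envFeatures(env)
  f[, "salinity"] <- 35                      # constant, hence ignorable
  env2 <- EnvTable(f, sampleIds(env))
  temp <- f[, "temperature"]
  alpha <- alphaFromVector(0.02 + 0.001 * temp, sampleIds(env2))
  m <- fitRadm(alpha, env2, seed = 1)
  fi <- permutationImportance(m, env2, alpha, nRepeats = 3, seed = 2)
  expect_identical(unname(importanceValues(fi)[["salinity"]]), 0)
})

test_that("PFI ranks the single planted driver first across replicates", {
  # parameter-recovery property: >= 95% of seeded replicates
  hits <- 0L
  reps <- 40L
  for (s in seq_len(reps)) {
    env <- gradientEnv(60, seed = 100 + s)
    temp <- envFeatures(env)[, "temperature"]
    alpha <- alphaFromVector(0.05 * plogis((temp - 15) / 2),
                             sampleIds(env))
    m <- fitRadm(alpha, env, seed = s, cvFolds = 3)
    fi <- permutationImportance(m, env, alpha, nRepeats = 5, seed = s)
    if (names(which.max(importanceValues(fi))) == "temperature")
      hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
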