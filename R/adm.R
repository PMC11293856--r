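# Association distribution models: cADM (three-state co-occurrence
# classifier) and rADM (alpha regressor), with cross-validated performance,
# learner comparison and permutation feature importance.

STATE_LEVELS <- c("copresence", "coabsence", "exclusion")

#' Discretize a pair's raw abundances into co-occurrence states
#'
#' Per sample: `copresence` if both raw abundances are > 0, `coabsence` if
#' both are 0, `exclusion` otherwise (either member absent while the other
#' is present; unordered). States are always derived from the raw
#' (pre-imputation) assay.
#'
#' @param x an [AdmExperiment-class]
#' @param pair character(2) taxon ids present in `x`
#' @return a [CooccurrenceStates-class]
#' @examples
#' ae <- AdmExperiment(matrix(c(2, 0, 0, 3, 0, 5), nrow = 3,
#'   dimnames = list(paste0("s", 1:3), c("a", "b"))))
#' stateVector(discretizeStates(ae, c("a", "b")))
#' @export
discretizeStates <- function(x, pair) {
  stopifnot(is(x, "AdmExperiment"))
  pair <- as.character(pair)
  missingTaxa <- setdiff(pair, taxonIds(x))
  if (length(missingTaxa))
    stop("unknown taxa: ", paste(missingTaxa, collapse = ", "))
  pres <- presenceMatrix(x)[pair, , drop = FALSE]
  st <- ifelse(pres[1L, ] & pres[2L, ], "copresence",
        ifelse(!pres[1L, ] & !pres[2L, ], "coabsence", "exclusion"))
  new("CooccurrenceStates", pair = pair,
      states = factor(st, levels = STATE_LEVELS),
      sampleIds = sampleIds(x))
}

# ---- learner engine ---------------------------------------------------

fitEngine <- function(X, y, learner, seed, classification) {
  X <- as.matrix(X)
  fit <- switch(learner,
    random_forest = {
      m <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 500L,
                          seed = as.integer(seed), num.threads = 1L,
                          probability = classification)
      list(model = m)
    },
    gradient_boosting = {
      m <- xgboost::xgboost(X, y, nrounds = 100L, max_depth = 4L,
                            nthreads = 1L, verbosity = 0,
                            seed = as.integer(seed))
      list(model = m,
           modelLevels = if (is.factor(y)) levels(y))
    },
    svm = {
      m <- withSeed(seed, e1071::svm(x = X, y = y, kernel = "radial",
                                     scale = apply(X, 2, sd) > 0))
      list(model = m)
    },
    memorize = {
      # exact-interpolation diagnostic learner: returns the training target
      # for an exactly matching feature row, nearest training row otherwise
      list(X = X, y = y,
           keys = apply(signif(X, 12), 1L, paste, collapse = "\r"))
    },
    stop("unknown learner: ", learner)
  )
  c(fit, list(engine = learner, classification = classification,
              levels = if (is.factor(y)) levels(y) else NULL,
              predictors = colnames(X)))
}

predictEngine <- function(fit, X, type = c("response", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(X)[, fit$predictors, drop = FALSE]
  engine <- fit$engine
  if (engine == "memorize") {
    keys <- apply(signif(X, 12), 1L, paste, collapse = "\r")
    idx <- match(keys, fit$keys)
    miss <- which(is.na(idx))
    for (i in miss) {
      d2 <- rowSums(sweep(fit$X, 2L, X[i, ])^2)
      idx[i] <- which.min(d2)
    }
    out <- fit$y[idx]
    if (type == "prob") {
      p <- matrix(0, nrow = length(out), ncol = length(fit$levels),
                  dimnames = list(NULL, fit$levels))
      p[cbind(seq_along(out), as.integer(out))] <- 1
      return(p)
    }
    return(out)
  }
  if (engine == "random_forest") {
    pr <- predict(fit$model, data = as.data.frame(X),
                  num.threads = 1L)$predictions
    if (fit$classification) {
      if (type == "prob") return(pr)
      lev <- colnames(pr)
      return(factor(lev[max.col(pr, ties.method = "first")], levels = fit$levels))
    }
    return(as.numeric(pr))
  }
  if (engine == "gradient_boosting") {
    pr <- predict(fit$model, X)
    if (fit$classification) {
      if (is.null(dim(pr))) {  # binary fit collapses to one column
        pm <- cbind(1 - pr, pr)
        colnames(pm) <- fit$modelLevels
      } else pm <- pr
      pm <- pm[, fit$levels[fit$levels %in% colnames(pm)], drop = FALSE]
      if (type == "prob") return(pm)
      return(factor(colnames(pm)[max.col(pm, ties.method = "first")],
                    levels = fit$levels))
    }
    return(as.numeric(pr))
  }
  if (engine == "svm") {
    pr <- predict(fit$model, X)
    if (fit$classification) {
      if (type == "prob") stop("class probabilities not enabled for svm")
      return(factor(as.character(pr), levels = fit$levels))
    }
    return(as.numeric(pr))
  }
  stop("unknown engine: ", engine)
}

# stratified (classification) or shuffled (regression) k-fold test indices
makeFolds <- function(y, k, seed) {
  n <- length(y)
  fold <- integer(n)
  withSeed(seed, {
    if (is.factor(y)) {
      for (lev in levels(y)) {
        idx <- which(y == lev)
        if (length(idx))
          fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold[] <- sample(rep_len(seq_len(k), n))
    }
  })
  lapply(seq_len(k), function(f) which(fold == f))
}

balancedAccuracy <- function(truth, pred) {
  lev <- intersect(levels(droplevels(truth)), levels(truth))
  recalls <- vapply(lev, function(l) {
    i <- truth == l
    mean(pred[i] == l)
  }, numeric(1))
  mean(recalls)
}

rSquared <- function(truth, pred) {
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sst
}

# out-of-fold predictions are pooled and scored once: a per-fold mean is
# unstable when a small fold happens to have (near-)constant truth
crossValidate <- function(X, y, learner, seed, cvFolds, classification) {
  folds <- makeFolds(y, cvFolds, seed)
  oof <- if (classification)
    factor(rep(NA_character_, length(y)), levels = levels(y))
  else rep(NA_real_, length(y))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    if (!length(test)) next
    ytr <- y[-test]
    if (classification) {
      ytr <- droplevels(ytr)
      if (nlevels(ytr) < 2L) next
    }
    fit <- fitEngine(X[-test, , drop = FALSE], ytr, learner,
                     seed + f, classification)
    oof[test] <- predictEngine(fit, X[test, , drop = FALSE])
  }
  got <- !is.na(oof)
  if (!any(got)) return(NA_real_)
  if (classification)
    balancedAccuracy(droplevels(y[got]), oof[got])
  else rSquared(y[got], oof[got])
}

alignEnv <- function(env, ids) {
  stopifnot(is(env, "EnvTable"))
  idx <- match(ids, env@sampleIds)
  if (anyNA(idx))
    stop("environment table is missing samples: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  env@features[idx, , drop = FALSE]
}

trainingQuantiles <- function(X, qLo = 2.5, qHi = 97.5) {
  rng <- apply(X, 2L, stats::quantile, probs = c(qLo, qHi) / 100,
               names = FALSE)
  rownames(rng) <- c("q2.5", "q97.5")
  rng
}

# ---- model fitting ----------------------------------------------------

#' Fit a classification ADM (cADM)
#'
#' Trains a three-state classifier of per-sample co-occurrence state as a
#' function of environmental predictors. Performance is the mean balanced
#' accuracy over stratified `cvFolds`-fold cross-validation on the training
#' data; the final model is refit on all samples. Deterministic for a fixed
#' seed.
#'
#' @param states a [CooccurrenceStates-class]
#' @param env an [EnvTable-class] covering the states' samples
#' @param learner `"random_forest"` (default), `"gradient_boosting"`,
#'   `"svm"` or `"memorize"`
#' @param seed integer
#' @param cvFolds folds for cross-validation (default 5)
#' @return an [AdmModel-class] with `variant = "cADM"`
#' @export
fitCadm <- function(states, env, learner = "random_forest", seed = 1L,
                    cvFolds = 5L) {
  stopifnot(is(states, "CooccurrenceStates"))
  y <- droplevels(states@states)
  if (nlevels(y) < 2L)
    stop("degenerate cADM: only one co-occurrence state ('",
         levels(y), "') observed; no model can be fit")
  X <- alignEnv(env, states@sampleIds)
  perf <- crossValidate(X, y, learner, seed, as.integer(cvFolds), TRUE)
  fit <- fitEngine(X, y, learner, seed, TRUE)
  new("AdmModel", pair = states@pair, variant = "cADM", learner = learner,
      predictors = colnames(X), fit = fit,
      performance = c(balanced_accuracy = perf),
      trainingRanges = trainingQuantiles(X), nTrain = nrow(X),
      trainingRho = NA_real_, seed = as.integer(seed))
}

#' Fit a regression ADM (rADM)
#'
#' Trains a regressor of per-sample alpha as a function of environmental
#' predictors. Performance is the mean R^2 over `cvFolds`-fold
#' cross-validation; the observed pair rho (`1 - sum(alpha)`) and the
#' training sample count are stored for later rho* reconstruction.
#'
#' @param alpha an [AlphaMatrix-class]
#' @inheritParams fitCadm
#' @return an [AdmModel-class] with `variant = "rADM"`
#' @export
fitRadm <- function(alpha, env, learner = "random_forest", seed = 1L,
                    cvFolds = 5L) {
  stopifnot(is(alpha, "AlphaMatrix"))
  y <- alpha@alpha
  if (length(y) < cvFolds)
    stop("need at least cvFolds samples")
  constant <- stats::sd(y) == 0
  if (constant)
    warning("constant alpha vector: model will predict the constant; ",
            "cross-validated R^2 is undefined")
  X <- alignEnv(env, alpha@sampleIds)
  perf <- if (constant) NA_real_ else
    crossValidate(X, y, learner, seed, as.integer(cvFolds), FALSE)
  fit <- fitEngine(X, y, learner, seed, FALSE)
  new("AdmModel", pair = alpha@pair, variant = "rADM", learner = learner,
      predictors = colnames(X), fit = fit, performance = c(r2 = perf),
      trainingRanges = trainingQuantiles(X), nTrain = nrow(X),
      trainingRho = reconstructRho(y), seed = as.integer(seed))
}

#' Predict from a fitted AdmModel
#'
#' @param model an [AdmModel-class]
#' @param newdata matrix or data.frame containing the model's predictor
#'   columns
#' @param type `"response"` (states / alpha) or `"prob"` (class
#'   probabilities, cADM learners that provide them)
#' @return factor of states, numeric alpha, or a probability matrix
#' @export
predictAdm <- function(model, newdata, type = c("response", "prob")) {
  stopifnot(is(model, "AdmModel"))
  type <- match.arg(type)
  newdata <- as.matrix(as.data.frame(newdata)[, model@predictors,
                                              drop = FALSE])
  predictEngine(model@fit, newdata, type = type)
}

#' Fit and rank several learners on the same association
#'
#' Fits one model per learner (cADM when given states, rADM when given an
#' alpha vector) and returns them sorted by cross-validated performance,
#' best first; exact ties are broken by learner name order so the ranking
#' is deterministic.
#'
#' @param target a [CooccurrenceStates-class] or [AlphaMatrix-class]
#' @param env an [EnvTable-class]
#' @param learners character vector of at least 2 learner names
#' @param seed integer
#' @param cvFolds folds
#' @return named list of [AdmModel-class], sorted
#' @export
compareLearners <- function(target, env,
                            learners = c("random_forest",
                                         "gradient_boosting", "svm"),
                            seed = 1L, cvFolds = 5L) {
  if (length(learners) < 1L) stop("need at least one learner")
  fitOne <- if (is(target, "CooccurrenceStates")) fitCadm
            else if (is(target, "AlphaMatrix")) fitRadm
            else stop("target must be CooccurrenceStates or AlphaMatrix")
  models <- lapply(learners, function(l)
    fitOne(target, env, learner = l, seed = seed, cvFolds = cvFolds))
  perf <- vapply(models, function(m) m@performance[[1L]], numeric(1))
  ord <- order(-perf, learners)
  setNames(models[ord], learners[ord])
}

#' Permutation feature importance
#'
#' For each predictor, the importance is the mean drop in model performance
#' (balanced accuracy for cADM, R^2 for rADM, evaluated on the supplied
#' data) over `nRepeats` seeded permutations of that predictor's column.
#' Useless features give importances near (possibly below) zero; permuting
#' a constant column changes nothing, so its importance is exactly 0.
#'
#' @param model a fitted [AdmModel-class]
#' @param env an [EnvTable-class] aligned to the target
#' @param target a [CooccurrenceStates-class] (cADM) or
#'   [AlphaMatrix-class] (rADM)
#' @param nRepeats permutations per feature (>= 1)
#' @param seed integer
#' @return a [FeatureImportance-class]
#' @export
permutationImportance <- function(model, env, target, nRepeats = 10L,
                                  seed = 1L) {
  stopifnot(is(model, "AdmModel"))
  nRepeats <- as.integer(nRepeats)
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  if (model@variant == "cADM") {
    stopifnot(is(target, "CooccurrenceStates"))
    y <- droplevels(target@states)
    ids <- target@sampleIds
    score <- function(yhat) balancedAccuracy(y, yhat)
  } else {
    stopifnot(is(target, "AlphaMatrix"))
    y <- target@alpha
    ids <- target@sampleIds
    score <- function(yhat) rSquared(y, yhat)
  }
  X <- alignEnv(env, ids)[, model@predictors, drop = FALSE]
  baseline <- score(predictEngine(model@fit, X))
  n <- nrow(X)
  imp <- setNames(numeric(length(model@predictors)), model@predictors)
  withSeed(seed, {
    for (f in model@predictors) {
      drops <- numeric(nRepeats)
      for (r in seq_len(nRepeats)) {
        Xp <- X
        Xp[, f] <- Xp[sample.int(n), f]
        drops[r] <- baseline - score(predictEngine(model@fit, Xp))
      }
      imp[f] <- mean(drops)
    }
  })
  new("FeatureImportance", pair = model@pair, importance = imp,
      nRepeats = nRepeats, seed = as.integer(seed))
}
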