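# The proportionality metric rho, its per-sample alpha decomposition, and
# bootstrap-FDR significance thresholds.

popVar <- function(v) mean((v - mean(v))^2)  # population variance, /n

#' Proportionality metric rho for one pair of CLR vectors
#'
#' `rho = 1 - var(mj - mk) / (var(mj) + var(mk))` with population variances
#' (divisor n). Identical vectors give 1, sign-flipped vectors give -1, and
#' the value never exceeds 1. The result is symmetric in its arguments and
#' invariant to adding a common constant to both.
#'
#' @param mj,mk numeric CLR vectors of equal length n >= 2
#' @return a single numeric in \[-1, 1\]
#' @examples
#' v <- c(-1, 0, 2)
#' pairRho(v, v)    # 1
#' pairRho(v, -v)   # -1
#' @export
pairRho <- function(mj, mk) {
  checkRhoInput(mj, mk)
  1 - popVar(mj - mk) / (popVar(mj) + popVar(mk))
}

checkRhoInput <- function(mj, mk) {
  if (length(mj) != length(mk))
    stop("vectors must have equal length")
  if (length(mj) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(mj)) || any(!is.finite(mk)))
    stop("non-finite values in CLR vectors")
  if (popVar(mj) + popVar(mk) == 0)
    stop("association undefined: both vectors are constant")
  invisible(TRUE)
}

#' Decompose rho into per-sample local contributions alpha
#'
#' With `d_i = mj_i - mk_i`, each `alpha[i] = (d_i - mean(d))^2 /
#' (sum((mj - mean(mj))^2) + sum((mk - mean(mk))^2))`, which is
#' non-negative and satisfies `1 - sum(alpha) == pairRho(mj, mk)` exactly.
#' Individual alphas carry the local deviation of the pair's co-abundance
#' at each sample; their sum, not any single value, is ecologically
#' interpretable.
#'
#' @param mj,mk numeric CLR vectors of equal length
#' @param pair character(2) taxon ids for labelling
#' @param sampleIds character sample ids (defaults to names or indices)
#' @return an [AlphaMatrix-class]
#' @export
alphaDecompose <- function(mj, mk, pair = c("taxon_j", "taxon_k"),
                           sampleIds = NULL) {
  checkRhoInput(mj, mk)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(names(mj))) names(mj)
                 else as.character(seq_along(mj))
  d <- mj - mk
  denom <- sum((mj - mean(mj))^2) + sum((mk - mean(mk))^2)
  alpha <- (d - mean(d))^2 / denom
  new("AlphaMatrix", pair = as.character(pair), alpha = as.numeric(alpha),
      sampleIds = as.character(sampleIds))
}

#' Reconstruct rho from an alpha vector
#'
#' @param alpha numeric vector of local contributions, or an
#'   [AlphaMatrix-class]
#' @return `1 - sum(alpha)`
#' @export
reconstructRho <- function(alpha) {
  if (is(alpha, "AlphaMatrix")) alpha <- alpha@alpha
  if (!length(alpha)) stop("empty alpha vector")
  if (any(!is.finite(alpha))) stop("non-finite alpha values")
  1 - sum(alpha)
}

#' Proportionality rho for all taxon pairs
#'
#' Computes rho for each of the m(m-1)/2 unordered taxon pairs of the CLR
#' assay via the covariance identity `rho = 2 cov / (var_j + var_k)`
#' (population moments), which agrees entrywise with per-pair [pairRho()]
#' calls. Pairs where both taxa are constant across samples have no defined
#' rho; they are excluded with a warning and listed in the result's
#' `dropped` slot rather than silently assigned `NaN`.
#'
#' @param x an [AdmExperiment-class] with a `"clr"` assay, or a numeric CLR
#'   matrix with taxa as rows
#' @return an [AssociationSet-class] (thresholds unset)
#' @export
allPairsRho <- function(x) {
  clr <- if (is(x, "AdmExperiment")) clrValues(x) else as.matrix(x)
  m <- nrow(clr)
  if (m < 2L) stop("need at least 2 taxa")
  n <- ncol(clr)
  taxa <- rownames(clr)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(m))
  cen <- clr - rowMeans(clr)
  vars <- rowMeans(cen^2)
  cv <- tcrossprod(cen) / n
  ij <- which(upper.tri(cv), arr.ind = TRUE)
  # upper.tri walks columns, so order pairs by (row j, col k) with j < k
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  j <- ij[, 1L]; k <- ij[, 2L]
  denom <- vars[j] + vars[k]
  rho <- 2 * cv[ij] / denom
  ok <- denom > 0
  dropped <- character()
  if (!all(ok)) {
    dropped <- paste(taxa[j[!ok]], taxa[k[!ok]], sep = "|")
    warning(length(dropped),
            " constant pair(s) excluded (rho undefined): ",
            paste(head(dropped, 5), collapse = ", "))
  }
  pairs <- data.frame(taxon_j = taxa[j[ok]], taxon_k = taxa[k[ok]],
                      rho = rho[ok], stringsAsFactors = FALSE)
  new("AssociationSet", pairs = pairs, nSamples = as.integer(n),
      dropped = dropped)
}

#' Bootstrap-FDR thresholds for rho
#'
#' Parametric p values are unavailable for proportionality, so signed rho
#' thresholds are calibrated against a permutation null: each bootstrap
#' replicate permutes every taxon's sample labels independently, destroying
#' pairwise covariation while preserving marginal distributions. For each
#' candidate threshold t, `FDR(t) = mean_b #\{null pairs beyond t\} /
#' max(1, #\{observed pairs beyond t\})` (capped at 1); `t_pos` is the
#' smallest positive grid value with FDR <= `fdrLevel` and `t_neg` the
#' largest (closest to zero) negative one. Deterministic for a fixed seed.
#'
#' @param x an [AdmExperiment-class] with a `"clr"` assay, or a CLR matrix
#'   (taxa x samples)
#' @param nBoot number of null replicates (>= 1)
#' @param fdrLevel target FDR in (0, 1\]
#' @param seed integer seed
#' @param thresholdGrid candidate thresholds; default -1 to 1 in steps of
#'   0.05, the granularity at which such thresholds are usually reported
#' @return named numeric `c(t_neg, t_pos)`, with attributes `fdr_neg`,
#'   `fdr_pos` (the FDR curves over the grid)
#' @export
bootstrapFdrThresholds <- function(x, nBoot = 100L, fdrLevel = 0.01,
                                   seed = 1L,
                                   thresholdGrid = seq(-1, 1, by = 0.05)) {
  clr <- if (is(x, "AdmExperiment")) clrValues(x) else as.matrix(x)
  nBoot <- as.integer(nBoot)
  if (nBoot < 1L) stop("nBoot must be >= 1")
  if (fdrLevel <= 0 || fdrLevel > 1) stop("fdrLevel must lie in (0, 1]")
  obs <- allPairsRho(clr)@pairs$rho
  tg <- sort(thresholdGrid)
  pos <- tg[tg > 0]
  neg <- tg[tg < 0]
  obsPos <- vapply(pos, function(t) sum(obs >= t), numeric(1))
  obsNeg <- vapply(neg, function(t) sum(obs <= t), numeric(1))
  n <- ncol(clr)
  nullPos <- matrix(0, nrow = nBoot, ncol = length(pos))
  nullNeg <- matrix(0, nrow = nBoot, ncol = length(neg))
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      perm <- t(apply(clr, 1L, function(v) v[sample.int(n)]))
      nullRho <- suppressWarnings(allPairsRho(perm)@pairs$rho)
      nullPos[b, ] <- vapply(pos, function(t) sum(nullRho >= t), numeric(1))
      nullNeg[b, ] <- vapply(neg, function(t) sum(nullRho <= t), numeric(1))
    }
  })
  fdrPos <- pmin(1, colMeans(nullPos) / pmax(1, obsPos))
  fdrNeg <- pmin(1, colMeans(nullNeg) / pmax(1, obsNeg))
  okPos <- which(fdrPos <= fdrLevel)
  okNeg <- which(fdrNeg <= fdrLevel)
  if (!length(okPos) || !length(okNeg))
    stop(sprintf(paste0("no grid threshold attains FDR <= %g ",
                        "(minimum attainable: %g positive, %g negative)"),
                 fdrLevel, min(fdrPos), min(fdrNeg)))
  tPos <- pos[min(okPos)]           # smallest positive t passing
  tNeg <- neg[max(okNeg)]           # largest (closest to 0) negative t
  structure(c(t_neg = tNeg, t_pos = tPos),
            fdr_neg = setNames(fdrNeg, neg),
            fdr_pos = setNames(fdrPos, pos))
}

#' Apply significance thresholds to an AssociationSet
#'
#' A pair is significant iff `rho >= t_pos` or `rho <= t_neg`; significant
#' pairs carry the sign of the threshold they crossed.
#'
#' @param x an [AssociationSet-class]
#' @param thresholds named numeric `c(t_neg, t_pos)` from
#'   [bootstrapFdrThresholds()]
#' @param fdrLevel the FDR level the thresholds were derived at (recorded)
#' @return the [AssociationSet-class] with `significant` and `sign` columns
#' @export
callSignificance <- function(x, thresholds, fdrLevel = NA_real_) {
  stopifnot(is(x, "AssociationSet"))
  if (!all(c("t_neg", "t_pos") %in% names(thresholds)))
    stop("thresholds must be named c(t_neg, t_pos)")
  tn <- thresholds[["t_neg"]]; tp <- thresholds[["t_pos"]]
  if (!(tn < 0 && tp > 0)) stop("expected t_neg < 0 < t_pos")
  p <- x@pairs
  p$significant <- p$rho >= tp | p$rho <= tn
  p$sign <- ifelse(!p$significant, NA_character_,
                   ifelse(p$rho >= tp, "positive", "negative"))
  x@pairs <- p
  x@thresholds <- c(t_neg = tn, t_pos = tp)
  x@fdrLevel <- as.numeric(fdrLevel)
  validObject(x)
  x
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
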