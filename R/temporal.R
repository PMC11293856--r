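# Temporal response analysis: persistence filtering, OLS slopes of
# co-presence proportion and rho* against calendar year, and the
# five-group climate-response classification.

RESPONSE_GROUPS <- c("pp", "pm", "mp", "mm", "neutral")

#' Validate and order a trajectory table
#'
#' @param projections long-format data.frame with columns
#'   `association_id`, `year`, `copresence` (proportion in \[0, 1\]) and
#'   `rho_star`, one row per association and time point
#' @return long-format data.frame `association_id`, `year`, `copresence`,
#'   `rho_star`, ordered by id then year
#' @export
trajectoryTable <- function(projections) {
  tr <- as.data.frame(projections)
  need <- c("association_id", "year", "copresence", "rho_star")
  if (!all(need %in% names(tr)))
    stop("trajectories need columns ", paste(need, collapse = ", "))
  tr <- tr[order(tr$association_id, tr$year), need]
  dup <- duplicated(tr[, c("association_id", "year")])
  if (any(dup)) stop("duplicate (association, year) rows")
  rownames(tr) <- NULL
  tr
}

#' Keep associations persistently co-present over time
#'
#' Retains associations whose projected co-presence proportion is at least
#' `minCopresence` at EVERY time point; a single violating time point
#' drops the trajectory.
#'
#' @param trajectories long-format data.frame (see [trajectoryTable()])
#' @param minCopresence threshold in \[0, 1\] (default 0.30)
#' @return the filtered data.frame
#' @export
filterPersistent <- function(trajectories, minCopresence = 0.30) {
  tr <- trajectoryTable(trajectories)
  if (!nrow(tr)) stop("empty trajectory table")
  keepId <- vapply(split(tr$copresence, tr$association_id),
                   function(v) all(v >= minCopresence), logical(1))
  tr[tr$association_id %in% names(keepId)[keepId], , drop = FALSE]
}

olsLine <- function(x, y) {
  # closed-form simple least squares of y on x
  if (stats::sd(x) == 0) stop("constant time vector: slope undefined")
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  if (stats::sd(y) == 0)
    return(c(slope = 0, pearson = NA_real_, r2 = NA_real_))
  r <- stats::cor(x, y)
  c(slope = slope, pearson = r, r2 = r^2)
}

#' OLS slopes of co-presence proportion and rho* against year
#'
#' Simple linear regression of each series on calendar year, with Pearson
#' r and R^2 as linearity diagnostics. Constant series get slope 0 with
#' missing diagnostics. Requires at least 3 time points per association.
#'
#' @param trajectories long-format data.frame (see [trajectoryTable()])
#' @return data.frame with one row per association: `association_id`,
#'   `slope_c`, `pearson_c`, `r2_c`, `slope_r`, `pearson_r`, `r2_r`
#' @export
fitSlopes <- function(trajectories) {
  tr <- trajectoryTable(trajectories)
  out <- lapply(split(tr, tr$association_id), function(d) {
    if (nrow(d) < 3L)
      stop("association '", d$association_id[1L],
           "' has fewer than 3 time points")
    fc <- olsLine(d$year, d$copresence)
    fr <- olsLine(d$year, d$rho_star)
    data.frame(association_id = d$association_id[1L],
               slope_c = fc[["slope"]], pearson_c = fc[["pearson"]],
               r2_c = fc[["r2"]], slope_r = fr[["slope"]],
               pearson_r = fr[["pearson"]], r2_r = fr[["r2"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify associations into the five climate-response groups
#'
#' Each metric (co-presence slope `slope_c`, rho* slope `slope_r`) gets a
#' neutral band around zero: with `bandMode = "max"` (default) the band is
#' `bandFraction` times the metric's maximum absolute slope; with
#' `bandMode = "quantile"` it is the central `bandFraction` mass of the
#' metric's slope distribution. An association is `neutral` iff BOTH its
#' slopes fall in their bands; otherwise it is labelled by the raw sign of
#' each slope: `pp` = (+c)(+r), `pm` = (+c)(-r), `mp` = (-c)(+r),
#' `mm` = (-c)(-r). A metric inside its band while the other is outside
#' still contributes its raw sign (the five groups leave no room for
#' half-neutral labels); an exactly zero slope forced to carry a sign maps
#' to "+". The partition is exhaustive, disjoint, order-invariant, and
#' invariant to rescaling either metric's slopes by a positive constant.
#'
#' @param slopes data.frame from [fitSlopes()] (needs `association_id`,
#'   `slope_c`, `slope_r`)
#' @param bandFraction width parameter of the neutral band (default 0.10)
#' @param bandMode `"max"` or `"quantile"`
#' @return the input data.frame with added columns `neutral_c`,
#'   `neutral_r`, `group` (factor over pp, pm, mp, mm, neutral) and
#'   `group_label` (e.g. `"(+c)(-r)"`)
#' @export
classifyResponse <- function(slopes, bandFraction = 0.10,
                             bandMode = c("max", "quantile")) {
  bandMode <- match.arg(bandMode)
  slopes <- as.data.frame(slopes)
  if (!all(c("association_id", "slope_c", "slope_r") %in% names(slopes)))
    stop("slopes must have association_id, slope_c and slope_r")
  if (!nrow(slopes)) stop("need at least one association")
  if (bandFraction < 0 || bandFraction > 1)
    stop("bandFraction must lie in [0, 1]")
  inBand <- function(s) {
    if (bandMode == "max") {
      half <- bandFraction * max(abs(s))
      abs(s) <= half
    } else {
      qs <- stats::quantile(s, probs = 0.5 + c(-1, 1) * bandFraction / 2,
                            names = FALSE)
      s >= qs[1L] & s <= qs[2L]
    }
  }
  nc <- inBand(slopes$slope_c)
  nr <- inBand(slopes$slope_r)
  signChar <- function(s) ifelse(s >= 0, "p", "m")
  grp <- ifelse(nc & nr, "neutral",
                paste0(signChar(slopes$slope_c), signChar(slopes$slope_r)))
  pretty <- c(pp = "(+c)(+r)", pm = "(+c)(-r)", mp = "(-c)(+r)",
              mm = "(-c)(-r)", neutral = "neutral")
  slopes$neutral_c <- nc
  slopes$neutral_r <- nr
  slopes$group <- factor(grp, levels = RESPONSE_GROUPS)
  slopes$group_label <- unname(pretty[grp])
  slopes
}

#' Contingency of response group by biogeographic cluster
#'
#' @param classifications data.frame from [classifyResponse()]
#' @param clusterLabels named vector (names = association ids) of cluster
#'   labels, e.g. from [clusterLabels()]
#' @return a `table` of group x cluster counts (all five group rows kept)
#' @export
summarizeGroups <- function(classifications, clusterLabels) {
  classifications <- as.data.frame(classifications)
  if (!nrow(classifications))
    return(table(group = factor(character(), levels = RESPONSE_GROUPS),
                 cluster = character()))
  idx <- match(classifications$association_id, names(clusterLabels))
  if (anyNA(idx))
    stop("cluster labels missing for association(s): ",
         paste(head(classifications$association_id[is.na(idx)], 5),
               collapse = ", "))
  table(group = factor(as.character(classifications$group),
                       levels = RESPONSE_GROUPS),
        cluster = as.character(clusterLabels[idx]))
}
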