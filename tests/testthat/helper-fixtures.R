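# Shared fixture builders and independent oracles. Oracles are coded from
# first principles (closed forms, brute-force enumeration) and never call
# the implementation paths they check.

# a CLR matrix (taxa x samples) built directly from log-normal draws,
# independently of clrTransform()
randomClrMatrix <- function(m, n, seed = 1) {
  set.seed(seed)
  lg <- matrix(rnorm(m * n, mean = 2, sd = 1), nrow = n, ncol = m)
  clr <- lg - rowMeans(lg)  # centre each sample (row) by its mean
  t(structure(clr, dimnames = list(paste0("s", seq_len(n)),
                                   paste0("t", seq_len(m)))))
}

# oracle for rho, written straight from the defining formula with /n
# population variances
oracleRho <- function(x, y) {
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  1 - pv(x - y) / (pv(x) + pv(y))
}

# oracle for the alpha sum: the expanded per-sample sum of squared
# deviations of the difference vector over the summed squared deviations
oracleAlphaSum <- function(x, y) {
  d <- x - y
  sum((d - mean(d))^2) / (sum((x - mean(x))^2) + sum((y - mean(y))^2))
}

# brute-force normalized edge betweenness by explicit BFS path enumeration
oracleEdgeBetweenness <- function(edges, nNodes) {
  # edges: 2-column matrix of integer node ids
  adj <- lapply(seq_len(nNodes), function(i) integer())
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  ekey <- paste(pmin(edges[, 1], edges[, 2]),
                pmax(edges[, 1], edges[, 2]), sep = "-")
  counts <- setNames(numeric(length(ekey)), ekey)
  allShortestPaths <- function(s, t) {
    # enumerate all shortest s-t paths by BFS layering + backtracking
    dist <- rep(Inf, nNodes); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (v in adj[[u]])
        if (dist[v] > dist[u] + 1) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(node, acc) {
      if (node == s) { paths[[length(paths) + 1]] <<- rev(acc); return() }
      for (v in adj[[node]]) if (dist[v] == dist[node] - 1)
        walk(v, c(acc, v))
    }
    walk(t, t)
    paths
  }
  for (s in seq_len(nNodes - 1)) for (t in (s + 1):nNodes) {
    paths <- allShortestPaths(s, t)
    if (!length(paths)) next
    w <- 1 / length(paths)
    for (p in paths) for (i in seq_len(length(p) - 1)) {
      k <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]), sep = "-")
      counts[k] <- counts[k] + w
    }
  }
  counts / (nNodes * (nNodes - 1) / 2)
}

# a deterministic 3-state labelling driven by temperature thresholds
separableStates <- function(temp) {
  st <- ifelse(temp > 15, "copresence",
        ifelse(temp < 5, "coabsence", "exclusion"))
  factor(st, levels = c("copresence", "coabsence", "exclusion"))
}

# EnvTable with a temperature gradient and three noise predictors
gradientEnv <- function(n, seed = 1) {
  set.seed(seed)
  EnvTable(cbind(temperature = runif(n, 0, 30),
                 salinity = rnorm(n, 35, 0.3),
                 nitrate = runif(n, 0, 20),
                 silicate = runif(n, 0, 30)),
           sampleIds = paste0("s", seq_len(n)))
}

statesFromFactor <- function(f, ids = paste0("s", seq_along(f))) {
  new("CooccurrenceStates", pair = c("a", "b"),
      states = factor(as.character(f),
                      levels = c("copresence", "coabsence", "exclusion")),
      sampleIds = ids)
}

alphaFromVector <- function(a, ids = paste0("s", seq_along(a))) {
  new("AlphaMatrix", pair = c("a", "b"), alpha = as.numeric(a),
      sampleIds = ids)
}

# small regular grid with a latitudinal temperature field
smallGrid <- function(latStep = 5, lonStep = 60, seed = 1) {
  cells <- expand.grid(lat = seq(-60, 60, by = latStep),
                       lon = seq(-180, 120, by = lonStep))
  set.seed(seed)
  feats <- cbind(temperature = 28 - 0.3 * abs(cells$lat),
                 salinity = rnorm(nrow(cells), 35, 0.2),
                 nitrate = pmax(0.1, 2 + 0.2 * abs(cells$lat)),
                 silicate = pmax(0.1, 5 + 0.2 * abs(cells$lat)))
  GridField(cells, feats, timeLabel = "present")
}
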