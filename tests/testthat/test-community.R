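fakeCadmProjection <- function(states, idx, pair = c("a", "b")) {
  new("ProjectionResult", pair = pair, variant = "cADM",
      timeLabel = "present", cellIndex = as.integer(idx),
      states = factor(states,
                      levels = c("copresence", "coabsence", "exclusion")),
      alphaStar = numeric(),
      copresenceProportion = mean(states == "copresence"))
}

test_that("stacked co-presence matrix reflects per-cell states", {
  idx <- 1:4
  p1 <- fakeCadmProjection(rep("copresence", 4), idx, c("a", "b"))
  p2 <- fakeCadmProjection(c("copresence", "coabsence", "exclusion",
                             "copresence"), idx, c("a", "c"))
  st <- stackCopresence(list(p1, p2))
  expect_equal(unname(st["a|b", ]), rep(1L, 4))
  expect_equal(unname(st["a|c", ]), c(1L, 0L, 0L, 1L))
  # row sums recount each projection's copresence cells
  expect_equal(unname(rowSums(st)),
               c(4L, sum(p2@states == "copresence")))
  p3 <- fakeCadmProjection(rep("coabsence", 3), 1:3, c("b", "c"))
  expect_error(stackCopresence(list(p1, p3)), "different grids")
})

# well-separated binary archetypes with per-row noise
plantedSignatures <- function(k, perCluster, nCells, seed, flip = 0.03) {
  set.seed(seed)
  arch <- matrix(rbinom(k * nCells, 1, 0.5), nrow = k)
  while (k > 1 && min(dist(arch, method = "manhattan")) < nCells * 0.3) {
    arch <- matrix(rbinom(k * nCells, 1, 0.5), nrow = k)
  }
  rows <- arch[rep(seq_len(k), each = perCluster), ]
  noise <- matrix(rbinom(length(rows), 1, flip), nrow = nrow(rows))
  list(mat = abs(rows - noise),
       truth = rep(seq_len(k), each = perCluster))
}

test_that("silhouette scan recovers the planted number of archetypes", {
  for (k in c(2L, 4L)) {
    ps <- plantedSignatures(k, perCluster = 12, nCells = 40, seed = 30 + k)
    rownames(ps$mat) <- paste0("assoc", seq_len(nrow(ps$mat)))
    res <- clusterSignatures(ps$mat, kRange = 2:8, seed = 1)
    expect_equal(chosenK(res), k)
    # labels match ground truth up to permutation
    expect_equal(length(unique(paste(clusterLabels(res), ps$truth))), k)
  }
})

test_that("clustering is deterministic and row-order invariant", {
  ps <- plantedSignatures(3, 10, 30, seed = 41)
  rownames(ps$mat) <- paste0("assoc", seq_len(30))
  r1 <- clusterSignatures(ps$mat, kRange = 2:6, seed = 9)
  r2 <- clusterSignatures(ps$mat, kRange = 2:6, seed = 9)
  expect_identical(clusterLabels(r1), clusterLabels(r2))
  perm <- sample(30)
  r3 <- clusterSignatures(ps$mat[perm, ], kRange = 2:6, seed = 9)
  # same partition up to label permutation
  expect_equal(length(unique(paste(clusterLabels(r1)[rownames(ps$mat)],
                                   clusterLabels(r3)[rownames(ps$mat)]))),
               chosenK(r1))
  expect_error(clusterSignatures(matrix(1L, 20, 5), kRange = 2:4, seed = 1),
               "identical")
  expect_error(clusterSignatures(ps$mat[1:4, ], kRange = 2:6, seed = 1),
               "at least")
})

test_that("association graphs are undirected, weighted and deduplicated", {
  assoc <- data.frame(taxon_j = c("a", "b", "a"),
                      taxon_k = c("b", "c", "c"),
                      rho_star = c(0.9, 0.8, 0.7))
  g <- buildGraph(assoc, cluster = "blue")
  expect_equal(igraph::vcount(graphOf(g)), 3)
  expect_equal(igraph::ecount(graphOf(g)), 3)
  expect_equal(sort(igraph::E(graphOf(g))$weight), c(0.7, 0.8, 0.9))
  expect_error(buildGraph(rbind(assoc, assoc[1, ])), "duplicate")
  empty <- buildGraph(assoc[0, ])
  expect_equal(igraph::vcount(graphOf(empty)), 0)
  set.seed(31)
  taxa <- paste0("t", 1:40)
  pairsAll <- t(combn(taxa, 2))
  pick <- sample(nrow(pairsAll), 100)
  big <- buildGraph(data.frame(taxon_j = pairsAll[pick, 1],
                               taxon_k = pairsAll[pick, 2],
                               rho_star = runif(100)))
  expect_equal(igraph::vcount(graphOf(big)),
               length(unique(c(pairsAll[pick, ]))))
})

test_that("edge betweenness matches closed forms and the brute-force oracle", {
  path <- buildGraph(data.frame(taxon_j = c("a", "b"),
                                taxon_k = c("b", "c"),
                                rho_star = c(1, 1)))
  eb <- edgeBetweennessCentrality(path)
  expect_equal(unname(eb), rep(2 / 3, 2))   # each edge on 2 of 3 pair paths
  k4 <- t(combn(letters[1:4], 2))
  full <- buildGraph(data.frame(taxon_j = k4[, 1], taxon_k = k4[, 2],
                                rho_star = 1))
  expect_equal(var(edgeBetweennessCentrality(full)), 0)  # symmetry
  # random 12-node graphs against BFS path enumeration
  for (s in 1:3) {
    set.seed(50 + s)
    cand <- t(combn(12, 2))
    pick <- cand[runif(nrow(cand)) < 0.3, , drop = FALSE]
    g <- buildGraph(data.frame(taxon_j = paste0("n", pick[, 1]),
                               taxon_k = paste0("n", pick[, 2]),
                               rho_star = 1))
    ig <- graphOf(g)
    idOf <- setNames(seq_len(igraph::vcount(ig)), igraph::V(ig)$name)
    ends <- igraph::ends(ig, igraph::E(ig))
    em <- cbind(idOf[ends[, 1]], idOf[ends[, 2]])
    want <- oracleEdgeBetweenness(em, igraph::vcount(ig))
    gotKeys <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]),
                     sep = "-")
    expect_equal(unname(edgeBetweennessCentrality(g)),
                 unname(want[gotKeys]), tolerance = 1e-9)
  }
})

test_that("on trees the unnormalized betweenness is a side-size product", {
  for (s in 1:5) {
    set.seed(60 + s)
    n <- sample(10:50, 1)
    # random recursive tree
    parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), numeric(1)))
    df <- data.frame(taxon_j = paste0("v", parent[-1]),
                     taxon_k = paste0("v", 2:n), rho_star = 1)
    g <- buildGraph(df)
    eb <- edgeBetweennessCentrality(g, normalized = FALSE)
    ig <- graphOf(g)
    for (e in seq_len(igraph::ecount(ig))) {
      cut <- igraph::delete_edges(ig, e)
      sizes <- igraph::components(cut)$csize
      expect_equal(unname(eb[e]), prod(sizes))
    }
  }
})

test_that("edge-per-node ratio and conventional density are distinct", {
  tri <- t(combn(c("a", "b", "c"), 2))
  g <- buildGraph(data.frame(taxon_j = tri[, 1], taxon_k = tri[, 2],
                             rho_star = 1))
  expect_equal(edgeNodeRatio(g), 1)
  expect_equal(graphDensity(g), 1)
  star <- buildGraph(data.frame(taxon_j = "hub",
                                taxon_k = paste0("leaf", 1:5),
                                rho_star = 1))
  expect_equal(edgeNodeRatio(star), 5 / 6)
  expect_equal(graphDensity(star), 5 / choose(6, 2))
})

test_that("cross-cluster metric normalization follows the min-max rule", {
  r <- normalizeClusterMetrics(c(A = 2, B = 4))
  expect_equal(r$normalized, c(A = 0, B = 1))
  expect_equal(r$spread_percent, 50)
  rEq <- normalizeClusterMetrics(c(A = 5, B = 5))
  expect_equal(rEq$normalized, c(A = 0, B = 0))
  expect_equal(rEq$spread_percent, 0)
  set.seed(70)
  v <- setNames(runif(4, 1, 9), LETTERS[1:4])
  rr <- normalizeClusterMetrics(v)
  expect_equal(rr$normalized, (v - min(v)) / (max(v) - min(v)))
  expect_equal(rr$spread_percent, (max(v) - min(v)) / max(v) * 100)
  expect_error(normalizeClusterMetrics(c(A = 1)), "at least 2")
})
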