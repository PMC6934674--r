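# Network construction, density, centralities, walktrap clustering.

unit_assoc <- function(edges, ids, w = 1, directed = FALSE) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    m[i, j] <- w
    if (!directed) m[j, i] <- w
  }
  make_assoc(m, directed = directed)
}

test_that("build_network mirrors the association matrix", {
  ids <- c("A", "B", "C")
  m <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(m) <- 0
  g <- build_network(make_assoc(m))
  expect_false(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::V(g)$name), ids)
  # zero matrix -> edgeless
  g0 <- build_network(make_assoc(matrix(0, 3, 3, dimnames = list(ids, ids))))
  expect_equal(igraph::ecount(g0), 0)
  # asymmetric affiliative -> directed with unequal reciprocal weights
  ma <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  ma["A", "B"] <- 0.4; ma["B", "A"] <- 0.1
  gd <- build_network(make_assoc(ma, directed = TRUE))
  expect_true(igraph::is_directed(gd))
  expect_equal(sort(igraph::E(gd)$weight), c(0.1, 0.4))
})

test_that("density counts present edges over possible ones", {
  ids3 <- c("A", "B", "C"); ids4 <- c("A", "B", "C", "D")
  tri <- unit_assoc(cbind(c("A", "A", "B"), c("B", "C", "C")), ids3)
  expect_equal(net_density(build_network(tri)), 1)
  two <- unit_assoc(cbind(c("A", "C"), c("B", "D")), ids4)
  expect_equal(net_density(build_network(two)), 2 / 6)
  dir2 <- unit_assoc(cbind(c("A", "B"), c("B", "C")), ids3, directed = TRUE)
  expect_equal(net_density(build_network(dir2)), 2 / 6)
  one <- build_network(make_assoc(matrix(0, 1, 1, dimnames = list("A", "A"))))
  expect_error(net_density(one), "two nodes")
})

test_that("path-graph centralities match closed forms", {
  g <- build_network(unit_assoc(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C")))
  nm <- node_metrics(g)
  b <- nm[nm$id == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1 / 2)
  expect_equal(nm$closeness[nm$id == "A"], 1 / 3)
  expect_equal(nm$betweenness[nm$id == "A"], 0)
})

test_that("star eigenvector centrality has the sqrt(3) centre/leaf ratio", {
  ids <- c("hub", "L1", "L2", "L3")
  g <- build_network(unit_assoc(cbind("hub", c("L1", "L2", "L3")), ids))
  eig <- eigenvector_centrality(g)
  expect_equal(unname(eig[["hub"]]), 1, tolerance = 1e-8)
  expect_equal(unname(eig[["hub"]] / eig[["L1"]]), sqrt(3), tolerance = 1e-8)
  expect_equal(attr(eig, "lambda"), sqrt(3), tolerance = 1e-8)
})

test_that("complete uniform graphs have all-equal eigenvector values and Q = 0", {
  ids <- LETTERS[1:5]
  m <- matrix(0.3, 5, 5, dimnames = list(ids, ids)); diag(m) <- 0
  g <- build_network(make_assoc(m))
  eig <- eigenvector_centrality(g)
  expect_equal(as.numeric(eig), rep(1, 5), tolerance = 1e-8)
  cl <- walktrap_clusters(g)
  expect_equal(length(unique(cl$membership)), 1)
  expect_equal(cl$modularity, 0, tolerance = 1e-8)
})

test_that("eigenvector solves W x = lambda x and agrees with igraph", {
  set.seed(4)
  ids <- letters[1:8]
  m <- matrix(0, 8, 8, dimnames = list(ids, ids))
  m[upper.tri(m)] <- round(runif(28) * (runif(28) < 0.6), 3)
  m <- m + t(m)
  g <- build_network(make_assoc(m))
  x <- eigenvector_centrality(g)
  lam <- attr(x, "lambda")
  expect_lt(max(abs(m %*% as.numeric(x) - lam * as.numeric(x))), 1e-8)
  ref <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  expect_equal(as.numeric(x), as.numeric(ref[names(x)]), tolerance = 1e-6)
})

test_that("walktrap recovers two cliques joined by a weak bridge", {
  ids <- paste0("n", 1:8)
  m <- matrix(0, 8, 8, dimnames = list(ids, ids))
  m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1; diag(m) <- 0
  m[4, 5] <- m[5, 4] <- 0.1
  g <- build_network(make_assoc(m))
  cl <- walktrap_clusters(g)
  expect_equal(unname(cl$membership[1:4]), rep(1L, 4))
  expect_equal(unname(cl$membership[5:8]), rep(2L, 4))
  # oracle: best bipartition by exhaustive weighted-modularity maximisation
  best_q <- -Inf
  for (mask in 1:(2^8 - 2)) {
    part <- as.integer(intToBits(mask))[1:8] + 1L
    q <- igraph::modularity(g, part, weights = igraph::E(g)$weight)
    best_q <- max(best_q, q)
  }
  expect_equal(cl$modularity, best_q, tolerance = 1e-10)
})

test_that("degenerate graphs cluster sensibly", {
  ids <- c("A", "B", "C")
  g0 <- build_network(make_assoc(matrix(0, 3, 3, dimnames = list(ids, ids))))
  cl0 <- walktrap_clusters(g0)
  expect_equal(length(unique(cl0$membership)), 3)
  expect_equal(cl0$modularity, 0)
  # single clique
  tri <- unit_assoc(cbind(c("A", "A", "B"), c("B", "C", "C")), ids)
  cl1 <- walktrap_clusters(build_network(tri))
  expect_equal(length(unique(cl1$membership)), 1)
  expect_equal(cl1$modularity, 0)
})

test_that("directed networks are symmetrised for clustering and metrics run", {
  ma <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ma["a", "b"] <- 0.5; ma["b", "a"] <- 0.2; ma["c", "d"] <- 0.6
  g <- build_network(make_assoc(ma, directed = TRUE))
  cl <- walktrap_clusters(g)
  expect_equal(length(cl$membership), 4)
  nm <- node_metrics(g)
  expect_equal(nm$degree[nm$id == "a"], 0.7)  # in + out strength
})

test_that("removing an edge never increases density or weighted degree", {
  set.seed(8)
  for (rep in 1:5) {
    ids <- letters[1:6]
    m <- matrix(0, 6, 6, dimnames = list(ids, ids))
    m[upper.tri(m)] <- runif(15) * (runif(15) < 0.7)
    m <- m + t(m)
    if (sum(m > 0) == 0) next
    g <- build_network(make_assoc(m))
    idx <- which(m > 0 & upper.tri(m), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 1), ]
    m2 <- m; m2[pick[1], pick[2]] <- m2[pick[2], pick[1]] <- 0
    g2 <- build_network(make_assoc(m2))
    expect_lte(net_density(g2), net_density(g))
    d1 <- metric_vector(node_metrics(g), "degree")
    d2 <- metric_vector(suppressWarnings(node_metrics(g2)), "degree")
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("unit-weight betweenness and closeness equal unweighted values", {
  set.seed(15)
  ids <- letters[1:7]
  m <- matrix(0, 7, 7, dimnames = list(ids, ids))
  m[upper.tri(m)] <- as.numeric(runif(21) < 0.5)
  m <- m + t(m)
  g <- build_network(make_assoc(m))
  nm <- node_metrics(g)
  expect_equal(nm$betweenness,
               as.numeric(igraph::betweenness(g, weights = NA)))
  dmat <- igraph::distances(g, weights = NA)
  clo <- apply(dmat, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / sum(d)
  })
  expect_equal(nm$closeness, as.numeric(clo))
})

test_that("weighted degree and eigenvector centrality are strongly rank-correlated on dense simulated networks", {
  sim <- small_sim(seed = 31)
  excl <- apply_exclusions(sim$scans, sim$interactions, sim$roster)
  h <- hwi(joint_counts(excl$scans, excl$roster, "forest", "proximity"),
           tally_sightings(excl$scans, excl$roster, "forest"))
  nm <- node_metrics(build_network(h))
  rho <- cor(nm$degree, nm$eigenvector, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("empty graphs yield zero metrics with a warning", {
  ids <- c("A", "B")
  g <- build_network(make_assoc(matrix(0, 2, 2, dimnames = list(ids, ids))))
  expect_warning(nm <- node_metrics(g), "empty")
  expect_true(all(nm[, c("degree", "betweenness", "closeness", "eigenvector")] == 0))
})
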