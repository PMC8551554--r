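unit_ring <- function(n = 4) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    w[i, j] <- w[j, i] <- 1
  }
  w
}

complete_graph <- function(n, weight = 1) {
  w <- matrix(weight, n, n); diag(w) <- 0; w
}

test_that("proportional thresholding keeps exactly the top-k edges", {
  set.seed(1)
  m <- matrix(runif(68 * 68), 68, 68); m <- (m + t(m)) / 2; diag(m) <- 1
  tg <- proportional_threshold(m, 0.05)
  expect_equal(sum(tg$weights[upper.tri(tg$weights)] > 0), 114)  # round(.05*2278)
  ## retained set equals the top-k of a full sort (distinct weights)
  ut <- m[upper.tri(m)]
  kth <- sort(ut, decreasing = TRUE)[114]
  expect_setequal(which(tg$weights[upper.tri(tg$weights)] > 0),
                  which(ut >= kth))
  ## sparsity 1 only zeroes the diagonal
  full <- proportional_threshold(m, 1)
  off <- upper.tri(m)
  expect_equal(full$weights[off], m[off])
  expect_equal(unname(diag(full$weights)), rep(0, 68))
  expect_error(proportional_threshold(m, 0), "sparsity")
})

test_that("metrics match hand-enumerated values on canonical graphs", {
  ring <- unit_ring(4)
  expect_equal(characteristic_path_length(ring), 4 / 3)   # exhaustive paths
  expect_equal(global_efficiency(ring), 5 / 6)
  k5 <- complete_graph(5)
  expect_equal(characteristic_path_length(k5), 1)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(clustering_coefficient(k5)$mean, 1)
  expect_equal(local_efficiency(complete_graph(4))$mean, 1)
  ## star graph: no triangles, empty neighbour subgraphs
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star)$mean, 0)
  expect_equal(local_efficiency(star)$mean, 0)
  ## halving the weights doubles the distances
  expect_equal(characteristic_path_length(ring / 2), 8 / 3)
  ## disconnected graphs: Eglob contribution 0, L errors
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(global_efficiency(iso), 1 / 6)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_error(characteristic_path_length(iso), "disconnected")
})

test_that("all four metrics agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    w <- random_weighted_graph(n, p_edge = 0.7)
    if (all(w == 0)) next
    expect_equal(global_efficiency(w), global_efficiency_oracle(w),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(w)$per_node, clustering_oracle(w),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(w)$per_node, local_efficiency_oracle(w),
                 tolerance = 1e-12)
    d <- floyd_warshall_oracle(w)
    if (all(is.finite(d)))
      expect_equal(characteristic_path_length(w), path_length_oracle(w),
                   tolerance = 1e-12)
  }
})

test_that("node relabelling permutes per-node metrics and keeps the means", {
  set.seed(7)
  w <- random_weighted_graph(6, 0.8)
  p <- sample(6)
  wp <- w[p, p]
  expect_equal(clustering_coefficient(wp)$per_node,
               clustering_coefficient(w)$per_node[p])
  expect_equal(local_efficiency(wp)$mean, local_efficiency(w)$mean)
  expect_equal(global_efficiency(wp), global_efficiency(w))
})

test_that("global efficiency is monotone non-decreasing in sparsity", {
  set.seed(3)
  m <- matrix(runif(30 * 30), 30, 30); m <- (m + t(m)) / 2; diag(m) <- 1
  eg <- vapply(seq(0.05, 0.5, by = 0.05), function(s)
    global_efficiency(proportional_threshold(m, s)), numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("surrogate normalization behaves like its null model", {
  set.seed(11)
  ## dense random graph: its own rewired ensemble is statistically identical
  m <- matrix(runif(24 * 24, 0.3, 1), 24, 24); m <- (m + t(m)) / 2; diag(m) <- 0
  tg <- proportional_threshold(m, 0.4)
  nv <- normalize_vs_random(tg, n_null = 10, seed = 5)
  expect_lt(abs(nv$normalized_L - 1), 0.1)
  ## ring lattice clusters far above its random null
  lat <- matrix(0, 16, 16)
  for (i in 1:16) for (k in 1:2) {
    j <- (i + k - 1) %% 16 + 1
    lat[i, j] <- lat[j, i] <- 1
  }
  tg_lat <- structure(list(weights = lat, sparsity = 0.27, connected = TRUE),
                      class = "thresholded_graph")
  expect_gt(normalize_vs_random(tg_lat, n_null = 10, seed = 2)$normalized_C, 1)
  ## fixed seed reproduces the surrogates exactly
  expect_identical(normalize_vs_random(tg, n_null = 5, seed = 9),
                   normalize_vs_random(tg, n_null = 5, seed = 9))
})

## independent scan oracle: sort edges, take top round(s * E), check
## connectivity of the retained edge list with igraph
min_sparsity_oracle <- function(m, grid = seq(0.05, 0.5, by = 0.05)) {
  n <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ord <- order(m[idx], decreasing = TRUE)
  for (s in grid) {
    k <- round(s * n * (n - 1) / 2)
    el <- idx[ord[seq_len(k)], , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (igraph::is_connected(g)) return(s)
  }
  NA_real_
}

test_that("minimum connected sparsity matches a brute-force scan", {
  set.seed(13)
  ## hub-anchored weights: every node has one strong edge to node 1, so the
  ## top 5% of the 68-node matrix already spans all nodes
  n <- 68
  m <- matrix(runif(n * n, 0.1, 0.5), n, n); m <- (m + t(m)) / 2
  m[1, 2:n] <- m[2:n, 1] <- 0.9
  diag(m) <- 1
  expect_equal(minimum_connected_sparsity(m), 0.05)
  expect_equal(min_sparsity_oracle(m), 0.05)
  ## one near-isolated node forces a higher threshold; agree with the oracle
  weak <- m
  weak[n, 1:(n - 1)] <- weak[1:(n - 1), n] <- runif(n - 1, 0.38, 0.40)
  got <- minimum_connected_sparsity(weak)
  expect_equal(got, min_sparsity_oracle(weak))
  expect_gt(got, 0.05)
  ## spanning-tree-only structure: connects when the tree's weakest edge
  ## enters the retained set (union-find style oracle)
  nt <- 10
  tree <- matrix(0.05, nt, nt)
  for (i in 2:nt) tree[i - 1, i] <- tree[i, i - 1] <- runif(1, 0.8, 0.9)
  diag(tree) <- 1
  expect_equal(minimum_connected_sparsity(tree), min_sparsity_oracle(tree))
  expect_equal(minimum_connected_sparsity(tree), 0.2)   # 9 of 45 edges
})

test_that("the sparsity sweep emits one row per metric and grid point", {
  set.seed(15)
  m <- matrix(runif(16 * 16, 0.2, 1), 16, 16); m <- (m + t(m)) / 2; diag(m) <- 1
  sw <- graph_metric_sweep(m)
  expect_equal(nrow(sw), 10 * 4)
  expect_setequal(unique(sw$metric), c("L", "Eglob", "C", "Eloc"))
})
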