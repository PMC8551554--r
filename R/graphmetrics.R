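#' Proportional (density) threshold of a weighted connectivity matrix
#'
#' Retains the `k = round(sparsity * n(n-1)/2)` strongest off-diagonal
#' weights of a symmetric matrix and zeroes the rest (weights are retained,
#' not binarized). Ties at the cutoff are broken by stable (row, column)
#' lexicographic order.
#'
#' @param cm A `connectivity_matrix` or symmetric numeric matrix.
#' @param sparsity Fraction of edges to keep, in `(0, 1]`.
#' @return Object of class `thresholded_graph`: `weights` (zero where
#'   pruned, zero diagonal), `sparsity`, and logical `connected`.
#' @export
proportional_threshold <- function(cm, sparsity) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(w)
  if (!isSymmetric(unname(w), tol = 1e-10)) stop("matrix must be symmetric")
  diag(w) <- 0
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]  # (row, col) lexicographic
  ## order() is stable, so ties at the cutoff resolve in (row, col) order
  vals <- w[ut]
  k <- round(sparsity * n * (n - 1) / 2)
  keep_idx <- order(vals, decreasing = TRUE)[seq_len(k)]
  out <- matrix(0, n, n)
  sel <- ut[keep_idx, , drop = FALSE]
  out[sel] <- w[sel]
  out <- out + t(out)
  dimnames(out) <- dimnames(w)
  g <- igraph::graph_from_adjacency_matrix(out > 0, mode = "undirected")
  structure(list(weights = out, sparsity = sparsity,
                 connected = igraph::is_connected(g)),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (sparsity %.2f), %sconnected\n",
              nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
              x$sparsity, if (x$connected) "" else "NOT "))
  invisible(x)
}

## internal: igraph with distances 1/w on the retained edges
as_distance_graph <- function(g) {
  w <- if (inherits(g, "thresholded_graph")) g$weights else as.matrix(g)
  diag(w) <- 0
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  igraph::E(ig)$distance <- 1 / igraph::E(ig)$weight
  ig
}

shortest_distances <- function(g) {
  ig <- as_distance_graph(g)
  if (igraph::vcount(ig) == 0) return(matrix(0, 0, 0))
  igraph::distances(ig, weights = igraph::E(ig)$distance)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all node pairs, with edge distances
#' `d = 1/w`. Defined only for connected graphs.
#'
#' @param g A `thresholded_graph` (or symmetric weight matrix).
#' @return Scalar `L`.
#' @export
characteristic_path_length <- function(g) {
  d <- shortest_distances(g)
  if (any(is.infinite(d)))
    stop("graph is disconnected; characteristic path length undefined ",
         "(respect the minimum connected sparsity, see minimum_connected_sparsity)")
  n <- nrow(d)
  sum(d) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over all node pairs (the
#' Latora-Marchiori form); unreachable pairs contribute 0, so disconnection
#' is handled gracefully. `inverse_of_L = TRUE` instead returns the literal
#' reciprocal of the characteristic path length.
#'
#' @param g A `thresholded_graph` (or symmetric weight matrix).
#' @param inverse_of_L Use `1/L` instead of the mean of inverse distances.
#' @return Scalar efficiency in `[0, 1]` for weights in `[0, 1]`.
#' @export
global_efficiency <- function(g, inverse_of_L = FALSE) {
  if (inverse_of_L) return(1 / characteristic_path_length(g))
  d <- shortest_distances(g)
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted clustering coefficient (Onnela)
#'
#' `C_i = (1/(k_i (k_i - 1))) * sum_{j,h} (w~_ij w~_jh w~_ih)^(1/3)` with
#' weights normalized by the largest weight in the graph; `C_i = 0` for
#' degree < 2. Reduces to the binary clustering coefficient when all retained
#' weights are equal.
#'
#' @param g A `thresholded_graph` (or symmetric weight matrix).
#' @return List: `per_node` vector and `mean`.
#' @export
clustering_coefficient <- function(g) {
  w <- if (inherits(g, "thresholded_graph")) g$weights else as.matrix(g)
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) return(list(per_node = rep(0, nrow(w)), mean = 0))
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wh %*% wh %*% wh)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  list(per_node = as.numeric(cc), mean = mean(cc))
}

#' Local efficiency
#'
#' For each node, the [global_efficiency] of the subgraph induced on its
#' neighbors (the node itself removed); 0 for degree < 2.
#'
#' @param g A `thresholded_graph` (or symmetric weight matrix).
#' @return List: `per_node` vector and `mean`.
#' @export
local_efficiency <- function(g) {
  w <- if (inherits(g, "thresholded_graph")) g$weights else as.matrix(g)
  diag(w) <- 0
  n <- nrow(w)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    eloc[i] <- global_efficiency(w[nb, nb, drop = FALSE])
  }
  list(per_node = eloc, mean = mean(eloc))
}

#' Normalize path length and clustering against degree-preserving surrogates
#'
#' Divides the graph's characteristic path length and mean clustering
#' coefficient by their means over `n_null` Maslov-Sneppen rewired surrogates
#' (degree sequence preserved; the original weights are shuffled onto the
#' rewired topology). Surrogates that come out disconnected are re-drawn up
#' to a retry budget and skipped (with a warning) if that fails.
#'
#' @param g A connected `thresholded_graph`.
#' @param n_rewires Edge-swap multiplier: each surrogate uses
#'   `n_rewires * |E|` swap attempts (default 10).
#' @param n_null Number of surrogates (default 20).
#' @param seed Integer seed; fixed seed gives identical surrogates.
#' @return List: `normalized_L`, `normalized_C`, and the surrogate means
#'   `null_L`, `null_C`.
#' @export
normalize_vs_random <- function(g, n_rewires = 10, n_null = 20, seed = 1) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (!g$connected) stop("normalization requires a connected graph")
  L <- characteristic_path_length(g)
  C <- clustering_coefficient(g)$mean
  w <- g$weights
  ig <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  wvals <- w[upper.tri(w) & w > 0]
  nulls <- with_seed(derive_seed(seed, "null-model"), {
    out <- list()
    for (r in seq_len(n_null)) {
      surro <- NULL
      for (try in 1:10) {
        rg <- igraph::rewire(ig, igraph::keeping_degseq(
          niter = n_rewires * igraph::ecount(ig)))
        if (igraph::is_connected(rg)) { surro <- rg; break }
      }
      if (is.null(surro)) { warning("disconnected surrogate skipped"); next }
      a <- igraph::as_adjacency_matrix(surro, sparse = FALSE)
      idx <- which(upper.tri(a) & a > 0)
      wm <- matrix(0, nrow(a), ncol(a))
      wm[idx] <- sample(wvals, length(idx))
      wm <- wm + t(wm)
      out[[length(out) + 1L]] <- c(L = characteristic_path_length(wm),
                                   C = clustering_coefficient(wm)$mean)
    }
    out
  })
  if (!length(nulls)) stop("no connected surrogate could be generated")
  nm <- do.call(rbind, nulls)
  list(normalized_L = L / mean(nm[, "L"]), normalized_C = C / mean(nm[, "C"]),
       null_L = mean(nm[, "L"]), null_C = mean(nm[, "C"]))
}

#' Minimum sparsity at which the thresholded graph is connected
#'
#' Scans the sparsity grid and returns the smallest value whose
#' proportionally thresholded graph is connected (binary connectivity on
#' retained edges).
#'
#' @param cm Connectivity matrix (object or plain symmetric matrix).
#' @param grid Sparsity grid (default `seq(0.05, 0.5, by = 0.05)`, extended
#'   by 1 as a last resort check).
#' @return Smallest connected grid sparsity.
#' @export
minimum_connected_sparsity <- function(cm, grid = seq(0.05, 0.5, by = 0.05)) {
  for (s in grid) {
    if (proportional_threshold(cm, s)$connected) return(s)
  }
  if (proportional_threshold(cm, 1)$connected)
    stop("graph connects only above the sparsity grid (sparsity > ",
         max(grid), ")")
  stop("graph is disconnected even at sparsity 1")
}

#' Global graph metrics across a sparsity sweep
#'
#' Computes the four global metrics (characteristic path length, global
#' efficiency, mean clustering coefficient, mean local efficiency) for each
#' sparsity in the grid. Path length is `NA` where the thresholded graph is
#' disconnected. With `normalize = TRUE`, `L` and `C` are additionally
#' normalized against degree-preserving surrogates.
#'
#' @param cm Connectivity matrix (object or plain symmetric matrix).
#' @param grid Sparsity grid (default 0.05 to 0.5, step 0.05).
#' @param normalize Add `normalized_L` / `normalized_C` columns (slower).
#' @param seed Seed for the surrogate null model.
#' @return Long-format data frame: sparsity, metric, value.
#' @export
graph_metric_sweep <- function(cm, grid = seq(0.05, 0.5, by = 0.05),
                               normalize = FALSE, seed = 1) {
  rows <- list()
  for (s in grid) {
    tg <- proportional_threshold(cm, s)
    L <- if (tg$connected) characteristic_path_length(tg) else NA_real_
    vals <- c(L = L,
              Eglob = global_efficiency(tg),
              C = clustering_coefficient(tg)$mean,
              Eloc = local_efficiency(tg)$mean)
    if (normalize && tg$connected) {
      nv <- normalize_vs_random(tg, seed = derive_seed(seed, paste0("sw", s)))
      vals <- c(vals, normalized_L = nv$normalized_L,
                normalized_C = nv$normalized_C)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sparsity = s, metric = names(vals), value = as.numeric(vals),
      row.names = NULL)
  }
  do.call(rbind, rows)
}
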