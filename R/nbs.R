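#' Network-based statistic (NBS)
#'
#' Permutation-based familywise-error control for edgewise group contrasts on
#' connectivity matrices. The procedure: (1) an edgewise t statistic on every
#' unordered node pair; (2) a primary one-sided threshold at edge-level
#' p < `edge_alpha` (Student t quantile at the test's degrees of freedom),
#' applied separately for the `a > b` ("increase") and `a < b` ("decrease")
#' contrasts; (3) connected components of each supra-threshold edge graph;
#' (4) component statistic: intensity (summed supra-threshold t, default) or
#' extent (edge count); (5) group labels permuted (or signs flipped, paired
#' design) with the maximal component statistic recorded per permutation;
#' (6) component `p = (1 + #(max* >= stat)) / (1 + n_perm)`.
#'
#' @param group_a,group_b Lists of `connectivity_matrix` objects (or plain
#'   symmetric matrices, or a 3-d array subjects x nodes x nodes). Paired
#'   designs require equal counts with aligned subjects.
#' @param spec A [stat_spec]; `paired`, `edge_alpha`, `component_alpha`,
#'   `n_perm_nbs`, `component_stat` and `seed` are honoured.
#' @return List with elements `increase` and `decrease`, each an `nbs_result`
#'   with `components` (list of edge index matrices), `node_sets`, `extents`,
#'   `stats`, `p_values`, `observed_t` (full symmetric matrix), `threshold`
#'   and `significant` (mask at `component_alpha`).
#' @export
nbs <- function(group_a, group_b, spec = stat_spec()) {
  Xa <- stack_edges(group_a)
  Xb <- stack_edges(group_b)
  if (Xa$n_nodes != Xb$n_nodes) stop("node-count mismatch between groups")
  n_nodes <- Xa$n_nodes
  E <- ncol(Xa$edges)
  ei <- Xa$idx[, 1]; ej <- Xa$idx[, 2]
  na <- nrow(Xa$edges); nb <- nrow(Xb$edges)
  if (spec$paired && na != nb) stop("paired NBS requires equal group sizes")
  df <- if (spec$paired) na - 1 else na + nb - 2
  if (df < 1) stop("not enough subjects for an edgewise t test")
  thr <- stats::qt(1 - spec$edge_alpha, df)
  use_intensity <- spec$component_stat == "intensity"

  ## observed edgewise t
  t_obs <- if (spec$paired) paired_t_edges(Xa$edges - Xb$edges) else
    indep_t_edges(Xa$edges, Xb$edges)
  t_obs[!is.finite(t_obs)] <- 0

  ## permutation null of the max component statistic, per direction
  n_perm <- spec$n_perm_nbs
  max_inc <- numeric(n_perm); max_dec <- numeric(n_perm)
  block <- 500L
  done <- 0L
  with_seed(derive_seed(spec$seed, "nbs"), {
    while (done < n_perm) {
      p_blk <- min(block, n_perm - done)
      if (spec$paired) {
        S <- matrix(sample(c(-1, 1), na * p_blk, replace = TRUE), na, p_blk)
        Tm <- paired_t_perm(Xa$edges - Xb$edges, S)
      } else {
        M <- matrix(0, na + nb, p_blk)
        for (p in seq_len(p_blk)) M[sample.int(na + nb, na), p] <- 1
        Tm <- indep_t_perm(rbind(Xa$edges, Xb$edges), M, na, nb)
      }
      Tm[!is.finite(Tm)] <- 0
      for (p in seq_len(p_blk)) {
        tv <- Tm[, p]
        max_inc[done + p] <- max_comp_stat(tv, thr, ei, ej, n_nodes, use_intensity)
        max_dec[done + p] <- max_comp_stat(-tv, thr, ei, ej, n_nodes, use_intensity)
      }
      done <- done + p_blk
    }
  })

  build <- function(tv, max_null, direction) {
    sup <- which(tv > thr)
    comps <- list(); nodes <- list(); extents <- integer(); stats_ <- numeric()
    if (length(sup)) {
      g <- igraph::graph_from_edgelist(cbind(ei[sup], ej[sup]), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
      memb <- igraph::components(g)$membership
      ecomp <- memb[ei[sup]]
      for (cid in unique(ecomp)) {
        rows <- sup[ecomp == cid]
        comps[[length(comps) + 1L]] <- cbind(i = ei[rows], j = ej[rows])
        nodes[[length(nodes) + 1L]] <- sort(unique(c(ei[rows], ej[rows])))
        extents <- c(extents, length(rows))
        stats_ <- c(stats_, if (use_intensity) sum(tv[rows]) else length(rows))
      }
    }
    pv <- vapply(stats_, function(s)
      (1 + sum(max_null >= s)) / (1 + n_perm), numeric(1))
    tm <- matrix(0, n_nodes, n_nodes)
    tm[Xa$idx] <- tv; tm <- tm + t(tm)
    structure(list(direction = direction, components = comps,
                   node_sets = nodes, extents = extents, stats = stats_,
                   p_values = pv, significant = pv < spec$component_alpha,
                   observed_t = tm, threshold = thr, n_perm = n_perm),
              class = "nbs_result")
  }
  list(increase = build(t_obs, max_inc, "increase"),
       decrease = build(-t_obs, max_dec, "decrease"))
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s: %d supra-threshold component(s) (t > %.3f)\n",
              x$direction, length(x$components), x$threshold))
  if (length(x$extents))
    for (k in seq_along(x$extents))
      cat(sprintf("  component %d: %d edges, %d nodes, p = %.4g%s\n", k,
                  x$extents[k], length(x$node_sets[[k]]), x$p_values[k],
                  if (x$significant[k]) " *" else ""))
  invisible(x)
}

## ---- internals -------------------------------------------------------------

## subjects x edges matrix from a list/array of symmetric matrices
stack_edges <- function(group) {
  mats <- if (is.array(group) && length(dim(group)) == 3L)
    lapply(seq_len(dim(group)[1]), function(s) group[s, , ]) else
      lapply(group, function(m)
        if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m))
  n <- nrow(mats[[1]])
  idx <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  edges <- t(vapply(mats, function(m) {
    if (nrow(m) != n) stop("node-count mismatch within a group")
    m[idx]
  }, numeric(nrow(idx))))
  list(edges = edges, idx = idx, n_nodes = n)
}

indep_t_edges <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (colMeans(A) - colMeans(B)) / sqrt(sp2 * (1 / na + 1 / nb))
}

paired_t_edges <- function(D) {
  n <- nrow(D)
  colMeans(D) / (apply(D, 2, stats::sd) / sqrt(n))
}

## edges x perms t matrix for independent label permutations; M is a
## (na+nb) x perms 0/1 membership matrix for group A
indep_t_perm <- function(X, M, na, nb) {
  tX <- t(X)                       # E x n
  tX2 <- tX^2
  sum_a <- tX %*% M                # E x P
  sq_a <- tX2 %*% M
  tot <- rowSums(tX); sqtot <- rowSums(tX2)
  mean_a <- sum_a / na
  mean_b <- (tot - sum_a) / nb
  ss_a <- sq_a - na * mean_a^2
  ss_b <- (sqtot - sq_a) - nb * mean_b^2
  sp2 <- (ss_a + ss_b) / (na + nb - 2)
  (mean_a - mean_b) / sqrt(sp2 * (1 / na + 1 / nb))
}

## edges x perms t matrix for paired sign flips; S is n x perms of +-1
paired_t_perm <- function(D, S) {
  n <- nrow(D)
  tD <- t(D)                       # E x n
  m <- (tD %*% S) / n              # E x P
  sq <- rowSums(tD^2)
  s2 <- (sq - n * m^2) / (n - 1)
  m / sqrt(s2 / n)
}

## max component statistic among supra-threshold edges (t > thr)
max_comp_stat <- function(tv, thr, ei, ej, n_nodes, use_intensity) {
  sup <- which(tv > thr)
  if (!length(sup)) return(0)
  if (use_intensity)
    max_component_weight(ei[sup], ej[sup], n_nodes, tv[sup])
  else
    max_component_extent(ei[sup], ej[sup], n_nodes)
}
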