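#' Statistical specification for group analyses
#'
#' Collects the permutation counts, thresholds and seed used by the group
#' statistics: 1,000 randomizations for the spectral permutation tests, and
#' for the network-based statistic an edge-level p of 0.05, a component-level
#' p of 0.01 and 5,000 permutations; FDR q = 0.05 for the global graph
#' metrics.
#'
#' @param n_perm_psd Permutations for [permutation_test] (default 1000).
#' @param n_perm_nbs Permutations for [nbs] (default 5000).
#' @param edge_alpha One-sided edge-level p threshold for NBS (default 0.05).
#' @param component_alpha Component-level significance for NBS (default 0.01).
#' @param fdr_q FDR level for graph-metric tests (default 0.05).
#' @param paired Paired design (sign-flip permutations) or independent.
#' @param component_stat NBS component statistic: `"intensity"` (summed
#'   supra-threshold t, default) or `"extent"` (edge count). At the liberal
#'   edge threshold of p = 0.05 the supra-threshold noise graph percolates on
#'   dense networks, which makes extent insensitive to compact effects;
#'   intensity remains sensitive because genuine edges carry far larger t.
#' @param seed Integer seed.
#' @return Object of class `stat_spec`.
#' @export
stat_spec <- function(n_perm_psd = 1000, n_perm_nbs = 5000, edge_alpha = 0.05,
                      component_alpha = 0.01, fdr_q = 0.05, paired = FALSE,
                      component_stat = c("intensity", "extent"), seed = 1) {
  if (n_perm_psd < 100 || n_perm_nbs < 100) stop("permutation counts must be >= 100")
  for (a in c(edge_alpha, component_alpha, fdr_q))
    if (a <= 0 || a >= 1) stop("alpha levels must be in (0, 1)")
  structure(list(n_perm_psd = n_perm_psd, n_perm_nbs = n_perm_nbs,
                 edge_alpha = edge_alpha, component_alpha = component_alpha,
                 fdr_q = fdr_q, paired = paired,
                 component_stat = match.arg(component_stat),
                 seed = as.integer(seed)),
            class = "stat_spec")
}

#' Non-parametric permutation test for a group difference
#'
#' Two-sided permutation test on the difference of group means (independent)
#' or the mean of paired differences (paired). The null distribution is built
#' by label shuffling (independent) or random sign flips (paired);
#' `p = (1 + #(|T*| >= |T|)) / (1 + n_perm)`, so the attainable minimum is
#' `1/(n_perm + 1)` and p is never 0.
#'
#' @param a,b Numeric sample vectors (paired: equal length).
#' @param paired Use sign-flip permutations of the paired differences.
#' @param n_perm Number of random permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `p`, observed `statistic`, `n_perm`.
#' @export
permutation_test <- function(a, b, paired = FALSE, n_perm = 1000, seed = 1) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations per group")
  if (paired && length(a) != length(b)) stop("paired test requires equal lengths")
  with_seed(derive_seed(seed, "perm-test"), {
    if (paired) {
      d <- a - b
      n <- length(d)
      obs <- mean(d)
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
      null <- colMeans(d * signs)
    } else {
      x <- c(a, b)
      na <- length(a)
      obs <- mean(a) - mean(b)
      tot <- sum(x)
      idx <- replicate(n_perm, sample.int(length(x), na))
      sums_a <- colSums(matrix(x[idx], na, n_perm))
      null <- sums_a / na - (tot - sums_a) / length(b)
    }
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
    list(p = p, statistic = obs, n_perm = n_perm)
  })
}

#' Student t statistic for a group difference
#'
#' Pooled-variance two-sample t (independent) or one-sample t on the paired
#' differences. Errors when there is no variance to test against.
#'
#' @param a,b Numeric sample vectors.
#' @param paired Paired design.
#' @return Scalar t statistic (sign follows `mean(a) - mean(b)`).
#' @export
t_statistic <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 observations per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) stop("zero variance: paired differences are constant")
    return(mean(d) / (s / sqrt(length(d))))
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both groups")
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure: reject all p-values up to the largest k with
#' `p(k) <= k q / m`. Implemented via `stats::p.adjust(..., "BH")`, whose
#' adjusted values are below `q` exactly for the step-up rejection set.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask aligned with `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Edge-count summary across frequency bands
#'
#' Summarizes, per contrast direction, the per-band counts of significant
#' edges: mean and sample standard deviation across bands, plus a two-sided
#' Welch t-test comparing the increased-edge counts against the
#' decreased-edge counts.
#'
#' @param counts Data frame with columns `band`, `direction` (`"increase"` /
#'   `"decrease"`) and `edges` (and optionally `nodes`). Build it from NBS
#'   results with [nbs_edge_table()], or supply counts directly.
#' @return List: `by_direction` data frame (direction, mean, sd, n_bands) and
#'   `welch` (htest comparing increase vs decrease counts).
#' @export
edge_count_summary <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("band", "direction", "edges") %in% names(counts)))
  if (length(unique(counts$band)) < 2) stop("need counts for at least 2 bands")
  agg <- do.call(rbind, lapply(split(counts, counts$direction), function(d)
    data.frame(direction = d$direction[1], mean = mean(d$edges),
               sd = stats::sd(d$edges), n_bands = nrow(d))))
  rownames(agg) <- NULL
  inc <- counts$edges[counts$direction == "increase"]
  dec <- counts$edges[counts$direction == "decrease"]
  welch <- if (length(inc) >= 2 && length(dec) >= 2)
    tryCatch(stats::t.test(inc, dec), error = function(e) NULL) else NULL
  list(by_direction = agg, welch = welch)
}

#' Edge/node counts per band from NBS results
#'
#' @param nbs_by_band Named list (band -> result of [nbs()]).
#' @param alpha Component significance level (default 0.01): only components
#'   with `p < alpha` contribute edges.
#' @return Data frame: band, direction, edges, nodes.
#' @export
nbs_edge_table <- function(nbs_by_band, alpha = 0.01) {
  rows <- list()
  for (bn in names(nbs_by_band)) {
    res <- nbs_by_band[[bn]]
    for (dir in c("increase", "decrease")) {
      r <- res[[dir]]
      sig <- which(r$p_values < alpha)
      edges <- if (length(sig)) do.call(rbind, r$components[sig]) else
        matrix(integer(), 0, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        band = bn, direction = dir, edges = nrow(edges),
        nodes = length(unique(as.vector(edges))))
    }
  }
  do.call(rbind, rows)
}

#' UPDRS-III improvement rate
#'
#' `(mean_off - mean_on) / mean_off`: fractional improvement of the motor
#' score between stimulation-OFF and stimulation-ON.
#'
#' @param mean_off Mean score in the OFF condition (> 0).
#' @param mean_on Mean score in the ON condition.
#' @return Improvement fraction.
#' @export
updrs_improvement <- function(mean_off, mean_on) {
  if (mean_off <= 0) stop("baseline (OFF) score must be positive")
  (mean_off - mean_on) / mean_off
}

#' Group tests of global graph metrics across the sparsity grid
#'
#' For each band, metric and sparsity grid point, computes the group t
#' statistic and p-value (independent pooled t or paired t), then applies
#' Benjamini-Hochberg FDR across the grid-point x metric family within each
#' band.
#'
#' @param metrics_a,metrics_b Data frames from [graph_metric_sweep] rows
#'   bound per subject, with columns `subject`, `band`, `sparsity`, `metric`,
#'   `value`.
#' @param paired Paired design.
#' @param q FDR level (default 0.05).
#' @return Data frame: band, sparsity, metric, t, p, significant.
#' @export
graph_metric_group_test <- function(metrics_a, metrics_b, paired = FALSE,
                                    q = 0.05) {
  key <- function(d) interaction(d$band, d$sparsity, d$metric, drop = TRUE)
  rows <- list()
  for (k in levels(key(metrics_a))) {
    da <- metrics_a[key(metrics_a) == k, ]
    db <- metrics_b[key(metrics_b) == k, ]
    if (!nrow(da) || !nrow(db) || anyNA(da$value) || anyNA(db$value)) next
    tt <- tryCatch(t_statistic(da$value, db$value, paired = paired),
                   error = function(e) NA_real_)
    df <- if (paired) nrow(da) - 1 else nrow(da) + nrow(db) - 2
    rows[[length(rows) + 1L]] <- data.frame(
      band = da$band[1], sparsity = da$sparsity[1], metric = da$metric[1],
      t = tt, p = if (is.na(tt)) NA else 2 * stats::pt(-abs(tt), df))
  }
  out <- do.call(rbind, rows)
  out$significant <- FALSE
  for (bn in unique(out$band)) {
    i <- which(out$band == bn & !is.na(out$p))
    if (length(i)) out$significant[i] <- fdr_bh(out$p[i], q)
  }
  out
}
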