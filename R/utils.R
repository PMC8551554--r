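## Internal numerical helpers shared across modules.

## Deterministic substream seed derived from a master seed and a string key.
## Linear congruential mix over the key bytes; result always in [1, 2^31 - 2]
## so it is a valid R integer seed.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- as.double(seed %% m)
  for (b in utf8ToInt(as.character(key))) h <- (h * 48271 + b + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

## evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## stationary AR(1) with unit marginal variance and correlation time tau (s)
ar1_process <- function(n, fs, tau) {
  a <- exp(-1 / (fs * tau))
  as.numeric(stats::filter(stats::rnorm(n) * sqrt(1 - a^2), a,
                           method = "recursive", init = stats::rnorm(1)))
}

## trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## union-find max component extent (edge count) for an edge list on n nodes;
## hot path of the network-based statistic, so kept allocation-free
max_component_extent <- function(ei, ej, n) {
  m <- length(ei)
  if (m == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, integer(1))
  max(tabulate(roots, nbins = n))
}

## like max_component_extent but maximizing the summed edge weight
max_component_weight <- function(ei, ej, n, wt) {
  m <- length(ei)
  if (m == 0L) return(0)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find, integer(1))
  acc <- numeric(n)
  for (k in seq_len(m)) acc[roots[k]] <- acc[roots[k]] + wt[k]
  max(acc)
}
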