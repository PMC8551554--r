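## Independent oracles used to validate the implementation. These are written
## from the textbook definitions (series expansions, exhaustive enumeration,
## Floyd-Warshall) and never call the package's own code paths.

## modified Bessel function of the first kind via its power series
bessel_i_series <- function(x, nu, terms = 60) {
  m <- 0:(terms - 1)
  sum((x / 2)^(2 * m + nu) / (factorial(m) * gamma(m + nu + 1)))
}

bessel_ratio_oracle <- function(kappa) {
  bessel_i_series(kappa, 1) / bessel_i_series(kappa, 0)
}

## all-pairs shortest paths by Floyd-Warshall on distances d = 1/w
floyd_warshall_oracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

path_length_oracle <- function(w) {
  d <- floyd_warshall_oracle(w)
  n <- nrow(d)
  mean(d[row(d) != col(d)])
}

global_efficiency_oracle <- function(w) {
  d <- floyd_warshall_oracle(w)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

## Onnela weighted clustering by explicit enumeration over node triples
clustering_oracle <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  cc <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j == i || h == i || j == h) next
      s <- s + (wh[i, j] * wh[j, h] * wh[i, h])^(1 / 3)
    }
    cc[i] <- s / (k * (k - 1))
  }
  cc
}

local_efficiency_oracle <- function(w) {
  n <- nrow(w)
  e <- numeric(n)
  for (i in 1:n) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- global_efficiency_oracle(w[nb, nb, drop = FALSE])
  }
  e
}

## random symmetric weighted graph on n nodes with given edge probability
random_weighted_graph <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < p_edge]
  w[on] <- runif(length(on), 0.1, 1)
  w + t(w)
}

## quick single-subject source simulation used by several tests
tiny_sources <- function(n_regions = 6, fs = 250, duration = 12, seed = 1, ...) {
  simulate_coupled_sources(
    simulation_spec(n_regions = n_regions, fs = fs, duration = duration,
                    seed = seed, ...))
}
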