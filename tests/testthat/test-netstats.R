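test_that("permutation test hits its boundary cases", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(permutation_test(a, a)$p, 1)            # identical groups
  ## complete separation: the observed statistic is maximal
  set.seed(1)
  x <- rnorm(10, 10, 0.1); y <- rnorm(10, 0, 0.1)
  expect_equal(permutation_test(x, y, n_perm = 1000)$p, 1 / 1001)
  ## paired: only 2^10 distinct sign patterns, so the identity pattern
  ## recurs among the draws; p still lands at the attainable floor
  expect_lt(permutation_test(x, y, paired = TRUE, n_perm = 1000)$p, 0.01)
  expect_error(permutation_test(1, c(1, 2)), "at least 2")
  expect_error(permutation_test(1:3, 1:4, paired = TRUE), "equal lengths")
  ## deterministic under a fixed seed
  u <- rnorm(8); v <- rnorm(8)
  expect_identical(permutation_test(u, v, seed = 3),
                   permutation_test(u, v, seed = 3))
})

test_that("t statistic matches the pooled formula and stats::t.test", {
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)), -3.674, tolerance = 1e-3)
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)),
               unname(stats::t.test(c(1, 2, 3), c(4, 5, 6),
                                    var.equal = TRUE)$statistic))
  set.seed(2)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(t_statistic(a, b, paired = TRUE),
               unname(stats::t.test(a, b, paired = TRUE)$statistic))
  expect_equal(t_statistic(c(1, 2, 3), c(0, 2, 4)), 0)
  expect_error(t_statistic(c(1, 2), c(2, 3), paired = TRUE), "zero variance")
  expect_error(t_statistic(c(1, 1), c(2, 2)), "zero variance")
})

test_that("BH step-up reproduces the hand-enumerated rejection sets", {
  expect_true(all(fdr_bh(rep(0.001, 40), 0.05)))
  ## {0.01, 0.02, 0.03, 0.04}: k* = 4 since 0.04 <= 4*0.05/4
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  ## {0.04, 0.9, 0.9, 0.9}: 0.04 > 1*0.05/4 so nothing is rejected
  expect_equal(fdr_bh(c(0.04, 0.9, 0.9, 0.9), 0.05), rep(FALSE, 4))
  ## monotone: lowering q never adds rejections
  set.seed(3)
  p <- runif(50)^2
  expect_true(all(fdr_bh(p, 0.01) <= fdr_bh(p, 0.10)))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("NBS finds nothing when the groups are identical", {
  set.seed(4)
  mats <- lapply(1:6, function(i) {
    m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 1; m
  })
  res <- nbs(mats, mats, stat_spec(n_perm_nbs = 200, seed = 1))
  expect_length(res$increase$components, 0)
  expect_length(res$decrease$components, 0)
  resp <- nbs(mats, mats, stat_spec(n_perm_nbs = 200, paired = TRUE, seed = 1))
  expect_length(resp$increase$components, 0)
  ## p floors at 1/(n_perm+1); a vanishing edge threshold empties the result
  expect_error(nbs(mats[1:2], mats, stat_spec(n_perm_nbs = 200, paired = TRUE)),
               "equal group sizes")
  expect_error(nbs(mats, lapply(mats, function(m) m[1:9, 1:9])), "mismatch")
})

test_that("NBS recovers a planted clique difference with FWER-calibrated p", {
  ## effect +0.2 (PLV scale) on a 10-edge clique, within-group SD 0.05
  set.seed(10)
  nodes <- c(3, 10, 17, 24, 31)
  pl <- t(utils::combn(nodes, 2))
  successes <- 0
  for (rep in 1:5) {
    mk <- function(eff) {
      m <- matrix(rnorm(68^2, 0.3, 0.05), 68, 68); m <- (m + t(m)) / 2
      for (k in seq_len(nrow(pl))) {
        m[pl[k, 1], pl[k, 2]] <- m[pl[k, 1], pl[k, 2]] + eff
        m[pl[k, 2], pl[k, 1]] <- m[pl[k, 1], pl[k, 2]]
      }
      diag(m) <- 1; m
    }
    ga <- lapply(1:15, function(i) mk(0.2))
    gb <- lapply(1:15, function(i) mk(0))
    r <- nbs(ga, gb, stat_spec(n_perm_nbs = 1000, seed = rep))$increase
    best <- which.max(r$stats)
    comp <- r$components[[best]]
    found <- sum(apply(pl, 1, function(e)
      any((comp[, 1] == e[1] & comp[, 2] == e[2]) |
            (comp[, 1] == e[2] & comp[, 2] == e[1]))))
    successes <- successes + (found >= 9 && r$p_values[best] < 0.01)
  }
  expect_gte(successes, 4)
})

test_that("edge-count summaries reproduce the reported band statistics", {
  counts <- data.frame(
    band = rep(c("theta", "alpha", "beta1", "beta2"), 2),
    direction = rep(c("decrease", "increase"), each = 4),
    edges = c(85, 88, 112, 84, 207, 91, 156, 168))
  s <- edge_count_summary(counts)
  dec <- s$by_direction[s$by_direction$direction == "decrease", ]
  inc <- s$by_direction[s$by_direction$direction == "increase", ]
  expect_equal(round(dec$mean, 2), 92.25)
  expect_equal(round(dec$sd, 2), 13.28)
  expect_equal(round(inc$mean, 2), 155.50)
  expect_equal(round(inc$sd, 2), 48.20)
  expect_s3_class(s$welch, "htest")
  ## identical counts across bands collapse the SD to zero
  same <- data.frame(band = c("a", "b"), direction = "decrease", edges = c(7, 7))
  expect_equal(edge_count_summary(rbind(same,
    data.frame(band = c("a", "b"), direction = "increase",
               edges = c(9, 9))))$by_direction$sd, c(0, 0))
})

test_that("UPDRS improvement rate is the relative OFF-ON drop", {
  expect_equal(round(updrs_improvement(46.5, 17.1), 2), 0.63)
  expect_equal(updrs_improvement(40, 40), 0)
  expect_equal(updrs_improvement(40, 0), 1)
  expect_error(updrs_improvement(0, 1), "positive")
})

test_that("graph-metric group tests flag a shifted metric after FDR", {
  set.seed(6)
  mk <- function(shift) do.call(rbind, lapply(1:10, function(s)
    data.frame(subject = s, band = "alpha",
               sparsity = rep(seq(0.1, 0.5, by = 0.1), 2),
               metric = rep(c("C", "L"), each = 5),
               value = c(rnorm(5, 1 + shift, 0.05), rnorm(5, 3, 0.05)))))
  res <- graph_metric_group_test(mk(0.5), mk(0))
  expect_true(all(res$significant[res$metric == "C"]))
  expect_false(any(res$significant[res$metric == "L"]))
})
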