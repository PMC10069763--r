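test_that("exact periodic series finds zero-distance neighbors at whole-period offsets", {
  pat <- c(1, 3, 7, 2, 8)
  p <- length(pat)
  s <- edm_series(rep(pat, 5))
  hp <- edm_hyperparams(E = 3, n = 2, tp = 2, theta = 1)
  ns <- find_neighbors(s, hp, current_t = s$n_obs)
  # every whole-period offset is an exact repeat (d = 0); the d = 0 tie is
  # broken deterministically toward the earliest occurrences
  expect_true(all((s$n_obs - ns$t_i) %% p == 0))
  expect_equal(ns$d_i, c(0, 0))
  expect_equal(ns$t_i, c(p, 2 * p))
})

test_that("neighbor search matches the brute-force oracle on random cases", {
  set.seed(42)
  for (rep in 1:25) {
    cs <- random_case()
    s <- edm_series(cs$values)
    hp <- edm_hyperparams(E = cs$E, n = cs$n, tp = cs$tp)
    ns <- suppressWarnings(find_neighbors(s, hp, cs$len))
    oracle <- brute_neighbors(cs$values, cs$E, cs$n, cs$tp, cs$len)
    expect_identical(ns$t_i, as.integer(oracle$t_i))
    expect_equal(ns$d_i, oracle$d_i)
  }
})

test_that("the shortest usable series yields exactly one neighbor", {
  hp <- edm_hyperparams(E = 3, n = 5, tp = 2)
  s <- edm_series(rnorm(hp$E + hp$tp))
  expect_warning(ns <- find_neighbors(s, hp, s$n_obs), "only 1 eligible")
  expect_equal(length(ns$t_i), 1)
  expect_equal(ns$t_i, hp$E)
})

test_that("insufficient history is an error, not a silent empty result", {
  hp <- edm_hyperparams(E = 3, n = 5, tp = 3)
  expect_error(find_neighbors(edm_series(rnorm(5)), hp, 5), "insufficient history")
  expect_error(find_neighbors(edm_series(rnorm(5)), hp, 2), "current_t")
})

test_that("weights follow exp(-theta d / d_bar) with its degenerate cases", {
  set.seed(7)
  s <- edm_series(rnorm(60))
  hp <- edm_hyperparams(E = 3, n = 5, tp = 2, theta = 0)
  ns0 <- find_neighbors(s, hp)
  expect_equal(ns0$w_i, rep(1, 5))

  ns1 <- compute_weights(ns0, theta = 1)
  expect_equal(ns1$w_i, exp(-ns1$d_i / mean(ns1$d_i)))
  expect_true(all(ns1$w_i > 0 & ns1$w_i <= 1))
  # weight is non-increasing in distance for the sorted set
  expect_true(all(diff(ns1$w_i) <= 0))

  # a neighbor at exactly the mean distance has weight e^-1
  close <- which.min(abs(ns1$d_i - ns1$d_bar))
  expect_equal(exp(-ns1$d_i[close] / ns1$d_bar), ns1$w_i[close])

  # all-zero distances: equal weights of 1
  rep_s <- edm_series(rep(c(2, 4, 6), 8))
  nsr <- find_neighbors(rep_s, edm_hyperparams(E = 3, n = 3, tp = 3, theta = 2))
  expect_equal(nsr$d_i, rep(0, 3))
  expect_equal(nsr$w_i, rep(1, 3))
})

test_that("simplex forecast is the normalized weighted mean of futures", {
  # equal weights: plain mean
  set.seed(11)
  s <- edm_series(rnorm(80))
  hp <- edm_hyperparams(E = 2, n = 4, tp = 3, theta = 0)
  ns <- find_neighbors(s, hp)
  pf <- simplex_forecast(ns)
  expect_equal(pf$values, colMeans(ns$Z))

  # hand-computed two-neighbor weighted mean: 0.8*10 + 0.2*20 = 12
  ns2 <- ns
  ns2$enabled <- c(TRUE, TRUE, FALSE, FALSE)
  ns2$w_i <- c(0.8, 0.2, NA, NA)
  ns2$Z <- rbind(rep(10, 3), rep(20, 3), ns$Z[3:4, ])
  expect_equal(simplex_forecast(ns2)$values, rep(12, 3))

  # single enabled neighbor: forecast is its future vector exactly
  ns1 <- ns
  for (ti in ns$t_i[-1]) ns1 <- set_neighbor_enabled(ns1, ti, FALSE)
  expect_equal(simplex_forecast(ns1)$values, as.numeric(ns$Z[1, ]))
})

test_that("forecasts are convex combinations of enabled futures", {
  set.seed(99)
  for (rep in 1:20) {
    s <- edm_series(rnorm(sample(40:120, 1)))
    hp <- edm_hyperparams(E = sample(1:4, 1), n = sample(2:8, 1),
                          tp = sample(1:5, 1), theta = runif(1, 0, 3))
    ns <- suppressWarnings(find_neighbors(s, hp))
    pf <- simplex_forecast(ns)
    Z <- ns$Z[ns$enabled, , drop = FALSE]
    for (r in seq_along(pf$values)) {
      expect_gte(pf$values[r], min(Z[, r]) - 1e-12)
      expect_lte(pf$values[r], max(Z[, r]) + 1e-12)
    }
  }
})

test_that("disabling a neighbor recomputes d_bar and weights over the enabled subset", {
  set.seed(5)
  s <- edm_series(rnorm(60))
  hp <- edm_hyperparams(E = 3, n = 4, tp = 2, theta = 1)
  ns <- find_neighbors(s, hp)
  orig <- ns

  ns2 <- set_neighbor_enabled(ns, ns$t_i[2], FALSE)
  expect_false(ns2$enabled[2])
  expect_true(is.na(ns2$w_i[2]))
  expect_equal(ns2$d_bar, mean(ns2$d_i[-2]))
  expect_equal(ns2$w_i[-2], exp(-ns2$d_i[-2] / ns2$d_bar))

  # involution: disable then re-enable restores the original set
  ns3 <- set_neighbor_enabled(ns2, ns$t_i[2], TRUE)
  expect_equal(ns3, orig)

  # a single remaining neighbor has d_bar equal to its own distance
  only <- Reduce(function(x, ti) set_neighbor_enabled(x, ti, FALSE),
                 ns$t_i[-1], ns)
  expect_equal(only$w_i[1], exp(-1 * 1))

  all_off <- set_neighbor_enabled(only, ns$t_i[1], FALSE)
  expect_error(simplex_forecast(all_off), "all neighbors disabled")
  expect_error(set_neighbor_enabled(ns, 99999, FALSE), "no neighbor")
})

test_that("neighbor search is deterministic and lookahead-free", {
  set.seed(21)
  vals <- rnorm(100)
  hp <- edm_hyperparams(E = 4, n = 6, tp = 3, theta = 1)
  a <- find_neighbors(edm_series(vals), hp, 80)
  b <- find_neighbors(edm_series(vals), hp, 80)
  expect_identical(a, b)

  # values after the origin cannot influence the result
  vals2 <- vals
  vals2[81:100] <- vals2[81:100] + rnorm(20, 50)
  c <- find_neighbors(edm_series(vals2), hp, 80)
  expect_identical(a$t_i, c$t_i)
  expect_equal(a$d_i, c$d_i)
  expect_equal(a$w_i, c$w_i)
  expect_equal(simplex_forecast(a)$values, simplex_forecast(c)$values)
})

test_that("historical mean neighbor distance matches explicit recomputation", {
  expect_equal(mean_distance_history(edm_series(rep(3, 30)),
                                     edm_hyperparams(E = 2, n = 3, tp = 2)), 0)

  set.seed(31)
  s <- edm_series(rnorm(50))
  hp <- edm_hyperparams(E = 3, n = 4, tp = 2)
  got <- mean_distance_history(s, hp, 50)
  origins <- (hp$E + hp$tp):49
  manual <- mean(vapply(origins, function(tt) {
    mean(suppressWarnings(find_neighbors(s, hp, tt))$d_i)
  }, numeric(1)))
  expect_equal(got, manual)

  expect_error(mean_distance_history(s, hp, hp$E + hp$tp), "no eligible prior")
})
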