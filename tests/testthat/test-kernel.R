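test_that("kernel constants satisfy their defining identities", {
  set.seed(2)
  s <- edm_series(rnorm(50))
  hp1 <- edm_hyperparams(n = 1)
  kp1 <- kernel_params(s, hp1)
  # s = 1/(f(0) * n): for n = 1 that is sqrt(2*pi)
  expect_equal(kp1$s, sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(kp1$s * hp1$n * dnorm(0), 1, tolerance = 1e-12)

  # q: the standardized kernel must fall to density c at half-width,
  # checked against an independent root solve of dnorm(x) = c
  x_c <- uniroot(function(x) dnorm(x) - hp1$c, c(0.1, 10), tol = 1e-14)$root
  expect_equal(kp1$q, 1 / (2 * x_c), tolerance = 1e-9)
  expect_equal(dnorm(1 / (2 * kp1$q)), kp1$c, tolerance = 1e-12)

  # alpha scales with the series sd and the kw multiplier
  expect_equal(kp1$alpha, sd(s$values))
  kp2 <- kernel_params(s, edm_hyperparams(n = 1, kw = 2))
  expect_equal(kp2$alpha, 2 * kp1$alpha)
  expect_equal(kp2$q, kp1$q)
  expect_equal(kp2$s, kp1$s)

  # constant series: no natural width, explicit override required
  expect_error(kernel_params(edm_series(rep(1, 10)), hp1), "alpha")
  kp3 <- kernel_params(edm_series(rep(1, 10)), hp1, alpha = 0.5)
  expect_equal(kp3$alpha, 0.5)
})

test_that("kernel peak and edge values match their closed forms", {
  s <- edm_series(c(rnorm(30)))
  kp <- kernel_params(s, edm_hyperparams(n = 1))
  z <- 0.7
  expect_equal(kernel_value(z, z, w = 1, kp), 1, tolerance = 1e-9)
  expect_equal(kernel_value(z + kp$alpha / 2, z, w = 1, kp),
               kp$c / dnorm(0), tolerance = 1e-9)
  expect_equal(kernel_value(z - kp$alpha / 2, z, w = 1, kp),
               kernel_value(z + kp$alpha / 2, z, w = 1, kp))

  # peak is w/n
  kp2 <- kernel_params(s, edm_hyperparams(n = 2))
  expect_equal(kernel_value(z, z, w = 0.5, kp2), 0.25, tolerance = 1e-12)
})

test_that("density grids sum per-neighbor kernels over the stated range", {
  set.seed(13)
  s <- edm_series(rnorm(80))
  hp <- edm_hyperparams(E = 3, n = 5, tp = 4, theta = 1, grid_points = 64)
  ns <- find_neighbors(s, hp)
  kp <- kernel_params(s, hp)
  dg <- density_grid(ns, kp)

  expect_equal(nrow(dg), hp$tp * hp$grid_points)
  for (r in seq_len(hp$tp)) {
    step <- dg[dg$step == r, ]
    z_r <- ns$Z[ns$enabled, r]
    expect_equal(min(step$v), min(z_r) - kp$alpha)
    expect_equal(max(step$v), max(z_r) + kp$alpha)
    # additivity oracle: explicit loop over neighbors
    manual <- rep(0, nrow(step))
    w <- ns$w_i[ns$enabled]
    for (i in seq_along(z_r)) {
      manual <- manual + kp$s * w[i] * dnorm((step$v - z_r[i]) / (kp$alpha * kp$q))
    }
    expect_equal(step$density, manual)
    expect_lte(max(step$density), sum(w) / hp$n + 1e-12)
  }
  expect_true(all(dg$opacity >= 0 & dg$opacity <= 1))
  expect_equal(dg$opacity, pmin(dg$density, 1))
})

test_that("single and coincident neighbors reach the exact peak heights", {
  # one enabled neighbor at theta = 0: peak density 1 at its future value
  s <- edm_series(rep(c(1, 2, 3, 4), 6))
  hp <- edm_hyperparams(E = 2, n = 1, tp = 2, theta = 0, grid_points = 401)
  ns <- find_neighbors(s, hp)
  kp <- kernel_params(s, hp)
  dg <- density_grid(ns, kp)
  for (r in 1:2) {
    step <- dg[dg$step == r, ]
    expect_equal(max(step$density), 1, tolerance = 1e-6)
    expect_equal(step$v[which.max(step$density)], ns$Z[1, r],
                 tolerance = diff(range(step$v)) / 400)
  }

  # two neighbors with identical futures at equal weight: 2 * (1/2) = 1
  hp2 <- edm_hyperparams(E = 2, n = 2, tp = 2, theta = 0, grid_points = 401)
  ns2 <- find_neighbors(s, hp2)
  expect_equal(ns2$Z[1, ], ns2$Z[2, ])
  dg2 <- density_grid(ns2, kernel_params(s, hp2))
  expect_equal(max(dg2$density[dg2$step == 1]), 1, tolerance = 1e-6)
})

test_that("well-separated future clusters produce a bimodal density", {
  fx <- bimodal_fixture()
  kp <- kernel_params(fx$series, fx$hp, alpha = 1)
  dg <- density_grid(fx$ns, kp, grid_points = 512)
  for (r in 1:fx$hp$tp) {
    dens <- dg$density[dg$step == r]
    d1 <- diff(dens)
    n_modes <- sum(d1[-length(d1)] > 0 & d1[-1] <= 0)
    expect_equal(n_modes, 2)
  }
  # the point forecast falls strictly between the two clusters
  pf <- simplex_forecast(fx$ns)
  expect_true(all(pf$values > 0 & pf$values < 10))
})

test_that("disabling a neighbor never raises the density under frozen weights", {
  set.seed(17)
  s <- edm_series(rnorm(70))
  hp <- edm_hyperparams(E = 3, n = 5, tp = 3, theta = 1, grid_points = 64)
  ns <- find_neighbors(s, hp)
  kp <- kernel_params(s, hp)
  dg <- density_grid(ns, kp)
  # freeze weights: drop one neighbor's kernel by direct subtraction oracle
  drop_i <- 3
  for (r in seq_len(hp$tp)) {
    step <- dg[dg$step == r, ]
    reduced <- step$density -
      kp$s * ns$w_i[drop_i] * dnorm((step$v - ns$Z[drop_i, r]) / (kp$alpha * kp$q))
    expect_true(all(reduced <= step$density + 1e-15))
    expect_true(all(reduced >= -1e-15))
  }
})

test_that("the normalized predictive pdf integrates to one", {
  set.seed(23)
  for (rep in 1:10) {
    s <- edm_series(rnorm(sample(40:100, 1)))
    hp <- edm_hyperparams(E = sample(1:4, 1), n = sample(2:8, 1),
                          tp = sample(1:4, 1), theta = runif(1, 0, 2),
                          kw = runif(1, 0.3, 2))
    ns <- suppressWarnings(find_neighbors(s, hp))
    kp <- kernel_params(s, hp)
    for (r in seq_len(hp$tp)) {
      pdf <- predictive_pdf(ns, kp, r, grid_points = 512)
      expect_gte(trapz(pdf$v, pdf$pdf), 0.999)
      expect_lte(trapz(pdf$v, pdf$pdf), 1.001)
    }
  }
})

test_that("a single kernel's pdf is the Gaussian it claims to be", {
  s <- edm_series(rep(c(1, 2, 3, 4), 6))
  hp <- edm_hyperparams(E = 2, n = 1, tp = 1, theta = 0, grid_points = 301)
  ns <- find_neighbors(s, hp)
  kp <- kernel_params(s, hp)
  pdf <- predictive_pdf(ns, kp, 1)
  expect_equal(pdf$pdf, dnorm(pdf$v, mean = ns$Z[1, 1], sd = kp$alpha * kp$q),
               tolerance = 1e-12)
})

test_that("increasing kw widens a kernel without changing its peak", {
  set.seed(3)
  s <- edm_series(rnorm(40))
  half_width <- function(kw) {
    kp <- kernel_params(s, edm_hyperparams(n = 1, kw = kw))
    # half-maximum points of a Gaussian: sd * sqrt(2 log 2)
    v <- seq(-5, 5, length.out = 4001)
    dens <- kernel_value(v, 0, 1, kp)
    diff(range(v[dens >= max(dens) / 2]))
  }
  w1 <- half_width(1); w2 <- half_width(2)
  expect_gt(w2, w1 * 1.9)
  kpa <- kernel_params(s, edm_hyperparams(n = 1, kw = 1))
  kpb <- kernel_params(s, edm_hyperparams(n = 1, kw = 2))
  expect_equal(kernel_value(0, 0, 1, kpa), kernel_value(0, 0, 1, kpb))
})
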