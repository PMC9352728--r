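test_that("dipolar kernel has the powder-average limits and bounds", {
  grid <- distance_grid()
  time <- default_time(101, 2)
  K <- dipolar_kernel(grid, time)
  expect_equal(dim(K), c(101L, 131L))
  # zero evolution time: cosine of zero integrates to one at every r
  expect_equal(K[1, ], rep(1, 131))
  # infinite-distance limit: dipolar frequency vanishes
  far <- distance_grid(900, 1000, 3)
  expect_equal(dipolar_kernel(far, time), matrix(1, 101, 3),
               tolerance = 1e-6)
  expect_true(all(K >= -0.5 & K <= 1 + 1e-12))
  expect_error(dipolar_kernel(grid, c(1, 0.5)), "increasing")
})

test_that("kernel matches brute-force orientation quadrature to 1e-6", {
  x <- seq(0, 1, length.out = 1e5 + 1)
  brute <- function(t_us, r_ang) {
    om <- 2 * pi * 52.04 * (r_ang / 10)^-3
    pracma::trapz(x, cos((1 - 3 * x^2) * om * t_us))
  }
  for (r in c(20, 30, 55)) {
    g <- distance_grid(r, r + 1e-4, 2)
    for (t_us in c(0.05, 0.2, 1.1, 2.4)) {
      K <- dipolar_kernel(g, c(0, t_us))
      expect_equal(K[2, 1], brute(t_us, r), tolerance = 1e-6)
    }
  }
})

test_that("stretched-exponential background behaves as a decay law", {
  bg <- background_model(0.02, 1.0)
  expect_identical(background_decay(0, bg), 1)
  expect_equal(background_decay(1, bg), exp(-0.02))
  expect_equal(background_decay(default_time(), background_model(0, 1.1)),
               rep(1, 251))
  t <- seq(-2, 2, by = 0.1)
  B <- background_decay(t, background_model(0.3, 1.1))
  expect_true(all(diff(B[t >= 0]) <= 0))    # non-increasing in |t|
  expect_equal(B, rev(B))                    # even in t
  expect_error(background_model(0.1, 0), "positive")
  expect_error(background_model(-1, 1), "non-negative")
})

test_that("pathway models validate amplitudes", {
  pm <- pathway_model_4p(0.4)
  expect_equal(pm$unmodulated, 0.6)
  p5 <- pathway_model_5p(0.5, 0.4, 0.1, t0_2 = 1.5)
  expect_equal(p5$amplitudes, c(0.4, 0.1))
  expect_error(pathway_model(c(0.8, 0.4)), "sum above 1")
  expect_error(pathway_model(-0.1), "non-negative")
})

test_that("simulated trace reduces to pure background with no pathways", {
  dist <- as_distribution(apo_model())
  bg <- background_model(0.2, 1.1)
  tr <- simulate_trace(dist, pathway_model(0, unmodulated = 1), bg,
                       default_time(51, 2))
  expect_equal(tr$signal, background_decay(tr$time, bg))
})

test_that("a delta-like distribution with full depth returns the kernel column", {
  grid <- distance_grid()
  dist <- as_distribution(bigaussian_model(30, 1e-3, 1, 45, 1), grid)
  time <- default_time(101, 2)
  tr <- simulate_trace(dist, pathway_model_4p(1), background_model(0, 1),
                       time, grid = grid)
  Kcol <- dipolar_kernel(distance_grid(30, 30.001, 2), time)[, 1]
  expect_equal(tr$signal, Kcol, tolerance = 1e-6)
})

test_that("noiseless background-free simulation is linear in the distribution", {
  grid <- distance_grid()
  time <- default_time(61, 2)
  p1 <- as_distribution(bigaussian_model(22, 2, 1, 50, 2), grid)
  p2 <- as_distribution(bigaussian_model(45, 6, 1, 60, 2), grid)
  mix <- distance_distribution(grid, 0.3 * p1$density + 0.7 * p2$density)
  sim <- function(p) simulate_trace(p, pathway_model_4p(1),
                                    background_model(0, 1), time)$signal
  expect_equal(sim(mix), 0.3 * sim(p1) + 0.7 * sim(p2), tolerance = 1e-9)
})

test_that("bi-Gaussian simulation matches a 10x finer-grid direct summation", {
  model <- bigaussian_model(22, 1.5, 0.68, 45, 8)
  time <- default_time(101, 2.5)
  bg <- background_model(0.1, 1)
  # 0.25 A step: the narrow compact component needs it for 1e-4 accuracy
  tr <- simulate_trace(model, pathway_model_4p(0.4), bg, time,
                       grid = distance_grid(15, 80, 261))
  fine <- distance_grid(15, 80, 2601)
  dens <- 0.68 * dnorm(fine$r, 22, 1.5) + 0.32 * dnorm(fine$r, 45, 8)
  dens <- dens / pracma::trapz(fine$r, dens)
  K <- dipolar_kernel(fine, time)
  w <- rep(fine$dr, fine$n_points); w[c(1, fine$n_points)] <- fine$dr / 2
  V <- (0.6 + 0.4 * drop(K %*% (w * dens))) * background_decay(time, bg)
  expect_equal(tr$signal, V, tolerance = 1e-4)
})

test_that("simulation randomness is seeded and reproducible", {
  m <- apo_model()
  a <- canonical_trace(m, noise_sigma = 0.005, seed = 42)
  b <- canonical_trace(m, noise_sigma = 0.005, seed = 42)
  c <- canonical_trace(m, noise_sigma = 0.005, seed = 43)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  expect_error(canonical_trace(m, noise_sigma = 0.01), "seed")
  # noiseless repeat is bit-identical
  expect_identical(canonical_trace(m)$signal, canonical_trace(m)$signal)
})
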