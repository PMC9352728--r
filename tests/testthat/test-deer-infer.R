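test_that("bi-Gaussian fit recovers noiseless ground truths across the window", {
  # seeded grid of truths spanning the compact/extended parameter space
  set.seed(11)
  truths <- data.frame(
    p1 = runif(10, 0.3, 0.9),
    r1 = runif(10, 20, 30),
    r2 = runif(10, 38, 55)
  )
  for (i in seq_len(nrow(truths))) {
    m <- bigaussian_model(truths$r1[i], 1.5, truths$p1[i], truths$r2[i], 6)
    tr <- canonical_trace(m, time = default_time(201))
    fit <- fit_bigaussian(tr, n_starts = 4, seed = 1)
    expect_lt(abs(fit$model$p1 - truths$p1[i]), 0.01)
    expect_lt(abs(fit$model$r1 - truths$r1[i]), 0.2)
    expect_lt(abs(fit$model$r2 - truths$r2[i]), 0.2)
  }
})

test_that("a single-Gaussian truth yields a vanishing second component", {
  m <- bigaussian_model(28, 2.5, 1, 50, 6)
  tr <- canonical_trace(m, time = default_time(151))
  fit <- fit_bigaussian(tr, n_starts = 4, seed = 1)
  expect_lte(fit$model$p2, 0.02)
  expect_lt(abs(fit$model$r1 - 28), 0.2)
})

test_that("mean recovered population over noisy replicates matches truth", {
  m <- apo_model()
  p1_hat <- vapply(1:25, function(s) {
    tr <- canonical_trace(m, time = default_time(151),
                          noise_sigma = 0.005, seed = s)
    fit_bigaussian(tr, n_starts = 2, seed = 1)$model$p1
  }, numeric(1))
  expect_lt(abs(mean(p1_hat) - 0.68), 0.02)
  expect_lt(sd(p1_hat), 0.05)
})

test_that("fit rejects degenerate inputs", {
  expect_error(fit_bigaussian(deer_trace(1:5 / 10, rep(1, 5) + 1e-3 * (1:5))),
               "fewer than 8")
  expect_error(fit_bigaussian(deer_trace(1:10 / 10, rep(1, 10))),
               "constant")
})

test_that("Tikhonov inversion recovers a known mode and obeys limits", {
  g <- distance_grid()
  m <- bigaussian_model(35, 3, 1, 60, 5)
  tr <- simulate_trace(m, pathway_model_4p(0.4), background_model(0.1, 1),
                       default_time(151, 2.5))
  sol <- tikhonov_solve(tr, g, alpha = 1, lambda = 0.4,
                        bg = background_model(0.1, 1))
  mode_r <- g$r[which.max(sol$distribution$density)]
  expect_lte(abs(mode_r - 35), g$dr)  # within one grid step
  expect_true(all(sol$distribution$density >= 0))
  expect_equal(pracma::trapz(g$r, sol$distribution$density), 1,
               tolerance = 1e-6)
  # huge alpha drives the solution to the smoothest nonnegative density:
  # curvature (second differences) collapses relative to the sharp solve
  flat <- tikhonov_solve(tr, g, alpha = 1e5, lambda = 0.4,
                         bg = background_model(0.1, 1))
  L <- deerens:::second_difference_operator(g$n_points)
  roughness <- function(s) sqrt(sum((L %*% s$distribution$density)^2))
  expect_lt(roughness(flat), 0.02 * roughness(sol))
  expect_error(tikhonov_solve(tr, g, alpha = -1, lambda = 0.4,
                              bg = background_model(0.1, 1)), "positive")
})

test_that("GCV-selected solution fits a noisy trace to the noise level", {
  g <- distance_grid()
  m <- bigaussian_model(30, 3, 1, 55, 5)
  sigma <- 0.01
  tr <- simulate_trace(m, pathway_model_4p(0.4), background_model(0.1, 1),
                       default_time(151, 2.5), noise_sigma = sigma, seed = 9)
  sol <- tikhonov_solve(tr, g, alpha = "gcv", lambda = 0.4,
                        bg = background_model(0.1, 1))
  expect_lte(sol$residual_rms, sigma * 1.2)
})

test_that("GCV picks large alpha for pure noise and smaller for high SNR", {
  g <- distance_grid(15, 80, 40)
  noise_tr <- deer_trace(default_time(80, 2),
                         1 + deerens:::with_seed(3, rnorm(80, 0, 0.01)))
  agrid <- 10^seq(-3, 2, length.out = 25)
  a_noise <- suppressWarnings(
    gcv_select(noise_tr, g, agrid, lambda = 0.3,
               bg = background_model(0.1, 1)))
  expect_gte(as.numeric(a_noise), agrid[13])  # upper half of the grid
  m <- bigaussian_model(30, 3, 1, 55, 5)
  clean <- simulate_trace(m, pathway_model_4p(0.4), background_model(0.1, 1),
                          default_time(151, 2.5), noise_sigma = 1e-4,
                          seed = 2, grid = g)
  a_clean <- suppressWarnings(
    gcv_select(clean, g, agrid, lambda = 0.4,
               bg = background_model(0.1, 1)))
  expect_lte(as.numeric(a_clean), agrid[12])  # lower half
  expect_error(gcv_select(clean, g, alpha_grid = c(1, 2), lambda = 0.4,
                          bg = background_model(0.1, 1)), "20 points")
})

test_that("GCV curve is finite and selects near the brute-force LOO optimum", {
  g <- distance_grid(15, 80, 40)
  m <- bigaussian_model(30, 4, 1, 60, 5)
  tr <- simulate_trace(m, pathway_model_4p(0.5), background_model(0.1, 1),
                       seq(0, 2, length.out = 30), noise_sigma = 0.01,
                       seed = 5, grid = g)
  sys <- deerens:::deer_linear_system(tr, g, 0.5, background_model(0.1, 1))
  L <- deerens:::second_difference_operator(40)
  alphas <- 10^seq(-2, 2, length.out = 21)
  gcv <- vapply(alphas, function(a)
    deerens:::gcv_score(sys$A, sys$b, a), numeric(1))
  expect_true(all(is.finite(gcv)))
  # brute-force leave-one-out: drop each point, re-solve, predict it
  loo <- vapply(alphas, function(a) {
    mean(vapply(seq_len(30), function(i) {
      P <- pracma::lsqnonneg(rbind(sys$A[-i, ], a * L),
                             c(sys$b[-i], rep(0, nrow(L))))$x
      (sys$b[i] - sum(sys$A[i, ] * P))^2
    }, numeric(1)))
  }, numeric(1))
  a_gcv <- alphas[which.min(gcv)]
  a_loo <- alphas[which.min(loo)]
  # selected alpha within one log-grid step of the LOO optimum
  expect_lte(abs(log10(a_gcv) - log10(a_loo)), 0.21)
})

test_that("bootstrap CIs are seeded, reproducible, and collapse without noise", {
  m <- apo_model()
  tr <- canonical_trace(m, time = default_time(121, 2),
                        noise_sigma = 0.01, seed = 7)
  fit <- fit_bigaussian(tr, n_starts = 2, seed = 1)
  b1 <- bootstrap_ci(fit, n_samples = 40, seed = 3)
  b2 <- bootstrap_ci(fit, n_samples = 40, seed = 3)
  expect_identical(b1$ci95, b2$ci95)
  expect_true(all(b1$ci95["lower", ] <= b1$ci95["upper", ]))
  # point estimate inside its own interval
  est <- fit$theta[colnames(b1$ci95)]
  expect_true(all(b1$ci95["lower", ] <= est + 1e-8 &
                    est <= b1$ci95["upper", ] + 1e-8))
  expect_error(bootstrap_ci(fit, n_samples = 10), "at least 20")
  # zero-noise trace: residuals vanish, intervals collapse
  tr0 <- canonical_trace(m, time = default_time(121, 2))
  fit0 <- fit_bigaussian(tr0, n_starts = 2, seed = 1)
  b0 <- bootstrap_ci(fit0, n_samples = 25, seed = 1)
  widths <- b0$ci95["upper", ] - b0$ci95["lower", ]
  expect_true(all(widths < 1e-3))
})

test_that("population extraction splits mixtures at the density minimum", {
  g <- distance_grid()
  mix <- distance_distribution(
    g, 0.7 * dnorm(g$r, 22, 1.5) + 0.3 * dnorm(g$r, 45, 8))
  p <- extract_populations(mix, split = "auto")
  expect_lt(abs(p[["p_compact"]] - 0.70), 0.01)
  expect_equal(sum(p), 1)
  # explicit split below all density: everything is "extended"
  p_lo <- extract_populations(mix, split = 15)
  expect_equal(unname(p_lo), c(0, 1))
  p_hi <- extract_populations(mix, split = 80)
  expect_equal(unname(p_hi), c(1, 0))
  # bi-Gaussian models return their parameters directly
  expect_equal(unname(extract_populations(apo_model())), c(0.68, 0.32))
  uni <- distance_distribution(g, dnorm(g$r, 40, 5))
  expect_error(extract_populations(uni, split = "auto"), "unimodal")
})

test_that("parametric and regularized populations agree on separated modes", {
  g <- distance_grid()
  m <- bigaussian_model(24, 2, 0.6, 50, 5)
  tr <- simulate_trace(m, pathway_model_4p(0.4), background_model(0.1, 1),
                       default_time(201), noise_sigma = 0.002, seed = 4)
  fit <- fit_bigaussian(tr, n_starts = 4, seed = 1)
  sol <- tikhonov_solve(tr, g, alpha = "gcv", lambda = fit$amplitudes[["lambda"]],
                        bg = fit$background)
  p_par <- extract_populations(fit$model)
  p_reg <- extract_populations(sol$distribution, split = "auto")
  expect_lt(abs(p_par[["p_compact"]] - p_reg[["p_compact"]]), 0.05)
})
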