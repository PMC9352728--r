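test_that("effective DEER distance is the linear population average", {
  g <- distance_grid(15, 80, 651)
  # delta-like density at 30 A
  delta <- as_distribution(bigaussian_model(30, 0.05, 1, 60, 1), g)
  expect_equal(effective_deer_distance(delta), 30, tolerance = 1e-3)
  # symmetric equal mixture of narrow components
  sym <- as_distribution(bigaussian_model(20, 0.5, 0.5, 40, 0.5), g)
  expect_equal(effective_deer_distance(sym), 30, tolerance = 1e-3)
  # apo-like 68:32 mixture against an independent quadrature oracle
  mix_pdf <- function(r) 0.68 * dnorm(r, 22, 1.5) + 0.32 * dnorm(r, 45, 8)
  z <- integrate(mix_pdf, 15, 80, rel.tol = 1e-10)$value
  oracle <- integrate(function(r) r * mix_pdf(r) / z, 15, 80,
                      rel.tol = 1e-10)$value
  got <- effective_deer_distance(as_distribution(apo_model(), g))
  expect_equal(got, oracle, tolerance = 0.01 / 30)
  expect_equal(got, 29.36, tolerance = 0.01 / 29)
  # unnormalized input is normalized with a warning
  raw <- as_distribution(apo_model(), g)
  raw$density <- raw$density * 3
  expect_warning(e2 <- effective_deer_distance(raw), "normaliz")
  expect_equal(e2, got)
})

test_that("restraint limits bracket the distance with the default tolerance", {
  expect_equal(make_limits(29.4), c(lower = 24.4, upper = 34.4))
  expect_equal(make_limits(30, tolerance = 0), c(lower = 30, upper = 30))
  # batch preserves count and order
  lims <- make_limits(c(29.4, 45, 18))
  expect_equal(dim(lims), c(3L, 2L))
  expect_equal(lims[, "upper"], c(34.4, 50, 23))
  expect_warning(cl <- make_limits(4), "clamped")
  expect_equal(cl[["lower"]], 1)
})

test_that("restraint constructor applies kind-specific defaults", {
  rs <- distance_restraint(c(15, "CB"), c(90, "CB"), "DEER", 24.4, 34.4)
  expect_equal(rs$weight, 1)
  expect_equal(rs$averaging, "linear")
  pre <- distance_restraint(c(15, "CB"), c(120, "H"), "PRE", 10, 18)
  expect_equal(pre$weight, 0.01)
  expect_equal(pre$averaging, "r6")
  expect_error(distance_restraint(c(1, "CA"), c(2, "CA"), "NOE", 5, 3),
               "lower bound exceeds")
})

test_that("ensemble averaging matches closed forms and the power-mean order", {
  pair <- label_pair()
  same <- toy_two_state(12, 12)
  expect_equal(ensemble_average_distance(same, pair, "r6"), 12)
  expect_equal(ensemble_average_distance(same, pair, "linear"), 12)
  mix <- toy_two_state(3, 30)
  expect_equal(ensemble_average_distance(mix, pair, "r6"),
               (0.5 * 3^-6 + 0.5 * 30^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal(ensemble_average_distance(mix, pair, "r6"), 3.367,
               tolerance = 1e-3)
  expect_equal(ensemble_average_distance(mix, pair, "linear"), 16.5)
  # r6 average never exceeds the linear average (power-mean inequality)
  set.seed(8)
  for (i in 1:25) {
    e <- toy_two_state(runif(1, 2, 50), runif(1, 2, 50), runif(1, 0.05, 0.95))
    expect_lte(ensemble_average_distance(e, pair, "r6"),
               ensemble_average_distance(e, pair, "linear") + 1e-12)
  }
  expect_error(ensemble_average_distance(mix, label_pair(1, 99), "r6"),
               "missing")
})

test_that("target function is the weighted sum of squared violations", {
  ens <- toy_two_state(20, 20)
  sat <- list(distance_restraint(c(1, "CB"), c(50, "CB"), "NOE", 1, 25))
  expect_equal(target_function(ens, sat)$tf, 0)
  viol <- list(distance_restraint(c(1, "CB"), c(50, "CB"), "NOE", 1, 18))
  rep1 <- target_function(ens, viol)
  expect_equal(rep1$tf, 4)           # 2 A violation, weight 1
  expect_equal(rep1$n_violated, 1L)
  pre <- list(distance_restraint(c(1, "CB"), c(50, "CB"), "PRE", 1, 18))
  expect_equal(target_function(ens, pre)$tf, 0.04)  # weight 0.01
  # flat-bottom: violation from below counts too
  below <- list(distance_restraint(c(1, "CB"), c(50, "CB"), "DEER", 23, 30))
  expect_equal(target_function(ens, below)$tf, 9)
  expect_warning(empty <- target_function(ens, list()), "empty")
  expect_equal(empty$tf, 0)
  # consistency: tf equals the recomputed sum of contributions
  expect_equal(rep1$tf, sum(rep1$per_restraint$contribution), tolerance = 1e-9)
})

test_that("widening any restraint never increases the target function", {
  ens <- toy_two_state(8, 35, 0.6)
  base <- list(
    distance_restraint(c(1, "CB"), c(50, "CB"), "NOE", 1, 6),
    distance_restraint(c(1, "CB"), c(50, "CB"), "DEER", 25, 28))
  tf0 <- target_function(ens, base)$tf
  for (i in seq_along(base)) {
    wider <- base
    wider[[i]]$lower <- wider[[i]]$lower - 3
    wider[[i]]$upper <- wider[[i]]$upper + 3
    expect_lte(target_function(ens, wider)$tf, tf0 + 1e-12)
  }
})

test_that("Karplus back-calculation reproduces the cosine closed form", {
  # cos(theta) = 1: J = A + B + C for an offset-free coefficient set
  abc <- c(A = 7, B = -1.3, C = 0.4, offset_deg = 0)
  expect_equal(karplus_backcalc(0, coefficients = abc), 7 - 1.3 + 0.4)
  # pure cos^2 term is even in the dihedral
  sym <- c(A = 9.5, B = 0, C = 1.8, offset_deg = 0)
  th <- seq(-180, 180, by = 15)
  expect_equal(karplus_backcalc(th, coefficients = sym),
               karplus_backcalc(-th, coefficients = sym))
  # registered set matches an independent evaluation over a phi grid
  phi <- seq(-180, 175, by = 5)
  co <- karplus_coefficients[["3JHNHA"]]
  oracle <- co[["A"]] * cos((phi + co[["offset_deg"]]) * pi / 180)^2 +
    co[["B"]] * cos((phi + co[["offset_deg"]]) * pi / 180) + co[["C"]]
  expect_equal(karplus_backcalc(phi, "3JHNHA"), oracle, tolerance = 1e-9)
  expect_error(karplus_backcalc(60, "3JXX"), "unregistered")
})

test_that("rigid-body optimization reaches a realizable single-state truth", {
  truth <- make_two_domain_system(seed = 3)
  # restraints generated from the compact placement alone
  lab <- truth$label_sites
  d_lab <- truth$r_compact_achieved
  rest <- list(
    distance_restraint(c(lab[1], "CB"), c(lab[2], "CB"), "DEER",
                       d_lab - 1, d_lab + 1),
    distance_restraint(c(lab[1], "CA"), c(lab[2], "CA"), "NOE", 1, 40))
  out <- optimize_two_state(truth$domain_a, truth$domain_b, rest,
                            n_states = 1, n_starts = 4, seed = 2)
  expect_lte(out$report$tf, 1e-3)
  expect_error(optimize_two_state(truth$domain_a, truth$domain_b, rest,
                                  n_states = 3), "1 or 2")
  intra <- list(distance_restraint(c(1, "CA"), c(5, "CA"), "NOE", 1, 20))
  expect_error(optimize_two_state(truth$domain_a, truth$domain_b, intra),
               "interdomain")
})

test_that("rigid-body moves leave intradomain geometry untouched", {
  truth <- make_two_domain_system(seed = 4)
  lab <- truth$label_sites
  rest <- list(distance_restraint(c(lab[1], "CB"), c(lab[2], "CB"), "DEER",
                                  30, 40))
  out <- optimize_two_state(truth$domain_a, truth$domain_b, rest,
                            n_states = 1, n_starts = 2, seed = 1)
  placed <- out$ensemble$conformers[[1]]
  intra_dist <- function(df, res) {
    a <- df[df$residue %in% res, c("x", "y", "z")]
    as.vector(dist(a))
  }
  res_b <- unique(truth$domain_b$residue)[1:10]
  expect_equal(intra_dist(placed, res_b),
               intra_dist(truth$domain_b, res_b), tolerance = 1e-8)
})
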