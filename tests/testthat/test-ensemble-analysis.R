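test_that("state classification counts planted compact/extended conformers", {
  truth <- make_two_domain_system(seed = 2)
  compact <- rbind(truth$domain_a, truth$compact_b)
  extended <- rbind(truth$domain_a, truth$extended_b)
  confs <- c(rep(list(compact), 70), rep(list(extended), 30))
  sorted <- classify_states(confs)
  expect_equal(length(sorted$compact), 70L)
  expect_equal(length(sorted$extended), 30L)
  # degenerate cutoff: nothing can be in contact
  all_ext <- classify_states(confs[1:5], contact_cutoff = 0)
  expect_equal(length(all_ext$compact), 0L)
  # sensitivity report spans the 4-6 A convention window
  expect_equal(sorted$sensitivity$cutoff, c(4, 5, 6))
  expect_true(all(diff(sorted$sensitivity$n_compact) >= 0))
})

test_that("classification is invariant to conformer order and global rotation", {
  truth <- make_two_domain_system(seed = 5)
  compact <- rbind(truth$domain_a, truth$compact_b)
  extended <- rbind(truth$domain_a, truth$extended_b)
  confs <- list(compact, extended, compact)
  base <- classify_states(confs)$is_compact
  perm <- c(2, 3, 1)
  expect_equal(classify_states(confs[perm])$is_compact, base[perm])
  # rigid rotation + translation of the whole complex changes nothing
  R <- deerens:::euler_rotation(0.4, -1.1, 2.2)
  rotated <- lapply(confs, function(cf) {
    cf[, c("x", "y", "z")] <-
      sweep(as.matrix(cf[, c("x", "y", "z")]) %*% t(R), 2, c(5, -3, 8), "+")
    cf
  })
  expect_equal(classify_states(rotated)$is_compact, base)
})

test_that("RMSD profile is zero for identical or rigidly shifted sets", {
  truth <- make_two_domain_system(seed = 6)
  cf <- rbind(truth$domain_a, truth$compact_b)
  prof <- rmsd_profile(list(cf), list(cf), superposition_residues = 50:163)
  expect_true(all(prof$rmsd < 1e-8))
  shifted <- cf
  shifted[, c("x", "y", "z")] <- shifted[, c("x", "y", "z")] + 3
  prof2 <- rmsd_profile(list(cf), list(shifted),
                        superposition_residues = unique(cf$residue),
                        backbone_atoms = c("CA", "CB"))
  expect_true(all(prof2$rmsd < 1e-8))
})

test_that("RMSD profile localizes a planted single-residue displacement", {
  truth <- make_two_domain_system(seed = 6)
  cf <- rbind(truth$domain_a, truth$compact_b)
  moved <- cf
  sel <- moved$residue == 130
  moved[sel, "x"] <- moved[sel, "x"] + 4
  # superpose on untouched residues so the displacement stays visible
  core <- setdiff(50:163, 130)
  prof <- rmsd_profile(list(cf), list(moved), superposition_residues = core,
                       backbone_atoms = c("CA", "CB"))
  hit <- prof$rmsd[prof$residue == 130]
  rest <- prof$rmsd[prof$residue != 130]
  expect_equal(hit, 4, tolerance = 0.02)
  expect_true(all(rest < 0.2))
  # symmetry under swapping the sets
  prof_sw <- rmsd_profile(list(moved), list(cf), superposition_residues = core,
                          backbone_atoms = c("CA", "CB"))
  expect_equal(prof$rmsd, prof_sw$rmsd, tolerance = 1e-6)
})

test_that("RMSD uncertainty follows the summed-variance rule", {
  truth <- make_two_domain_system(seed = 6)
  cf <- rbind(truth$domain_a, truth$compact_b)
  jitter_set <- function(sd, seed) {
    deerens:::with_seed(seed, lapply(1:6, function(i) {
      out <- cf
      out[, c("x", "y", "z")] <- out[, c("x", "y", "z")] +
        matrix(rnorm(3 * nrow(out), 0, sd), ncol = 3)
      out
    }))
  }
  # superpose on everything so jitter is the only variance source
  prof <- rmsd_profile(jitter_set(0.3, 1), jitter_set(0.3, 2),
                       superposition_residues = unique(cf$residue),
                       backbone_atoms = c("CA", "CB"))
  expect_true(all(prof$uncertainty > 0))
  # expected scale: sqrt(2 * 3 sigma^2) per atom pair of sets
  expect_equal(median(prof$uncertainty), sqrt(2 * 3 * 0.3^2),
               tolerance = 0.35)
})

test_that("restraint overlap reports shared fractions per kind", {
  mk <- function(i, kind = "NOE")
    distance_restraint(c(i, "CA"), c(i + 60, "CA"), kind, 1, 5)
  a <- lapply(1:20, mk)
  expect_equal(restraint_overlap(a, a)$frac_a, 1)
  disjoint <- restraint_overlap(lapply(1:5, mk), lapply(11:15, mk))
  expect_equal(disjoint$frac_a, 0)
  # 13 of 20 shared
  b <- c(lapply(1:13, mk), lapply(31:37, mk))
  ov <- restraint_overlap(a, b)
  expect_equal(ov$n_shared, 13L)
  expect_equal(ov$frac_a, 0.65)
  expect_equal(ov$frac_b, 0.65)
  # atom order is normalized in the identity
  flip <- list(distance_restraint(c(61, "CA"), c(1, "CA"), "NOE", 1, 5))
  expect_equal(restraint_overlap(list(mk(1)), flip)$n_shared, 1L)
  # empty set of a kind reports NA
  mixed <- restraint_overlap(a, list(distance_restraint(c(1, "CB"),
                                                        c(70, "H"), "PRE",
                                                        10, 18)))
  expect_true(is.na(mixed$frac_b[mixed$kind == "NOE"]))
})

test_that("classification rate matches the planted state populations", {
  # conformer-level binomial sampling commutes with the ground-truth
  # distribution's population split
  truth <- make_two_domain_system(seed = 9, p_compact = 0.7)
  compact <- rbind(truth$domain_a, truth$compact_b)
  extended <- rbind(truth$domain_a, truth$extended_b)
  n <- 1000
  draw <- deerens:::with_seed(31, stats::rbinom(n, 1, truth$p_compact))
  confs <- lapply(draw, function(d) if (d == 1) compact else extended)
  frac <- mean(classify_states(confs)$is_compact)
  p_dist <- extract_populations(truth_to_distribution(truth), split = "auto")
  # binomial 99% half-width at n=1000 is ~0.037
  expect_lt(abs(frac - p_dist[["p_compact"]]), 0.04)
})
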