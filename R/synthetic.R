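#' Synthetic ground-truth two-domain system
#'
#' Builds a two-domain rigid-body system that samples one compact and
#' one extended state with prescribed populations, for end-to-end
#' testing of the analysis pipeline against known truth. Domains are
#' CA+CB bead chains with 3.8 A CA spacing collapsed into globules
#' (synthetic stand-ins for real domain coordinates, so no structure
#' download is ever needed). Residue numbering mirrors a WW-like small
#' domain (1-39) and a PPIase-like large domain (50-163). The compact
#' placement has interdomain contact (< 5 A) and a label-site CB-CB
#' distance close to `r_compact`; the extended placement has no contact
#' below 8 A and label distance `r_extended`.
#'
#' @param seed Integer seed; the construction is deterministic per seed.
#' @param n_residues_a,n_residues_b Residues per domain.
#' @param label_sites Residue indices carrying the spin labels (one per
#'   domain).
#' @param r_compact,r_extended Target label-site CB-CB distances (A).
#' @param p_compact Population of the compact state, in (0, 1).
#' @param sigma_label Gaussian distance broadening per state (A):
#'   narrow for the contact-locked compact state, wide for the loosely
#'   tethered extended state.
#' @param contact_gap Interdomain heavy-atom gap of the compact
#'   placement (A).
#' @return An object of class `ground_truth` with the domain and
#'   placed-state coordinates, achieved label distances, populations
#'   and broadenings.
#' @export
#' @examples
#' truth <- make_two_domain_system(seed = 7)
#' truth$r_compact_achieved
make_two_domain_system <- function(seed = 1, n_residues_a = 39,
                                   n_residues_b = 114,
                                   label_sites = c(15, 90),
                                   r_compact = 22, r_extended = 45,
                                   p_compact = 0.7,
                                   sigma_label = c(1.5, 8),
                                   contact_gap = 4) {
  stopifnot(p_compact > 0, p_compact < 1, r_compact < r_extended)
  with_seed(seed, {
    dom_a <- bead_domain(seq_len(n_residues_a))
    dom_b <- bead_domain(seq.int(50, 50 + n_residues_b - 1))
    placed <- place_two_states(dom_a, dom_b, label_sites,
                               r_compact, r_extended, contact_gap)
    structure(list(
      domain_a = dom_a, domain_b = dom_b,
      compact_b = placed$compact_b, extended_b = placed$extended_b,
      label_sites = label_sites,
      r_compact_achieved = placed$r_compact,
      r_extended_achieved = placed$r_extended,
      p_compact = p_compact, sigma_label = sigma_label,
      seed = seed
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground truth: labels %d/%d, compact %.2f A (p = %.2f), extended %.2f A\n",
    x$label_sites[1], x$label_sites[2], x$r_compact_achieved,
    x$p_compact, x$r_extended_achieved))
  invisible(x)
}

# Compact globular CA+CB bead chain: 3.8 A CA steps biased back toward
# the centroid beyond the expected globule radius, CB 1.53 A off each CA.
bead_domain <- function(residues) {
  n <- length(residues)
  rmax <- 2.5 * n^(1 / 3) + 2
  ca <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  for (i in seq_len(n)) {
    best <- NULL; best_clear <- -Inf
    for (attempt in 1:30) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      if (sqrt(sum(pos^2)) > rmax)  # steer back inside the globule
        dir <- -pos / sqrt(sum(pos^2)) + 0.5 * dir
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + 3.8 * dir
      # soft self-avoidance against previous CA positions
      clear <- if (i < 3) Inf else
        min(sqrt(rowSums(sweep(ca[seq_len(i - 1), , drop = FALSE],
                               2, cand)^2)))
      if (clear > best_clear) { best <- cand; best_clear <- clear }
      if (clear > 3.2) break
    }
    pos <- best
    ca[i, ] <- pos
  }
  ca <- sweep(ca, 2, colMeans(ca))
  cb_dir <- matrix(stats::rnorm(3 * n), n, 3)
  cb_dir <- cb_dir / sqrt(rowSums(cb_dir^2))
  cb <- ca + 1.53 * cb_dir
  data.frame(
    residue = rep(residues, each = 2),
    atom = rep(c("CA", "CB"), n),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3]))
  )
}

# Solve compact and extended placements of domain B against fixed A:
# compact touches A (minimum heavy-atom gap = contact_gap) with the
# label distance hit by root-finding over a spin angle; extended slides
# B out along the approach direction to the extended label distance.
place_two_states <- function(dom_a, dom_b, label_sites,
                             r_compact, r_extended, contact_gap,
                             max_tries = 50) {
  lab_a <- atom_xyz(dom_a, label_sites[1], "CB")
  xyz_a <- as.matrix(dom_a[, c("x", "y", "z")])
  for (try in seq_len(max_tries)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ang <- stats::runif(3, -pi, pi)
    b0 <- apply_rigid(dom_b, ang, c(0, 0, 0))
    place_at <- function(s, spin) {
      b <- apply_rigid(b0, c(spin, 0, 0), c(0, 0, 0))
      b[, c("x", "y", "z")] <- sweep(as.matrix(b[, c("x", "y", "z")]),
                                     2, s * u, FUN = "+")
      b
    }
    touch_s <- function(spin) {
      gap <- function(s) {
        b <- place_at(s, spin)
        min_pair_distance(xyz_a, as.matrix(b[, c("x", "y", "z")])) -
          contact_gap
      }
      stats::uniroot(gap, c(5, 120), extendInt = "upX", tol = 1e-4)$root
    }
    label_dist <- function(spin) {
      b <- place_at(touch_s(spin), spin)
      sqrt(sum((atom_xyz(b, label_sites[2], "CB") - lab_a)^2))
    }
    spins <- seq(0, 2 * pi, length.out = 25)
    dl <- vapply(spins, label_dist, numeric(1))
    hit <- which(diff(sign(dl - r_compact)) != 0)
    if (length(hit) == 0) next
    spin <- stats::uniroot(function(s) label_dist(s) - r_compact,
                           spins[hit[1] + 0:1], tol = 1e-6)$root
    compact_b <- place_at(touch_s(spin), spin)
    rc <- sqrt(sum((atom_xyz(compact_b, label_sites[2], "CB") - lab_a)^2))

    # extended: slide out along u at the same spin until the label
    # distance reaches the extended target
    ext_dist <- function(s) {
      b <- place_at(s, spin)
      sqrt(sum((atom_xyz(b, label_sites[2], "CB") - lab_a)^2)) - r_extended
    }
    s_ext <- try(stats::uniroot(ext_dist, c(touch_s(spin) + 5, 200),
                                extendInt = "upX", tol = 1e-4)$root,
                 silent = TRUE)
    if (inherits(s_ext, "try-error")) next
    extended_b <- place_at(s_ext, spin)
    gap_ext <- min_pair_distance(xyz_a,
                                 as.matrix(extended_b[, c("x", "y", "z")]))
    if (gap_ext < 8) next
    re <- sqrt(sum((atom_xyz(extended_b, label_sites[2], "CB") - lab_a)^2))
    return(list(compact_b = compact_b, extended_b = extended_b,
                r_compact = rc, r_extended = re))
  }
  stop("could not construct a valid two-state placement; try another seed")
}

#' Ground-truth label-site distance distribution
#'
#' The two-Gaussian mixture implied by a ground truth: components at
#' the achieved compact and extended label distances, broadened by the
#' per-state `sigma_label`, weighted by the state populations.
#'
#' @param truth A [make_two_domain_system()] result.
#' @param grid A [distance_grid()].
#' @return A [distance_distribution()].
#' @export
truth_to_distribution <- function(truth, grid = distance_grid()) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- bigaussian_model(truth$r_compact_achieved, truth$sigma_label[1],
                        truth$p_compact,
                        truth$r_extended_achieved, truth$sigma_label[2])
  as_distribution(m, grid)
}

# The ground truth as a two-conformer, two-state ensemble.
truth_to_ensemble <- function(truth) {
  two_state_ensemble(
    list(rbind(truth$domain_a, truth$compact_b),
         rbind(truth$domain_a, truth$extended_b)),
    state_labels = c(1, 2),
    populations = c(truth$p_compact, 1 - truth$p_compact))
}

#' Forward-simulate all measurements from a ground truth
#'
#' Generates the four restraint classes the integrative analysis
#' combines, each consistent with the assumptions the analysis stages
#' encode:
#' * a DEER trace simulated from the ground-truth distance distribution
#'   (single-pathway model, stretched-exponential background, seeded
#'   white noise),
#' * a relaxation table whose PRE rates follow the forward
#'   Solomon-Bloembergen equation applied to the population-weighted
#'   r^-6 average of the per-state label-to-amide distances,
#' * interdomain NOE upper limits only for compact-state contact pairs
#'   (the extended state contributes no interdomain NOEs),
#' * scalar couplings back-calculated from synthetic dihedrals via the
#'   Karplus relation.
#'
#' @param truth A [make_two_domain_system()] result.
#' @param noise List: `deer_sigma` (trace units; the conventional
#'   ladder is 0, 0.002, 0.005, 0.02), `rate_sigma` (1/s on PRE rates).
#' @param seed Integer seed; byte-identical outputs per seed.
#' @param deer_time Trace time axis (us).
#' @param pathways,bg Pathway and background models of the DEER
#'   simulation.
#' @param pre_params [pre_parameters()] of the PRE forward model.
#' @param noe_cutoff Contact cutoff for interdomain NOEs (A).
#' @return List with `deer` ([deer_trace()]), `relaxation` (data
#'   frame), `noes` (list of [distance_restraint()]), `couplings`
#'   (data frame), and the ground-truth `distribution`.
#' @export
truth_to_measurements <- function(truth,
                                  noise = list(deer_sigma = 0.005,
                                               rate_sigma = 0),
                                  seed = 1,
                                  deer_time = seq(0, 2.5, length.out = 251),
                                  pathways = pathway_model_4p(0.4),
                                  bg = background_model(0.1, 1),
                                  pre_params = pre_parameters(),
                                  noe_cutoff = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  dist <- truth_to_distribution(truth)
  deer <- simulate_trace(dist, pathways, bg, deer_time,
                         noise_sigma = noise$deer_sigma, seed = seed)

  lab_a <- atom_xyz(truth$domain_a, truth$label_sites[1], "CB")
  res_b <- unique(truth$domain_b$residue)
  r_per_state <- vapply(res_b, function(rr) {
    c(sqrt(sum((atom_xyz(truth$compact_b, rr, "CA") - lab_a)^2)),
      sqrt(sum((atom_xyz(truth$extended_b, rr, "CA") - lab_a)^2)))
  }, numeric(2))
  p <- truth$p_compact
  r_eff <- (p * r_per_state[1, ]^-6 + (1 - p) * r_per_state[2, ]^-6)^(-1 / 6)
  r2sp <- distance_to_r2sp(r_eff, pre_params)
  # 15N rates consistent with the tumbling time of the conversion
  # parameters (reduced spectral-density forward model, see vignette)
  rates <- rates_from_tauc(pre_params$tau_c, larmor_n = pre_params$larmor_h *
                             0.10136673)
  relaxation <- with_seed(seed + 1, data.frame(
    residue = res_b,
    r2_para = 30 + r2sp + stats::rnorm(length(res_b), 0, noise$rate_sigma),
    r2_dia = 30,
    r1 = rates[["r1"]], r2 = rates[["r2"]]
  ))

  xyz_a <- as.matrix(truth$domain_a[, c("x", "y", "z")])
  xyz_bc <- as.matrix(truth$compact_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_bc^2), "+") -
    2 * xyz_a %*% t(xyz_bc)
  close <- which(sqrt(pmax(d2, 0)) < noe_cutoff, arr.ind = TRUE)
  noes <- lapply(seq_len(nrow(close)), function(k) {
    i <- close[k, 1]; j <- close[k, 2]
    distance_restraint(
      c(truth$domain_a$residue[i], truth$domain_a$atom[i]),
      c(truth$compact_b$residue[j], truth$compact_b$atom[j]),
      kind = "NOE", lower = 1, upper = noe_cutoff)
  })

  all_res <- c(unique(truth$domain_a$residue), res_b)
  couplings <- with_seed(seed + 2, {
    phi <- stats::runif(length(all_res), -180, 180)
    data.frame(residue = all_res, dihedral = phi, type = "3JHNHA",
               j_hz = karplus_backcalc(phi, "3JHNHA"))
  })

  list(deer = deer, relaxation = relaxation, noes = noes,
       couplings = couplings, distribution = dist)
}

# 15N R1/R2 from an isotropic correlation time via the reduced
# spectral-density model (J(0) and J(omega_N) terms) that the R2/R1
# tumbling estimator inverts exactly.
rates_from_tauc <- function(tau_c_ns, larmor_n, scale = 1.0) {
  tau <- tau_c_ns * 1e-9
  omega_n <- 2 * pi * larmor_n * 1e6
  j0 <- tau
  jn <- tau / (1 + omega_n^2 * tau^2)
  a <- 1.3e9 * scale  # effective dipolar+CSA prefactor, s^-2
  c(r1 = 3 * a * jn, r2 = (a / 2) * (4 * j0 + 3 * jn))
}
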