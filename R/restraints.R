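#' Distance restraint between two atoms
#'
#' An upper/lower distance bound between two atoms, of kind NOE, PRE or
#' DEER. Default weights follow the relative weighting used in
#' multi-state ensemble calculations: NOE 1, DEER 1, PRE 0.01 (PRE
#' distances are population averages with large conversion uncertainty,
#' so they are down-weighted). NOE and PRE restraints are compared to
#' the r^-6 ensemble average; DEER effective distances are themselves
#' population averages, so they use linear averaging.
#'
#' @param atom_a,atom_b Length-2 vectors `c(residue_index, atom_name)`.
#' @param kind `"NOE"`, `"PRE"` or `"DEER"`.
#' @param lower,upper Bounds (Angstrom), `lower <= upper`.
#' @param weight Positive weight; default by kind.
#' @param averaging `"r6"` or `"linear"`; default by kind.
#' @return An object of class `distance_restraint`.
#' @export
#' @examples
#' distance_restraint(c(15, "CB"), c(90, "CB"), "DEER", 24.4, 34.4)
distance_restraint <- function(atom_a, atom_b,
                               kind = c("NOE", "PRE", "DEER"),
                               lower, upper,
                               weight = NULL, averaging = NULL) {
  kind <- match.arg(kind)
  if (is.null(weight))
    weight <- c(NOE = 1, PRE = 0.01, DEER = 1)[[kind]]
  if (is.null(averaging))
    averaging <- c(NOE = "r6", PRE = "r6", DEER = "linear")[[kind]]
  averaging <- match.arg(averaging, c("r6", "linear"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (lower > upper) stop("lower bound exceeds upper bound")
  if (weight <= 0) stop("weight must be positive")
  structure(list(
    atom_a = list(residue = as.integer(atom_a[1]), atom = as.character(atom_a[2])),
    atom_b = list(residue = as.integer(atom_b[1]), atom = as.character(atom_b[2])),
    kind = kind, lower = lower, upper = upper,
    weight = weight, averaging = averaging
  ), class = "distance_restraint")
}

#' @export
print.distance_restraint <- function(x, ...) {
  cat(sprintf("%s %d.%s - %d.%s  [%.2f, %.2f] A  w = %g (%s)\n",
              x$kind, x$atom_a$residue, x$atom_a$atom,
              x$atom_b$residue, x$atom_b$atom,
              x$lower, x$upper, x$weight, x$averaging))
  invisible(x)
}

#' Effective (population- and fluctuation-averaged) DEER distance
#'
#' The linear average \eqn{\langle r\rangle = \int r P(r)\,dr} of a
#' distance distribution: the effective label-site distance that a
#' two-state ensemble must reproduce as the population-weighted mean
#' over its states.
#'
#' @param dist A [distance_distribution()] (normalized; unnormalized
#'   densities are normalized with a warning) or [bigaussian_model()].
#' @return Mean distance (Angstrom).
#' @export
#' @examples
#' effective_deer_distance(as_distribution(bigaussian_model(22, 1.5, 0.68, 45, 8)))
effective_deer_distance <- function(dist) {
  if (inherits(dist, "bigaussian_model"))
    dist <- as_distribution(dist)
  stopifnot(inherits(dist, "distance_distribution"))
  z <- trapz_grid(dist$grid, dist$density)
  if (abs(z - 1) > 1e-6) {
    warning("density not normalized; normalizing")
    dist$density <- dist$density / z
  }
  trapz_grid(dist$grid, dist$grid$r * dist$density)
}

#' Upper/lower limits around an effective distance
#'
#' Symmetric tolerance around an effective distance, giving the lower
#' and upper limit of a flat-bottom restraint. The default +/- 5 A
#' tolerance reflects the width of the underlying distance
#' distributions. The lower limit is clamped at 1 A (with a warning)
#' when the distance does not exceed the tolerance.
#'
#' @param distance Effective distance(s), Angstrom.
#' @param tolerance Half-width (Angstrom).
#' @return For one distance, `c(lower, upper)`; vectorized input gives
#'   a two-column matrix in input order.
#' @export
#' @examples
#' make_limits(29.4)
make_limits <- function(distance, tolerance = 5) {
  lower <- distance - tolerance
  if (any(lower < 1)) {
    warning("distance within tolerance of zero; lower limit clamped at 1 A")
    lower <- pmax(lower, 1)
  }
  out <- cbind(lower = lower, upper = distance + tolerance)
  if (length(distance) == 1) out <- out[1, ]
  out
}

#' Two-state conformer ensemble
#'
#' A set of conformers partitioned into one or two states with state
#' populations. Each conformer is a data frame with columns `residue`,
#' `atom`, `x`, `y`, `z` (Angstrom).
#'
#' @param conformers List of conformer data frames.
#' @param state_labels Integer 1 or 2 per conformer.
#' @param populations Fraction per state, summing to 1.
#' @return An object of class `two_state_ensemble`.
#' @export
two_state_ensemble <- function(conformers, state_labels, populations) {
  stopifnot(length(conformers) == length(state_labels))
  state_labels <- as.integer(state_labels)
  n_states <- length(unique(state_labels))
  if (!all(state_labels %in% c(1L, 2L)))
    stop("state labels must be 1 or 2")
  if (length(populations) != n_states)
    stop("one population per state required")
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1")
  for (cf in conformers)
    stopifnot(is.data.frame(cf),
              all(c("residue", "atom", "x", "y", "z") %in% names(cf)))
  structure(list(conformers = conformers, state_labels = state_labels,
                 populations = as.numeric(populations)),
            class = "two_state_ensemble")
}

#' @export
print.two_state_ensemble <- function(x, ...) {
  cat(sprintf("two-state ensemble: %d conformer(s), states %s, populations %s\n",
              length(x$conformers),
              paste(x$state_labels, collapse = "/"),
              paste(round(x$populations, 3), collapse = "/")))
  invisible(x)
}

# Coordinates of one atom in a conformer; errors name the offender.
atom_xyz <- function(conformer, residue, atom, conformer_id = NA) {
  i <- which(conformer$residue == residue & conformer$atom == atom)
  if (length(i) != 1)
    stop(sprintf("atom %d.%s missing in conformer %s", residue, atom,
                 conformer_id))
  as.numeric(conformer[i, c("x", "y", "z")])
}

#' Ensemble-averaged distance for an atom pair
#'
#' Back-calculated effective distance of a restraint over a two-state
#' ensemble. The per-state distance is the population-weighted mean
#' over the conformers of that state; states are then combined by
#' \deqn{r_{eff} = (\sum_s pop_s\, r_s^{-6})^{-1/6}} for `"r6"`
#' (NOE/PRE-style, short distances dominate) or
#' \deqn{r_{eff} = \sum_s pop_s\, r_s} for `"linear"` (DEER effective
#' distances).
#'
#' @param ensemble A [two_state_ensemble()].
#' @param pair List with `atom_a`, `atom_b`
#'   (each `list(residue =, atom =)`), e.g. a [distance_restraint()].
#' @param averaging `"r6"` or `"linear"`.
#' @return Effective distance (Angstrom).
#' @export
ensemble_average_distance <- function(ensemble, pair,
                                      averaging = c("r6", "linear")) {
  stopifnot(inherits(ensemble, "two_state_ensemble"))
  averaging <- match.arg(averaging)
  states <- sort(unique(ensemble$state_labels))
  r_state <- vapply(states, function(s) {
    idx <- which(ensemble$state_labels == s)
    mean(vapply(idx, function(i) {
      a <- atom_xyz(ensemble$conformers[[i]], pair$atom_a$residue,
                    pair$atom_a$atom, i)
      b <- atom_xyz(ensemble$conformers[[i]], pair$atom_b$residue,
                    pair$atom_b$atom, i)
      sqrt(sum((a - b)^2))
    }, numeric(1)))
  }, numeric(1))
  pops <- ensemble$populations
  if (averaging == "r6") sum(pops * r_state^-6)^(-1 / 6)
  else sum(pops * r_state)
}

#' Target function of an ensemble against distance restraints
#'
#' Sum of weighted squared violations, the score used to judge whether
#' an ensemble satisfies its restraints. Violations are flat-bottom:
#' zero inside `[lower, upper]`, linear distance outside, squared and
#' weighted in the sum
#' \deqn{TF = \sum_i w_i \cdot \max(0,\, r_i - u_i,\, l_i - r_i)^2,}
#' with each restraint's back-calculated [ensemble_average_distance()]
#' using its own averaging mode.
#'
#' @param ensemble A [two_state_ensemble()].
#' @param restraints List of [distance_restraint()].
#' @return An object of class `target_function_report`: `tf` (A^2),
#'   `per_restraint` data frame (kind, effective distance, violation,
#'   weighted squared contribution), `n_violated` (count above zero
#'   violation).
#' @export
target_function <- function(ensemble, restraints) {
  stopifnot(inherits(ensemble, "two_state_ensemble"))
  if (length(restraints) == 0) {
    warning("empty restraint list; target function is 0")
    return(structure(list(
      tf = 0,
      per_restraint = data.frame(kind = character(), r_eff = numeric(),
                                 violation = numeric(),
                                 contribution = numeric()),
      n_violated = 0L), class = "target_function_report"))
  }
  rows <- lapply(restraints, function(rs) {
    r_eff <- ensemble_average_distance(ensemble, rs, rs$averaging)
    viol <- max(0, r_eff - rs$upper) + max(0, rs$lower - r_eff)
    data.frame(kind = rs$kind, r_eff = r_eff, violation = viol,
               contribution = rs$weight * viol^2)
  })
  per <- do.call(rbind, rows)
  structure(list(tf = sum(per$contribution), per_restraint = per,
                 n_violated = sum(per$violation > 1e-9)),
            class = "target_function_report")
}

#' @export
print.target_function_report <- function(x, ...) {
  cat(sprintf("target function: %.4g A^2 over %d restraints (%d violated)\n",
              x$tf, nrow(x$per_restraint), x$n_violated))
  invisible(x)
}

# Rotation matrix from three Euler angles (ZYZ convention, radians).
euler_rotation <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Apply a rigid transform (rotation about the centroid + translation)
# to the xyz columns of a conformer data frame.
apply_rigid <- function(conformer, angles, translation) {
  xyz <- as.matrix(conformer[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  R <- euler_rotation(angles[1], angles[2], angles[3])
  moved <- sweep(xyz, 2, ctr) %*% t(R)
  moved <- sweep(moved, 2, ctr + translation, FUN = "+")
  conformer[, c("x", "y", "z")] <- moved
  conformer
}

#' Optimize a one- or two-state rigid-body ensemble against restraints
#'
#' Places a rigid mobile domain relative to a fixed domain, with one
#' placement per state, by minimizing the [target_function()] over the
#' six rigid-body degrees of freedom per state plus (for two states)
#' the state populations, bounded to \[0.05, 0.95\]. Seeded multi-start
#' local search (L-BFGS-B); deterministic given the seed. Intradomain
#' coordinates are untouched by construction (rigid-body contract).
#'
#' @param domain_a Fixed-domain conformer data frame.
#' @param domain_b Mobile-domain conformer data frame (disjoint residue
#'   numbering from `domain_a`).
#' @param restraints List of [distance_restraint()] spanning the two
#'   domains; at least one interdomain restraint is required.
#' @param n_states 1 or 2.
#' @param n_starts Number of seeded starts.
#' @param seed Integer seed.
#' @return List with `ensemble` (the best [two_state_ensemble()]) and
#'   `report` (its [target_function()] report).
#' @export
optimize_two_state <- function(domain_a, domain_b, restraints,
                               n_states = 2, n_starts = 8, seed = 1) {
  if (!n_states %in% c(1, 2)) stop("n_states must be 1 or 2")
  if (length(restraints) == 0) stop("no restraints supplied")
  res_a <- unique(domain_a$residue)
  interdomain <- vapply(restraints, function(rs) {
    xor(rs$atom_a$residue %in% res_a, rs$atom_b$residue %in% res_a)
  }, logical(1))
  if (!any(interdomain)) stop("no interdomain restraints")

  build <- function(par) {
    confs <- lapply(seq_len(n_states), function(s) {
      q <- par[(s - 1) * 6 + 1:6]
      rbind(domain_a, apply_rigid(domain_b, q[1:3], q[4:6]))
    })
    pops <- if (n_states == 2) c(par[13], 1 - par[13]) else 1
    two_state_ensemble(confs, seq_len(n_states), pops)
  }
  # vectorized objective on precomputed atom indices (the data-frame
  # path in target_function is far too slow inside the optimizer)
  xyz_a <- as.matrix(domain_a[, c("x", "y", "z")])
  xyz_b <- as.matrix(domain_b[, c("x", "y", "z")])
  ctr_b <- colMeans(xyz_b)
  key_a <- paste(domain_a$residue, domain_a$atom)
  key_b <- paste(domain_b$residue, domain_b$atom)
  locate <- function(at) {
    k <- paste(at$residue, at$atom)
    i <- match(k, key_a)
    if (!is.na(i)) return(c(0L, i))          # domain flag, row
    j <- match(k, key_b)
    if (is.na(j)) stop("atom ", k, " found in neither domain")
    c(1L, j)
  }
  loc_a <- t(vapply(restraints, function(rs) locate(rs$atom_a), integer(2)))
  loc_b <- t(vapply(restraints, function(rs) locate(rs$atom_b), integer(2)))
  lowers <- vapply(restraints, function(rs) rs$lower, numeric(1))
  uppers <- vapply(restraints, function(rs) rs$upper, numeric(1))
  weights <- vapply(restraints, function(rs) rs$weight, numeric(1))
  is_r6 <- vapply(restraints, function(rs) rs$averaging == "r6", logical(1))
  objective <- function(par) {
    d_state <- vapply(seq_len(n_states), function(s) {
      q <- par[(s - 1) * 6 + 1:6]
      R <- euler_rotation(q[1], q[2], q[3])
      bs <- sweep(sweep(xyz_b, 2, ctr_b) %*% t(R), 2, ctr_b + q[4:6],
                  FUN = "+")
      p1 <- matrix(0, nrow(loc_a), 3); p2 <- p1
      ia <- loc_a[, 1] == 0
      p1[ia, ] <- xyz_a[loc_a[ia, 2], , drop = FALSE]
      p1[!ia, ] <- bs[loc_a[!ia, 2], , drop = FALSE]
      ib <- loc_b[, 1] == 0
      p2[ib, ] <- xyz_a[loc_b[ib, 2], , drop = FALSE]
      p2[!ib, ] <- bs[loc_b[!ib, 2], , drop = FALSE]
      sqrt(rowSums((p1 - p2)^2))
    }, numeric(length(restraints)))
    d_state <- matrix(d_state, nrow = length(restraints), ncol = n_states)
    pops <- if (n_states == 2) c(par[13], 1 - par[13]) else 1
    r_eff <- numeric(length(restraints))
    r_eff[is_r6] <- drop(d_state[is_r6, , drop = FALSE]^-6 %*% pops)^(-1 / 6)
    r_eff[!is_r6] <- drop(d_state[!is_r6, , drop = FALSE] %*% pops)
    viol <- pmax(0, r_eff - uppers) + pmax(0, lowers - r_eff)
    sum(weights * viol^2)
  }

  npar <- 6 * n_states + (n_states == 2)
  lower <- rep(c(-2 * pi, -80), c(3, 3))
  upper <- rep(c(2 * pi, 80), c(3, 3))
  if (n_states == 2) {
    lower <- c(lower, lower, 0.05)
    upper <- c(upper, upper, 0.95)
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    p <- numeric(npar)
    for (s in seq_len(n_states)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      sep <- stats::runif(1, 10, 60)
      p[(s - 1) * 6 + 1:3] <- stats::runif(3, -pi, pi)
      p[(s - 1) * 6 + 4:6] <- u * sep
    }
    if (n_states == 2) p[13] <- stats::runif(1, 0.3, 0.7)
    p
  }))
  best <- NULL
  for (p0 in starts) {
    fit <- try(stats::optim(p0, objective, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) { last_err <- attr(fit, "condition"); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimization starts failed: ",
         conditionMessage(last_err))
  ens <- build(best$par)
  list(ensemble = ens, report = target_function(ens, restraints))
}

#' Karplus coefficient registry
#'
#' Standard three-bond scalar-coupling parameterizations
#' \eqn{J(\theta) = A\cos^2(\theta + \Delta) + B\cos(\theta + \Delta) + C}
#' with the phase offset \eqn{\Delta} relating the relevant backbone or
#' side-chain dihedral to the H-X-X-H dihedral.
#'
#' @format Named list of `c(A, B, C, offset_deg)`.
#' @export
karplus_coefficients <- list(
  "3JHNHA" = c(A = 6.51, B = -1.76, C = 1.60, offset_deg = -60),
  "3JHAHB" = c(A = 9.50, B = -1.60, C = 1.80, offset_deg = -120),
  "3JNCG"  = c(A = 1.29, B = -0.49, C = 0.37, offset_deg = 0)
)

#' Back-calculate a three-bond scalar coupling
#'
#' Karplus relation for a dihedral angle, using a registered
#' coefficient set or explicit coefficients.
#'
#' @param dihedral Dihedral angle(s), degrees.
#' @param coupling_type Name in [karplus_coefficients].
#' @param coefficients Optional explicit `c(A, B, C, offset_deg)`
#'   overriding the registry.
#' @return Coupling(s) in Hz.
#' @export
#' @examples
#' karplus_backcalc(-120, "3JHNHA")
karplus_backcalc <- function(dihedral, coupling_type = NULL,
                             coefficients = NULL) {
  if (is.null(coefficients)) {
    if (is.null(coupling_type) ||
        !coupling_type %in% names(karplus_coefficients))
      stop("unregistered coupling type: ", coupling_type)
    coefficients <- karplus_coefficients[[coupling_type]]
  }
  if (length(coefficients) == 3) coefficients <- c(coefficients, 0)
  th <- (dihedral + coefficients[[4]]) * pi / 180
  coefficients[[1]] * cos(th)^2 + coefficients[[2]] * cos(th) +
    coefficients[[3]]
}
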