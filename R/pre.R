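#' Transverse PRE rate from paramagnetic and diamagnetic relaxation
#'
#' The paramagnetic relaxation enhancement of the transverse rate is the
#' difference between rates measured on the spin-labeled (paramagnetic)
#' and quenched (diamagnetic) sample, \eqn{R_2^{sp} = R_{2,para} - R_{2,dia}}.
#' Small negative differences (noise) are flagged and truncated to zero
#' with a warning; records missing either rate are skipped.
#'
#' @param records Data frame with columns `residue`, `r2_para`, `r2_dia`
#'   (rates in 1/s), optionally `r1` and `r2`.
#' @return The input with an added `r2sp` column; rows with missing
#'   rates are dropped (with a message naming the residues).
#' @export
#' @examples
#' compute_r2sp(data.frame(residue = 1:2, r2_para = c(45, 30),
#'                         r2_dia = c(30, 30)))
compute_r2sp <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("residue", "r2_para", "r2_dia") %in% names(records)))
  ok <- stats::complete.cases(records[, c("r2_para", "r2_dia")])
  if (any(!ok))
    message("skipping residues with missing rates: ",
            paste(records$residue[!ok], collapse = ", "))
  out <- records[ok, , drop = FALSE]
  if (any(out$r2_para < 0 | out$r2_dia < 0, na.rm = TRUE))
    stop("relaxation rates must be non-negative")
  r2sp <- out$r2_para - out$r2_dia
  if (any(r2sp < 0)) {
    warning("negative R2sp for residue(s) ",
            paste(out$residue[r2sp < 0], collapse = ", "),
            "; treated as 0")
    r2sp[r2sp < 0] <- 0
  }
  out$r2sp <- r2sp
  out
}

#' Rotational correlation time from the R2/R1 ratio
#'
#' Standard isotropic-tumbling estimator from 15N relaxation,
#' \deqn{\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7},}
#' valid when high-frequency spectral-density terms are negligible.
#' Residues with \eqn{6R_2/R_1 < 7} (ratio below the validity boundary)
#' are excluded.
#'
#' @param r1,r2 Longitudinal and transverse 15N rates (1/s).
#' @param larmor_n 15N Larmor frequency (MHz).
#' @param trim Trim fraction of the summary mean.
#' @return A list: `tau_c` (ns, per residue; `NA` where excluded),
#'   `tau_c_mean` (trimmed mean, ns), `excluded` (indices).
#' @export
#' @examples
#' estimate_tauc(r1 = 1.4, r2 = 12, larmor_n = 60.8)
estimate_tauc <- function(r1, r2, larmor_n, trim = 0.1) {
  stopifnot(length(r1) == length(r2), larmor_n > 0)
  if (any(r1 <= 0 | r2 <= 0, na.rm = TRUE))
    stop("rates must be positive")
  disc <- 6 * r2 / r1 - 7
  bad <- !is.finite(disc) | disc < 0
  tau_s <- sqrt(pmax(disc, 0)) / (4 * pi * larmor_n * 1e6)
  tau_ns <- tau_s * 1e9
  tau_ns[bad] <- NA_real_
  list(tau_c = tau_ns,
       tau_c_mean = mean(tau_ns, trim = trim, na.rm = TRUE),
       excluded = which(bad))
}

#' Parameters of the PRE rate-to-distance conversion
#'
#' @param tau_c Rotational correlation time (ns).
#' @param larmor_h Proton Larmor frequency (MHz).
#' @param k_const Dipolar interaction constant of the
#'   Solomon-Bloembergen relation for a nitroxide electron and a proton
#'   (cm^6 s^-2); the standard value 1.23e-32 is the default.
#' @param max_distance Longest reliable PRE distance (Angstrom);
#'   conversions beyond it are reported but excluded from restraints.
#' @return An object of class `pre_parameters`.
#' @export
pre_parameters <- function(tau_c = 8, larmor_h = 600,
                           k_const = 1.23e-32, max_distance = 25) {
  stopifnot(tau_c > 0, larmor_h > 0, k_const > 0, max_distance > 0)
  structure(list(tau_c = tau_c, larmor_h = larmor_h,
                 k_const = k_const, max_distance = max_distance),
            class = "pre_parameters")
}

#' Electron-proton distance from a transverse PRE rate
#'
#' Solomon-Bloembergen relation for the transverse PRE of a proton near
#' a nitroxide,
#' \deqn{r = \left[\frac{K}{R_2^{sp}}\left(4\tau_c +
#'   \frac{3\tau_c}{1 + \omega_H^2\tau_c^2}\right)\right]^{1/6},}
#' with the dipolar constant K, the rotational correlation time and the
#' proton Larmor frequency. Distances are returned in Angstrom;
#' non-positive rates give `NA` (unrestrained).
#'
#' @param r2sp Transverse PRE rate(s) (1/s).
#' @param params A [pre_parameters()].
#' @return Distances (Angstrom), `NA` where `r2sp <= 0`.
#' @export
#' @examples
#' r2sp_to_distance(15, pre_parameters(tau_c = 8, larmor_h = 600))
r2sp_to_distance <- function(r2sp, params = pre_parameters()) {
  stopifnot(inherits(params, "pre_parameters"))
  tau_s <- params$tau_c * 1e-9
  omega_h <- 2 * pi * params$larmor_h * 1e6        # rad/s
  spectral <- 4 * tau_s + 3 * tau_s / (1 + omega_h^2 * tau_s^2)
  r_cm <- (params$k_const / r2sp * spectral)^(1 / 6)
  r <- r_cm * 1e8                                   # cm -> Angstrom
  r[!is.finite(r2sp) | r2sp <= 0] <- NA_real_
  r
}

# Forward Solomon-Bloembergen: PRE rate from a distance in Angstrom.
# Exact inverse of r2sp_to_distance; used by the synthetic generator.
distance_to_r2sp <- function(r_angstrom, params = pre_parameters()) {
  tau_s <- params$tau_c * 1e-9
  omega_h <- 2 * pi * params$larmor_h * 1e6
  spectral <- 4 * tau_s + 3 * tau_s / (1 + omega_h^2 * tau_s^2)
  params$k_const * spectral / (r_angstrom * 1e-8)^6
}

#' PRE distance restraints from a relaxation table
#'
#' Runs [compute_r2sp()] and [r2sp_to_distance()] over a relaxation
#' table and emits PRE distance restraints (weight 0.01, r^-6 ensemble
#' averaging) between the label site and each residue's amide proton.
#' Distances beyond `params$max_distance` are excluded as beyond the
#' reliable PRE range (not capped); distances are never emitted below
#' 1 Angstrom.
#'
#' @param records Relaxation table, see [compute_r2sp()].
#' @param label_site Residue index carrying the spin label.
#' @param params A [pre_parameters()].
#' @param tolerance Half-width of the restraint bounds (Angstrom).
#' @param target_atom Atom of the relaxing residue the distance refers
#'   to (amide proton by default; coarse-grained models may use `"CA"`).
#' @return A list with `restraints` (list of [distance_restraint()])
#'   and `beyond_range` (residues whose distance exceeded the cap).
#' @export
pre_restraints <- function(records, label_site, params = pre_parameters(),
                           tolerance = 4, target_atom = "H") {
  tab <- compute_r2sp(records)
  dist <- r2sp_to_distance(tab$r2sp, params)
  usable <- !is.na(dist) & dist <= params$max_distance
  beyond <- tab$residue[!is.na(dist) & dist > params$max_distance]
  res <- lapply(which(usable), function(i) {
    d <- max(dist[i], 1)
    lims <- make_limits(d, tolerance)
    distance_restraint(
      atom_a = c(label_site, "CB"), atom_b = c(tab$residue[i], target_atom),
      kind = "PRE", lower = lims[1], upper = lims[2])
  })
  list(restraints = res, beyond_range = beyond)
}
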