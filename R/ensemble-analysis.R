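#' Sort ensemble conformers into compact and extended states
#'
#' A conformer is compact when any interdomain heavy-atom pair lies
#' closer than the contact cutoff, extended otherwise (presence or
#' absence of interdomain contact). The default domain ranges are the
#' WW domain (residues 1-39) and the PPIase domain (residues 50-163)
#' of the two-domain system this package models. A sensitivity count
#' over cutoffs 4-6 A is attached, since the cutoff is a convention.
#'
#' @param ensemble A [two_state_ensemble()] or plain list of conformer
#'   data frames.
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom).
#' @param domain_a_residues,domain_b_residues Residue index ranges of
#'   the two domains.
#' @return An object of class `state_sorted_ensemble`: `compact` and
#'   `extended` conformer lists (exhaustive, disjoint),
#'   `contact_cutoff`, `is_compact` (logical per conformer) and a
#'   `sensitivity` data frame of compact counts at cutoffs 4, 5, 6 A.
#' @export
classify_states <- function(ensemble, contact_cutoff = 5,
                            domain_a_residues = 1:39,
                            domain_b_residues = 50:163) {
  confs <- if (inherits(ensemble, "two_state_ensemble"))
    ensemble$conformers else ensemble
  stopifnot(length(confs) >= 1)
  has_contact <- function(cf, cutoff) {
    heavy <- !startsWith(cf$atom, "H")
    a <- cf[heavy & cf$residue %in% domain_a_residues, c("x", "y", "z")]
    b <- cf[heavy & cf$residue %in% domain_b_residues, c("x", "y", "z")]
    if (nrow(a) == 0 || nrow(b) == 0)
      stop("both domains must be present in every conformer")
    if (cutoff <= 0) return(FALSE)
    min_pair_distance(as.matrix(a), as.matrix(b)) < cutoff
  }
  is_compact <- vapply(confs, has_contact, logical(1), cutoff = contact_cutoff)
  sens <- data.frame(
    cutoff = c(4, 5, 6),
    n_compact = vapply(c(4, 5, 6), function(co)
      sum(vapply(confs, has_contact, logical(1), cutoff = co)), numeric(1)))
  structure(list(compact = confs[is_compact],
                 extended = confs[!is_compact],
                 contact_cutoff = contact_cutoff,
                 is_compact = is_compact,
                 sensitivity = sens),
            class = "state_sorted_ensemble")
}

# Minimum pairwise distance between two coordinate matrices.
min_pair_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' @export
print.state_sorted_ensemble <- function(x, ...) {
  cat(sprintf("state-sorted ensemble: %d compact / %d extended (cutoff %.1f A)\n",
              length(x$compact), length(x$extended), x$contact_cutoff))
  invisible(x)
}

# Kabsch least-squares superposition: rigid transform of `mobile` that
# best fits `ref` over the atom subset `idx`; applied to all atoms.
kabsch_superpose <- function(mobile, ref, idx) {
  X <- as.matrix(mobile[idx, c("x", "y", "z")])
  Y <- as.matrix(ref[idx, c("x", "y", "z")])
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  all_xyz <- as.matrix(mobile[, c("x", "y", "z")])
  mobile[, c("x", "y", "z")] <- sweep(sweep(all_xyz, 2, cx) %*% t(R), 2, cy,
                                      FUN = "+")
  mobile
}

#' Per-residue RMSD profile between two conformer sets
#'
#' Superposes every conformer of both sets onto a common reference core
#' by least squares, computes each set's mean structure, and reports
#' the per-residue heavy-atom RMSD between the two mean structures. The
#' uncertainty is the square root of the summed per-residue positional
#' variances of the two sets, an upper bound on the uncertainty of the
#' mean difference. The superposition core defaults to the larger
#' domain's backbone and is recorded in the output, because the choice
#' of frame changes interdomain RMSD values.
#'
#' @param set_a,set_b Lists of conformer data frames with matching
#'   residue/atom naming (mismatched atoms are reported and excluded).
#' @param superposition_residues Residues forming the reference core;
#'   default 50-163 (the larger domain).
#' @param backbone_atoms Atom names used for the superposition fit.
#' @return A data frame (class `rmsd_profile`) with columns `residue`,
#'   `rmsd` and `uncertainty` (Angstrom); the superposition core is in
#'   `attr(, "superposition_residues")`.
#' @export
rmsd_profile <- function(set_a, set_b, superposition_residues = 50:163,
                         backbone_atoms = c("N", "CA", "C")) {
  stopifnot(length(set_a) >= 1, length(set_b) >= 1)
  ref <- set_a[[1]]
  key <- function(cf) paste(cf$residue, cf$atom)
  common <- Reduce(intersect, lapply(c(set_a, set_b), key))
  dropped <- setdiff(unique(unlist(lapply(c(set_a, set_b), key))), common)
  if (length(dropped) > 0)
    message("excluding atoms absent from some conformers: ",
            paste(dropped, collapse = ", "))
  align_set <- function(set) {
    lapply(set, function(cf) {
      cf <- cf[match(common, key(cf)), , drop = FALSE]
      idx <- which(cf$residue %in% superposition_residues &
                     cf$atom %in% backbone_atoms)
      if (length(idx) < 3)
        stop("superposition core must contain at least 3 atoms")
      kabsch_superpose(cf, ref[match(common, key(ref)), , drop = FALSE], idx)
    })
  }
  aligned_a <- align_set(set_a)
  aligned_b <- align_set(set_b)
  stack_xyz <- function(set)
    simplify2array(lapply(set, function(cf)
      as.matrix(cf[, c("x", "y", "z")])))  # atoms x 3 x conformers
  Xa <- stack_xyz(aligned_a); Xb <- stack_xyz(aligned_b)
  mean_a <- apply(Xa, c(1, 2), mean)
  mean_b <- apply(Xb, c(1, 2), mean)
  # total positional variance per atom: sum over xyz of coordinate
  # variances across conformers (0 for a single conformer)
  atom_var <- function(X) {
    if (dim(X)[3] < 2) return(rep(0, dim(X)[1]))
    rowSums(apply(X, c(1, 2), stats::var))
  }
  va <- atom_var(Xa); vb <- atom_var(Xb)
  resid <- aligned_a[[1]]$residue
  heavy <- !startsWith(aligned_a[[1]]$atom, "H")
  d2 <- rowSums((mean_a - mean_b)^2)
  out <- do.call(rbind, lapply(unique(resid), function(rr) {
    i <- which(resid == rr & heavy)
    data.frame(residue = rr,
               rmsd = sqrt(mean(d2[i])),
               uncertainty = sqrt(mean(va[i]) + mean(vb[i])))
  }))
  attr(out, "superposition_residues") <- superposition_residues
  class(out) <- c("rmsd_profile", class(out))
  out
}

#' Shared fraction of restraints between two restraint sets
#'
#' Restraint identity is the order-normalized atom pair plus the kind;
#' for each kind the shared counts and the shared fractions relative to
#' each set are reported (NA where a set has no restraints of a kind).
#'
#' @param set_a,set_b Lists of [distance_restraint()].
#' @return Data frame with columns `kind`, `n_a`, `n_b`, `n_shared`,
#'   `frac_a`, `frac_b`.
#' @export
restraint_overlap <- function(set_a, set_b) {
  rid <- function(rs) {
    a <- paste0(rs$atom_a$residue, ".", rs$atom_a$atom)
    b <- paste0(rs$atom_b$residue, ".", rs$atom_b$atom)
    paste(rs$kind, min(a, b), max(a, b))
  }
  ids_a <- vapply(set_a, rid, character(1))
  ids_b <- vapply(set_b, rid, character(1))
  kinds <- union(vapply(set_a, function(r) r$kind, character(1)),
                 vapply(set_b, function(r) r$kind, character(1)))
  do.call(rbind, lapply(sort(kinds), function(k) {
    a <- unique(ids_a[startsWith(ids_a, k)])
    b <- unique(ids_b[startsWith(ids_b, k)])
    shared <- length(intersect(a, b))
    data.frame(kind = k, n_a = length(a), n_b = length(b),
               n_shared = shared,
               frac_a = if (length(a) > 0) shared / length(a) else NA_real_,
               frac_b = if (length(b) > 0) shared / length(b) else NA_real_)
  }))
}
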