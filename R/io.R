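#' Read and write DEER traces as two-column ASCII
#'
#' Plain-text exchange format: two whitespace-separated columns
#' (time in microseconds, echo amplitude), `#` comment lines, and an
#' optional third column holding the per-point noise level. On reading,
#' the signal is normalized so its maximum is 1 (deposited traces do
#' not state their vertical scale); the applied factor is recorded in
#' `attr(trace, "scale_factor")`.
#'
#' @param path File path.
#' @return `read_deer_ascii`: a [deer_trace()].
#' @export
read_deer_ascii <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least two columns (time, amplitude)")
  scale <- max(tab[[2]])
  noise <- if (ncol(tab) >= 3) stats::median(tab[[3]]) / scale else NA_real_
  tr <- deer_trace(tab[[1]], tab[[2]] / scale, noise_sigma = noise)
  attr(tr, "scale_factor") <- scale
  tr
}

#' @param trace A [deer_trace()].
#' @rdname read_deer_ascii
#' @export
write_deer_ascii <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# DEER trace: time_us amplitude", con)
  writeLines(sprintf("%.6f %.8f", trace$time, trace$signal), con)
  invisible(path)
}

#' Read and write relaxation-rate tables
#'
#' CSV with header `residue,R2_para,R2_dia` and optional `R1,R2`
#' columns (all rates in 1/s).
#'
#' @param path File path.
#' @return `read_relaxation_csv`: data frame with lower-case columns
#'   as used by [compute_r2sp()].
#' @export
read_relaxation_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("residue", "r2_para", "r2_dia")
  if (!all(need %in% names(tab)))
    stop("relaxation CSV must have columns residue,R2_para,R2_dia")
  tab
}

#' @param records Relaxation data frame.
#' @rdname read_relaxation_csv
#' @export
write_relaxation_csv <- function(records, path) {
  out <- records
  up <- c(residue = "residue", r2_para = "R2_para", r2_dia = "R2_dia",
          r1 = "R1", r2 = "R2")
  names(out) <- ifelse(names(out) %in% names(up), up[names(out)], names(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fixed-format restraint row used by both limit files.
format_restraint_row <- function(rs, bound, resnames) {
  rn <- function(res) if (!is.null(resnames) && !is.na(resnames[as.character(res)]))
    resnames[[as.character(res)]] else "UNK"
  sprintf("%4d %-4s %-4s %4d %-4s %-4s %8.2f %6.2f # %s",
          rs$atom_a$residue, rn(rs$atom_a$residue), rs$atom_a$atom,
          rs$atom_b$residue, rn(rs$atom_b$residue), rs$atom_b$atom,
          bound, rs$weight, rs$kind)
}

#' Write distance restraints as upper/lower-limit text files
#'
#' CYANA-dialect limit rows,
#' `resnum resname atom resnum resname atom distance weight # kind`,
#' with upper limits in the `.upl` file and (when any restraint has a
#' lower bound above 1 A) lower limits in a companion `.lol` file. The
#' weight is a trailing numeric column and the restraint kind a
#' trailing comment; [read_restraints()] round-trips the files exactly.
#'
#' @param restraints List of [distance_restraint()].
#' @param path Path of the `.upl` file; the `.lol` file takes the same
#'   stem.
#' @param resnames Optional named character vector mapping residue
#'   numbers to residue names (default `UNK`).
#' @return Invisibly, the paths written.
#' @export
write_restraints <- function(restraints, path, resnames = NULL) {
  upl <- vapply(restraints, function(rs)
    format_restraint_row(rs, rs$upper, resnames), character(1))
  writeLines(upl, path)
  paths <- path
  lol_path <- sub("\\.upl$", ".lol", path)
  if (identical(lol_path, path)) lol_path <- paste0(path, ".lol")
  lowers <- vapply(restraints, function(rs) rs$lower, numeric(1))
  if (any(lowers > 1)) {
    lol <- vapply(restraints, function(rs)
      format_restraint_row(rs, rs$lower, resnames), character(1))
    writeLines(lol, lol_path)
    paths <- c(paths, lol_path)
  }
  invisible(paths)
}

#' Read distance restraints from upper/lower-limit text files
#'
#' @param upl_path Upper-limit file; a companion `.lol` file with the
#'   same stem supplies lower limits when present.
#' @return List of [distance_restraint()].
#' @export
read_restraints <- function(upl_path) {
  parse_rows <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    lapply(lines, function(ln) {
      main <- strsplit(ln, "#", fixed = TRUE)[[1]]
      kind <- if (length(main) > 1) trimws(main[2]) else "NOE"
      f <- strsplit(trimws(main[1]), "\\s+")[[1]]
      if (length(f) < 7) stop("malformed restraint row: ", ln)
      list(res_a = as.integer(f[1]), name_a = f[2], atom_a = f[3],
           res_b = as.integer(f[4]), name_b = f[5], atom_b = f[6],
           dist = as.numeric(f[7]),
           weight = if (length(f) >= 8) as.numeric(f[8]) else NULL,
           kind = kind)
    })
  }
  upl <- parse_rows(upl_path)
  lol_path <- sub("\\.upl$", ".lol", upl_path)
  if (identical(lol_path, upl_path)) lol_path <- paste0(upl_path, ".lol")
  lol <- if (file.exists(lol_path)) parse_rows(lol_path) else NULL
  lapply(seq_along(upl), function(i) {
    u <- upl[[i]]
    lower <- if (!is.null(lol)) lol[[i]]$dist else 1
    distance_restraint(c(u$res_a, u$atom_a), c(u$res_b, u$atom_b),
                       kind = u$kind, lower = lower, upper = u$dist,
                       weight = u$weight)
  })
}

#' Write a two-state ensemble as a multi-model PDB file
#'
#' One MODEL per conformer, with the state label of each conformer and
#' the state populations recorded in `REMARK 300` lines. Atom records
#' are produced by bio3d.
#'
#' @param ensemble A [two_state_ensemble()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "two_state_ensemble"))
  ref <- ensemble$conformers[[1]]
  xyz <- do.call(rbind, lapply(ensemble$conformers, function(cf) {
    if (!identical(cf[, c("residue", "atom")], ref[, c("residue", "atom")]))
      stop("all conformers must share the same atom list")
    as.vector(t(as.matrix(cf[, c("x", "y", "z")])))
  }))
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz,
                   resno = ref$residue, elety = ref$atom,
                   resid = rep("ALA", nrow(ref)),
                   chain = rep("A", nrow(ref)))
  remarks <- c(
    sprintf("REMARK 300 STATE LABELS %s",
            paste(ensemble$state_labels, collapse = " ")),
    sprintf("REMARK 300 POPULATIONS %s",
            paste(sprintf("%.4f", ensemble$populations), collapse = " ")))
  writeLines(c(remarks, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

#' Read a two-state ensemble from a multi-model PDB file
#'
#' Reads MODEL/ENDMDL conformers (via bio3d) and the state labels and
#' populations from `REMARK 300` lines written by
#' [write_ensemble_pdb()]; files without those remarks load as a
#' single-state ensemble.
#'
#' @param path PDB file path.
#' @return A [two_state_ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  lab_line <- grep("^REMARK 300 STATE LABELS", lines, value = TRUE)
  pop_line <- grep("^REMARK 300 POPULATIONS", lines, value = TRUE)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  confs <- lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(residue = pdb$atom$resno, atom = pdb$atom$elety,
               x = co[, 1], y = co[, 2], z = co[, 3])
  })
  if (length(lab_line) == 1 && length(pop_line) == 1) {
    labels <- as.integer(strsplit(sub(".*STATE LABELS ", "", lab_line),
                                  " ")[[1]])
    pops <- as.numeric(strsplit(sub(".*POPULATIONS ", "", pop_line),
                                " ")[[1]])
    pops <- pops / sum(pops)
  } else {
    labels <- rep(1L, n_models)
    pops <- 1
  }
  two_state_ensemble(confs, labels, pops)
}

#' Write a DEER fit report as JSON
#'
#' Machine-readable summary of a bi-Gaussian fit: parameters,
#' populations, residual RMS and (if present) bootstrap confidence
#' intervals.
#'
#' @param fit A `deer_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "deer_fit"))
  rep <- list(
    model = fit$model[c("r1", "sigma1", "p1", "r2", "sigma2", "p2")],
    amplitudes = as.list(fit$amplitudes),
    background = fit$background[c("kappa", "d")],
    residual_rms = fit$residual_rms,
    populations = list(compact = fit$model$p1, extended = fit$model$p2)
  )
  if (!is.null(fit$ci95))
    rep$ci95 <- list(parameter = colnames(fit$ci95),
                     lower = unname(fit$ci95["lower", ]),
                     upper = unname(fit$ci95["upper", ]))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a distance distribution as two-column ASCII
#'
#' @param dist A [distance_distribution()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distribution_ascii <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# distance distribution: r_angstrom density", con)
  writeLines(sprintf("%.4f %.8e", dist$grid$r, dist$density), con)
  invisible(path)
}

#' @rdname write_distribution_ascii
#' @export
read_distribution_ascii <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  r <- tab[[1]]
  grid <- distance_grid(min(r), max(r), length(r))
  distance_distribution(grid, tab[[2]])
}
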