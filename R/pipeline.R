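#' Pipeline configuration
#'
#' Assembles all tunable settings of the integrative pipeline with
#' defaults equal to the values used throughout the package: distance
#' window 15-80 A (131 points), background bounds 0.02-1 per us and
#' 0.9-1.2, 200 bootstrap samples, +/- 5 A DEER restraint tolerance,
#' restraint weights NOE 1 / DEER 1 / PRE 0.01, 5 A contact cutoff.
#' All randomness flows from the single top-level `seed`.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7, bootstrap_n = 50)
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    grid = list(r_min = 15, r_max = 80, n_points = 131),
    truth = list(r_compact = 22, r_extended = 45, p_compact = 0.7,
                 sigma_label = c(1.5, 8), label_sites = c(15, 90)),
    deer = list(lambda = 0.4, kappa = 0.1, d = 1.0,
                t_max = 2.5, n_points = 251, noise_sigma = 0.005),
    fit = list(n_starts = 8, bootstrap_n = 200, run_bootstrap = FALSE),
    pre = list(tau_c = 8, larmor_h = 600, max_distance = 25),
    restraints = list(tolerance = 5,
                      weights = c(NOE = 1, DEER = 1, PRE = 0.01)),
    optimize = list(n_starts = 8),
    analyze = list(contact_cutoff = 5),
    inputs = list(deer_trace = NULL, relaxation = NULL, restraints = NULL),
    out_dir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the integrative two-state pipeline
#'
#' Executes the full analysis: simulate (or load) measurements, fit the
#' DEER trace, extract state populations, build ensemble-averaged
#' distance restraints (NOE + PRE + DEER effective distance), optimize
#' one- and two-state rigid-body ensembles against them, and analyze
#' the result. When `out_dir` is set, each stage's outputs are written
#' as they complete (trace ASCII, fitted distribution, fit report JSON,
#' restraint files, ensemble PDB, report JSON), so earlier outputs
#' survive a later-stage failure. Reruns with the same configuration
#' are identical.
#'
#' @param config A [pipeline_config()].
#' @return A report list: fitted populations, effective DEER distance,
#'   target functions of the one- and two-state ensembles, recovered
#'   label distances, state classification counts and timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t_start, 3)
    t_start <<- proc.time()[["elapsed"]]
  }
  grid <- distance_grid(config$grid$r_min, config$grid$r_max,
                        config$grid$n_points)

  # -- stage 1: simulate or load ------------------------------------
  truth <- make_two_domain_system(
    seed = config$seed,
    label_sites = config$truth$label_sites,
    r_compact = config$truth$r_compact,
    r_extended = config$truth$r_extended,
    p_compact = config$truth$p_compact,
    sigma_label = config$truth$sigma_label)
  pre_par <- pre_parameters(tau_c = config$pre$tau_c,
                            larmor_h = config$pre$larmor_h,
                            max_distance = config$pre$max_distance)
  meas <- truth_to_measurements(
    truth, noise = list(deer_sigma = config$deer$noise_sigma,
                        rate_sigma = 0),
    seed = config$seed,
    deer_time = seq(0, config$deer$t_max,
                    length.out = config$deer$n_points),
    pathways = pathway_model_4p(config$deer$lambda),
    bg = background_model(config$deer$kappa, config$deer$d),
    pre_params = pre_par)
  if (!is.null(config$inputs$deer_trace))
    meas$deer <- read_deer_ascii(config$inputs$deer_trace)
  if (!is.null(config$inputs$relaxation))
    meas$relaxation <- read_relaxation_csv(config$inputs$relaxation)
  if (!is.null(out)) write_deer_ascii(meas$deer, file.path(out, "deer_trace.dat"))
  tick("simulate")

  # -- stage 2: DEER fit --------------------------------------------
  fit <- fit_bigaussian(meas$deer, grid, n_starts = config$fit$n_starts,
                        seed = config$seed)
  if (isTRUE(config$fit$run_bootstrap))
    fit <- bootstrap_ci(fit, n_samples = config$fit$bootstrap_n,
                        seed = config$seed)
  if (!is.null(out)) {
    write_fit_report(fit, file.path(out, "deer_fit.json"))
    write_distribution_ascii(as_distribution(fit$model, grid),
                             file.path(out, "distribution.dat"))
  }
  tick("fit")

  # -- stage 3: populations -----------------------------------------
  pops <- extract_populations(fit$model)

  # -- stage 4: restraints ------------------------------------------
  r_eff <- effective_deer_distance(as_distribution(fit$model, grid))
  lims <- make_limits(r_eff, config$restraints$tolerance)
  deer_rest <- distance_restraint(
    c(config$truth$label_sites[1], "CB"),
    c(config$truth$label_sites[2], "CB"),
    kind = "DEER", lower = lims[["lower"]], upper = lims[["upper"]],
    weight = config$restraints$weights[["DEER"]])
  tauc_est <- if (all(c("r1", "r2") %in% names(meas$relaxation)))
    estimate_tauc(meas$relaxation$r1, meas$relaxation$r2,
                  larmor_n = config$pre$larmor_h * 0.10136673)$tau_c_mean
  else config$pre$tau_c
  pre_par_used <- pre_parameters(tau_c = tauc_est,
                                 larmor_h = config$pre$larmor_h,
                                 max_distance = config$pre$max_distance)
  pre <- pre_restraints(meas$relaxation, config$truth$label_sites[1],
                        pre_par_used, target_atom = "CA")
  restraints <- c(meas$noes, pre$restraints, list(deer_rest))
  if (!is.null(out))
    write_restraints(restraints, file.path(out, "restraints.upl"))
  tick("restraints")

  # -- stage 5: one- vs two-state optimization ----------------------
  opt1 <- optimize_two_state(truth$domain_a, truth$domain_b, restraints,
                             n_states = 1,
                             n_starts = config$optimize$n_starts,
                             seed = config$seed)
  opt2 <- optimize_two_state(truth$domain_a, truth$domain_b, restraints,
                             n_states = 2,
                             n_starts = config$optimize$n_starts,
                             seed = config$seed)
  if (!is.null(out))
    write_ensemble_pdb(opt2$ensemble, file.path(out, "two_state.pdb"))
  tick("optimize")

  # -- stage 6: analysis --------------------------------------------
  sorted <- classify_states(opt2$ensemble,
                            contact_cutoff = config$analyze$contact_cutoff)
  lab <- config$truth$label_sites
  pair <- list(atom_a = list(residue = lab[1], atom = "CB"),
               atom_b = list(residue = lab[2], atom = "CB"))
  state_dist <- vapply(opt2$ensemble$conformers, function(cf) {
    a <- atom_xyz(cf, lab[1], "CB"); b <- atom_xyz(cf, lab[2], "CB")
    sqrt(sum((a - b)^2))
  }, numeric(1))
  tick("analyze")

  report <- list(
    populations = as.list(pops),
    fit = list(r1 = fit$model$r1, sigma1 = fit$model$sigma1,
               p1 = fit$model$p1, r2 = fit$model$r2,
               sigma2 = fit$model$sigma2,
               residual_rms = fit$residual_rms),
    effective_deer_distance = r_eff,
    n_restraints = length(restraints),
    tf_one_state = opt1$report$tf,
    tf_two_state = opt2$report$tf,
    two_state_preferred = opt2$report$tf < opt1$report$tf,
    high_single_state_tf = opt1$report$tf > 10 * max(opt2$report$tf, 1e-6),
    state_label_distances = state_dist,
    n_compact_conformers = length(sorted$compact),
    truth = list(r_compact = truth$r_compact_achieved,
                 r_extended = truth$r_extended_achieved,
                 p_compact = truth$p_compact),
    timings_s = as.list(timings),
    seed = config$seed
  )
  if (!is.null(out))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
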