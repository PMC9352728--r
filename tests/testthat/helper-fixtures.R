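# Shared fixtures: small, fast objects rebuilt in code at test time.

default_time <- function(n = 251, t_max = 2.5) seq(0, t_max, length.out = n)

# Canonical apo-like two-state model used across tests.
apo_model <- function() bigaussian_model(22, 1.5, 0.68, 45, 8)

canonical_trace <- function(model = apo_model(), lambda = 0.4,
                            kappa = 0.1, d = 1, time = default_time(),
                            noise_sigma = 0, seed = NULL) {
  simulate_trace(model, pathway_model_4p(lambda),
                 background_model(kappa, d), time,
                 noise_sigma = noise_sigma, seed = seed)
}

# Tiny two-domain conformer: a fixed pair of residues per domain with
# hand-placed coordinates, for restraint arithmetic tests.
toy_conformer <- function(shift_b = c(0, 0, 0)) {
  data.frame(
    residue = c(1L, 1L, 2L, 50L, 50L),
    atom = c("CA", "CB", "CA", "CA", "CB"),
    x = c(0, 1.5, 3.8, 10, 11.5) + c(0, 0, 0, shift_b[1], shift_b[1]),
    y = c(0, 0, 0, 0, 0) + c(0, 0, 0, shift_b[2], shift_b[2]),
    z = c(0, 0, 0, 0, 0) + c(0, 0, 0, shift_b[3], shift_b[3])
  )
}

# Two-state ensemble whose label pair (1.CB - 50.CB) sits at exactly
# the given distances in the two states.
toy_two_state <- function(d1, d2, p1 = 0.5) {
  conf_at <- function(d) data.frame(
    residue = c(1L, 50L), atom = c("CB", "CB"),
    x = c(0, d), y = c(0, 0), z = c(0, 0))
  two_state_ensemble(list(conf_at(d1), conf_at(d2)), c(1, 2),
                     if (p1 < 1) c(p1, 1 - p1) else 1)
}

label_pair <- function(res_a = 1L, res_b = 50L)
  list(atom_a = list(residue = res_a, atom = "CB"),
       atom_b = list(residue = res_b, atom = "CB"))
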