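---
title: "Quantifying a two-domain conformational equilibrium from DEER and ensemble-averaged restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a two-domain conformational equilibrium from DEER and ensemble-averaged restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerens)
```

## The problem

Many signaling proteins consist of two folded domains joined by a
flexible linker. The prolyl isomerase Pin1 is the canonical example: a
small WW binding domain (residues 1–39) and a larger catalytic PPIase
domain (residues 50–163) exchange between a *compact* state, with a
specific interdomain interface, and an *extended* state in which the
domains tumble semi-independently. The position of this equilibrium —
roughly 70:30 compact:extended for the apo protein, shifted toward
extended by some phosphopeptide ligands — controls catalytic activity,
so measuring the state populations and the geometry of both states is
the central analysis task.

No single measurement determines both. This package implements the
integrative strategy used for such systems:

1. **DEER (double electron–electron resonance)** on spin-labeled double
   mutants measures the full interspin distance distribution between
   labels on the two domains, resolving both states and their
   populations directly (15–80 Å window, frozen solution).
2. **PRE (paramagnetic relaxation enhancement)** gives shorter-range
   (≤ 25 Å), population-averaged label-to-amide distances in solution.
3. **Interdomain NOEs** report contacts (< ~5 Å) that exist only in the
   compact state.
4. A **two-state ensemble calculation** places rigid domain copies so
   that the *population-weighted averages* of back-calculated distances
   satisfy all restraints simultaneously; the drop in the target
   function from one to two states is the evidence that two states are
   required.

Every stage is testable against a synthetic ground truth generated by
the package itself.

## DEER forward model

The modulated echo of a spin pair at distance $r$ is, after powder
averaging over orientations $x = \cos\theta$,

$$K(t, r) = \int_0^1 \cos\!\big[(1 - 3x^2)\,\omega_{dd}(r)\,t\big]\,dx,
\qquad \omega_{dd}(r) = \frac{2\pi \cdot 52.04\ \mathrm{MHz}}{(r/\mathrm{nm})^3},$$

which `dipolar_kernel()` evaluates in closed form through Fresnel
integrals (series expansion below a phase of $10^{-3}$; accuracy
$10^{-6}$ against brute-force quadrature). A measured trace adds an
unmodulated fraction, a stretched-exponential background
$B(t) = e^{-\kappa |t|^d}$ from the surrounding spin bath, and noise:

$$V(t) = \Big[\Lambda_0 + \textstyle\sum_k \lambda_k \int P(r)\,
K(t - T_0^{(k)}, r)\,dr\Big]\, B(t).$$

The single-pathway (4-pulse) model has one modulation depth $\lambda$;
the 5-pulse variant adds a secondary artefact pathway refocusing at a
configurable $T_0^{(2)}$ (default: the trace midpoint, since published
experiment descriptions give the pathway structure but rarely the
numeric refocusing times). With several pathways the background is
applied as a product of per-pathway stretched exponentials with
$\kappa$ scaled by each amplitude — the convention of the established
dipolar-analysis frameworks; with one pathway it is the plain $B(t)$
above. Distances are Å and times µs everywhere at the interface;
conversion to nm happens only inside $\omega_{dd}$.

## Inference: bi-Gaussian fit and regularized inversion

Two complementary inversions are provided.

**Parametric.** `fit_bigaussian()` fits
$(r_1, \sigma_1, p_1, r_2, \sigma_2, \lambda, \kappa, d)$ jointly by
bounded Levenberg–Marquardt least squares. The background bounds
($\kappa \in [0.02, 1]\ \mu s^{-1}$, $d \in [0.9, 1.2]$) are the
defaults throughout. Components are sorted so index 1 is always the
compact (shorter) state. Two design points matter:

* *Multi-start with tail initialization.* The modulation depth and
  background are first estimated from the trace tail
  (`fit_deer_background()`); distribution parameters are then started
  from one deterministic heuristic plus seeded random draws.
* *Profiling over the stretch exponent.* $(\kappa, d, \lambda)$ lie on
  a nearly flat ridge, and joint optimization reliably stalls at a
  boundary stationary point with $d$ pinned at a bound and a biased
  population. Each start therefore runs twice: first with $d$ frozen
  at a ladder value (1.0, 0.9, 1.1, 1.2, …), then released. On
  noiseless synthetic traces this recovers ground truth to machine
  precision, where the unprofiled fit leaves population errors of
  2–3 points.

**Parameter-free.** `tikhonov_solve()` minimizes
$\|V - KP\|^2 + \alpha^2 \|L_2 P\|^2$ subject to $P \ge 0$ ($L_2$ the
second-difference operator) via Lawson–Hanson non-negative least
squares on the stacked system, with $\alpha$ chosen by generalized
cross-validation (`gcv_select()`). The GCV influence matrix comes from
the unconstrained solve — the constrained solve has no closed-form
trace, and this substitution is the usual approximation. Because the
early-time rows of the dipolar kernel carry most of the information,
leverage across trace points is strongly non-uniform, so GCV is *not*
numerically close to brute-force leave-one-out error; it does select a
regularization weight within one log-grid step of the LOO optimum,
which is what the tests assert.

**Uncertainty.** `bootstrap_ci()` resamples residuals (200 samples by
default, which is where the intervals converge) and refits from the
point estimate; percentile intervals are the default, the basic
(reversed percentile) form is an option, and both are clipped to the
parameter box. Typical population intervals are about ±0.03.

A calibration caveat, established by simulation with known truth: the
population parameter inherits the background ridge's nonregularity.
Because refits start from the point estimate they rarely hop between
the stretch-exponent basins the full estimator explores, so the
bootstrap draws under-disperse (draw sd ≈ 0.017 against an estimator
sd ≈ 0.024 across replicates at the default trace design), and
measured 95% coverage of a known compact population is ~66–86%
depending on trace length and interval type — below nominal. The
component centers are regular and cover at the nominal rate. A
bootstrap that re-runs the complete multi-start profiled estimator for
every resample restores coverage in spot checks but is two orders of
magnitude slower, so it is not the default; treat population intervals
as optimistic. Published intervals from the same residual-resampling
scheme share this property.

**Populations.** `extract_populations()` returns $(p_1, 1 - p_1)$ for
a parametric model; for a gridded distribution it integrates the
density on either side of a split placed at the density minimum
between the two highest modes (`split = "auto"`), and refuses to guess
for unimodal densities.

```{r, fig.width = 6, fig.height = 4}
truth <- bigaussian_model(r1 = 22, sigma1 = 1.5, p1 = 0.68,
                          r2 = 45, sigma2 = 8)
trace <- simulate_trace(truth, pathway_model_4p(0.4),
                        background_model(0.1, 1),
                        time = seq(0, 2.5, length.out = 251))
fit <- fit_bigaussian(trace, n_starts = 4)
fit
g <- distance_grid()
plot(g$r, as_distribution(fit$model, g)$density, type = "l",
     xlab = "r (A)", ylab = "P(r) (1/A)",
     main = "Recovered two-state distance distribution")
```

## PRE distances

The transverse enhancement $R_2^{sp} = R_{2,\mathrm{para}} -
R_{2,\mathrm{dia}}$ converts to a distance through the
Solomon–Bloembergen relation

$$r = \left[\frac{K}{R_2^{sp}}\left(4\tau_c +
\frac{3\tau_c}{1 + \omega_H^2 \tau_c^2}\right)\right]^{1/6},$$

with $K = 1.23\times10^{-32}\ \mathrm{cm^6\,s^{-2}}$ (the standard
nitroxide–proton dipolar constant; the literature cites it rather than
reprinting it) and a single global $\tau_c$ — the trimmed mean of the
per-residue estimates $\tau_c = \sqrt{6R_2/R_1 - 7}/(4\pi\nu_N)$ —
because the restraints are interdomain and tumbling is reported at
domain level. Distances beyond 25 Å are *excluded*, not capped: the
$r^{-6}$ dependence makes longer distances unreliable, and an
unreliable restraint is worse than none. Because the estimator inverts
the reduced spectral-density model ($J(0)$ and $J(\omega_N)$ terms
only), the synthetic generator produces rates from that same model, so
the round trip is exact by construction; on real data the neglected
high-frequency terms bias $\tau_c$ by a few percent.

## Ensemble-averaged restraints and the two-state target function

Restraints never apply to a single conformer. For a restraint between
atoms $a, b$ the back-calculated distance of a two-state ensemble is

$$r_{\mathrm{eff}} = \Big(\sum_s p_s\, r_s^{-6}\Big)^{-1/6}
\quad\text{(NOE, PRE)} \qquad
r_{\mathrm{eff}} = \sum_s p_s\, r_s \quad\text{(DEER)},$$

where $r_s$ is the mean distance over the conformers of state $s$.
DEER effective distances $\langle r \rangle = \int r P(r)\,dr$
(`effective_deer_distance()`) are already population averages of a
distance, hence linear averaging — a modeling choice documented here,
since experiment papers rarely state it. Each effective distance
becomes a flat-bottom restraint with ±5 Å tolerance
(`make_limits()`), weight 1; PRE restraints carry weight 0.01 against
the NOE weight of 1. The target function is the weighted sum of
squared violations (Å²), zero inside the bounds.

`optimize_two_state()` replaces a full torsion-angle annealing engine
with rigid-body placement of the mobile domain (6 degrees of freedom
per state plus the state populations, bounded to [0.05, 0.95]),
minimized by seeded multi-start L-BFGS-B. This is deliberate: the
question "is one state enough?" is about the *joint infeasibility of
interdomain restraints*, which rigid bodies expose at desk scale, with
intradomain geometry untouched by construction. The absolute target
function of a full structure-calculation engine is not reproduced —
only the order-of-magnitude contrast between one- and two-state fits
is meaningful here, and that is what the tests assert (a ≥ 20-fold
drop on restraint sets that combine compact-state NOEs with an
extended DEER distance).

With a *single* label pair, satisfying the averaged DEER distance
pins only a one-dimensional combination of the two placements: the
one-state/two-state contrast appears when the DEER effective distance
is long (extended-shifted equilibria), while a 70:30 compact-dominated
restraint set with one label pair is genuinely satisfiable by one
placement. This is a property of the restraint content, not a failure
of the optimizer; the published analyses rely on several label pairs.

## Synthetic ground truth

`make_two_domain_system()` builds CA+CB bead-chain domains (3.8 Å
virtual bonds collapsed into globules of protein-like radius) —
synthetic stand-ins chosen so no structure download is ever required —
and solves compact and extended rigid placements such that the
label-site CB–CB distance hits 22 Å with interdomain contact (< 5 Å)
and 45 Å with clearance (≥ 8 Å), respectively, by root-finding over an
approach translation and a spin angle. Defaults (70:30 populations,
σ of 1.5 Å for the contact-locked compact state and 8 Å for the
loosely tethered extended state, λ = 0.4, κ = 0.1 µs⁻¹, d = 1, noise
ladder 0–0.02) reproduce the regime of the published measurements.
`truth_to_measurements()` then emits all four data types with the
*same* statistical structure the analysis assumes: DEER from the
mixture distribution, PRE rates from the forward Solomon–Bloembergen
equation on $r^{-6}$-averaged distances, NOEs only for compact-contact
pairs, couplings from the Karplus relation. Synthetic tests therefore
verify implementation correctness, not model adequacy on real data:
they cannot detect label-rotamer effects, anisotropic tumbling,
orientation selection, multispin effects, or non-Gaussian state
distributions, all of which real measurements contain.

## Numerical choices

* Default grid 15–80 Å, 131 points (0.5 Å): matching the detection
  window; fine enough for σ ≥ 1 Å components (narrower synthetic
  components in oracle tests use a 0.25 Å grid).
* Kernel: Fresnel closed form, series below phase $10^{-3}$.
* Non-negative solve: Lawson–Hanson active set (`pracma::lsqnonneg`).
* Optimizer tolerances: LM `ptol = ftol = 1e-12`, 500 iterations;
  bootstrap refits 200 iterations from the point estimate.
* Tie-breaks: best-of-starts by deviance; component order by center.
* Degenerate inputs error early (constant traces, < 8 points,
  unimodal auto-split, missing atoms named in the message).
* Problem sizes in the test-suite simulations (trace lengths 121–251,
  50 coverage replicates, 200 bootstrap samples, 8 optimizer starts)
  are chosen so the full suite runs on a laptop-class single core in
  minutes while leaving every statistical check at its stated
  tolerance.

## Limitations

* The rigid-body surrogate cannot report intradomain rearrangements;
  per-residue RMSD profiles (`rmsd_profile()`) are meaningful only
  between ensembles computed with a full engine or between synthetic
  states.
* GCV is a selection rule here, not an estimate of out-of-sample error
  (see above).
* PRE conversion assumes a single isotropic $\tau_c$ and no internal
  label motion.
* The 5-pulse artefact pathway is modeled, but nuclear modulation and
  orientation selection are out of scope.
* Distances are referenced to labeled-residue Cβ atoms throughout, the
  convention used for the published effective-distance restraints;
  rotamer-cloud averaging of the label position is not modeled.
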