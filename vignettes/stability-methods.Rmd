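---
title: "Estimating mutation-induced stability changes with biased sampling and constrained-entropy reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation-induced stability changes with biased sampling and constrained-entropy reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmec)
```

## The problem

A single-point mutation changes how much reversible work it takes to
unfold a protein.  The quantity of interest is

$$\Delta\Delta G \;=\;
 \bigl[G_X(s_\mathrm{unf}) - G_X(s_\mathrm{fold})\bigr] -
 \bigl[G_0(s_\mathrm{unf}) - G_0(s_\mathrm{fold})\bigr],$$

where $G_X$ and $G_0$ are free energies of the variant and the reference
sequence as functions of a structural order parameter $s$, and the two
states are the folded and unfolded ends of the transition.  A positive
$\Delta\Delta G$ means the variant needs more work to unfold — a
stabilizing mutation — and its sign tracks the sign of the
melting-temperature shift measured in thermal-denaturation experiments.
`stabmec` implements the full statistical machinery of this estimate at
desk scale: the collective variable, the biased sampler, the
maximum-entropy post-processing and the mean-field solute energy.

## The collective variable

The order parameter is a *switched count of native hydrogen bonds*.  For
each donor-N/acceptor-O pair listed in a pair table the contribution is
the rational switch

$$f(r) = \frac{1 - x^{n}}{1 - x^{m}}, \qquad x = \frac{r - d_0}{r_0},$$

continuously extended to $n/m$ at $x = 1$.  Defaults are $r_0 = 2.5$ Å,
$d_0 = 0$, $n = 8$, $m = 12$ on the heavy-atom N–O distance; hydrogens
are ignored.  The switch is total on $r \ge 0$, bounded in $[0,1]$, and
monotonically non-increasing beyond $d_0$, so the CV is bounded by the
number of pairs and invariant under rigid-body motion.  These switching
constants are a configurable stand-in — the literature uses several
variants of the rational switch — and every function takes a
`switching_params` object.

For the 58-residue reference protein the native pair list
(`bpti_hbond_pairs()`) has 16 pairs — 8 in the β-sheet, 3 in helix α1, 5
in helix α2 — so ξ spans 0…16.  Pair selectors match residue *number*
and atom name only, never residue name, so the same table applies to
point variants whose backbone N/O atoms survive the mutation.  For
larger proteins the biased CV may cover only the β-sheet while the
reweighting constrains the *extended* variable ξ′ = β + α; this is the
`cv = "xi_prime"` column switch in the MEC functions.

## Well-tempered metadynamics

The sampler deposits repulsive Gaussians of width δ on visited CV values
every $\tau_G$; under well-tempering the deposited height shrinks with
the bias already accumulated,

$$h = w\,e^{-V_G(s)/k_B\Delta T},$$

so the bias converges to $-\frac{\Delta T}{T+\Delta T}F(s)$ up to a
constant and the free energy follows from
$F(s)-F(s_0) = -\frac{T+\Delta T}{\Delta T}\bigl(V_G(s)-V_G(s_0)\bigr)$.
The biasing factor $(T{+}\Delta T)/T$ defaults to 20, i.e.
$\Delta T = 5700$ K at $T = 300$ K; $R\,\Delta T$ is then of the order
of a single hydrogen-bond barrier, which is what the CV granularity
calls for.  Gaussian height and width are not dictated by theory; the
defaults $w = 1$ kJ/mol and δ = 1 CV unit (one hydrogen bond) are
mandatory, explicit fields of `wt_params()`.  Two deposition paces are
in common use, 20 ps and 10 ps; both are presets and `tau_G` is always
explicit.

**Multiple walkers and altruistic sharing.**  A swarm of walkers builds
the bias jointly.  Every `exchange_ns` (default 2 ns) each walker's bias
is replaced by the convex combination

$$V_i' = (1-\alpha)V_i + \alpha\bigl[w\,V_i + (1-w)\,\bar V\bigr],$$

with $\bar V$ the swarm mean.  The production staging
(`table_schedule()`) is: 8 ns of bias-free equilibration; four 2-ns
stages with $\alpha$ ramped through 0, 1/4, 1/2, 3/4 at self-share
$w = 1$; 14 ns at full mixing $\alpha = 1$, $w = 1/2$; then the biases
are averaged into one (`average_bias_final()`) and frozen while the
metastatistics is collected (10–30 ns, frames every ps).  Bias-updated
stages therefore total 22 ns and the staging through construction
30 ns.  The exact combination rule used by the multi-walker literature
is not uniquely fixed; the rule above is the package's documented
default and `altruistic_combine()` accepts any replacement through its
`rule` argument.  We read the $w$ column of the staging table as the
sharing weight, not as a rescaling of the Gaussian height, since it
enters the bias exchange and not the deposition.

**Toy sampler.**  Real deployments take the CV series and bias from an
MD engine (the COLVAR/HILLS text dialect is read and written natively).
For testing, `run_toy_walker()` integrates overdamped Euler–Maruyama
Langevin dynamics on analytic one-dimensional landscapes:
$s_{t+1} = s_t - \gamma^{-1}\partial_s[F+V_G]\,\mathrm{d}t +
\sqrt{2k_BT\,\mathrm{d}t/\gamma}\,\eta$, with reflecting walls.  Only
the bias and reweighting logic are under test, not integrator accuracy,
so first-order integration suffices.  Defaults $\gamma = 2$ ps$^{-1}$
and $\mathrm{d}t = 0.02$ ps keep the scheme stable
($\mathrm{d}t\,F''_{\max}/\gamma \approx 0.13$ at the default landscape
curvature) while letting the CV diffuse across the filled landscape
many times per nanosecond.  The bias lives on a uniform grid (0.1 CV
units) so force evaluation is O(1); hill deposition updates the grid
exactly, and the cached grid is asserted against the analytic Gaussian
sum on its nodes.  Runs are bitwise reproducible from the system seed.

The convergence check used throughout is that
$V_G + \frac{\Delta T}{T+\Delta T}F$ is constant over the sampled
region.  On the 15 kJ/mol double well with biasing factor 20 and $10^6$
steps (14 ns construction, 10 ps pace + 6 ns frozen-bias collection)
the RMSD of that combination stays below 0.5 $k_BT$ over the region
whose collection-stage occupancy exceeds 1% of the modal bin; the
frozen-bias frames, reweighted by $e^{+V_G/k_BT}$, recover the
symmetric well populations within ±0.1, the Monte-Carlo error we
allow for a correlated 6-ns trajectory (a few hundred effective
samples).

## Maximal-constrained-entropy reweighting

The frozen-bias frames form the *metastatistics*
$\tilde P_\gamma = \tilde w_\gamma/\sum\tilde w$ (multiplicities default
to 1; a multiplicity column supports pre-aggregated histograms).  For a
target mean $\langle\xi\rangle = s$ the distribution closest to
$\tilde P$ in Kullback–Leibler divergence is the exponential tilt

$$P_\gamma = \frac{\tilde P_\gamma\,e^{-\lambda\xi_\gamma}}{Z_\lambda},
\qquad
Z_\lambda = \sum_\gamma \tilde P_\gamma e^{-\lambda\xi_\gamma},$$

with λ solving $\langle\xi\rangle_\lambda = s$.  Because
$\mathrm{d}\langle\xi\rangle_\lambda/\mathrm{d}\lambda =
-\mathrm{Var}_\lambda(\xi) < 0$, the map is strictly decreasing and a
geometrically expanded bracket followed by bisection converges globally
— robustness was preferred over Newton steps.  The solver tolerance is
$10^{-10}$ of the CV range; all exponential sums are max-shifted
log-sum-exp, since λξ reaches hundreds for sharp constraints.  At the
solution the maximal cross-entropy obeys two identities that the code
computes *both* ways and asserts equal:
$\bar S_c = \ln Z_\lambda + \lambda s = -\sum_\gamma P_\gamma
\ln(P_\gamma/\tilde P_\gamma) \le 0$, with equality only at the
unconstrained mean.  The free energy of the constrained macrostate is

$$G(s) = \langle \bar U\rangle_\lambda - T_\mathrm{eff}\,k_B\,\bar S_c(s),$$

where $\langle\bar U\rangle_\lambda$ is the tilted average of the
per-frame mean-field energy.  The identification of the informational
entropy with a thermodynamic one is empirical, so $T_\mathrm{eff}$ is
an explicit argument everywhere (default 300 K, the simulation
temperature).  Profiles are referenced to $G(s_0)=0$; per-point
uncertainty is a leave-one-walker-out jackknife over the walker labels,
the natural blocking unit of a multi-walker run.  How the original
error bars on such profiles were computed is not fully specified in the
method literature we follow; the jackknife is our documented choice.

## Mean-field MM/PBSA energy

Per configuration the effective solute energy is
$\bar U = U_\mathrm{intra} + G_\mathrm{solv,np} + G_\mathrm{solv,pol}$.
The five intramolecular force-field terms (stretch, bend, torsion,
Lennard-Jones, Coulomb) are *consumed, not computed* — implementing a
biomolecular force field is out of scope; the statistical machinery is
the contribution, and the synthetic generator supplies consistent term
tables for testing.

*Nonpolar term:* $G_\mathrm{solv,np} = \sum_i \sigma_i\,\mathrm{SASA}_i$
with per-atom coefficients (positive hydrophobic, negative
hydrophilic); a single-value default of 0.0226 kJ/mol/Å$^2$ applies
when no override table is given.  SASA is Shrake–Rupley on a
deterministic Fibonacci sphere (default 960 points, probe 1.4 Å), so
results are exactly reproducible and rotation tests can co-rotate the
point set.

*Polar term:* a finite-difference linearized Poisson–Boltzmann solve on
a uniform lattice: 7-point stencil, harmonic-mean face dielectrics,
trilinear charge spreading, Dirichlet boundaries from the Debye–Hückel
superposition of the atomic charges, and a second uniform-dielectric
solve with identical charge spreading whose subtraction cancels the
grid self-energy.  The linear system is symmetric positive definite, so
we solve it with Jacobi-preconditioned conjugate gradients (relative
residual $10^{-8}$) rather than successive over-relaxation: CG needs no
relaxation-parameter tuning and vectorizes cleanly over the lattice.
The solute dielectric region is the van der Waals union of the atom
spheres with the interface smoothed linearly over one grid cell and
blended harmonically; a sharp staircase boundary makes the
discretization error oscillate with node alignment, while the smoothed
interface restores a monotone decrease under refinement (the Born-ion
error falls monotonically through spacings 0.8, 0.4, 0.2 Å and is
within 5% of the analytic value at 0.4 Å).  Grid spacing, permittivities
(defaults $\varepsilon_\mathrm{in}=1$, $\varepsilon_\mathrm{out}=80$),
screening constant (default $\kappa = 0$; set it for saline
environments) and the probe-inflated boundary option are all explicit
`pb_grid` fields, since the upstream method literature defers these choices
to their references.

## The pipeline

`run_pipeline()` ingests a reference and any number of variant
ensembles, histograms the CV on unit bins, selects the folded state as
the highest peak and the unfolded state as the highest remaining local
maximum at least 5 CV units away (3-bin moving-average smoothing,
deterministic tie-break toward lower $s$; published state conventions
such as folded $s=14$/unfolded $s=4$, or ξ′ 37/21, are reproducible
verbatim through the `states` override).  It then computes MEC profiles
on a shared grid, $\Delta\Delta G$ per variant, per-term energy deltas
(tilted averages of any term columns present, unfolded minus folded),
and — when a bias grid is supplied — the direct metadynamics route
$-\frac{T+\Delta T}{\Delta T}\Delta V_G$, optionally through a
least-squares quartic interpolant with C$^1$ linear tails.  Both ΔΔG
routes are always reported side by side because they can legitimately
disagree when the biased CV misses slow degrees of freedom; the
discrepancy is diagnostic, not an error.  Reports serialize to
JSON/TSV byte-identically for fixed inputs and seed.

## What the synthetic generator does and does not emulate

`ensemble_spec()`/`sample_metastatistics()` draw CV values from a
bimodal truncated-Gaussian mixture — a sharp folded peak at $s=14$
(s.d. 0.8) and a broad unfolded one at $s=4$ (s.d. 1.5), equal weights
on $[0,16]$ — mimicking the shape of a real frozen-bias metastatistics.
Energies are $U(\xi) = 3(14-\xi) + \Delta\,
\frac{14-\xi}{10} + \mathcal N(0,\sigma_E)$ with $\sigma_E = 2$ kJ/mol
by default, walker labels round-robin over 90 walkers to mirror the
production swarm.  Because the stability gap Δ enters *linearly* in ξ,
its tilted average at any constraint $\langle\xi\rangle = s$ is exactly
$\Delta\,(14-s)/10$, independent of the proposal and of λ: the injected
ΔΔG between a gap-Δ ensemble and a gap-0 reference is *exactly* Δ in
the infinite-sample limit.  This is the generator-is-oracle property
the recovery tests score, complemented by `g_star()`, which computes
the exact large-sample MEC free energy by dense quadrature on the
analytic proposal density (4001 nodes), independently of any sampled
frames.

What passing these tests shows: the tilt solver, the entropy
identities, the jackknife and the ΔΔG bookkeeping are correct, and
recovery converges at the advertised rate.  What they do not show: that
a hydrogen-bond CV captures all slow degrees of freedom of a real
protein, that the mean-field energy is an adequate surrogate for the
explicit-solvent enthalpy, or that 90 × 30 ns of real sampling
converges — those are properties of the simulation data fed to the
package, not of the statistics implemented here.  The toy peptide
generator likewise produces geometric fixtures (donor–acceptor pairs
packed well inside the switching radius, or stretched beyond 8 Å), not
physical peptide conformers.

## Numerical choices and degenerate inputs

* λ-solver: bracket expansion capped, then bisection to $10^{-10}$ of
  the CV range; targets outside the open support hull raise an
  explicit unreachable-target error; degenerate (single-valued) CVs are
  rejected.
* Unreachable profile grid points are skipped with a warning and
  returned as `NA`, never silently dropped.
* Quartic bias interpolation uses a QR least-squares fit on a centered
  basis (at least 5 nodes required) with analytic-derivative linear
  tails; the fit is checked against a normal-equations oracle in the
  tests.
* The toy integrator raises a diagnostic error if the CV leaves the
  reflecting domain (timestep too large for the landscape curvature).
* PB solves reject solutes closer than the declared margin (5 Å) to
  the box boundary; the all-zero-charge case short-circuits to zero.
* Histogram normalization is exact by construction
  ($\sum_i P_i = 1$); single-frame series give a single unit bin.

## Problem sizes used in the shipped checks

The package's own validation runs at sizes a laptop handles in minutes:
$10^6$-step toy metadynamics ($10^5$ frozen-bias frames), MEC recovery
on $10^5$-frame ensembles with 90 walkers, 100-replicate sign studies
at a 5 kJ/mol gap, Born-ion lattices up to 71³ nodes, and ≤12-frame
ensembles for the brute-force entropy-maximization cross-check.  These
sizes were chosen so every advertised tolerance (0.5 $k_BT$ bias
convergence, 3-jackknife-SE recovery, 5% Born error, $10^{-7}$
brute-force agreement) is met with margin at fixed seeds, while the
whole suite stays fast enough to run on every change.

## Known limitations

* Single scalar constraint only; no multi-CV maximum-entropy
  reweighting.
* Strictly post-processing: the modulation never feeds back into the
  sampler.
* No nonlinear PB, no molecular (reentrant) surface, no solute
  vibrational entropy, no explicit ions.
* The altruistic combination rule and the switching-function constants
  are documented stand-ins where the upstream literature leaves the
  exact form unspecified; both are pluggable.
* ΔT_m magnitudes are out of scope — the method maps the *sign* of the
  stability change.
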