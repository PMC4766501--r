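---
title: "Methods: from binding kinetics to Phi-restrained transition-state ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binding kinetics to Phi-restrained transition-state ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many intrinsically disordered proteins (IDPs) acquire structure only
upon binding a folded partner.  `templefold` implements a complete
analysis chain for characterising the transition state (TS) of such a
coupled folding-and-binding reaction, in the mould of the classical
study of a short helical transactivation peptide binding a small
globular receptor domain:

1. observed binding rates from stopped-flow fluorescence traces,
2. association/dissociation rate constants from pseudo-first-order
   series,
3. mutational free-energy changes, Phi values and the Bronsted (LFER)
   alpha,
4. TS ensembles from Phi-restrained sampling of a structure-based
   model,
5. ensemble statistics (fluctuation, contact frequencies, hydrophobic
   SASA) and their cross-correlations.

The headline scientific question the chain can address is whether the
disordered chain folds through a robust, partner-independent nucleus
(as globular proteins do) or whether its folding is *templated* — its
TS structure dictated by the partner's binding surface, so that
perturbing the partner reshapes the folding pathway.

# Kinetic model

Under pseudo-first-order conditions (ligand in large excess over the
probe) binding relaxes as a single exponential with

$$k_\mathrm{obs} = k_\mathrm{on}\,[L] + k_\mathrm{off}.$$

`fit_single_exponential()` fits `offset + A exp(-k t)` by
Gauss–Newton least squares, initialised deterministically (rate from a
log-linearised early decay, amplitude/offset from the endpoints);
standard errors come from the Jacobian covariance with a
residual-resampling bootstrap (`bootstrap_k_obs()`) as an independent
cross-check.  `fit_pseudo_first_order()` then regresses the observed
rates on concentration: the slope is $k_\mathrm{on}$
(µM⁻¹ s⁻¹), the intercept — a linear extrapolation to zero ligand —
is $k_\mathrm{off}$ (s⁻¹).  A negative intercept is reported but
flagged rather than clipped.

Design choices worth knowing:

* **Validity guard.** Ligand/probe ratios below 2 are refused; below
  10 a warning marks the pseudo-first-order approximation as marginal.
* **Replicates enter individually.** `fit_trace_set()` regresses every
  replicate's $k_\mathrm{obs}$ rather than per-concentration means.
  With 5 concentrations and 3–6 replicates this leaves the residual
  degrees of freedom needed for honest standard errors; averaging
  first gave 3-SE coverage of only ~82–90% in simulation, versus
  ~97% for the per-replicate design.  Weighting by replicate variances
  is available but off by default (with 2 df per concentration the
  weights are noisier than the data).

# Energetics: Phi values and the LFER

With $K_D = k_\mathrm{off}/k_\mathrm{on}$ and $R = 1.98720425\times
10^{-3}$ kcal mol⁻¹ K⁻¹ (natural logarithms, $T = 283.15$ K for
experiments at 10 °C):

$$\Delta\Delta G_\mathrm{eq} = RT\,\ln\!\frac{K_D^\mathrm{mut}}{K_D^\mathrm{wt}},
\qquad
\Delta\Delta G^{\ddagger} = RT\,\ln\!\frac{k_\mathrm{on}^\mathrm{wt}}{k_\mathrm{on}^\mathrm{mut}},
\qquad
\Phi = \frac{\Delta\Delta G^{\ddagger}}{\Delta\Delta G_\mathrm{eq}}.$$

Destabilisation is positive on both axes, so $\Phi \approx 1$ marks a
contact already formed in the TS and $\Phi \approx 0$ one that forms
only afterwards.  Because the ratio explodes for small perturbations,
variants with $|\Delta\Delta G_\mathrm{eq}| < 0.4$ kcal mol⁻¹ (the
customary threshold, exposed as a parameter) carry no Phi value at
all: `phi_value()` marks them excluded rather than propagating an
unstable number.

`lfer_fit()` regresses $\Delta\Delta G^{\ddagger}$ on
$\Delta\Delta G_\mathrm{eq}$ by ordinary least squares; the slope is
the Bronsted $\alpha$ (0 reactant-like, 1 product-like) and the
intercept is reported in kcal/mol — a detectably non-zero offset can
indicate kinetically silent steps in the recognition mechanism.
Uncertainties are case-resampling bootstrap standard deviations
(default 1000 replicates, seed mandatory; degenerate resamples with
fewer than 3 distinct abscissae are redrawn).  Two deliberate
decisions:

* **Phi-excluded variants stay in the LFER.**  The 0.4 kcal/mol rule
  protects the *ratio*; the individual free energies of small
  perturbations are fine, and the LFER plots free-energy pairs.  The
  stricter mode is available (`use_excluded = FALSE`).
* **The TS axis uses association rates only** ($k_\mathrm{on}$),
  matching the TS-for-binding framing; a dissociation-side variant
  (`ddG_ts_off()`) exists but is not the default.
* **The ~0.5 kcal/mol offset** is interpreted as the *y*-intercept of
  the $\Delta\Delta G^{\ddagger}$ vs $\Delta\Delta G_\mathrm{eq}$
  fit (the x-intercept reading would differ; this choice is
  documented rather than resolved by the data).

# Structure: native contacts and SASA

`native_contacts()` implements the contact rule used throughout: for
every residue pair that is not nearest neighbours (different chains,
or $|i-j| > 1$ within a chain), the number of heavy side-chain atom
pairs strictly within 0.65 nm in the native structure.  Glycine,
which the rule would otherwise orphan, contributes its CA as a
side-chain proxy.  Strict inequality at the cutoff is part of the
contract so that brute-force oracles match bit-exactly.

`mutate_residue()` is deletion-only (I→V drops one carbon, L→A keeps
CB): the conservative hydrophobic substitutions this analysis uses are
all deletions, and rotamer building is out of scope.  Growth mutations
raise an explicit error directing users to supply a pre-built
structure.

`hydrophobic_sasa()` is a Shrake–Rupley implementation (Fibonacci
sphere lattice, default 960 points/atom, Bondi radii, 0.14 nm probe)
summed over the side-chain atoms of a declared binding-site residue
set.  It is validated against analytic one- and two-sphere cases.  An
ensemble-averaged mode (`ensemble_sasa()`) approximates coarse-grained
sites by single spheres (side-chain radius $0.23\,n^{1/3}$ nm for $n$
heavy atoms) and averages over a native-reference ensemble; this is
the default mode in the pipeline, the static single-structure value
being the alternative.

# The sampling engine and its substitution

The reference protocol determines TS ensembles by restrained
all-atom molecular dynamics in explicit solvent.  That engine is
deliberately replaced here by a **two-site-per-residue Gō model
sampled with Metropolis Monte Carlo** (C++ core): desk-scale,
bit-reproducible from a seed, and preserving the one bespoke
ingredient — the Phi-value pseudo-energy — exactly.  Every ensemble
records this substitution in its provenance.  The consequence is that
*absolute* structural statistics (e.g. fluctuation magnitudes in nm)
are not comparable with all-atom values; orderings and correlations
across restraint scenarios are the meaningful outputs.

Model terms (kcal/mol, nm): harmonic pseudo-bonds (CA–CA 1-2, CA–SC)
with 1-3 and 1-4 CA distance surrogates for angles/dihedrals; a 12-10
well per native contact at the native side-chain centroid distance
with depth $0.9 + 0.12\,\min(n_\mathrm{pairs}, 10)$; generic
$r^{-12}$ repulsion elsewhere with $\sigma_{ij} = \min(0.35,\,0.85\,
r^\mathrm{nat}_{ij})$ so native packing is never penalised; a harmonic
tether on receptor sites (CA 50, SC 10 kcal mol⁻¹ nm⁻²) — the folded
partner is the frame of reference, the TS search concerns the ligand
and interface; and a flat-bottom sphere (radius 3.5 nm) on the ligand
centroid so an unbound ligand cannot diffuse away irreversibly.

**The restraint.** For residue $i$ with $n_i$ native contact pairs,
$\Phi^\mathrm{sim}_i$ is the fraction currently formed; a pair is
formed when its centroid distance is within 1.2 × its native
distance.  The pseudo-energy is

$$E_\Phi = k_\Phi \sum_i \left(\Phi^\mathrm{exp}_i - \Phi^\mathrm{sim}_i\right)^2 .$$

In the Monte Carlo energy the formed/not-formed step is replaced by a
logistic switch of width 0.015 nm centred at the contact radius, so
the restraint exerts a usable force near the boundary; reported
$\Phi^\mathrm{sim}$ values always use the hard criterion.
Experimental Phi values outside $[0,1]$ are accepted and restrained
as-is (they are flagged, not clamped), though note that the per-pair
fraction cannot exceed 1, so targets above 1 are unreachable by
construction.

**Calibration of $k_\Phi$ and the Gō depth.**  These two constants
compete: the restraint must win every per-contact decision, while the
unrestrained model must still hold the native complex together at
283 K.  Pilot simulations showed that a weak restraint (a few $k_BT$
at Phi mismatch 0.5) leaves a systematic native-ward bias of 0.1–0.3
Phi units, and that a switching width much above ~0.02 nm lets
contacts park just outside the hard criterion radius while collecting
partial smooth credit (another ~0.1–0.2 bias).  The defaults
($k_\Phi = 120$, width 0.015 nm, base depth 0.9) recover per-residue
restraint targets in $[0.2, 1.0]$ to within 0.10 on the packaged toy
complex at the desk schedule, while the unrestrained native reference
keeps a mean $\Phi^\mathrm{sim}$ of ~0.90 and relaxes back to >0.8
native contact fraction after annealing.  All constants are exposed
via `cg_defaults()` / `build_cg_model(params =)`.

**Annealing protocol.** `anneal()` runs cycles that ramp the
temperature linearly 383 K → 283 K; each cycle starts from the
previous endpoint and contributes its final, cold conformation to the
ensemble.  Defaults mirror the reference protocol: 300 cycles, with
one "150 ps" cycle mapped to 2000 MC sweeps (a sweep = one trial move
per site plus 8 rigid-body ligand moves); the desk-scale schedule used
in tests is 50 × 1000.  Cycle 1 starts from a ligand pose randomised
within 3 nm of the site (a TS search should not start at the
product).  Two discarded burn-in segments precede recording: 10
cycles with a widened switching width (0.08 nm), whose longer-ranged
restraint force funnels the ligand into the interface quickly, then
10 cycles at the model's sharp width to re-equilibrate.  Without
this, the stochastic first capture and the width switch-over leave a
decaying transient that inflates the fluctuation of strongly
restrained ensembles by up to a factor of two.
Acceptance below 1% over a cycle halves the
step sizes (logged in the output).  The RNG (xoshiro256+,
Box–Muller) lives in the engine, so a seed reproduces an ensemble
bit-for-bit.

`native_reference()` provides the constant-temperature unrestrained
baseline (the stand-in for the long native-state reference
simulation); `subset_restraint_control()` repeats an annealing with a
restraint subset and reports the contact-frequency comparison — the
classical robustness control run with four positions.

# Ensemble statistics

`ensemble_fluctuation()` iteratively superposes all members on the
evolving mean over the receptor CA sites (Kabsch), takes the mean
structure as the coordinate average, and reports the mean RMS
deviation of the ligand CA sites from it.  The alignment/selection
choice is explicit because the original analysis does not state one;
aligning on the folded template and measuring the disordered chain is
the reading most consistent with displaying the ligand ensemble about
its average.  `contact_frequency_map()` scores native pairs with the
same formed-criterion as the Phi values and additionally reports
*non-native* pairs formed in ≥10% of members — the signature of a
shifted binding mode.  `correlate()` supplies the Pearson/OLS
cross-correlations used by the pipeline: fluctuation vs
$\log_{10} k_\mathrm{on}$, fluctuation vs $\alpha$, and $\alpha$ vs
hydrophobic SASA.  $\log_{10}$ is used for rates; correlation signs
are base-invariant.

# Synthetic data: the stated world

The generators produce every input with known ground truth:

* `gen_trace()`/`gen_trace_series()`: single-exponential traces at the
  experimental design (probe 3 µM, ligand 8–80 µM, 3–6 replicates,
  2% Gaussian amplitude noise as the default noise floor; Gaussian
  because no instrument noise model is available).
* `gen_toy_complex()`: a 30-residue receptor of two packed
  antiparallel helices with a hydrophobic groove, plus a 10-residue
  amphipathic helical ligand docked in it.  Side chains are compact
  pseudo-atom blobs with the correct heavy-atom count per type, so
  contact counting and deletion mutations behave realistically.
  Ligand side chains are tilted toward the groove — a construction
  device guaranteeing every ligand residue ≥1 inter-chain native
  contact (radial placement cannot, for residues on the solvent
  face).  Geometry (axis separation 1.4 nm, ligand height 0.95 nm)
  was fixed once from steric screening (no inter-chain atom pair
  closer than ~0.19 nm).
* `gen_phi_set()`: per-residue Phi targets from a Beta distribution
  rescaled to [0, 1.2] and moment-matched to a requested mean and
  spread — emulating experimental Phi tables with tunable
  heterogeneity.
* `gen_lfer_dataset()`: free-energy pairs with a chosen slope,
  intercept and noise for LFER recovery and bootstrap-calibration
  studies.

What a green test does **not** establish: the toy complex has no real
side-chain packing, solvent, or electrostatics; noise is idealised
Gaussian; and the coarse-grained fluctuation scale is not the
all-atom one.  Green tests establish that the *method* — fitting,
free-energy algebra, restraint satisfaction, ordering and
correlation logic — behaves as specified on data whose truth is
known.

# Numerical choices and degenerate inputs

* Strict `<` at the 0.65 nm contact cutoff; formed-criterion factor
  1.2 on native centroid distances.
* Exponential fits: failure is a value (`ok = FALSE` with the
  residual norm), not an exception; constant signals short-circuit.
* Rank-deficient regressions (all concentrations equal, all
  $\Delta\Delta G_\mathrm{eq}$ equal) raise classed errors.
* Bootstrap resamples with <3 distinct points are redrawn, not
  silently accepted.
* All seeds are explicit arguments; generator functions restore the
  caller's RNG state.  Pipeline stages derive their seeds by hashing
  stage names into the master seed (`derive_seed()`).

# Known limitations

* Mutations are deletion-only; growth mutations need an external
  structure.
* The engine substitution makes absolute nm-scale statistics
  incomparable with all-atom references; only orderings/correlations
  transfer.
* Phi targets above 1 cannot be matched by the per-pair fraction
  criterion (they are restrained toward 1 from below).
* The LFER alpha values of the original study can only be reproduced
  literally from its (unpublished-here) supplementary rate tables;
  the packaged scenario instead generates data *with* those alpha
  values and verifies recovery.
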