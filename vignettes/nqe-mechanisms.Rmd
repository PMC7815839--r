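---
title: "Models and methods: how nqemd probes quantum strengthening of molecular interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`nqemd` implements a closed loop for studying how nuclear quantum effects
(NQE) modify molecular interactions: analytic model surfaces with exact
gradients stand in for quantum-chemistry reference data; a Boltzmann
sampler turns them into energy/force training sets; a gradient-domain
kernel model learns the force field; classical and path-integral Langevin
dynamics sample thermal (and thermal-plus-quantum) ensembles; and a set of
analysis operators extracts the signatures of quantum strengthening —
free-energy reshaping, rotor localization, steep power-law attraction, and
polarizability-driven dispersion gains.

This vignette records the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic surfaces do and
do not establish about real molecules.

# Gradient-domain force-field regression

The regression target is the force field, not the energy. For a
configuration with descriptor $D(x)$ (inverse interatomic distances
$1/\|r_a - r_b\|$, all pairs $a<b$), the model energy is a linear
combination of kernel derivatives at the $M$ training points, and the
predicted forces are its exact analytic negative gradient. Training solves
the $3NM \times 3NM$ symmetric system whose blocks are second derivatives
of the kernel through the descriptor chain rule, with the training forces
as labels and ridge regularization $\lambda$ on the diagonal. Because one
scalar function underlies both outputs, energy conservation is structural,
not fitted; the tests verify $F = -\nabla E$ by central differences at
random probes (tolerance $10^{-5}$ relative).

Choices and rationale:

* **Kernel**: Matérn $\nu = 5/2$, $k(d) = (1 + \sqrt5 d/\sigma +
  5d^2/3\sigma^2)\,e^{-\sqrt5 d/\sigma}$. Force–force covariances need two
  derivatives; $\nu = 5/2$ is the minimum-smoothness Matérn with that
  property, avoiding the over-smooth squared exponential.
* **Permutational symmetry** is a prior: the kernel is averaged over a
  user-supplied group of atom index maps, making predictions exactly
  invariant ($\le 10^{-8}$ kcal/mol in tests). Automatic symmetry
  recovery is out of scope; groups are declared explicitly.
* **Energy offset**: forces determine the energy only up to a constant, so
  the offset $c$ matches the mean predicted to the mean reference training
  energy.
* **Linear algebra**: Cholesky factorization; if it fails at
  $\lambda > 0$, jitter is added starting at $10^{-10}$ of the mean
  diagonal and escalated tenfold with a warning; at $\lambda = 0$ a
  singular system raises an error carrying a condition estimate.
* **Memory guard**: the dense system scales as $(3NM)^2$; training refuses
  jobs above a configurable byte budget (default 2 GB) instead of
  swapping. Published models for real molecules use $M \approx 1000$;
  the package's test problems use $M \le 150$ on dimers, where the model
  reaches force MAEs orders of magnitude below the published 0.7
  kcal/mol/Å bound.
* **Hyperparameters**: the selection protocol (random validation split,
  grid search on validation force MAE, ties broken toward the smallest
  $\sigma$ then smallest $\lambda$) is a package decision — the source
  literature does not state one.

# Path-integral Langevin dynamics

Each nucleus is represented by $P$ beads coupled by harmonic springs; the
bead system is propagated with an OBABO splitting: half-step Langevin
thermostat in ring-polymer normal modes, half-step force kick, exact free
ring-polymer evolution, second kick, second thermostat half-step. Mode $k$
has frequency $\omega_k = 2\omega_P \sin(k\pi/P)$ with $\omega_P =
P/\beta\hbar$; internal modes get friction $\gamma_k = 2\omega_k$ (the
standard optimal-damping choice) and the centroid a user-set friction
$1/\tau$ (default $\tau = 100$ fs). Internally beads are sampled at the
ring-polymer temperature $PT$ with full physical forces — equivalent, by
the usual convention change, to sampling at $T$ with $V/P$ and spring
frequency $\omega_P/\sqrt P$. The estimator records are written in the
$\beta$ convention, so the spring term in the primitive estimator uses
$\omega_P^2/P$.

$P = 1$ reduces exactly to classical Langevin dynamics, and with the
thermostat off to velocity Verlet (tests verify bounded, non-drifting
energy error). Quantum correctness is tested against closed forms: the
stationary bead covariance on a harmonic surface matches the analytic
normal-mode Gaussian integrals for $P \in \{1,2,4,8\}$, and the total
energy at $\beta\hbar\omega = 5$ with $P = 32$ lands within 5% of
$(\hbar\omega/2)\coth(\beta\hbar\omega/2)$.

Defaults follow the standard protocol of the field: $dt = 0.2$ fs, $T =
300$ K, bead ramp $P \in \{1,4,8,16,32\}$ with convergence declared when
the centroid-virial energy changes by less than 1% between successive bead
counts. Masses come from a most-abundant-isotope table; units are Å,
kcal/mol, fs, amu (1 kcal/mol = 4.184×10⁻⁴ amu Å²/fs²), with CODATA
constants ($k_B$ = 1.987204259×10⁻³ kcal/mol/K, $\hbar$ = 15.1787
kcal/mol·fs).

One master seed per run derives separate initialization and propagation
streams, both recorded in the trajectory provenance; identical settings
reproduce estimator series bitwise.

# Model surfaces and the synthetic-data generator

The surfaces isolate one mechanism each:

* **Bond-coupled methyl rotor** (`rotor_pes`): $V(\theta,\delta d) =
  \tfrac{V_6}{2}(1-\cos 6\theta) + \tfrac{V_3\max(\delta d,0)}{2}
  (1-\cos 3\theta) + \tfrac{k}{2}\delta d^2$, propagated as two
  generalized coordinates — the torsion $\theta$ (effective mass = moment
  of inertia, 3.2 amu Å²) and the bond dilation $\delta d$ (reduced mass 6
  amu, stiffness 470 kcal/mol/Å², an aromatic C–C force constant).
  $V_6 = 0.024$ kcal/mol is the coupled-cluster toluene barrier.
  $V_3 = 25$ kcal/mol/Å is calibrated so that the barrier the *quantum*
  rotor actually experiences — the ring-polymer average of
  $V_3\max(\delta d, 0)$, about 0.02 Å at 300 K — is ≈0.5 kcal/mol,
  i.e. comparable to $k_BT$, the regime in which hindered rotation is
  reported. This calibration matters: the harmonic bond decorrelates in
  tens of femtoseconds, so the rotor feels only the *mean* coupling
  amplitude; anchoring the 0.55 kcal/mol barrier scale to rare bond
  excursions instead leaves the mean barrier near 0.2 $k_BT$, where the
  rotor's own zero-point delocalization outweighs the hindering and the
  localization phenomenology disappears. The linear dependence of the
  three-fold amplitude on bond dilation is a modelling choice (the
  underlying relation is known only graphically), as is using a single
  explicit $\delta d$ with the companion bond encoded by an
  anticorrelation slope rather than simulating a ring.
* **Steep donor–acceptor attraction** (`npistar_pes`,
  `npistar_toy_energy`): exponential wall plus $-A r^{-11}$ tail, wall
  amplitude fixed by placing the single minimum at $r_{eq}$ (default 2.9
  Å, a Bürgi–Dunitz-like contact); log–log tail slope is exactly −11, and
  a companion dihedral can modulate the attraction amplitude. The −11
  exponent encodes the near-contact orbital-overlap decay that
  `gaussian_overlap` illustrates in closed form.
* **Partial-charge electrostatics** (`chargepair_pes`): Coulomb attraction
  between $q_O = -0.55\,e$ and $q_H = +0.25\,e$ with a short-range wall,
  plus a geometric map from a companion dihedral to the O⋯H separation.
* **Morse dimer with damped dispersion** (`morse_dimer_pes`): the
  anharmonic workhorse for training sets and for the
  polarizability/dispersion pipeline. The $-C_6/r^6$ tail is Fermi-damped
  (midpoint 1.0 Å, width 0.15 Å) to remove the $r \to 0$ divergence; the
  true minimum therefore sits slightly inside the Morse $r_e$, which is
  why reference geometries come from `relax_geometry`, not from a
  parameter.
* **Harmonic and double-well surfaces** for every closed-form check.

`sample_training_set` is a Metropolis sampler targeting $e^{-V/k_BT}$ with
the proposal width adapted toward ≈40% acceptance during burn-in and then
frozen, so chains are exactly seed-reproducible; acceptance rates outside
[0.15, 0.85] raise a warning. Every record carries the surface's energy
and exact forces.

What the generator emulates: Boltzmann configuration/energy/force sets at
a stated temperature, the six-fold→three-fold torsional switch, the
$r^{-11}$ attraction, the partial-charge toy, and geometry ensembles whose
effective radii dilate more under quantum than under thermal sampling.
What it does not: real electronic structure (no orbital energies, no
ab initio polarizability tensors, no many-body dispersion), conformational
complexity of real molecules, or solvent. Passing tests therefore
establish the *mechanisms* and the correctness of the machinery, not
chemical accuracy for any specific molecule.

# Analysis operators

* **Free-energy surfaces**: $F = -k_BT\ln(\rho/\rho_{max})$ on occupied
  histogram bins, minimum at 0; empty bins are masked `NA`, never imputed
  — an unvisited region has no defined free energy.
* **Rotor localization**: maximal intervals in which the wrapped angle
  stays within ±30° of a well for at least 1 ps (both knobs exposed; the
  criterion for "stopped rotating" is operational, not a literature
  constant). Angle unwrapping is by shortest-path increments. The
  mechanism comparisons also report a 0.5 ps dwell count — five times the
  model rotor's ~0.1 ps thermal crossing time — because at the model's
  timescales 1 ps events are rare enough to make fixed-length counts
  noisy.
* **Power-law fits**: ordinary least squares of $\log|E|$ on $\log r$
  inside $[r_{min}, r_{max}]$ (default start 3.8 Å, the free-attractive
  regime); sign changes inside the window are refused rather than
  silently absolute-valued.
* **Casimir–Polder $C_6$**: Gauss–Legendre quadrature (200 nodes) on the
  half-line mapped through $\omega = \omega_s t/(1-t)$ with
  $\omega_s = \sqrt{\omega_A\omega_B}$; agrees with the Drude/London
  closed forms to better than $10^{-6}$ relative across a broad parameter
  sweep.
* **Polarizability surrogate**: per-configuration effective radius =
  mass-weighted radius of gyration + 1.7 Å shell, mapped through
  $\alpha \propto R^7$. This preserves the scaling mechanism — small
  dilations amplify sevenfold into polarizability, and convexity makes
  even symmetric fluctuations contribute — but the absolute increments
  are surrogate numbers, not ab initio ones. Quantum ensembles are drawn
  from the beads (the bead marginal is the quantum thermal ensemble);
  classical ensembles from $P=1$ positions.
* **Ensemble interaction scans**: mean ± SE of a pair potential over 50
  paired configurations per separation (zipped by default; all-pairs mode
  available because the original pairing protocol is not fully specified).

# Problem sizes and numerical tolerances

The test and acceptance runs use: dimer training sets of 40–150
configurations; harmonic-oscillator PIMD with 30 000 steps of 0.4 fs at
$P \le 32$; ring-polymer covariance runs of 50 000–60 000 steps at
$P \le 8$; rotor mechanism runs of 300–400 ps at 0.5 fs steps
($P = 1$ and $P = 32$); and 500-member geometry ensembles for the
polarizability increments. These sizes were chosen so that each statistic
resolves its expected effect at 2–3 standard errors while a full run of
the suite stays in the minutes range on one core. Stochastic assertions
use fixed seeds and 3-SE bands; exact assertions use the tolerances stated
above next to each oracle.

# Known limitations

* The rotor model reproduces the six→three-fold surface transformation,
  the quantum enhancement of localized-state counts and the three-fold
  occupancy contrast, but with a fast harmonic bond it cannot sustain the
  multi-picosecond dwells seen in full molecular simulations; dwell
  durations here are of order 1 ps.
* The dispersion pipeline's polarizability increments are surrogate
  ($R^7$-law) quantities; only their ordering and sign pattern (quantum >
  classical > 0) carry over to real systems.
* Gradient-domain training is dense: systems beyond a few thousand force
  components need more memory than the default budget permits.
* No ring-polymer contraction, colored-noise thermostats, replica
  exchange, or constant-pressure ensembles; no deuteration switch.
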