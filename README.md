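# nqemd — nuclear quantum effects on molecular interactions

Nuclear quantum effects (NQE) — zero-point motion, tunnelling, the
delocalization of light nuclei — are usually pictured as *smearing out*
molecular structure. Yet at finite temperature they can do the opposite:
quantum delocalization of bond lengths can raise torsional barriers and
transiently pin methyl rotors, shorten donor–acceptor distances and so
strengthen steep orbital-overlap (n→π\*-type) and electrostatic
interactions, and dilate a molecule's effective volume, which amplifies its
polarizability (α ∼ R⁷vdW) and hence its van der Waals attraction through
the Casimir–Polder integral

C₆ᴬᴮ = (3/π) ∫₀^∞ αᴀ(iω) αʙ(iω) dω,  E_vdW ≈ −C₆/R⁶.

`nqemd` is an R toolkit for studying these mechanisms at desk scale. It
provides, as tested, self-contained components:

* **Gradient-domain force-field regression** (`train_forcefield`,
  `predict`, `select_hyperparameters`): kernel ridge regression on forces
  with a Matérn‑5/2 kernel over inverse-interatomic-distance descriptors.
  The model is the analytic gradient of a single scalar function (energy
  conservation by construction) and is averaged over a user-supplied atom
  permutation group (exact permutational invariance).
* **Classical and path-integral molecular dynamics** (`run_trajectory`,
  `init_state`, `pimd_step`, `kinetic_estimators`, `bead_ramp`): OBABO
  Langevin propagation of a P-bead ring polymer in normal modes, with
  primitive and centroid-virial quantum kinetic-energy estimators; P = 1 is
  exactly classical Langevin dynamics.
* **Analytic model potentials** (`rotor_pes`, `morse_dimer_pes`,
  `npistar_pes`, `chargepair_pes`, `harmonic_pes`, `double_well_pes`) with
  exact gradients, plus a Metropolis Boltzmann sampler
  (`sample_training_set`) that generates energy/force training sets.
* **Analysis operators** (`free_energy_surface`, `dihedral_angle`,
  `time_angle_histogram`, `detect_localized_states`, `fit_power_law`,
  `casimir_polder_c6`, `vdw_energy`, `ensemble_polarizability_increment`,
  `ensemble_interaction_scan`).
* **I/O** for extended‑XYZ configurations and the z/R/E/F named-array
  dataset archives used by published gradient-domain force-field datasets,
  and a command-line interface (`cli_main`; executable wrapper in
  `inst/exec/nqemd`) with `fixtures`, `train`, `predict`, `md`, `pimd` and
  `analyze` subcommands.

Units throughout: Å, kcal/mol, fs, amu, K; angles in degrees at interfaces.

## Worked example: a quantum-hindered methyl rotor

A methyl rotor on a six-fold surface with a 0.024 kcal/mol barrier is
essentially free at 300 K (k\_BT ≈ 0.6 kcal/mol). Coupling the rotor to a
harmonic ring bond whose dilation switches on a three-fold term changes the
picture once the bond is treated quantum mechanically:

```r
library(nqemd)

pes <- rotor_pes()                      # bond-coupled methyl rotor model
cl <- run_trajectory(pes, steps = 8e5, dt = 0.5, T = 300, P = 1,
                     seed = 7001, stride = 20, thermostat_time = 200)
qm <- run_trajectory(pes, steps = 6e5, dt = 0.5, T = 300, P = 32,
                     seed = 7002, stride = 20, thermostat_time = 200)

angle <- function(tr) ((tr$centroid[, 1, 1] * 180 / pi + 180) %% 360) - 180
rate <- function(tr) {
  loc <- detect_localized_states(angle(tr), tr$dt * tr$stride,
                                 min_duration = 500)
  attr(loc, "count") / (max(tr$times) * 1e-6)
}
rate(cl)   # 150   localized states per ns, classical nuclei
rate(qm)   # 243.3 localized states per ns, quantum nuclei (P = 32)
```

With classical nuclei the rotor diffuses almost freely (three-well
occupancy 0.55, barely above the uniform 0.5); with quantum nuclei the
bond's zero-point dilation sustains an effective three-fold barrier
comparable to k\_BT, the occupancy rises to 0.59, and transient localized
states become substantially more frequent — quantum delocalization of the
bond *localizes* the rotor.

The same machinery exposes the other mechanisms: `fit_power_law` recovers
the r⁻¹¹ tail exponent of the steep donor–acceptor toy
(`npistar_toy_energy`) to `n = 11.00`, and bead-sampled Morse-dimer
ensembles give a mean polarizability increment of ≈1.5 % under PIMD versus
≈0.45 % classically, which `ensemble_interaction_scan` translates into
uniformly deeper C₆/R⁶ dispersion curves.

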