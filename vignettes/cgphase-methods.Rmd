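---
title: "The cgphase model: energies, dynamics, phase analysis and parameter fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgphase model: energies, dynamics, phase analysis and parameter fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgphase)
```

## The model

cgphase implements a residue-level coarse-grained model for proteins
(disordered and folded) and RNA aimed at concentration-dependent phase
behaviour: each amino acid or nucleotide is one spherical bead, and the
total potential energy is

$$U_\mathrm{total} = U_\mathrm{bond} + U_\mathrm{angle} +
  U_\mathrm{short\,range} + U_\mathrm{electrostatic},$$

with harmonic bonds between consecutive residues
($k_\mathrm{bond} = 4184$ kJ mol$^{-1}$ nm$^{-2}$, $l_0 = 0.38$ nm for
proteins, $0.5$ nm for RNA), harmonic angles on all consecutive triples
($k_\mathrm{angle} = 4.184$ kJ mol$^{-1}$ rad$^{-2}$,
$\theta_0 = 180^\circ$), a 10–5 Lennard-Jones-like short-range term

$$U_\mathrm{short\,range} = \sum_{i<j} \xi_i \xi_j \,
  4(\varepsilon_{ij} + \varepsilon_\mathrm{mod})
  \left[ \left(\tfrac{\sigma_{ij}}{r}\right)^{10} -
         \left(\tfrac{\sigma_{ij}}{r}\right)^{5} \right],$$

and a screened Debye–Hückel electrostatic term

$$U_\mathrm{elec} = \sum_{i<j} P\,(A_i A_j + A_{0,i} A_{0,j})\,
  \frac{e^{-r/\kappa}}{r}, \qquad \kappa = 1\ \mathrm{nm}
  \ (\approx 100\ \mathrm{mM\ ionic\ strength}).$$

Folded domains are held together by an elastic network
($k_\mathrm{ENM} = 500$ kJ mol$^{-1}$ nm$^{-2}$) over residue pairs whose
reference distance is at most 0.9 nm and whose sequence separation is at
least two bonds. Nonbonded terms use plain truncation at 3 nm under the
minimum-image convention, with one-bond neighbours excluded. Units are
nm, kJ/mol, ps, amu and elementary charges throughout.

Combination rules: $\sigma_{ij} = (\sigma_i + \sigma_j)/2$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$. Well depths and
solvation-repulsion amplitudes $A_0$ are class-level parameters (polar,
hydrophobic, nucleotide), which keeps the model deliberately
low-dimensional. Three pair classes receive a fixed bonus
$\varepsilon_\mathrm{mod}$ inside the bracket: cation–aromatic
(0.3 kJ/mol), cation–nucleotide (0.2) and, in the COCOMO2 preset,
aromatic–aromatic (0.1). Two presets ship with the package
(`cg_params("COCOMO")`, `cg_params("COCOMO2")`); every field can be
overridden individually or from a YAML file.

```{r presets}
cg_params("COCOMO2")
```

### Surface-exposure scaling

The central extension for folded proteins is the per-residue interaction
scale $\xi$. For residues in declared folded ranges,

$$\xi = \begin{cases} 1 & S_\mathrm{ratio} \ge \lambda \\
  S_\mathrm{ratio}/\lambda & S_\mathrm{ratio} < \lambda \end{cases}$$

where $S_\mathrm{ratio} = S_\mathrm{residue}/S_\mathrm{ref}$ compares a
residue's solvent-accessible surface area in the reference structure to
an amino-acid-specific fully-exposed reference area. Disordered residues
always have $\xi = 1$; $\lambda = 0$ disables scaling. $\xi$ is computed
once from the reference structure and never updated during dynamics —
the elastic network keeps burial essentially constant, and this keeps
the surface term free at run time.

SASA is computed with an in-package Shrake–Rupley routine
(probe 0.14 nm, 960 deterministic quasi-uniform sphere points per bead),
validated against analytic two-sphere cap areas to within 5%. Both
$S_\mathrm{residue}$ and $S_\mathrm{ref}$ are evaluated at bead
resolution with radii $\sigma_i/2$; $S_\mathrm{ref}$ embeds the residue
bead at the centre of an ideal 11-residue poly-alanine helix (radius
0.23 nm, rise 0.15 nm, 100°/residue). Using one representation for
numerator and denominator was a deliberate design choice: mixing an
atomistic numerator with a bead-resolution reference (or vice versa)
would make $S_\mathrm{ratio}$ systematically biased, whereas the ratio
of two bead-level areas is internally consistent. The absolute scale of
$S_\mathrm{ref}$ therefore differs from atomistic conventions, but only
the ratio enters the model. Isolated residues can have
$S_\mathrm{ratio} > 1$ (they are more exposed than in the reference
helix); $\xi$ is capped at 1.

### Resolved ambiguities

Two pieces of the electrostatic term required a decision. First, the
per-charge amplitude is implemented as
$A_i = \mathrm{sign}(q_i)\,0.75\,|q_i|^a$ with the exponent $a$ exposed
as `charge_exponent` (default 0.5). All standard residues carry integer
charges 0 or ±1 (Asp/Glu −1, Lys/Arg +1, His neutral, one negative
charge per nucleotide), for which every choice of $a$ coincides, so the
option only matters for hypothetical fractional charges. Second, the
overall prefactor $P$ of the screened term (`elec_prefactor`, units
kJ nm mol$^{-1}$) defaults to 1; it is a single multiplicative constant
that can be recalibrated without touching any other machinery. Likewise
$\xi$ multiplies only the short-range term by default; the flag
`xi_scales_electrostatics` switches on the alternative reading in which
it also scales electrostatics.

Residue volumes behind $\sigma_i = 2 r_i 2^{-1/6}$ are the Zamyatnin
(1972) amino-acid volumes with approximate ribonucleotide volumes;
masses are standard residue masses. Nucleotide well depth and $A_0$ are
exposed as `eps_nucleotide` and `A0_nucleotide` (defaults 0.40 kJ/mol
and 0.05, the original polar-class values) because the RNA parameters
are inherited, not refitted, in this package. The angle constants for
proteins and nucleic acids are separate config keys with identical
defaults (4.184).

## Topology construction

`chain_spec()` declares a chain (sequence, kind, folded ranges, 1-based
inclusive intervals, reference coordinates, copy count) and
`build_topology()` expands chains into beads, bonds, angles, ENM
restraints, exclusions and per-bead $\xi$. ENM restraints are confined
to a single declared folded range by default; a flag allows restraints
bridging two ranges of the same chain when their reference distance
qualifies, since reasonable users may want rigid multi-domain
arrangements. Angle terms span folded and disordered residues alike —
the elastic network acts in addition to, not instead of, the generic
chain stiffness.

## Dynamics

`run_langevin()` integrates Langevin dynamics with the BAOAB splitting,
chosen for its accurate configurational sampling at large time steps.
Protocol defaults: 298 K, friction 0.01 ps$^{-1}$, 10 fs equilibration
and 20 fs production time steps. The noise stream is an in-package
splitmix64 generator with Box–Muller transforms, so trajectories are
bitwise reproducible for a given seed and build, independent of the C++
standard library. Nonbonded forces run through a Verlet neighbour list
(0.3 nm skin, displacement-triggered rebuild from an $O(N^2)$ scan); at
the package's problem sizes (up to a few thousand beads) the list build
is negligible and cell decomposition would add complexity without
measurable benefit. The list path is contractually identical to the
direct double loop and is oracle-tested against it.

Angle forces at the equilibrium angle $\theta_0 = 180^\circ$ have a
0/0 form; the implementation switches to the analytic limit
$(\theta - \pi)/\sin\theta \to -1$ when $\sin\theta < 10^{-6}$.
Energy minimization is bounded quasi-Newton (L-BFGS-B) on the analytic
forces; `minimize_then_equilibrate()` errors if any nonbonded pair
remains below $0.2\,\sigma_{ij}$ afterwards. With zero friction and
temperature the integrator reduces to velocity Verlet and conserves
energy to the usual symplectic bounded oscillation. Like all BAOAB
implementations, the *kinetic* temperature carries an $O(\Delta t^2)$
discretization bias (about 1–3 % low at 10–20 fs for bonded beads,
while configurational averages stay accurate); temperature checks in
the test suite therefore use a 5 fs step with the equilibration
transient discarded.

## Phase analysis

`build_start()` places chains in `random`, `condensate` or `mixed`
mode; the mixed mode (a pre-formed droplet coexisting with dispersed
monomers) is the preferred protocol for saturation-concentration
estimation because simulations started fully dispersed overestimate and
fully condensed underestimate csat on accessible time scales — the
package's hysteresis study reproduces this gap. Droplet volume assumes
an effective bead volume of 0.065 nm$^3$ at 20% packing; placement
enforces a minimum inter-chain bead distance with bounded retries.

Chains are clustered by single linkage on the contact graph (any
inter-chain bead pair closer than 1.0 nm, minimum image); chains in
clusters smaller than 5 count as the dilute phase. Both thresholds are
arguments, not constants, because the underlying experimental
observable ("free monomer concentration") does not prescribe them; csat
estimates move by tens of percent when the contact cutoff moves by
±0.2 nm, which is well inside the scatter of the short-trajectory
estimates themselves. `estimate_csat()` averages the dilute-phase
concentration over the trailing 20% of a trajectory by default (an echo
of averaging the last microsecond of a 5 μs run), reports a block-average
spread, and refuses to report a number when the window shows no
coexistence (condensate dissolved, or no dilute chains at all). Radii
of gyration are mass-weighted with bonded-walk unwrapping across
periodic images.

## Parameter optimization

The optimizer never re-runs simulations. `rescore()` evaluates stored
condensate snapshots under candidate parameters (re-thresholding $\xi$
when $\lambda$ changes) and returns the mean potential energy per
residue — per-residue normalization makes systems of different size
commensurable. Because csat depends exponentially on the interaction
energy, $\log_{10} c_\mathrm{sat}$ is, to good approximation, linear in
this energy; `fit_energy_csat()` fits that line robustly with RANSAC
(minimal sample 2, 1000 seeded trials, residual threshold scaled by the
median absolute deviation, ordinary least squares on the final inlier
set — with clean collinear data this reduces exactly to OLS).

`optimize_parameters()` runs the three-stage protocol: a grid scan over
the disordered systems only ($\lambda$ excluded, since it cannot affect
chains without folded ranges), bounded L-BFGS-B refinement on the same
systems, and a joint bounded refinement over all systems with $\lambda$
included and capped at 0.7 — higher thresholds change condensate
morphology and undermine the fixed-burial assumption, so the cap is
part of the protocol. The objective is the sum of squared deviations
between predicted and experimental $\log_{10} c_\mathrm{sat}$. Scan
axes are geometrically spaced for strictly positive parameters (well
depths span orders of magnitude) and square-root spaced towards zero
for the solvation amplitudes. Because the objective is multi-modal in
the well depths — the combination rule
$\sqrt{\varepsilon_i \varepsilon_j}$ lets distinct class pairs mimic
one another on a finite system set — `optimize_staged()` refines the
best few scan points separately and offers every distinct refined
candidate to the joint stage, keeping the lowest joint objective. With
too few disordered training systems the disordered-only stages are
genuinely underdetermined (a spurious exact root appears with four
systems and four free parameters); six compositions remove it.

The ten representative conformations per system are taken as evenly
strided frames from the trailing part of the generating trajectory; no
clustering is attempted, since the rescoring average is insensitive to
the exact frame choice once the condensate is formed.

## What the synthetic fixtures emulate

The generators in this package produce: disordered sequences drawn from
class compositions (polar/hydrophobic/charged/aromatic, or pinned
residues), seven-helix bundles traversed as a single chain whose
central-helix residues are geometrically buried (with
construction-derived burial labels for SASA validation), and
self-consistent rescoring problems in which synthetic "experimental"
csat values are generated from a known parameter set through the same
energy–csat relationship the optimizer assumes. They deliberately do
not emulate: real secondary-structure geometry beyond ideal helices,
sequence patterning effects, condensate morphology transitions, or
experimental noise structure. A passing suite therefore demonstrates
internal correctness of the machinery (energies, thermostat, cluster
analysis, fit and optimization), and qualitative phase phenomenology
(hysteresis, $\lambda$–csat coupling, proxy validity) — not quantitative
agreement with any experimental system.

## Study conditions used by the tests and the acceptance script

All validation studies are desk-scale by design; the sizes are the
package's documented study conditions. Energy-oracle checks use ~100
random configurations up to 200 beads. Thermostat statistics use a free
bead and a bonded dimer over 10 ns equivalents and a 100-residue chain
over 4 ns. The hysteresis study uses 30 copies of a sticky 12-residue
hydrophobic/aromatic chain in a 14 nm box (about 18 mM total) run for
0.4 ns from random versus condensate starts over three seeds — far
shorter than the microsecond scale of production studies, which is
precisely why the kinetic gap between the two starts is visible. The
$\lambda$ study uses 14 copies of a 42-residue helix bundle whose
aromatics are confined to the partially-buried, contact-capable zone
($S_\mathrm{ratio}$ 0.35–0.8), so that the surface-exposure threshold
gates the dominant inter-chain glue; csat estimates are averaged over
two to three seeds at $\lambda \in \{0.4, 0.55, 0.7\}$, with
fully-condensed windows entering as zero (csat below resolution) and
dissolved droplets excluded (no estimate). Parameter recovery uses
eight synthetic systems (six disordered compositions, two bundles) with
noise-free synthetic csat, and the proxy study compares predicted
against directly simulated csat at two off-probe parameter settings of
a 20-chain toy system.

## Known limitations

* The electrostatic prefactor is a convention (default 1 kJ nm/mol);
  absolute electrostatic energies are only meaningful relative to it.
* Short trajectories make csat estimates kinetically biased; the
  package reports block spreads and coexistence flags rather than
  pretending convergence.
* The built-in integrator is CPU-bound and single-threaded; it is meant
  for desk-scale studies and verification, not for hundreds of chains
  over microseconds.
* RNA parameters are inherited defaults, not refitted; protein–RNA
  results should be read qualitatively.
* No pressure coupling, no slab geometry, no Ewald electrostatics — the
  model's screened short-range electrostatics is the design, not an
  approximation to PME.
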