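---
title: "Exhaustive low-energy minima search and multiwell binding free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive low-energy minima search and multiwell binding free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockminima)
```

## The problem

Docking programs usually equate the ligand binding pose with the global
minimum of a target function — a force-field or quantum-chemical energy of
the protein-ligand system, possibly with an implicit-solvent term.  Whether
that is a good model depends entirely on the target function: if its global
minimum sits far from the crystallographic pose, no search algorithm can
rescue it.  `dockminima` implements the machinery needed to *evaluate* a
target function on this question: an exhaustive Monte Carlo enumeration of
its low-energy local minima for a rigid receptor and a fully flexible
ligand, metrics that compare the resulting minima spectrum with the
experimentally observed pose, and a multiwell (mining-minima style)
estimate of the binding free energy built from those minima.

The receptor is frozen; the ligand moves with all Cartesian degrees of
freedom.  This is the standard rigid-receptor approximation: it makes the
exhaustive search tractable and isolates the target function itself as the
object under study, at the cost of ignoring induced fit.

## The search procedure

One *test optimization* is: draw a random pose, reject it if any atom pair
comes too close, locally minimize the survivors, and offer the minimum to a
bounded collection.

1. **Pose draw.**  The ligand's geometric center (unweighted centroid,
   hydrogens included) is moved to a point drawn uniformly from a sphere —
   by default radius 8 Å around the native pose center, which covers the
   active site.  The ligand is then rotated as a whole about a random axis
   through its center by an angle uniform in \[-π, π\], and every rotatable
   torsion is turned by an independent uniform angle.  Two deliberate
   literalisms: the axis/angle draw is *not* the Haar measure on SO(3), and
   the pose is not re-centered after the torsion turns (so a flexible
   ligand's centroid may end slightly outside the sphere).  Both follow the
   procedure as stated in the original description of the method; the
   search-area guarantee is enforced where it matters, at insertion time.
2. **Clash filter.**  A pose survives only if every receptor-ligand and
   every non-bonded ligand-ligand pair (1-2 and 1-3 pairs exempt) is
   separated by *more than* 0.5 Å; a pair exactly at the cutoff rejects.
   Without the bonded exemption every pose would fail — bond lengths are
   shorter than the cutoff.
3. **Local minimization.**  L-BFGS on all ligand Cartesian coordinates,
   unconstrained, until the maximum gradient component falls to
   10⁻⁵ kcal/mol/Å.  The optimizer is restarted from its end point until
   the analytic-gradient criterion is met; a 10,000-iteration cap turns
   pathological starts into counted failures rather than hangs.
4. **Minima set.**  A capacity-bounded (default 1024), energy-sorted
   collection.  A new minimum enters only if its geometric center is still
   inside the search sphere, it differs from every stored member by more
   than 0.1 Å heavy-atom RMSD (identity atom mapping, no superposition, no
   chemical-symmetry correction — poses live in the fixed receptor frame),
   and either the set is below capacity or it beats the current worst
   member, which is then evicted.

The trial index of every set change is recorded.  A flat tail in this
update curve is the operational signal that the search has saturated; the
`run_search` diagnostics expose it together with full trial accounting.

Rotatable torsions are single, acyclic (non-ring) bonds with at least one
heavy neighbour on each side beyond the axis atoms.  Excluding
hydrogen-only rotors (methyl, hydroxyl) keeps the torsion count consistent
with how flexible ligands are conventionally counted; ring bonds never
rotate.  For an evenly split chain the rotating side is chosen by atom
index, which is arbitrary but deterministic.

## Target functions

Energies enter through a minimal contract: a pure function from
(receptor, ligand, conformation) to energy (kcal/mol) and the gradient
over ligand coordinates (kcal/mol/Å).  Production target functions —
MMFF94, semiempirical methods, PCM/COSMO/SGB implicit-solvent rescorers —
are external programs in practice and plug in as adapters through a named
registry; the package deliberately implements none of them.

What it does ship is a small **toy force field** (harmonic bonds and
angles with rest values taken from the reference conformation, a cosine
torsion series, Lennard-Jones plus Coulomb non-bonded terms with 1-2/1-3
exclusions and full-weight 1-4 pairs) whose only purpose is to make every
downstream component testable on systems with analytically known minima.
The 1-4 convention is the simplest defensible one; it is configurable and
documented rather than hidden.  An optional distance cutoff exists but
defaults to off.

Two set-level operations carry a spectrum from one target function to
another: `rescore_set` (same geometries, new energies, re-sorted — the
"+ solvent" pattern) and `reoptimize_set` (each member re-minimized under
the new model, then re-deduplicated, so members that fall into a common
basin collapse).

## Pose metrics

With the minima sorted by energy and the optimized native pose (the
crystal pose after local minimization under the same target function) as
reference:

* **IN** — the rank the optimized-native energy would take in the sorted
  list: 1 + the number of stored minima strictly below it.  IN = 1 means
  no found minimum beats the native pose.  If *every* stored member lies
  below, the true rank is unknowable from a truncated set and IN = ∞.
  Ties rank after the incumbent, so IN = 1 retains its "nothing beats the
  native" meaning.
* **INN** — the smallest rank within 2 Å heavy-atom RMSD of the
  *non-optimized* native pose; ∞ if none.
* **Clustering** — the pairwise rule "same cluster if RMSD < 1.4 Å" is not
  transitive; its minimal closure, single linkage (connected components),
  is the default, with complete linkage available.  Clusters are numbered
  by ascending lowest member energy, and the native pose is assigned to
  the lowest-numbered cluster with a member within the linkage distance,
  or ∞.
* **Window count** — how many minima lie within a thermal window (default
  5 kT at 310 K ≈ 3.08 kcal/mol) of the global minimum; only these
  contribute appreciably to the free energy.
* **RMSD profile** — all member RMSDs to the native pose, sorted; its
  first element is the "best pose found" statistic.

## Multiwell binding free energy

The configuration integral of a species is approximated as a sum over its
distinct wells,

$$Z = \sum_i e^{-E_0^i/kT}\, Z_\nu^i\, Z_t\, Z_r, \qquad G = -kT\ln Z,$$

with the well-bottom energies from the minima set, the vibrational factor
of well *i* the quantum harmonic-oscillator product
$Z_\nu^i = \prod_l e^{-\hbar\omega_l^i/2kT}\,(1-e^{-\hbar\omega_l^i/kT})^{-1}$
over its normal modes, and species-level translational and rotational
factors

$$Z_t = \frac{e\,(2\pi M k T)^{3/2}}{h^3 \rho}, \qquad
  Z_r = \frac{(8\pi^2 k T)^{3/2}}{h^3}\sqrt{\pi I_A I_B I_C},$$

at the standard concentration ρ = 1 mol/L (the Euler-number prefactor in
$Z_t$ is kept literally as the method defines it).  Frequencies come from
a mass-weighted Hessian built by central finite differences of the
analytic gradient (step 10⁻⁴ Å, symmetrized).  For the ligand inside the
rigid receptor all 3n modes are kept — the external field breaks
translational and rotational invariance.  For the free ligand the
rigid-body modes are removed by count with a geometry check: 6 for a
nonlinear molecule, 5 for a linear one, 3 for a single atom.  Eigenvalues
more negative than a 1 cm⁻¹ equivalent mean the input was not a minimum
and raise an error; the narrow band above that is clamped out with a
warning.

`binding_breakdown` assembles ΔG_bind = G(PL) − G(P) − G(L) and reports
the conventional additive pieces: ΔE (global-minimum potential energies;
ligand strain is automatically included because free and bound species use
their own global minima), ΔG_ν, ΔG_t, ΔG_r evaluated at the global minima,
and ΔG_all, the correction from counting all wells rather than only the
global ones.  The identity ΔG_bind = ΔE + ΔG_ν + ΔG_t + ΔG_r + ΔG_all
holds to machine precision by construction.  Two conventions are genuinely
open in the method description and resolved as follows: translation and
rotation are counted for all three species (complex, protein, ligand) by
default — this matches the ~10-11 kcal/mol magnitudes of the published
per-complex corrections — with a ligand-only switch available; and the
species-level $Z_t Z_r$ is shared across wells of one species (it cancels
exactly in ΔG_all, which therefore does not depend on the convention).
The protein is rigid throughout: potential energy plus whole-body
translation/rotation, no vibrations.  Experimental reference values come
from inhibition constants via ΔG_exp = kT ln K_i at 310 K.

All partition functions are evaluated in SI units internally (log-space
summation for overflow safety); energies cross the interface in kcal/mol,
lengths in Å, masses in amu.

## Synthetic systems and what they do (and do not) show

Real benchmark structures require supercomputer-scale searches, so the
test surface is built on toy systems whose minima are known by
construction:

* **Double-well pocket** — two attractive Lennard-Jones sites at
  (±5, 0, 0) Å with contact distance 3.0 Å and well depth 0.2 kcal/mol.
  A single-atom probe sees exactly two interior minima, on the symmetry
  axis near (±2, 0, 0): each site's contact shell, tilted toward the other
  site.  Because the minima lie on the axis by symmetry, an exhaustive
  1-D lattice scan at 10⁻³ Å is a valid independent oracle for their
  positions and energies (a naive 3-D lattice scan is not: the contact
  shells are nearly flat tangentially, and coarse grids sprout
  discretization artifacts there).  The search is run inside a sphere of
  radius 4 Å about the origin, which contains both minima and excludes
  the outer-shell saddle regions.
* **Spherical cavity** — an icosahedral shell of radius 2.6 Å, *inside*
  the 3.0 Å contact distance, so the probe is pressed to the exact center
  from all sides: one minimum, at the origin, by symmetry.
* **Chain ligands** — carbon chains (bond 1.526 Å, bend 112°) with
  exactly the requested number of rotatable torsions, plus terminal
  hydrogens to absorb any remaining atom budget without adding torsions.
  Under the default threefold torsion term a one-torsion chain has three
  torsional minima, which pins the torsion-series convention.

These fixtures exercise the search loop, the set bookkeeping, the
optimizer contract, the metrics and the thermodynamic identities.  They do
*not* emulate the ruggedness of a real protein-ligand energy surface, the
10⁵-10⁶ trial scale such surfaces require, chemical diversity, solvent, or
symmetry-equivalent poses — conclusions about a real target function still
require running the search with a production energy adapter.  Test problem
sizes were chosen to keep the full suite in the tens of seconds: 500
trials on the double-well (its update curve goes quiet after a handful of
trials), 10⁴ randomized insertions for the set invariants, and ligands of
up to eight atoms.

The two published benchmark tables the package carries (per-complex
binding-energy decompositions and per-target-function binding energies for
16 complexes) are shipped as checksummed transcriptions.  The evaluation
statistics (`energy_range`, `pearson`, `summarize_binding_table`,
`breakdown_consistency`) reproduce their printed summary rows.  Two
caveats a user should know: the printed decomposition rows for 1DWC and
2P94 are internally inconsistent as published (component sums miss the
printed totals by 1.0 and 10.0 kcal/mol — `breakdown_consistency` reports
this honestly), and the printed correlation for the Autodock score column
does not match a Pearson coefficient computed from its own printed values
(0.32 vs the printed 0.13).  All other summary cells reproduce within one
unit of their last printed digit.

## Numerical choices

* L-BFGS convergence is tested on the analytic gradient's max component,
  10⁻⁵ kcal/mol/Å; the optimizer's own tolerance is set to the same value
  and restarts cover the cases where its internal criterion stops early.
* Duplicate detection, clustering and INN all use heavy-atom, in-place
  RMSD; the boundary conventions are: *exceeds* 0.1 Å to be distinct,
  *strictly below* 1.4 Å to be linked, *strictly below* 2 Å to be near
  native, and distance exactly at the clash cutoff rejects.
* Energy ties in the sorted set keep insertion order; the capacity cut is
  applied before the duplicate scan (identical accept/reject outcomes,
  constant-time rejection of hopeless candidates).
* Hessian step 10⁻⁴ Å balances truncation against round-off for force
  constants of order 10²; the diatomic closed form reproduces to ~10⁻⁹
  relative.
* Random draws: direction vectors from normalized Gaussians, radii by the
  cube-root transform — a fixed number of draws per trial keeps the RNG
  stream alignment deterministic for a given seed.

## Limitations

* No receptor flexibility, no symmetry-aware RMSD, no bond-order or
  protonation perception: inputs are expected protonated with explicit
  hydrogens, and PDB-format formal-charge information is limited to what
  the format encodes.
* The worker-count setting is a scheduling contract (independent trial
  workers merging into one master set, which any schedule must reproduce
  as the serial reference ordering); this implementation executes the
  reference ordering itself.
* Wall-clock halting (`time_budget`) exists for queue-driven runs but
  makes results schedule-dependent; the trial-count stop is the
  reproducible one and is the default.
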