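---
title: "pH-dependent analysis of dendrimer-siRNA complexes: models and methods"
author: "dendripH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH-dependent analysis of dendrimer-siRNA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendripH)
```

## The problem

Cationic peptide dendrimers condense and deliver siRNA, and their binding
is governed by electrostatics that change with pH: the dendrimer
N-termini (intrinsic pKa near 7.5) titrate across the physiological and
endosomal range (pH 7 to 5), so acidification makes the carrier more
charged and the complex tighter. Constant-pH molecular dynamics studies
of this system quantify the effect through a set of recurring analyses:
group titration curves with Hill fits and apparent pKa values
(conditioned on whether an amine touches a phosphate or sits in a
groove), geometric binding-mode statistics along the duplex,
solvent-accessible-surface "shielding" of the phosphates, conditional
free-energy landscapes, a protonation-weighted MM/PBSA decomposition,
and the Wyman-Tanford proton-linkage free energy difference between pH
values. `dendripH` implements that analysis layer as reusable, tested R
functions, together with a synthetic-ensemble generator so the whole
pipeline runs and can be validated without any trajectory downloads.

The MD engine itself is out of scope: the package analyses coordinate
ensembles, it does not produce dynamics.

## The coupled-site titration model

Protonation is sampled from a binary coupled-site model. A microstate
$s \in \{0,1\}^N$ has energy (kcal/mol)

$$E(s, \mathrm{pH}) = \sum_i s_i\left[\ln(10)\,RT\,(\mathrm{pH} - \mathrm{p}K_{a,i}^{\mathrm{int}}) + \phi_i\right] + \sum_{i<j} W_{ij} s_i s_j,$$

where $\phi_i$ is an environment term (negative values stabilize the
protonated form) and $W_{ij} \ge 0$ penalizes simultaneous protonation
of nearby sites. `sampleStates()` runs single-site Metropolis flips at
T = 310 K (one cycle = N attempted flips, first tenth of the cycles
discarded as burn-in) and reports both the running mean occupancy and
the final state -- the state a constant-pH MD cycle would adopt.
`exactOccupancies()` enumerates all $2^N$ states ($N \le 20$) and is the
oracle the sampler is tested against; with $W = 0$ both reduce to
independent Henderson-Hasselbalch terms.

Tautomer bookkeeping is deliberately collapsed to binary sites; the
package does not attempt to reconstruct any particular tautomer-resolved
scheme.

## Hill fits and conditional pKa values

Group titration curves pool all sites of a group (N-termini `G3_NTR`,
third-generation side chains `G3_SIDE`, second-generation side chains
`G2`) as replicates of one another, over post-burn-in frames of every
replicate ensemble. `hillFit()` fits

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\,n(\mathrm{pH} - \mathrm{p}K_a)}}$$

by Levenberg-Marquardt least squares (start: pKa at the half-occupancy
pH, n = 1; bounds $n \in (0, 4]$, pKa $\in [0, 14]$). Degenerate curves
(flat, or fewer than three pH points) return `converged = FALSE` rather
than numbers. A Hill coefficient below one signals anti-cooperative
proton binding among coupled sites; on curves generated from the model
itself the fit recovers the true $n = 1$ for uncoupled sites and a
depressed $n$ once coupling is switched on.

Conditional curves restrict the pooling frame-by-frame to sites whose
context is `PHOS` (within 4.0 A of a phosphate) or `GROOVE` (not PHOS,
within 6.0 A of the nearer groove marker set). Phosphate contact takes
precedence because it is the stronger interaction the conditional pKa is
meant to isolate. Curves are fitted pooled; per-replicate fits supply
the standard errors reported in the pKa table (`conditionalPkaTable()`),
matching the replicate-SEM convention used for all reported errors.
Choosing pooled fitting over fit-then-average was a genuinely open
design point; pooled fitting matches how the scatter of all site-frame
observations is usually presented, and the per-replicate machinery
remains available through the returned curve object.

The synthetic titrations span pH 4.0-9.5 in 0.5 steps. Production-style
binding analyses use pH 5 and 7 only; a fit needs the full grid, which
is why the generator exposes both.

## Geometry

All geometric statistics operate per frame on the atom table plus a
coordinate matrix:

* **Position along the duplex** -- distance from the dendrimer centroid
  to the closer duplex end, projected on the end-to-end axis via the
  cosine of the angle at that end, and mapped to a global 0-100
  coordinate anchored at the end carrying the RNA_A 5' terminus.
  Projections beyond the ends yield values < 0 or > 100. The anchor is a
  package convention: a single global axis makes runs comparable, and
  the out-of-range values remain interpretable.
* **Bending angle** -- the angle at the centroid of the central
  7-base-pair block between the centroids of the two terminal base
  pairs; 180 degrees is straight.
* **Groove assignment** -- nearest-marker-set assignment with a signed
  distance (positive toward the major groove, negative toward the
  minor); exact ties go to MAJOR, a documented tie-break.
* **Contacts, Rg, RMSD, charge** -- amine-phosphate pairs within 4.0 A;
  unweighted radius of gyration ("geometric center" means centroid, not
  center of mass); RMSD after least-squares superposition; total charge
  as the deprotonated-state sum plus one elementary charge per
  protonated site (phosphates carry -1 e).

## Surfaces

`sasa()` is a Shrake-Rupley implementation with a deterministic
golden-spiral point set (default 960 points, probe 1.4 A). Shielding is
the percentage of phosphate SASA occluded by the dendrimer,
$100\,(1 - \mathrm{SASA}^{\mathrm{complex}}_{\mathrm{phos}} /
\mathrm{SASA}^{\mathrm{RNA\ alone}}_{\mathrm{phos}})$, clamped to
[0, 100]. The denominator is the RNA-only value: the quantity is
dendrimer coverage of the phosphates, so the dendrimer must be absent
from the reference. Interface area uses the standard buried-surface
convention $(\mathrm{SASA}_D + \mathrm{SASA}_R -
\mathrm{SASA}_{DR})/2$.

## Free-energy landscapes

Landscapes live on (signed groove distance, phosphate distance). The
density is a product-Gaussian KDE; the energy is the Boltzmann
inversion

$$E(r) = -RT \ln\frac{P(r)}{P_{\max}},$$

zero at the density maximum and masked (never zero) where the density
underflows. Bandwidth defaults to Scott's rule per axis with a 0.25 A
floor, on a 0.1 A grid padded 3 A beyond the data. A literature
convention of quoting a single volumetric grid spacing does not
transfer unambiguously to a two-dimensional estimator, so the package
states its 2-D choices explicitly instead. At 310 K, $RT = 0.616$
kcal/mol, so a cell at half the maximal density sits at 0.427 kcal/mol.

## MM/PBSA and the PB solver

`mmpbsaBinding()` implements the single-trajectory protocol: complex,
dendrimer and RNA energies come from the same coordinates, so
conformational terms cancel and

$$\Delta G_{\mathrm{bind}} = E_{\mathrm{Coul}} + E_{\mathrm{VdW}} +
\mathrm{Solv}_{\mathrm{polar}} + \mathrm{Solv}_{\mathrm{apolar}}$$

holds exactly per frame. Charges are resolved per frame from the
protonation occupancy, which is what makes the energies pH-weighted.
Frames are taken every fifth post-burn-in frame by default -- one
evaluation per 100 ps at the nominal 20 ps frame interval.

Numerical choices, in order of consequence:

* **Vacuum dielectric.** The Coulomb term uses $\varepsilon = 4$, the
  same value as the PB solute dielectric, so both legs of the
  thermodynamic cycle share one reference medium; it is configurable.
* **PB discretization.** The solver is a finite-difference Poisson
  solver (linearized PB at zero ionic strength) with solute/solvent
  dielectrics 4/80, trilinear charge spreading, analytic Coulomb
  Dirichlet boundaries, and successive over-relaxation. The dielectric
  on each grid edge is the harmonic mean of the two dielectrics
  weighted by the fraction of the edge inside the solute. This
  smoothed boundary is essential: a sharp in/out assignment makes the
  Born-ion energy oscillate with grid alignment instead of converging
  under refinement. With smoothing, the q = 1 e, a = 2 A Born ion
  (closed form -19.72 kcal/mol) is reproduced to 3% at 1.0 A spacing,
  0.6% at 0.5 A and 0.1% at 0.25 A.
* **Convergence.** Relaxation stops when the maximum per-sweep
  potential change falls below 0.001 of the maximum potential, but
  never before 2 x (largest grid dimension) sweeps -- information
  propagates roughly one cell per sweep, and without the floor fine
  grids stop early and regress.
* **Grid spacing.** The solver default is 0.5 A (two points per
  Angstrom). The ensemble pipeline uses 1.5 A: the bead models are
  smooth at that resolution and the binding differences of interest are
  tens of kcal/mol.
* **Apolar term.** $\gamma \cdot \mathrm{SASA} + \beta$ with the classic
  $\gamma = 0.00542$ kcal/(mol A^2), $\beta = 0.92$ kcal/mol. In the
  binding difference the intercept cancels, so non-interacting partners
  bind with exactly zero apolar energy.
* **Ionic strength.** Zero; counterions are not part of the analysis
  subsets.

## Wyman-Tanford linkage

`wtLinkDdg()` evaluates
$\Delta\Delta G = \ln(10)\,RT\,(\Delta Q_{\mathrm{pH}} - \Delta
Q_{\mathrm{pH_{ref}}})$ with $\Delta Q$ the bound-minus-unbound mean
dendrimer charge at each pH, the unbound charge coming from apo
ensembles at matching pH. A charge difference of -1 e at 310 K gives
-1.419 kcal/mol. Strictly, proton linkage is an integral of $\Delta Q$
over pH; the two-point formula is the form in common use and is what
the package reports, while `wtLinkDdgIntegral()` provides the
trapezoidal integral for users who prefer the full relation. The two
agree when $\Delta Q$ varies slowly between the two pH values and
differ otherwise; no attempt is made to declare one of them "the"
answer.

## The synthetic-ensemble generator

`sampleEnsemble()` is the stand-in for constant-pH MD production runs.
It emulates, with deliberately simple geometry:

* a rigid idealized A-form-like 21-bp duplex (rise 2.81 A, twist 32.7
  degrees, phosphates at 8.8 A from the axis, one phosphate per
  nucleotide except the two 5' termini, so 40 phosphates carrying -1 e);
  major/minor groove marker sets at fixed phase offsets between the
  strands; base-pair pseudo-atoms on the axis carrying the terminal and
  central-window flags;
* a branched dendrimer bead tree (core tail, 2 G1, 4 G2, 8 G3 arms)
  with 8 N-termini, 8 G3 side-chain amines and 4 G2 amines (MH47: 0 G2
  amines, hydrophobic beads instead), every bond exactly 3.8 A;
* heterogeneous docking: per frame the dendrimer is randomly oriented,
  placed along the duplex around a target position with Gaussian
  jitter, and pulled radially until the closest amine-phosphate pair
  sits at a contact-forming distance drawn around 3.2 A, so nearly all
  frames have at least one electrostatic contact;
* protonation from the coupled-site model, with the environment field
  on each amine computed as a Debye-screened Coulomb sum over the
  phosphates ($\varepsilon_{\mathrm{eff}} = 40$, screening length 6 A,
  12 A cap) in the bound state and zero in the apo state, and
  amine-amine couplings as a weaker screened sum
  ($\varepsilon_{\mathrm{eff}} = 80$, same screening). The screening
  length matters: without it the summed field of the many phosphates
  within the cap overwhelms a single direct contact, pushing apparent
  pKa shifts far above the ~+1 unit regime the model is meant to
  emulate and inverting the phosphate-versus-groove ordering.

These choices give the ensembles the statistical structure the analyses
assume: binding raises N-termini protonation (so bound apparent pKa >
apo), phosphate-contact sites shift more than groove-buried ones,
lysine side chains stay > 95% protonated across pH 5-7, dendrimer
charge grows with acidity, and the less-charged MH47 binds more weakly
than MH18 at matched geometry.

What the generator does **not** emulate -- and therefore what passing
tests do and do not show about real systems: all-atom geometry and
sequence effects, duplex flexibility (the scaffold is rigid by design;
bending and RMSD analyses are validated on constructed cases),
conformational coupling between protonation and structure within a
frame, tautomers, counterions, and dendrimer aggregation. Direction-of-
effect agreement on these ensembles validates the analysis machinery,
not the force field of any particular simulation.

## Reproducibility and problem sizes

Every stochastic step runs under an explicit seed; replicate
identifiers offset the seed deterministically, and `runPipeline()`
writes byte-identical outputs for identical configurations. The test
suite validates the samplers against exact enumeration, the PB solver
against the Born ion, SASA against the analytic sphere, and the fits
against their generating parameters. Tests and examples run at desk
scale -- typically 2-3 replicates of 30-40 frames per condition, a pH
grid of 12 points, PB at 1.5 A spacing -- sizes chosen so the full
suite completes in a few minutes while keeping every statistical check
well clear of its tolerance.

## Known limitations

* The PB solver is linearized, zero-ionic-strength, single-grid; it is
  validated on bead systems and is not a replacement for production PB
  codes on all-atom solutes.
* Conditional pKa values inherit selection effects: sites enter the
  PHOS subset because of geometry, not protonation, so conditional
  shifts are larger than group-average shifts.
* The Hill fit reports fit-covariance standard errors that ignore
  between-replicate correlation; replicate SEMs are reported alongside
  for that reason.
* Absolute MM/PBSA values on bead models are not comparable to all-atom
  results; only differences and orderings are meaningful here.
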