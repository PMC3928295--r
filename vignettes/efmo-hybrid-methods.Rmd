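---
title: "Fragment-based hybrid RHF:MP2 energies and reaction-path scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based hybrid RHF:MP2 energies and reaction-path scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragopt)
```

## The model

`fragopt` implements a two-body fragment expansion of the total energy of a
large molecular system.  The system is divided into fragments; each fragment
is evaluated in the gas phase (without embedding), close fragment pairs are
evaluated quantum mechanically as dimers, and everything else is classical:

$$
E \;=\; \sum_I E^0_I
\;+\; \sum_{\substack{I>J\\ R_{IJ}\le R_\mathrm{cut}}}
      \left(\Delta E_{IJ} - E^\mathrm{pol}_{IJ}\right)
\;+\; \sum_{\substack{I>J\\ R_{IJ}> R_\mathrm{cut}}} E^\mathrm{elec}_{IJ}
\;+\; E^\mathrm{pol}_\mathrm{tot}
$$

where $E^0_I$ is the monomer energy, $\Delta E_{IJ} = E_{IJ} - E^0_I - E^0_J$
the two-body interaction of a dimer, $E^\mathrm{pol}_{IJ}$ the classical
induced-dipole energy of the isolated pair (subtracted so that polarization
is not double-counted between the quantum dimer term and the system-wide
classical term), $E^\mathrm{elec}_{IJ}$ the Coulomb interaction of
atom-centered charges for far pairs, and $E^\mathrm{pol}_\mathrm{tot}$ the
self-consistent induction energy of the whole system.  Many-body
polarization is thus carried entirely by the classical model built from
backend-supplied atom-centered isotropic polarizabilities — no embedding
potentials enter the fragment calculations.

The pair cutoff $R_{IJ}$ is the *unitless relative distance*: the minimum
interatomic distance of the pair divided by the sum of Bondi van der Waals
radii.  The default cutoff of 1.5 is the conventional choice for this family
of methods; pairs beyond it interact through charges only.

### Frozen domain and dimers (FDD)

For geometry optimization inside a large system, fragments are partitioned
into three domains: an **active** domain A whose atoms move, a **buffer** b
whose geometry is frozen but whose densities polarize, and a **frozen**
domain F whose geometry *and* densities are fixed after their first
evaluation.  In this implementation FDD is a caching semantics: every term
of the energy is always assembled, but records belonging to F (and to pairs
not touching A) are served from a geometry-keyed cache after their first
computation, so a cached record can never be served for coordinates that
have changed.  The assembled total is therefore bit-for-bit identical with
FDD on or off — which the test suite asserts — while the audit
(`fdd_cache_audit()`) verifies that frozen-domain work is done exactly once
per run.  The domain-resolved term structure (internal A and b energies, the
A–b and A–F interactions) is logged in every `energy_report`.

### The hybrid RHF:MP2 layer

A single *high-level* fragment H (a member of A — in an enzyme study, the
reacting substrate) is additionally treated at the MP2 level: the total
energy gains the strictly additive, non-positive correlation energy
$E^\mathrm{corr}_H$, evaluated with its own (typically larger) basis, and
the gradient gains the corresponding correlation gradient on H's atoms only.
Everything else in the expansion stays at the RHF level.  This keeps the
extra cost of a correlated optimization bounded by one fragment while
letting the reacting region relax on a correlated surface.

## Gradients

The analytic gradient is assembled on active-domain atoms only (all other
atoms are zero-masked): monomer gradients of A fragments, dimer interaction
gradients of pairs touching A, far-pair Coulomb gradients, and the
polarization gradient.  The induction gradient uses the stationarity of the
converged dipoles,
$\mathrm{d}E = -\mu^\top \mathrm{d}F - \tfrac12 \mu^\top \mathrm{d}T\,\mu$,
with fixed converged dipoles plus field-derivative terms.  Charges and
polarizabilities of b and F fragments are constants of the run (consistent
with density freezing), so the assembled gradient is exact for the
implemented energy; correctness is defined — and tested — against a central
finite-difference oracle (`numerical_gradient()`, default step $10^{-4}$
Bohr, agreement to $10^{-7}$ Hartree/Bohr on the mock backend).

## Polarization solver

Induced dipoles solve $\mu_i = \alpha_i (F^\mathrm{static}_i + \sum_j
T_{ij}\mu_j)$ with the dipole-field tensor restricted to *inter*-fragment
site pairs; intra-fragment response is already inside the quantum monomer
energies.  The solver is a Jacobi iteration (tolerance $10^{-10}$ a.u. on
the largest dipole change, at most 200 sweeps) with a dense linear solve
available as an oracle; both agree to $10^{-10}$ Hartree on the test
systems.  No short-range damping is applied by default — the simplest
defensible choice at these site separations; optional Thole-style
exponential damping is available behind `pol_damping` for the energy path
(the analytic gradient supports the undamped form only and says so if asked
otherwise).  Whether polarization spans all of F∪b∪A (default) or only b∪A
is switchable via `pol_domain`; both paths are tested.

## Backend contract and the mock engine

No SCF or MP2 code lives in this package.  Backends satisfy a small
contract (`backend_evaluate()`): given a subsystem with its fragment-group
structure, return the energy, correlation energy, analytic gradients,
atom-centered charges and isotropic polarizabilities.  Engines register by
string key (`register_backend()`), and the contract tests loop over every
registered backend.

The shipped `mock_backend()` is a documented closed form chosen so that
every framework property is *decidable*: harmonic terms on all
intra-fragment atom pairs (reference lengths per element pair; the water
reference geometry is an exact minimum), Lennard-Jones plus fixed-charge
Coulomb between fragments (strictly pairwise, so the two-body expansion is
exact and the supersystem energy is an oracle), and a damped dispersion
$-C_6/(r^6+d^6)$ as "MP2 correlation" — strictly negative, smooth, bounded
below, and scaled per basis label so basis-set effects are observable.
Per-fragment intra-potential overrides let fixtures install bespoke
surfaces.

## Restrained optimization and adiabatic mapping

Reaction paths are traced by a sequence of restrained optimizations:
harmonic distance restraints $\tfrac{k}{2}(r-r_0)^2$ (default
$k = 500$ kcal mol$^{-1}$ Å$^{-2}$, the only dimensionally coherent reading
of the force constant for a distance restraint) on the breaking and forming
bonds, each scan point starting from the previous converged structure.  The
reaction coordinate is $R = r_\mathrm{breaking} - r_\mathrm{forming}$,
negative on the reactant side.  The minimizer is quasi-Newton BFGS over
Cartesian coordinates of active atoms with Armijo backtracking (accepted
steps are non-increasing by construction; internal-coordinate optimization
is out of scope).  Convergence applies to the gradient *including* restraint
forces, by default the maximum component against a threshold of $10^{-4}$
Hartree/Bohr (`convergence_measure` switches to RMS).  Non-convergence is a
flagged result, not an error, and a scan continues past flagged points.

Because each point is restrained, the recovered profile carries a
restraint-stiffness bias.  For restraints of stiffness $k$ on both bonds the
effective restraint on $R$ is $k/2$, and with $k_\mathrm{well}$ the largest
curvature of the underlying profile over the scanned range, the recovered
barrier deviates from the true one by at most the conservative bound
$\Delta E^\ddagger\, k_\mathrm{well}/(k_\mathrm{well}+k/2)$; the acceptance
suite asserts recovery within this bound (observed deviations are two
orders of magnitude smaller, dominated by the scan-grid discretization).

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated systems:

* `make_water_chain()` / `make_water_cluster()` — rigid waters at the
  reference internal geometry on a line or a jittered grid, with seeded
  perturbations.  One fragment per molecule emulates the no-severed-bonds
  fragmentation this framework supports.
* `make_toy_reaction()` — a 4-atom substrate whose intra potential is a
  closed-form double well in $R$ (barrier ≈ 18.4 kcal/mol, reaction energy
  ≈ −4.8 kcal/mol, a desk-scale stand-in for an enzyme-catalysed
  rearrangement), embedded among neutral neon spectators assigned to b and
  F.  The substrate potential is defined identically at both levels (its
  correlation term is zero) so the scan probes the optimizer and FDD
  machinery against an analytic reference rather than the correlation term;
  hybrid additivity with nonzero correlation is exercised on the water
  fixtures.

Problem sizes are kept small — chains of up to 10 waters, 21-point scans,
12-site polarization systems — which is ample for the closed-form checks
these fixtures support.  What passing these tests shows is that the
*framework* (expansion, caching, gradients, solver, optimizer, bookkeeping)
is correct for the implemented energy.  What it cannot show is anything
about real electronic structure: the mock potential has no charge transfer,
no exchange repulsion anisotropy, no basis-set superposition, and its
"correlation" is a dispersion surrogate.  Conclusions about a real system
require a real backend behind the same contract, and fragmentations that
sever covalent bonds are outside this framework's scope.

## Numerical choices and degenerate inputs

* Internal units Bohr/Hartree; all file I/O and restraint inputs in
  Angstrom (1 Bohr = 0.52917721067 Å, 1 Hartree = 627.509474 kcal/mol).
* Cache keys round coordinates to $10^{-10}$ Bohr and include level and
  basis, making FDD reuse well-defined.
* Geometries reject non-finite coordinates and atoms closer than 0.1 Bohr;
  coincident inter-fragment sites raise singularity errors rather than
  producing infinities.
* A single-fragment system is legal everywhere and reduces to its monomer
  energy with zero pair, far and polarization terms.
* Charges are user-supplied per fragment, never inferred; only closed-shell
  fragments (multiplicity 1) are accepted.
* Atom indices are 1-based in the R API and 0-based half-open in the
  on-disk fragment-spec and scan formats.
* Domain assignment measures the active radius from the center fragment and
  the buffer radius from the whole active domain, using minimum interatomic
  distances over *all* atoms (not heavy atoms only) — the all-atom reading
  is documented rather than assumed.

## Known limitations

* No treatment of severed covalent fragment boundaries; fragmentations must
  cut no bonds.
* No three-body terms, no embedding-potential monomers, no Hessians.
* The buffer-domain response to active-atom motion is frozen (charges of b
  and F are run constants); the gradient is exact for the implemented
  energy, not for a model with relaxing buffer densities.
* Anisotropic polarizabilities and charge-penetration corrections are out
  of scope; far pairs use charges only.
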