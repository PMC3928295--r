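# fragopt

Fragment-based hybrid RHF:MP2 energies, analytic gradients and restrained
reaction-path scans for large molecular systems.

## What problem this solves

Quantum-chemical geometry optimization of a reacting site inside a large
system (an enzyme active site, a molecular cluster) is too expensive at a
correlated level for the whole system.  `fragopt` implements the two-body
effective fragment molecular orbital (EFMO) expansion with
frozen-domain-and-dimers (FDD) bookkeeping: the system is divided into
fragments, monomers and close dimers are evaluated quantum mechanically
(gas phase, no embedding), far pairs interact classically, and many-body
polarization is a self-consistent induced-dipole model over atom-centered
polarizabilities,

```
E = Σ_I E⁰_I + Σ_{R_IJ ≤ cut} (ΔE_IJ − E_pol,IJ) + Σ_{R_IJ > cut} E^elec_IJ + E_pol^tot .
```

On top of the RHF-level expansion, a single *high-level* fragment H — the
reacting substrate — receives its MP2 correlation energy and gradient,
strictly additively:  `E_hybrid = E_RHF + E_corr(H)`.  Geometry
optimization moves only the atoms of an *active* domain A; a polarizable
buffer b and a frozen domain F keep fixed geometries, and F's records are
computed exactly once per run (FDD caching).  Reaction paths are traced by
adiabatic mapping: sequences of optimizations restrained on the breaking
and forming bonds (k = 500 kcal mol⁻¹ Å⁻²), reported against the signed
reaction coordinate `R = r(breaking) − r(forming)`.

The electronic-structure engine sits behind a small backend contract; the
shipped deterministic mock backend (documented closed-form potential) makes
the entire framework testable without an SCF program, and a real engine can
register under the same contract.

Intended users: method developers and computational chemists who need the
fragment-expansion *framework* — bookkeeping, caching, gradients, scan
machinery — with every piece verifiable against closed-form oracles.

## Worked example

Three waters, everything active, water 1 as the MP2 fragment:

```r
library(fragopt)

w    <- make_water_chain(3, spacing = 3.0)
part <- domain_partition(frozen = integer(0), polarizable = integer(0),
                         active = 1:3, high_level = 1L, w$fragments)
cfg  <- run_config(mp2_basis = "cc-pVDZ")
efmo_hybrid_energy(w$geometry, w$fragments, part, cfg)
#> <energy_report> EFMO-RHF:MP2
#>   monomer sum                  0.0000000000 Hartree        0.000000 kcal/mol
#>   QM dimer sum                 0.1183414275 Hartree       74.260367 kcal/mol
#>   pair pol correction          0.0026344243 Hartree        1.653126 kcal/mol
#>   far pair sum                 0.0006800221 Hartree        0.426720 kcal/mol
#>   classical polarization      -0.0028463602 Hartree       -1.786118 kcal/mol
#>   MP2 correction (H)          -0.1309130999 Hartree      -82.149210 kcal/mol
#>   TOTAL                       -0.0121035863 Hartree       -7.595115 kcal/mol
```

The monomer sum is zero because the rigid reference water is an exact
minimum of the mock monomer potential; the dimer sum carries the pair
interactions of the two adjacent pairs (the 1–3 pair is beyond the 1.5
relative-distance cutoff and appears as classical far-pair electrostatics);
the pair-polarization correction removes from the quantum dimers what the
system-wide classical polarization term re-adds self-consistently; and the
MP2 correction is the (negative) correlation energy of fragment 1 in its
own cc-pVDZ-labelled basis.  The total is their exact sum.

Scanning the shipped toy double-well reaction (4-atom substrate among
frozen spectators) and summarizing:

```r
toy  <- make_toy_reaction()
path <- scan_reaction_path(toy$geometry, toy$fragments, toy$partition,
                           toy$breaking_pair, toy$forming_pair,
                           toy_scan_targets(21), run_config(),
                           backend = toy$backend)
glance(path)
#> # A tibble: 1 × 5
#>   n_points barrier_kcal reaction_energy_kcal ts_coordinate n_converged
#>      <int>        <dbl>                <dbl>         <dbl>       <int>
#> 1       21         18.3                -4.80        0.0104          21
```

The 21-point restrained scan recovers the fixture's analytic barrier
(18.39 kcal/mol) to 0.07 kcal/mol and the reaction energy (−4.80 kcal/mol)
to 6·10⁻⁴ kcal/mol; `tidy(path)` gives the full path table and
`autoplot(path)` the energy profile.

A command-line driver wraps the same pipeline
(`inst/scripts/fragopt energy|grad|opt|scan|fixture`), reading XYZ/PDB
geometries and the YAML fragment/domain spec (0-based half-open atom
ranges; see `inst/extdata/` for examples).

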