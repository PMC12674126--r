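---
title: "Quantifying the actin G-to-F transition: methods and design"
author: "actinconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the actin G-to-F transition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinconf)
```

## The problem

Actin subunits adopt two limiting conformations: the *twisted* state of the
free monomer (G-actin) and the *flattened* state of subunits inside a
filament (F-actin). The transition is a rigid-body rotation of the SD1/SD2
lobe against the SD3/SD4 lobe, and it is coupled to polymerization,
nucleation and severing. This package quantifies where a given subunit sits
on that axis, from ordinary PDB/mmCIF coordinates, using a small set of
geometric observables that are standard in the actin field:

* **φ SD1–SD4** — the torsion angle through the four subdomain centers of
  mass, taken in the order SD2–SD1–SD3–SD4. Twisted monomers sit near
  −23°, flattened filament subunits near −6°.
* **ΔSD1 / ΔSD2** — how far the SD1 and SD2 centers of mass sit from their
  position in a G- or F-actin reference after superposing the rigid SD3/SD4
  lobe (Cα Kabsch fit). ΔSD1 is reported both as a displacement and as the
  angle subtended at the SD3 center of mass.
* **W-loop gate** — the Tyr143 OH to Gly168 O hydrogen-bond distance
  (the "gate" guarding the Met44 binding pocket) and the Tyr143 Cα–Tyr169
  Cα width of the W-loop itself.
* **Matched-Cα RMSDs** — pairwise Kabsch superpositions matched by author
  residue number.
* **Interface buried areas** — half the solvent-accessible surface area
  lost on complexation (the PISA convention), from a Shrake–Rupley
  calculation.
* **Tilt/displacement** — after anchoring one subunit of a nucleus onto its
  filament counterpart, the residual rigid-body rotation of a second
  subunit and the displacement of a probe atom (by default Asp244 Cα, in
  SD4).

## Subdomain definition

The subdomains are fixed author-numbered residue ranges:
SD1 = 7–31, 74–136, 347–364; SD2 = 34–39, 53–68; SD3 = 149–179, 274–331;
SD4 = 185–256. These ranges avoid the termini and the mobile D-loop
(residues ~40–50), so they are modeled in essentially every deposited actin
structure; that is what makes center-of-mass comparisons across structures
meaningful. `assign_subdomains()` intersects the ranges with the residues
actually present: an empty subdomain is an error, and coverage below 80% of
a range warns, because a half-disordered subdomain silently biases its
center of mass. `delta_offsets()` goes one step further and uses only
residues modeled in *both* structures being compared.

Centers of mass are mass-weighted over all non-hydrogen atoms of the
realized residues by default (`weighting = "mass"`), matching the behavior
of the standard visualization tools this kind of analysis is usually done
in; `"geometric"` and `"calpha"` weightings are available for sensitivity
checks. On symmetric synthetic conformers all three agree to a fraction of
a degree.

## Sign convention and thresholds

`torsion_angle()` uses the standard right-handed (IUPAC-style) dihedral:
for the quadruple (1,0,0), (0,0,0), (0,0,1), (0,1,1) it returns +90°, in
agreement with the common structural-analysis libraries. Under this
convention the flattening dihedral of actin conformers is negative, with
observed F-like values spanning about −6.2° to −10.9° and G-like values
about −14.8° to −23.6°.

`classify_conformer()` is a step function with two thresholds placed inside
the gap between those ranges: F-like at φ ≥ −12°, G-like at φ ≤ −14°,
intermediate between. No observed value of either group lies within 1° of
the *opposite* class region (the nearest F-like value is 3.1° from the
G boundary, the nearest G-like value 2.8° from the F boundary), so a 1°
measurement error can never flip a conformer across the G/F divide. The
thresholds live in `default_config()`, not in code, and can be overridden.

Gate-state calls use closed ≤ 5 Å and open ≥ 8 Å. Observed closed gates
cluster near 3–4.1 Å (a hydrogen bond plus thermal spread) and open gates
at 8–12 Å, so 5 Å gives the closed call a margin over the largest observed
closed distances while 8 Å is the lower edge of the open range. Between the
two the state is reported honestly as `intermediate` rather than forced
into a binary.

## Superposition and matching

`kabsch_fit()` is the textbook SVD solution with the reflection suppressed
by sign-flipping the smallest singular vector, so the returned rotation
always has determinant +1; rank-deficient (collinear) point sets are
refused rather than silently resolved. Residue matching pairs one named
atom (Cα by default) per residue by identical author number and insertion
code — actin structures share author numbering, so no sequence alignment is
needed. The optional `trim = "iterative"` mode removes pairs deviating by
more than twice the current RMSD for up to 5 cycles; the default is no
trimming, and published matched-Cα counts obtained with unknown rejection
heuristics should be expected to differ from plain intersection matching by
a few residues.

`tilt_displacement()` defines tilt as the rotation angle (from the trace of
the Kabsch rotation) of the probe chain's residual fit after the anchor
chains have been superposed. For a probe that moved as a rigid body this
recovers the constructed hinge angle exactly, independent of where the
hinge axis passes; the probe-atom displacement, by contrast, does depend on
the atom's distance from the hinge, which is why both numbers are reported.

## Surface areas

`sasa()` is a Shrake–Rupley calculation on a deterministic golden-spiral
lattice (no random sampling — two runs give identical areas). Van der
Waals radii are C 1.70, N 1.55, O 1.52, S 1.80, others 1.80 Å; the probe
radius defaults to 1.4 Å. At the default 960 points per atom an isolated
carbon reproduces its analytic sphere area to well under 1% and totals
change by less than 1% when the lattice is doubled. `buried_area()` reports
half the SASA loss on complexation, the PISA interface-area convention, so
values are directly comparable to published interface areas. Exact
parameterizations of surface programs differ; agreement within a few
percent — not bit-exactness — is the reproducibility contract, and small
interfaces (tens of Å²) carry proportionally larger relative uncertainty.

## Trajectory statistics

`gate_timeseries()` extracts the two W-loop distances per frame of a
multi-model structure; frames with missing gate atoms abort with the frame
index named, because silently skipping frames biases occupancy statistics.
`open_fraction()` is the exact counting statistic
(#frames with d ≥ threshold)/n at a default threshold of 8 Å. It is
invariant to frame reordering and monotone non-increasing in the
threshold. Published open-state occupancies from long molecular-dynamics
runs require those trajectories as input; the package's contract, tested
here, is exact recovery of known generator parameters on synthetic
two-state trajectories.

## The synthetic generator

`make_conformer()` builds pseudo-actin chains for testing: four atom
clusters on an actin-scale scaffold (17–25 Å center separations) whose
centers of mass realize the requested φ *exactly* before noise. Cluster
offsets are generated zero-mean, and the SD3 cluster is shifted to
compensate for the explicitly placed gate atoms (Gly168/Tyr169 lie inside
SD3's range), so the construction is exact rather than approximate.
Residue numbers are drawn from the canonical subdomain ranges and Asp244 is
always included, so the real partitioning, lookup and probe code paths run
unchanged on synthetic structures. Each cluster residue carries three
heavy pseudo-atoms (CA/CB/CG) — real actin residues average about eight —
so coordinate noise is averaged over realistic atom counts in the
center-of-mass calculation; with 0.2 Å isotropic noise the dihedral is
recovered within 0.5° across the full G-to-F range.

`twist_series()` interpolates φ by rotating the SD1+SD2 block about the
SD1-COM → SD3-COM hinge axis, which adds directly to the torsion: the sweep
is exactly linear and the SD3/SD4 block is bit-identical across the series
(useful for testing fit/report selections). `make_gate_trajectory()`
produces two-state gate dynamics, either independent draws or a stationary
two-state Markov chain (stay parameter 0.95 by default) so the counting
statistics are also exercised under autocorrelation. `make_trimer()`
assembles rigid copies into nucleus-like oligomers; overlapping placements
warn rather than error, since deliberately clashing fixtures are useful.

What the generator does **not** emulate: real side-chain packing, sequence,
secondary structure, correlated (non-isotropic) coordinate error, and any
physics of the G-to-F pathway. Passing the round-trip tests therefore
demonstrates that the *measurement* chain is correct and self-consistent,
not that any particular real structure will yield any particular value.

## Numerical choices

* Torsions are computed with the atan2 formulation (never acos), range
  (−180°, 180°]; degenerate quadruples raise errors instead of returning
  garbage.
* Altloc resolution defaults to highest occupancy with alphabetic
  tie-break — fully deterministic.
* Occupancies outside [0,1], non-finite coordinates, empty atom sets,
  sub-3-point superpositions and missing gate atoms all fail loudly with
  the offending entity named.
* PDB output refuses residue numbers above 9999 rather than writing
  corrupted fixed-width records.
* Unknown elements fall back to the mass of carbon with a warning.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
fixtures: 31-point dihedral grids (one conformer per degree from −30° to
0°), 10⁴ random torsion quadruples, ≤6-point Kabsch toys against a
10°-grid + simplex brute force, 5000-frame gate trajectories, and trimers
of full-coverage conformers (~900 atoms per chain). These sizes were chosen
so every statistic is comfortably resolved (e.g. the 99% binomial band on a
5000-frame open fraction is ±1.8 percentage points) while the whole suite
runs in about a minute.

## Known limitations

* Residue matching assumes shared author numbering; structures renumbered
  away from the actin convention need renumbering before comparison.
* Buried areas depend mildly on the radii set; comparisons against values
  computed with other programs should allow several percent.
* The multi-model PDB reader requires identical atom composition across
  frames (the natural output of trajectory post-processing tools); binary
  trajectory formats are out of scope.
* ΔSD1's angle is defined at the SD3 center of mass; other reasonable
  vertex choices (e.g. the hinge midpoint) give slightly different angles,
  so the definition is part of the reported quantity.
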