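---
title: "Aromatic pathway geometry and Marcus transport in helical pili"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aromatic pathway geometry and Marcus transport in helical pili}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piliconduct)
```

## The model

Conductive type IV pili are helical polymers of a small pilin whose
N-terminal α-helix carries six aromatic residues (mature numbering: F1,
F24, Y27, Y32, F51, Y57). In the isolated subunit these rings are far
apart (≥ 8.7 Å), so any continuous π–π chain can only arise from the
packing of subunits in the assembled filament. The package treats the
question in two largely independent halves:

* **Geometry.** A pilus is one subunit repeated under a screw operation:
  subunit *i* is subunit 0 rotated by *i·θ* about the axis and
  translated by *i·h* along it. Given any assembly, the aromatic rings
  (the six-carbon carbocycle CG–CZ of each Phe/Tyr; the Tyr hydroxyl is
  not part of the conjugated ring we track) become nodes of a graph
  whose edges are interaromatic (centroid–centroid) distances. The
  electron-transfer pathway is the minimal-total-distance geodesic
  between F1 rings of distant subunits, and the *smallest symmetric
  unit* is its segment from F1 of subunit P−1 to F1 of subunit P —
  four rings whose three steps d₁ (F1,F24), d₂ (F24,Y27), d₃ (Y27,F1′)
  repeat with the helical period.

* **Transport.** Electronic couplings *t* (from dimer frontier-orbital
  splittings, energy-gap scheme: t = ΔE/2) and the reorganization
  energy λ (four-point scheme, λ = λ_D + λ_A) feed the zero-driving-force
  Marcus prefactor, an upper bound on the hopping rate:
  w = (t²/ħ)·√(π/(λ·k_B·T)). The slowest step along the symmetric unit —
  the one associated with the largest distance, the *bottleneck* —
  limits one-dimensional diffusion, D = w·z₀², and the Einstein relation,
  carrier density, conductivity and conductance follow:
  μ = eD/(k_BT), ρ = 4/(π r₀² z₀), σ = eρ(μ_h+μ_e), G = σS/l.

The split matters: the DFT-level scalars are *inputs* (a small JSON
block), never recomputed, while everything geometric and everything
downstream of the scalars is recomputed from first principles here.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| temperature T | 298 K | reproduces the published diffusion→mobility pairs to 3 significant figures (300 K errs by ~0.7 %) |
| periodic cell height z₀ | 3.10 Å | back-derived from the published rate/diffusion pairs via D = w·z₀²; consistent to ±0.01 Å across all four carrier/model combinations |
| packing radius r₀ | 13 Å | the stated radius of the aromatic packing cylinder |
| carriers per cell | 4 | one per ring of the smallest symmetric unit |
| graph cutoff | 7 Å | covers the largest observed pathway step (6.1 Å) while excluding the ≥ 8.7 Å intra-subunit pairs |
| ring cross-section S | π(1.39 + 1.7)² ≈ 30 Å² | carbocycle circumradius plus a carbon van der Waals radius |
| conductor length l | bottleneck distance | the largest interaromatic step |
| flat-harmonic (low res) | x₀ = 10, sd = 0.5, t = 5 Å on Cα | coarse contact restraint |
| flat-harmonic (high res) | x₀ = 4, sd = 2, t = 0.5 Å on N–O | salt-bridge distance scale; the (x₀, sd, t) assignment of the triple (4, 2, 0.5) is the physically sensible one (N–O ≈ 4 Å) and all three are exposed |
| RMSD cluster cutoff | 1.75 Å | structural-similarity basin clustering |
| DBSCAN | ε = 3, minPts = 10 | rotation-angle basin detection |
| k-means seed | 1234, 25 restarts | deterministic restarts, labels renumbered by ascending center |

Since S and l are not uniquely fixed by any published value, the
conductance G is reported as an order-of-magnitude quantity; σ and the
mobilities are the precise outputs.

## Design choices where the ground was open

* **Rate prefactor.** Several typeset variants of the Marcus prefactor
  circulate; we use the standard ΔG° = 0 form
  w = (t²/ħ)√(π/(λk_BT)) ≡ (2π/ħ)t²/√(4πλk_BT). With the published λ =
  0.37 eV and T = 298 K this reproduces the published diffusion
  coefficients through the single z₀ above, which is the strongest
  internal-consistency check available.
* **Flat harmonic.** Implemented as the symmetric two-branch form (zero
  inside the band, quadratic in the excursion outside, both directions):
  a restraint must penalize distances that are too small as well as too
  large.
* **Ambiguous constraints.** The minimum is taken per candidate *pair*
  penalty (min(C₁…Cₙ)), not over whole-assembly alternatives; adding a
  candidate can therefore never increase a score, which the tests assert.
* **Edge weights.** Pathway edges carry centroid (interaromatic)
  distances; proximal carbon–carbon distances (minimum over the 36
  ring-atom pairs) are reported alongside but do not steer the geodesic.
* **Tie-breaks.** Among equal-length shortest paths the lexicographically
  smallest (subunit, residue) sequence is returned, so results are
  reproducible across igraph versions.
* **Angles as scalars.** Rotation angles are clustered on the plain line:
  observed basins (32°–163°) never straddle the 0°/360° wrap. A circular
  metric would be needed for layouts that do.
* **Leader clustering.** The reference implementation of
  structural-similarity clustering in docking pipelines is unpublished;
  we use energy-ordered greedy leader clustering, which preserves its
  two key properties (the lowest-energy model founds the biggest basin;
  every member is within the cutoff of its leader).

## What the synthetic generators emulate

`make_ideal_pilin()` is a 61-residue poly-alanine α-helix (textbook
1.5 Å rise, 100° twist per residue, Cα–Cα = 3.8 Å) with ideal hexagonal
rings grafted at the six aromatic positions. It is *not* a
sequence-faithful pilin: every downstream operation consumes only
backbone and ring geometry, so chemical fidelity would add nothing to
the tests.

`make_pathway_pilus()` plants the pathway distances exactly: F1, F24,
Y27 of one subunit are stacked parallel to the axis at radius r,
separated by d₁ and d₂, and the screw operation fixes r so the closing
step to the next subunit's F1 is exactly d₃ (feasible iff
d₃² > (h − d₁ − d₂)²). The remaining rings are placed ≥ 8 Å off-path.
The default rotation is 100.8° per subunit — the helical symmetry of
the experimentally solved homologous type IV pilus from which pilus
models are conventionally seeded — while the default rise of 13 Å is a
modelling convention of the generator: it is chosen so that the planted
three-step chain is the *unique* geodesic at the 7 Å cutoff (at
smaller rises a diagonal Y27→F24′ contact dips under the cutoff and
would short-circuit F1). The generator verifies both the off-path
margin and this uniqueness property and raises an infeasibility error
rather than emitting an ambiguous fixture.

Consequences for interpretation: passing the planted-geometry tests
shows the measurement chain (ring extraction → graph → Dijkstra → unit
→ distances) is exact on ideal geometry and stable under small noise
(recovery error scales as O(σ)). It does not validate any claim about
real pilus conformations, which must come from experimentally derived
subunits fed through the same chain via `read_pdb()` and
`apply_helical_symmetry()`.

## Numerical conventions

* All coordinates are Å; unit conversion to SI happens exactly once, at
  the operation boundary (`diffusion_coefficient`, `carrier_density`,
  `conductance`); energies stay in eV with k_B and ħ in eV units.
* Ring normals are the smallest-principal-component eigenvector of the
  centered ring atoms, signed into the +z half-space; centroids are
  plain means, invariant under atom permutation.
* Kabsch superposition uses the SVD with the determinant correction, so
  the returned rotation is always proper; degenerate inputs (< 3
  points, length mismatch) are rejected rather than silently handled.
* Helical parameter recovery averages consecutive-centroid axial and
  azimuthal displacements; it is exact on ideal assemblies and its
  noise sensitivity is tested at σ = 0.01 Å.
* k-means uses Lloyd's algorithm with seeded random restarts (best of
  25 by WCSS); on small inputs it matches the exhaustive contiguous
  1-D partition minimizer, which the tests check directly.
* The problem sizes used throughout the suite — 14–21 subunits, ≤ 8-node
  brute-force path graphs, 100-model angle ensembles — are the package's
  own choices: large enough to exercise the helical periodicity and
  clustering structure, small enough that every oracle can be exhaustive.

## Known limitations

* No docking search: helical parameters are inputs (or planted), never
  optimized against an interface energy. The restraint scorer evaluates
  a given assembly; it does not move it.
* No electronic-structure calculations: couplings and reorganization
  energies enter as scalars. The orbital "fixtures" invert the
  energy-gap scheme exactly and are synthetic by construction.
* The conductance depends on an assumed ring cross-section; treat G as
  an order of magnitude.
* Multi-model NMR files are read one model at a time; no ensemble
  averaging.
* PDB writing is limited to single-character chain ids (the fixed-column
  format); in-memory assemblies beyond 26 subunits use two-character
  ids and must be split for export.
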