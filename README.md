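# piliconduct

Type IV pili of *Geobacter sulfurreducens* conduct electrons over
micrometres, and one proposed mechanism is a continuous π–π chain of
aromatic side chains (F1, F24, Y27 of the mature pilin) running along the
filament's helical axis. `piliconduct` implements the full computational
chain needed to evaluate that hypothesis from structure to conductance:

1. **Helical assembly** — build an N-subunit pilus by applying a screw
   operator (rise *h*, rotation *θ* about the axis) to one pilin subunit,
   and recover those parameters from any assembly.
2. **Restraint scoring** — flat-harmonic distance restraints
   *f(d) = ((|d − x₀| − t)/sd)²* outside the flat band |d − x₀| ≤ t, with
   ambiguous (min-over-candidate-pairs) contacts for unknown subunit
   arrangements.
3. **Model clustering** — k-means and DBSCAN on rotation angles, and
   energy-ordered greedy leader clustering by Kabsch RMSD (cutoff 1.75 Å).
4. **Pathway analysis** — the aromatic-ring graph (nodes = Phe/Tyr
   six-carbon rings, edges = interaromatic centroid distances ≤ 7 Å),
   Dijkstra geodesics, and the smallest symmetric unit
   F1(P−1) → F24 → Y27 → F1(P) with its distances d₁, d₂, d₃.
5. **Marcus transport** — from dimer orbital splittings and four-point
   reorganization energies to the zero-driving-force rate bound

   *w = (t²/ħ) · √(π / (λ k_B T))*,

   then D = w·z₀², μ = eD/(k_B T), ρ = 4/(π r₀² z₀), σ = eρ(μ_h + μ_e)
   and G = σS/l.

A synthetic-data module plants all of these quantities (ideal hexagonal
rings, an idealized aromatic-bearing pilin, assemblies with prescribed
pathway distances, orbital-energy fixtures) so every stage is testable
without external downloads.

## Worked example

```r
library(piliconduct)

# a pilus with the GS1-model pathway distances planted exactly
spec <- synthetic_spec(d1 = 3.9, d2 = 6.1, d3 = 5.1)
asm  <- make_pathway_pilus(spec)
g    <- build_ring_graph(asm, cutoff = 7)
p    <- shortest_ring_path(g, "s1:r1", "s14:r1")
unit <- extract_symmetric_unit(g, p, subunit_p = 7)
c(unit$d1, unit$d2, unit$d3)      # 3.9 6.1 5.1
bottleneck_distance(unit)         # 6.1

inp <- transport_inputs(t_hole = 1.56e-2, t_elec = 3.25e-2,
                        lambda = 0.37, rho = 4.00e26)
transport_report(unit, inp)
#> <transport_result>
#>   rate bound w      : hole 6.723e+12, electron 2.918e+13 s^-1
#>   diffusion D       : hole 6.461e-07, electron 2.804e-06 m^2/s
#>   mobility mu       : hole 2.516e-05, electron 1.092e-04 m^2/(V s)
#>   carrier density   : 4.000e+26 m^-3
#>   conductivity sigma: 8610.56 S/m
#>   conductance G     : 4.234e-06 S (l = 6.10 A)
```

The mobilities place the filament between redox-hopping protein wires
(~10⁻¹² m²V⁻¹s⁻¹) and robust π-stacked organic semiconductors, and the
conductivity (~8.6 × 10³ S·m⁻¹) sits in the semiconducting range — the
quantitative signature of the π–π transport mechanism.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (assembly geometry, restraint scoring, ensemble clustering,
pathway extraction, transport tables) and write their outputs under
`results/`.

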