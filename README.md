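# xlgeom

Crosslink restraint validation, domain-motion geometry, interface burial
and nucleotide-exchange kinetics for integrative structural models of
multi-domain proteins — built around the analysis toolset used to
establish the autoinhibited structure of the Rac exchanger P-Rex1, and
usable for any protein studied the same way.

## The problem

An integrative model of a large multi-domain protein (crystal fragments
docked into a cryo-EM map, predicted pieces filling gaps) needs
independent validation, and the conformational transition it implies
needs quantification. xlgeom implements the four standard measurements:

1. **Crosslinking-MS restraints.** Lysine–lysine crosslinks identified
   by a search engine are filtered (E-value < 10⁻⁴, ≥ 2 repeats),
   merged per unique residue pair with summed spectral counts, and
   mapped onto a model as Cβ–Cβ Euclidean distances against the 30 Å
   maximum compatible BS3 span (satisfied strictly `< 30 Å`). Models
   are scored by a frequency-weighted **model FDR**:

   FDR = Σ(violated links × frequency of observation) / Σ(all observed links × frequency)

   Mapping one crosslink set onto competing conformers ranks them:
   the conformation sampled in solution violates fewer restraints.
2. **Domain-motion geometry.** Kabsch (SVD) superposition, axis–angle
   rotation decomposition, cylinder-fit helix axes, helix kink angles
   and hinge-opening angles (e.g. the ~126° opening of the P-Rex1 DH
   hinge helix between closed and open conformations), and anchored
   rigid-body domain rotations.
3. **Interface burial.** Shrake–Rupley SASA (radii C 1.70 / N 1.55 /
   O 1.52 / S 1.80 / P 1.80 Å, probe 1.40 Å, 960 points — echoed in
   every output), per-residue buried surface area across a defined
   component split, and geometric hydrogen-bond detection.
4. **Exchange kinetics.** F/F0 normalization of mant-GDP fluorescence
   time courses against a buffer control and plateau-followed-by-
   one-phase-association fits, y(t) = y0 + (plateau − y0)(1 − e^(−k·t))
   with x0 = 0, yielding k_obs (min⁻¹) per replicate and per-variant
   mean ± s.d.

A synthetic-data module generates ground-truth fixtures for all of it —
ideal and kinked helices, two-domain systems with planted rigid
transforms, crosslink tables with planted violated fractions, noisy
exchange traces — so the whole toolchain is testable offline.
P-Rex1-specific presets (domain layout, ΔN40 / T4L / Δ1119–1211
construct numbering maps, hinge-helix segments split at Ile237, the
DEP1-latch interface components) are packaged.

## Worked example

```r
library(xlgeom)

closed <- make_helix(60, kink_deg = 126, kink_pos = 30,
                     res_name = "LYS", label = "closed")
open   <- make_helix(60, res_name = "LYS", label = "open")

xl   <- simulate_crosslinks(closed, n_links = 20, violated_fraction = 0.2,
                            seed = 11)
recs <- parse_crosslinks(xl)
model_fdr(map_crosslinks(closed, recs))
#> <fdr_report> model 'closed': FDR 27.1% (mapped denominator)
#>   links: 16 satisfied, 4 violated, 0 unmapped; frequencies 51/19/0
model_fdr(map_crosslinks(open, recs))$fdr
#> [1] 0.5428571

segs <- prex1_hinge_segments("A", n_half = c(18, 29), c_half = c(31, 42))
as.numeric(hinge_opening(closed, open, segs$seg1, segs$seg2))
#> [1] 126

sim <- simulate_exchange(k_per_min = 0.5, sigma = 0.01, seed = 11)
fit_one_phase(normalize_timecourse(sim$samples[[1]], sim$control))$k_obs
#> [1] 0.5102489
```

The crosslink set simulated on the bent conformer scores FDR 27.1% on
it (exactly the generator's frequency-weighted planted value) versus
54.3% on the straightened conformer — the restraints identify which
conformation produced them. The hinge measurement returns the planted
126° bend, and the kinetic fit recovers the planted rate constant of
0.5 min⁻¹ from a noisy simulated plate run.

`run_pipeline(pipeline_config(...))` chains the stages and writes a
deterministic report bundle (per-link TSV, FDR JSON, Circos-style link
table, geometry JSON, BSA TSV, kinetics TSV, run log).
`reproduce_deposited("deposited-data")` drives the deposited-structure
analyses (model FDR under both denominator conventions, hinge opening
with the packaged segments, Leu177/Leu178 and Met401/Met408 burial,
the Thr240 hydrogen-bond check) given a directory with local copies of
the coordinate files.

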