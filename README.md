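# lcptools

Structural analysis of lyotropic lipid mesophases from 1-D small-angle X-ray
scattering (SAXS), for people who design lipidic cubic phase (LCP) hosts for
membrane-protein crystallization and need to know, quantitatively, how big the
water channels of a mesophase are and how they evolve with hydration.

The package automates the chain that is usually done by hand in plotting
software:

1. **Peak detection** — baseline estimation (lower-envelope interpolation of
   rolling-minimum anchors) and Bragg-peak picking with prominence and
   noise-floor guards, sub-grid positions by parabolic refinement.
2. **Phase indexing** — matching peak-position ratios against the allowed
   reflections of the bicontinuous cubic phases
   (Ia3d: √6, √8, √14, √16, ...; Pn3m: √2, √3, √4, √6, ...;
   Im3m: √2, √4, √6, √8, ...), the lamellar stack (1, 2, 3, 4) and, optionally,
   the inverse hexagonal phase. The lattice parameter comes from a
   height-weighted least-squares fit of `q_i = k·m_i` with `a = 2π/k`;
   two-phase coexistence is resolved by greedy peeling.
3. **Water-channel geometry** — for a cubic phase of lattice parameter `a`
   and lipid volume fraction `φ`, the monolayer (chain) length `l` solves the
   triply-periodic-minimal-surface volume relation

   `φ = 2·A₀·(l/a) + (4/3)·π·χ·(l/a)³`

   on its physical branch, with surface-to-volume ratio `A₀` and
   Euler–Poincaré characteristic `χ` per phase (Ia3d: 3.091, −8;
   Pn3m: 1.919, −2; Im3m: 2.345, −4). The water-channel radius follows as
   `r = c·a − l` with `c` = 0.248 (Ia3d), 0.391 (Pn3m), 0.305 (Im3m), and the
   channel diameter is `d_w = 2r`. The inverse problem — the smallest lattice
   that hosts a guest of given size — is solved by monotone bisection.
4. **Phase diagrams and re-entrance** — per-sample assignments are collapsed
   along the hydration axis into phase runs; a phase occurring in two
   non-adjacent runs is re-entrant (e.g. Pn3m → Im3m → Pn3m upon increasing
   hydration).
5. **Synthetic data** — a seeded generator of powder-pattern profiles
   (Lorentzian peaks at the allowed reflections, m⁻² intensity decay,
   power-law background, multiplicative noise) with ground truth, so the whole
   pipeline is testable without instrument data.

Small crystallographic helpers (triclinic cell volume, Matthews coefficient,
solvent fraction) are included for the downstream protein-crystal arithmetic.

## Worked example

The headline numbers: an ultra-swollen Ia3d phase measured at `a = 525 Å`
under 80% w/w hydration (lipid density 0.982 g/cm³):

```r
library(lcptools)
channel_geometry(525, composition(water_wt_frac = 0.80), "Ia3d")
#> # A tibble: 1 × 6
#>   phase     a   phi     l     r   d_w
#>   <chr> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 Ia3d    525 0.203  17.3  113.  226.
```

φ ≈ 0.203 is the lipid volume fraction, `l` ≈ 17.3 Å the monolayer thickness,
and the water channels are `d_w` ≈ 226 Å in diameter — roughly five times a
conventional monoolein LCP, large enough for proteins with bulky extracellular
domains. The same call with `a = 301` and `"Pn3m"` gives 203 Å.

A full round trip through simulated data:

```r
sim   <- simulate_saxs_profile("Ia3d", lattice = 525, noise_rel_sigma = 0.01, seed = 7)
peaks <- find_peaks(sim$profile)
rank_phases(peaks)[, c("phase", "lattice", "n_matched", "rms_rel_residual", "score")]
#> # A tibble: 3 × 5
#>   phase lattice n_matched rms_rel_residual score
#>   <chr>   <dbl>     <int>            <dbl> <dbl>
#> 1 Ia3d     525.         4         0.000890  3.29
#> 2 Im3m     525.         4         0.000890  1.29
#> 3 Pn3m     371.         3         0.00101   1.19
```

Ia3d wins because it accounts for all four reflections without skipping
low-order ones (Im3m can only reuse them as a high-order subset, which the
score penalizes). A hydration series assembles into a diagram whose collapsed
sequence reveals re-entrant behavior:

```r
series  <- simulate_hydration_series(8, seed = 1)   # 8 wt% phospholipid level
diagram <- build_diagram(series)
detect_reentrance(collapse_sequence(diagram))
#> # A tibble: 1 × 4
#>   collapsed            n_runs is_reentrant reentrant_phase
#> 1 Ia3d -> Pn3m -> Ia3d      3 TRUE         Ia3d
channel_vs_hydration(diagram)[, c("water_wt_pct", "phase", "lattice", "d_w")]
#> 60% Ia3d 180 Å -> 65.1 Å ... 80% Ia3d 525 Å -> 226 Å
```

Inverse design — the minimum Pn3m lattice whose channels admit a ~75 Å
extracellular domain at 80% hydration:

```r
min_lattice_for_channel(75, composition(0.80), "Pn3m")
#> 1 Pn3m   111. 0.203  5.91  37.5  75.0
```

`autoplot()` (profiles), `plot_phase_diagram()` and
`plot_channel_vs_hydration()` produce the corresponding figures, and
`inst/cli/lcp-cli.R` exposes `index`, `geometry`, `diagram`, `simulate` and
`xtal` subcommands for shell use.

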