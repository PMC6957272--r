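# rckring

Structural and functional analysis of RCK-domain octameric rings — the
regulatory assemblies that gate bacterial K⁺ channels such as KtrAB — for
structural biologists and channel biophysicists working with coordinate
files, ortholog alignments and liposome flux assays.

RCK ("regulator of conductance of K⁺") domains dimerize and assemble into
eight-subunit rings whose conformation controls ion flux through the
attached membrane protein. The ring's state is summarised by the pair of
cross-ring diagonals **L1/L2** between marker Cα atoms of opposite
subunits: a **square** ring (L1 ≈ L2, ATP-bound) is active, a **non-square**
ring (L1 > L2, ADP-bound) is not. Activation additionally requires a
divalent cation — typically Mg²⁺, coordinated octahedrally by six oxygens
at ~2.07 Å in the intra-dimer interface — and the interface glutamate that
binds it is conserved across nucleotide-dependent RCK proteins carrying the
Rossmann nucleotide-binding motif GxGxxG[17-18]xE/D. Channel activity is
read out in ACMA fluorescence-quenching flux assays: exponential quench
fits give rate constants k = 1/τ, and titrations follow the Hill equation
y = Start + (End − Start)·xⁿ/(K½ⁿ + xⁿ).

The package provides, as composable data-frame-first functions:

* **Structure I/O** — PDB/mmCIF reading (via bio3d), assembly-operator
  expansion, ordered ring assembly, marker-atom access
  (`read_structure()`, `apply_assembly()`, `build_ring()`).
* **Ring conformation** — L1/L2 diagonals, intra-dimer distances,
  square/non-square classification, complete-linkage clustering of
  conformations, Kabsch Cα RMSD (`compute_l1_l2()`,
  `classify_conformation()`, `cluster_conformations()`,
  `superpose_rmsd()`).
* **Metal sites** — coordination-shell detection, polyhedral geometry
  assessment, Mg²⁺-vs-Ca²⁺ identity scoring with B-factor flags
  (`find_shell()`, `assess_geometry()`, `score_identity()`).
* **Motifs & conservation** — nucleotide-binding-motif scanning,
  alignment-column conservation and context motifs, Kef-family length
  classification (`scan_nbs_motif()`, `column_conservation()`).
* **Flux kinetics** — trace normalization, one/two-phase exponential fits
  with information-criterion model selection, rate extraction, Hill fits
  with replicate summaries (`normalize_trace()`, `fit_exponential()`,
  `fit_hill()`), plus broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods.
* **Synthetic data** — seeded generators for rings, metal sites,
  alignments, flux traces and titrations (`simulate_*()`), so every stage
  is testable offline.
* **Pipeline** — `rck_run()` and the thin `inst/cli/rckring` wrapper
  expose every stage with JSON + TSV reports embedding the effective
  configuration.

## Worked example

```r
library(rckring)

# A non-square ring: generate, rebuild from coordinates, classify
ring <- build_ring(simulate_ring(L1 = 40.7, L2 = 30.7))
ring_metrics(ring, id = "WT-ADP-like") |> dplyr::select(name:threshold)
#> # A tibble: 1 × 6
#>   name           L1    L2 asymmetry label      threshold
#>   <chr>       <dbl> <dbl>     <dbl> <chr>          <dbl>
#> 1 WT-ADP-like  40.7  30.7        10 non-square         2

# Flux assay: simulate a quench at k = 0.096 1/s, normalize, fit, invert tau
trace <- simulate_flux_trace(k_fast = 0.096, noise_sigma = 0.01, seed = 1)
fit <- fit_exponential(normalize_trace(trace, "steady_state"), order = 1)
extract_rate(fit)
#> # A tibble: 1 × 3
#>        k component fast_dominant
#>    <dbl> <chr>     <lgl>
#> 1 0.0948 single    NA

# Is this shell magnesium-like? CN 6, octahedral, 2.07 Å donors
shell <- find_shell(simulate_metal_site("MG", 6, 2.07, "octahedral"), "MG")
score_identity(shell)
#> # A tibble: 2 × 6
#>   element distance_term cn_term geometry_term total  rank
#>   <chr>           <dbl>   <dbl>         <dbl> <dbl> <int>
#> 1 MG              0           0             0 0         1
#> 2 CA              0.320       0             0 0.320     2
```

The ring report reads back the generated diagonals exactly and calls the
ring non-square (asymmetry 10 Å against the 2 Å threshold). The fitted rate
constant recovers the generating 0.096 s⁻¹ within the noise of a single
trace. The identity score ranks Mg²⁺ first because the mean donor distance
sits on the Mg–O ideal; the 0.32 total for Ca²⁺ is exactly the distance
penalty |2.07 − 2.39| Å.

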