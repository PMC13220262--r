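# cgpathway

Coarse-grained activation-pathway analysis for membrane proteins.

Receptor activation — the motivating system is a chemokine GPCR moving from
an antagonist-bound inactive state to an agonist/G-protein-bound active
state — can be read off a one-dimensional conformational free-energy profile
G(s): its minima are metastable intermediates (Int1, Int2, ...), its maxima
are transition states (TS1, TS2, ...), each TS carries an activation barrier
ΔG‡ = G(TS) − G(preceding Int), and the largest barrier is the rate-limiting
step. `cgpathway` builds that profile from a pair of endpoint structures and
quantifies perturbations on it:

* **Structure I/O** — PDB/mmCIF read (via bio3d), two beads per residue
  (Cα + side-chain centroid), optional rigid ligand/sterol beads, multi-model
  CG PDB output.
* **Pathway generation** — a steered-relaxation surrogate of targeted MD:
  gradient descent on `E_CG + ½ k (RMSD_to_target − ρ_i)²` with ρ_i scheduled
  linearly to zero; progress coordinate `s = d0/(d0+d1)` from best-fit RMSDs
  to the endpoints; 30 intermediates extracted uniformly along s by default.
* **CG membrane energy** — a transparent surrogate model: Wimley–White
  burial with a smooth membrane-depth switch, screened Coulomb with a
  distance-dependent dielectric, an 8-6 contact well, harmonic excluded
  volume, and rigid-ligand interaction terms. Every constant is a parameter
  of `energy_params()`.
* **Profile analysis** — smoothing, stationary-point detection with a
  prominence rule, per-TS barriers, rate-limiting TS.
* **Perturbation** — side-chain rotamer switches transferred from a
  reference state, and in-silico alanine scanning with per-TS
  ΔΔG‡ = ΔG‡_mutant − ΔG‡_WT (positive = inhibits activation, negative =
  facilitates, |ΔΔG‡| ≤ τ = neutral).
* **Synthetic ground truth** — two-state helix-hairpin toys with exact
  motion bookkeeping and analytic Gaussian multi-well landscapes, so the
  whole pipeline is testable without downloading anything.

Everything is tibble-first: structures are tibbles of residues, profiles and
scan reports are tibbles, fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_ddg()` ggplot2 graphics.

## Worked example

A 40-residue two-state hairpin whose tip lysine must cross the membrane slab
mid-activation; burial-only energy parameters make the expected barrier
analytic (the lysine pays +3 kcal/mol inside the slab, nothing at either
endpoint):

```r
library(cgpathway)

toy <- make_toy_two_state(n_res = 40, hinge_angle = 180, seed = 1,
                          switch_flip = FALSE)
toy$inactive$resname[40] <- "LYS"; toy$active$resname[40] <- "LYS"
p <- energy_params(membrane_z_min = 22, membrane_z_max = 32,
                   hydrophobicity_scale = c(LYS = 3, ALA = 0.3),
                   residue_charges = c(NONE = 0),
                   contact_epsilon = 0, repulsion_k = 0)
cfg <- morph_config(n_steps = 120, relax_iters = 4, step_size = 0.15,
                    k_steer = 2000)

path <- targeted_morph(toy$inactive, toy$active, p, cfg)
prof <- build_profile(extract_intermediates(path, 30), p)
find_stationary_points(prof, prominence_threshold = 0.05)
#> <stationary_report> 2 minima, 1 transition states, rate-limiting TS1
#> # A tibble: 1 × 5
#>   label index     s     G barrier
#>   <chr> <int> <dbl> <dbl>   <dbl>
#> 1 TS1      22 0.722     3       3
```

The profile has a single transition state at s ≈ 0.72 with a 3.0 kcal/mol
barrier — exactly the planted membrane-crossing penalty. Truncating the
lysine to alanine removes 2.7 kcal/mol of it:

```r
scan <- ddg_scan(toy$inactive, toy$active,
                 tibble::tibble(chain = "A", resno = 40, mode = "ALA"),
                 p, cfg, tau = 0.25, prominence_threshold = 0.05)
scan[, c("site", "ts_label", "dg_wt", "dg_mut", "ddg", "classification")]
#> # A tibble: 1 × 6
#>   site  ts_label dg_wt dg_mut   ddg classification
#>   <chr> <chr>    <dbl>  <dbl> <dbl> <chr>
#> 1 A40   TS1          3    0.3  -2.7 facilitates
```

The negative ΔΔG‡ says the mutation lowers the activation barrier —
the wild-type lysine was hindering activation — and the row is classified
`facilitates` under the sign convention.

For file-based runs, `run_config()` + `run_profile()` / `run_switch()` /
`run_alascan()` wrap the same pipeline with TSV/JSON outputs and full
config echo; `inst/scripts/cgpathway.R` exposes them as `profile`, `switch`,
`alascan`, `synth` and `superpose` shell subcommands.

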