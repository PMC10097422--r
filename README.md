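# pigmentnet

Structure-based excitation-energy-transfer (EET) analysis and
time-resolved spectroscopic fitting for photosynthetic pigment–protein
supercomplexes, written for people who work with photosystem and
light-harvesting-complex structures: extract the chlorophyll and
carotenoid cofactors from a coordinate model, compute pair geometry and
simplified Förster rates, rank the inter-complex transfer bridges, and
fit the matching spectroscopy (fluorescence decay-associated spectra,
P700 oxidation kinetics).

## The model at the core

For a donor–acceptor chlorophyll pair, the transfer rate in the
simplified Förster treatment is

    k = C · κ² / R⁶

where `R` is the Mg–Mg distance (Å),
`κ = d̂·â − 3 (d̂·r̂)(â·r̂)` is the orientation factor built from the
Qy transition-dipole unit vectors and the inter-Mg unit vector
(0 ≤ κ² ≤ 4), and `C` (Å⁶ ps⁻¹) is a coupling constant per unordered
species class (Chl a–Chl a, Chl a–Chl b, ...) that absorbs dipole
strengths and a spectral overlap taken as constant when all Chl
excited-state energies are treated as equal. `C` is never published
directly; `calibrate_coupling()` recovers it from a printed pair table
as the mean of the per-row implied constants `k·R⁶/κ²`, and
`pair_table_consistency()` verifies leave-one-out that the whole table
is reproduced within ±0.015 ps⁻¹ — flagging, not force-fitting, any
row that is inconsistent with the model.

On the spectroscopy side, wavelength-resolved fluorescence decays are
fitted by simultaneous reconvolution global analysis (Gaussian IRF,
shared lifetimes, free per-wavelength amplitudes = decay-associated
spectra), and P700 absorbance rises are min–max normalised and fitted
with `1 − exp(−t/τ)` to report the oxidation rate `τ⁻¹`, a functional
antenna-size readout.

## Worked example

Calibrate coupling constants from the packaged pair table, build a toy
two-pigment structure with prescribed geometry, and recover its rate:

```r
library(pigmentnet)

constants <- default_coupling_constants()
constants
#> # A tibble: 3 × 4
#>   class              C n_rows low_confidence
#>   <chr>          <dbl>  <int> <lgl>
#> 1 chl_a:chl_a 5636717.      4 FALSE
#> 2 chl_a:chl_b 1695507.      7 FALSE
#> 3 chl_a:mdp    354757.      1 TRUE

sites <- read_structure(make_toy_structure(toy_pair_spec(16.24, 0.95))) |>
  assign_complexes(c(A = "Trimer 3", B = "PSI core"))
rate_table(sites, constants) |>
  dplyr::select(donor, acceptor, R, kappa_sq, k_fret, is_chl_a_pair)
#> # A tibble: 1 × 6
#>   donor  acceptor     R kappa_sq k_fret is_chl_a_pair
#>   <chr>  <chr>    <dbl>    <dbl>  <dbl> <lgl>
#> 1 a101_A a101_B    16.2    0.947  0.291 TRUE
```

A Chl a–Chl a pair at 16.24 Å with κ² ≈ 0.95 transfers at ≈ 0.29 ps⁻¹
under the calibrated Chl a–a constant (5.6×10⁶ Å⁶ ps⁻¹). Ranking the
packaged table's Chl a–a pairs gives the three strongest
trimer-to-core bridges:

```r
read_pair_table() |>
  dplyr::mutate(is_chl_a_pair = chl_a_pair == "Yes") |>
  top_transfer_pairs(n = 3, chl_a_only = TRUE) |>
  dplyr::select(pair, k_fret, R, kappa_sq)
#> # A tibble: 3 × 4
#>   pair                 k_fret     R kappa_sq
#>   <chr>                 <dbl> <dbl>    <dbl>
#> 1 a612_W -> a201_K       0.29  16.2     0.95
#> 2 a611_R -> a302_H       0.17  20.1     1.99
#> 3 a612_R -> a610_Lhca6   0.15  19.4     1.42
```

Spectroscopy: simulate a two-component decay dataset (10 and 65 ps,
50 ps FWHM IRF, 2.44 ps channels, Poisson noise) and fit it; then fit a
synthetic P700 oxidation trace:

```r
d <- make_decay_dataset(lifetimes = c(10, 65), seed = 1)
fit <- global_fit(d$data, n_components = 2)
fit
#> Global reconvolution fit: 2 components, 6 wavelengths
#>   lifetimes (ps): 10.38, 64.59
#>   IRF: Gaussian, FWHM 50 ps, t0 = 149.9 ps
#>   reduced chi-square: 0.3196

p700 <- fit_p700(make_p700_trace(tau = 0.1, seed = 1)$data)
p700
#> P700 oxidation fit: rate = 10.09 s^-1 (tau = 0.09907 s)
```

Both ground-truth lifetimes are recovered within a few percent and the
10 s⁻¹ oxidation rate within 1%. `fdas(fit)`,
`reconstruct_steady_state(fit)`, `tidy()`, `glance()` and `autoplot()`
expose the fitted spectra and diagnostics; `run_pipeline()` executes
extract → geometry → calibrate → rates → network on a coordinate file
and writes a deterministic TSV/JSON/DOT report bundle (also available
from a shell via `inst/scripts/pigmentnet.R`).

## Package layout

- `R/` — structure parsing (`read_structure`), geometry
  (`pair_geometries`, `kappa_squared`), rate calibration
  (`calibrate_coupling`, `rate_table`), network analysis
  (`interfacial_pairs`, `top_transfer_pairs`, `assign_layers`),
  spectroscopy (`global_fit`, `fdas`, `fit_p700`), synthetic data
  (`make_toy_structure`, `make_decay_dataset`, `make_p700_trace`),
  pipeline (`run_pipeline`).
- `inst/extdata/` — the transcribed pair table, default ligand map and
  chain grouping.
- `vignettes/pigment-transfer-networks.Rmd` — models, assumptions,
  numerical choices and limitations.
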