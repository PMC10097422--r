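---
title: "Pigment transfer networks and spectroscopic fitting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pigment transfer networks and spectroscopic fitting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentnet)
library(dplyr)
```

pigmentnet analyses excitation energy transfer (EET) in photosynthetic
pigment–protein supercomplexes from two directions: forward from a
structural model (pigment coordinates → pair geometry → transfer rates →
network ranking) and backward from time-resolved spectroscopy
(fluorescence decays → lifetimes and decay-associated spectra; P700
absorbance rises → functional antenna size). This vignette records the
models, the assumptions behind them, and the numerical and design
choices, in the package's own terms.

## The simplified Förster model

Förster theory gives the EET rate between a donor and acceptor
chromophore as proportional to $\kappa^2 / R^6$ times a spectral overlap
factor. For chlorophylls within one supercomplex a common simplification
treats all Chl *a* and Chl *b* excited-state energies as identical, so
the overlap integral is a constant for each *pair of species*. Every
species-independent factor then collapses into a single coupling
constant $C$ per unordered species class:

$$k_{\mathrm{EET}} = C \,\frac{\kappa^2}{R^6},
\qquad \kappa = \hat d\cdot\hat a - 3(\hat d\cdot\hat r)(\hat a\cdot\hat r),$$

with $R$ the Mg–Mg distance (Å), $\hat d, \hat a$ the Qy
transition-dipole unit vectors and $\hat r$ the unit inter-Mg vector.
$\kappa^2 \in [0, 4]$; the package checks this bound and the sign-flip
invariance by property tests against an independently coded oracle.

**What $C$ is and how it is obtained.** $C$ (Å⁶ ps⁻¹) absorbs dipole
strengths and the constant overlap; it is a phenomenological class
constant, not a quantum-chemical quantity, and it is never published
directly. `calibrate_coupling()` recovers it from a printed rate table.
The default estimator is the mean of per-row implied constants
$k R^6 / \kappa^2$ — arithmetic a reader can audit row by row; a
least-squares estimator is available. Rows with printed $k < 0.05$
ps⁻¹ are excluded by default: at two-decimal rounding they constrain
$C$ only weakly. From the packaged pair table this yields

```{r constants}
default_coupling_constants()
```

The Chl *a*–*a* and Chl *a*–*b* constants each rest on several mutually
consistent rows (per-row implied constants agree within a few percent);
the Mdp (divinyl-pheoporphyrin) class has a single informative row and
is flagged `low_confidence`. One row of the packaged table,
`a612_R -> b606_Lhca6` (printed 0.00 ps⁻¹), cannot be reconciled with
any single class constant that fits the other Chl *b*-involving rows;
`pair_table_consistency()` flags it as anomalous and the calibration
never force-fits it.

**Assumptions and limits.** Point dipoles located at the Mg; a single
Qy axis per pigment; no refractive-index screening, per-site energies,
or excitonic delocalisation. These are exactly the approximations under
which the calibrated table was produced, so recomputed rates are
internally consistent with it; they are not ab initio predictions.

## Geometry from coordinate models

`read_structure()` parses PDB or mmCIF files via bio3d and keeps one
record per cofactor residue recognised by the ligand map. The Qy axis
defaults to the N-B → N-D ring-nitrogen pair — the textbook convention —
but is configurable, because published $\kappa^2$ tables rarely state
their convention; Mg–Mg distances are convention-free. The Mg atom is
found by atom name `MG`, falling back to the unique magnesium-element
atom. Chlorophyll records lacking an Mg are kept in inventories but
excluded from geometry, with a warning. Coordinates are used in the
deposited frame; no superposition is performed.

The ligand map and the chain grouping are plain TSV configuration, not
code: deposition dialects for prasinophyte pigments (prasinoxanthin,
dihydrolutein, Mdp) vary, and isolating them in config keeps that risk
out of the implementation. The packaged grouping covers the chains the
supercomplex literature names explicitly (A–O core, S/T/U, P/Q/R, V/W/X
trimers); LHCI belt chains are left to user config.

## Network analysis

`rate_table()` evaluates the calibrated model for every inter-complex
pigment pair within a cutoff (default 25 Å — above the largest
interfacial Mg–Mg distance discussed in the supercomplex literature,
23.9 Å, with margin). `interfacial_pairs()` orders pairs by descending
rate with deterministic tie-breaks (ascending distance, then
lexicographic labels), so ranking is a total order stable under input
permutation. `flag_low_orientation()` applies the $\kappa^2 < 0.7$
rule (strict inequality; the boundary is not flagged) under which even
short pairs transfer negligibly. A `chl_a_only` filter reflects the
observation that Chl *b* pigments are poor inter-complex bridges; it
defaults to off because applying it to summaries beyond the classic
top-3 claim is interpretive.

**Layer assignment.** Antenna chlorophylls sit in two tiers near the
stromal and lumenal membrane faces. `assign_layers()` estimates the
membrane normal as the principal component of the Mg point cloud whose
1-D projection splits best under a deterministic two-means clustering
(centres initialised at the extremes, Lloyd iterations), scored by
between-cluster over total sum of squares. We chose this separation
score as the axis criterion because it is deterministic,
dependency-free, and directly measures the two-slab structure we are
after; a formal bimodality statistic would serve the same role. Below a
minimum separation (default 0.5) the geometry is declared ambiguous and
an error is raised rather than returning an arbitrary split. The
partition is invariant under rigid motion; which side is called
"stromal" follows a deterministic axis-sign convention and may be
swapped relative to the true membrane sidedness in an arbitrarily
oriented frame.

## Reconvolution global fitting

A time-correlated single-photon-counting measurement records, per
wavelength, the molecular decay convolved with the instrument response
function (IRF). The model is

$$M(t, \lambda) = \mathrm{IRF} \circledast \sum_i A_i(\lambda)\,
e^{-t/\tau_i},$$

with lifetimes $\tau_i$ shared across wavelengths and amplitudes
$A_i(\lambda)$ free in sign — the decay-associated spectra (DAS), whose
negative lobes are the rise signature of downhill transfer. The IRF is
Gaussian with fitted centre $t_0$; for a Gaussian the convolution has
the closed exp–erfc form, which the package evaluates through the
log-normal-CDF for numerical stability and verifies in tests against
direct quadrature. The unit-normalised IRF preserves total counts:
$\int M = \sum_i A_i \tau_i$, which is also the basis of steady-state
reconstruction $S(\lambda) = \sum_{i} A_i(\lambda) \tau_i$ over the
chosen components (defaults to the first two, the practice for
photosystem supercomplex spectra).

`global_fit()` uses variable projection: for trial $(\log\tau_i, t_0)$
the amplitudes are solved exactly by weighted linear least squares per
wavelength, and only the nonlinear parameters are iterated
(Levenberg–Marquardt, minpack.lm). Weights are Neyman, $1/\max(y, 1)$,
matching Poisson counting noise. Lifetime starts come from a
log-spaced grid over the decay window with 5 multi-starts (best
χ² kept); the procedure is deterministic. Degenerate solutions —
collapsed lifetimes (ratio < 1.2), a component with negligible
amplitude everywhere, or a lifetime far beyond the observation
window — raise a classed warning instead of passing silently. We fit
all curves simultaneously rather than reproducing the older two-step
habit (fit each curve, reconstruct noiseless decays, then global-fit
those): the direct route is statistically cleaner and the two-step's
intermediate is underdocumented in the literature that uses it.

The P700 oxidation fit is deliberately simple, mirroring lab practice:
replicates averaged, min–max normalisation to [0, 1] using the
pre-illumination baseline, and a mono-exponential rise
$1 - e^{-t/\tau}$ (amplitude and baseline refined for robustness),
reporting the oxidation rate $\tau^{-1}$ in the caller's declared time
unit — larger functional antennae oxidise P700 faster at fixed light.

## The synthetic-data generators

The generators exist so that every pipeline stage is testable without
downloads, and they define the package's study conditions:

* `make_toy_structure()` writes minimal PDB files (Mg plus two axis
  atoms per pigment, ±1 Å about the Mg) that round-trip through the
  same parser as deposited models. `toy_pair_spec()` solves the
  placement of two dipoles for an exact target $(R, \kappa^2)$;
  `toy_monomer_spec()` builds a 14-chlorophyll two-slab monomer with
  the Lhcp stromal/lumenal composition (5 Chl a + 1 Chl b + 1 Mdp /
  3 Chl a + 4 Chl b).
* `make_decay_dataset()` emulates a picosecond fluorometer: 2.44
  ps channels, 50 ps FWHM Gaussian IRF, Poisson noise at a 10⁴-count
  peak, default lifetimes 10 and 65 ps (the antenna-equilibration and
  trapping scales of PSI), six wavelengths across 680–705 nm with a
  negative transfer lobe on the fast component. The window is 1024
  channels (2.5 ns), ample for these lifetimes. Ground truth travels
  with the data, and recovery tests compare against that sidecar only.
* `make_p700_trace()` produces replicate mono-exponential rises with a
  zero pre-illumination baseline and additive Gaussian noise (default
  2% of range, 8 technical replicates).

What the generators do *not* emulate: real protein scaffolds, detector
afterpulsing or background, IRF asymmetry, wavelength-dependent IRFs,
red-shifted emitting states, or actinic-intensity dependence of P700
kinetics. Passing recovery tests therefore demonstrates correctness of
the estimators within the stated model class, not instrument-grade
robustness.

Seeding: each generator takes an integer seed, uses an isolated RNG
state, and records the seed in its sidecar; identical seeds give
bit-identical outputs and the session RNG stream is untouched.

## Numerical choices and degenerate inputs

* $\kappa^2$ inputs must be unit vectors within 1e-8; violations are
  errors, not silent renormalisation.
* Self-pairs, coincident dipole atoms, missing Mg, and flat P700
  traces raise classed errors (`pigmentnet_data_error`); missing
  coupling classes and malformed config raise
  `pigmentnet_config_error`; non-convergence raises
  `pigmentnet_convergence_error`. The command-line wrapper maps these
  to exit codes 2/3/4.
* Rates are kept at full precision internally; report files add a
  two-decimal column to mirror how such tables are printed, and
  comparisons against printed tables use ±0.015 ps⁻¹ (half a final
  digit plus calibration scatter).
* Problem sizes in the test-suite simulations — 1024–2048 channels, 6
  wavelengths, 20 seeds for two-component recovery, 12-point lifetime
  sweeps — were chosen as the smallest sizes at which the estimators'
  contracts (10% recovery under Poisson noise; <0.1% noiseless; <1%
  steady-state agreement; 5% P700) are meaningfully exercised.

## Known limitations

* $C$ is only as good as the table it is calibrated from; applying
  constants across structures assumes comparable pigments and
  environments.
* The κ² column of a published table can only be reproduced from
  coordinates if the same dipole-atom convention was used; distances
  are convention-free, orientation factors are not.
* DAS component ordering is by lifetime; components with genuinely
  equal lifetimes are not identifiable and will trigger the degeneracy
  warning.
* Layer naming (as opposed to the partition) is a convention, see
  above.
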