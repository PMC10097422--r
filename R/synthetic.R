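#' Toy structure specification for a prescribed pigment pair
#'
#' Builds a two-chlorophyll specification with an exact Mg-Mg distance
#' and orientation factor: both Mg atoms sit on the x axis separated by
#' `R`, and both Qy axes lie in the xz plane at the angle
#' `alpha = acos(sqrt((1 + sqrt(kappa_sq)) / 3))` from the inter-Mg
#' vector, for which `kappa = sin^2(alpha) - 2 cos^2(alpha)` gives
#' `kappa^2` exactly. Any value in `[0, 4]` is reachable.
#'
#' @param R Mg-Mg distance, Angstrom.
#' @param kappa_sq Target orientation factor.
#' @param species Length-2 species vector for the two sites.
#' @return A toy-structure spec tibble (see [make_toy_structure()]).
#' @examples
#' spec <- toy_pair_spec(16.24, 0.95)
#' sites <- read_structure(make_toy_structure(spec))
#' pair_geometry(sites[1, ], sites[2, ])
#' @export
toy_pair_spec <- function(R, kappa_sq, species = c("chl_a", "chl_a")) {
  stopifnot(R > 0, kappa_sq >= 0, kappa_sq <= 4, length(species) == 2)
  alpha <- acos(sqrt((1 + sqrt(kappa_sq)) / 3))
  axis <- c(cos(alpha), 0, sin(alpha))
  tibble::tibble(
    species = species,
    chain = c("A", "B"),
    resnum = c(101L, 101L),
    mg_x = c(0, R), mg_y = 0, mg_z = 0,
    ax_x = axis[1], ax_y = axis[2], ax_z = axis[3]
  )
}

species_code <- function(species) {
  dplyr::case_match(species,
    "chl_a" ~ "CLA", "chl_b" ~ "CHL", "mdp" ~ "DVP",
    .default = toupper(substr(species, nchar(species) - 2, nchar(species)))
  )
}

#' Write a toy coordinate file with prescribed pigment geometry
#'
#' Emits a minimal PDB file containing, for each specified pigment, an
#' Mg atom at the given position and the two Qy-axis atoms (NB, ND)
#' placed 1 Angstrom either side of the Mg along the given axis. The
#' file round-trips through [read_structure()] with identical site ids,
#' species and coordinates (to the 3-decimal PDB precision), so toy
#' structures exercise exactly the same parsing path as deposited
#' models.
#'
#' @param spec Tibble with columns `species`, `chain`, `resnum`,
#'   `mg_x/mg_y/mg_z`, `ax_x/ax_y/ax_z` (axis need not be unit length).
#'   An empty spec yields a valid file with zero pigments.
#' @param path Output file (default: temporary `.pdb`).
#' @return `path`, invisibly usable as input to [read_structure()].
#' @export
make_toy_structure <- function(spec, path = tempfile(fileext = ".pdb")) {
  if (nrow(spec) > 0) {
    if (anyDuplicated(spec[c("chain", "resnum")])) {
      abort("duplicate chain/resnum in toy structure spec",
            class = "pigmentnet_config_error")
    }
    ax <- as.matrix(spec[, c("ax_x", "ax_y", "ax_z")])
    nrm <- sqrt(rowSums(ax^2))
    if (any(nrm == 0)) {
      abort("zero-length dipole axis in toy structure spec",
            class = "pigmentnet_config_error")
    }
    ax <- ax / nrm
  }
  lines <- character()
  serial <- 0L
  fmt <- function(name, ele, code, chain, resnum, xyz) {
    serial <<- serial + 1L
    sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, code, chain, resnum, xyz[1], xyz[2], xyz[3], ele)
  }
  for (i in seq_len(nrow(spec))) {
    mg <- c(spec$mg_x[i], spec$mg_y[i], spec$mg_z[i])
    code <- species_code(spec$species[i])
    lines <- c(lines,
               fmt("MG", "MG", code, spec$chain[i], spec$resnum[i], mg),
               fmt("NB", "N", code, spec$chain[i], spec$resnum[i], mg - ax[i, ]),
               fmt("ND", "N", code, spec$chain[i], spec$resnum[i], mg + ax[i, ]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Toy two-layer antenna monomer specification
#'
#' A 14-chlorophyll monomer arranged as two parallel slabs of seven
#' pigments each, mimicking the stromal/lumenal layering of an Lhcp
#' monomer (stromal slab: 5 Chl a, 1 Chl b, 1 Mdp; lumenal slab:
#' 3 Chl a, 4 Chl b).
#'
#' @param separation Distance between the two slabs, Angstrom.
#' @param chain Chain identifier.
#' @return A toy-structure spec tibble.
#' @export
toy_monomer_spec <- function(separation = 15, chain = "A") {
  ring <- function(z, n, radius = 8) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    tibble::tibble(mg_x = radius * cos(th), mg_y = radius * sin(th), mg_z = z)
  }
  stromal <- ring(separation / 2, 7)
  lumenal <- ring(-separation / 2, 7)
  tibble::tibble(
    species = c(rep("chl_a", 5), "chl_b", "mdp",
                rep("chl_a", 3), rep("chl_b", 4)),
    chain = chain,
    resnum = 601:614,
    dplyr::bind_rows(stromal, lumenal),
    ax_x = 1, ax_y = 0, ax_z = 0
  )
}

#' Generate a synthetic wavelength-resolved decay dataset
#'
#' Emulates time-correlated single-photon-counting data: a
#' multi-exponential decay with wavelength-dependent amplitudes is
#' convolved with a Gaussian IRF, sampled on a uniform channel grid,
#' scaled to a target peak count, and Poisson noise is applied. The
#' ground truth (lifetimes, scaled amplitude matrix, IRF, seed) is
#' returned alongside the data so recovery tests never rely on
#' hard-coded numbers.
#'
#' Defaults mirror a typical picosecond fluorometer configuration:
#' 2.44 ps channels, 50 ps FWHM Gaussian IRF, peak of 1e4 counts.
#'
#' @param lifetimes Ground-truth lifetimes, ps.
#' @param amplitudes Amplitude matrix (component x wavelength), any
#'   overall scale; rescaled so the noiseless model peaks at
#'   `peak_counts`.
#' @param wavelengths Wavelength axis, nm (length = ncol(amplitudes)).
#' @param irf_fwhm IRF FWHM, ps.
#' @param channel_width Channel width, ps.
#' @param n_channels Number of time channels.
#' @param t0 IRF centre, ps.
#' @param peak_counts Peak of the noiseless model; `Inf` disables noise
#'   scaling and returns the exact model (no Poisson noise applied).
#' @param seed Integer seed controlling the Poisson noise.
#' @return A list with `data` (long tibble `time`, `wavelength`,
#'   `counts`) and `truth` (list of generator parameters, including the
#'   scaled `amplitudes` and the `seed`).
#' @export
make_decay_dataset <- function(lifetimes = c(10, 65),
                               amplitudes = default_das(lifetimes, wavelengths),
                               wavelengths = seq(680, 705, by = 5),
                               irf_fwhm = 50, channel_width = 2.44,
                               n_channels = 1024, t0 = 150,
                               peak_counts = 1e4, seed = 0) {
  stopifnot(all(lifetimes > 0), channel_width > 0, n_channels > 1)
  amplitudes <- rbind(amplitudes)
  stopifnot(nrow(amplitudes) == length(lifetimes),
            ncol(amplitudes) == length(wavelengths))
  time <- (seq_len(n_channels) - 1) * channel_width
  model <- vapply(seq_along(wavelengths), function(j) {
    convolve_model(time, lifetimes, amplitudes[, j], irf_fwhm, t0)
  }, numeric(n_channels))
  noiseless <- is.infinite(peak_counts)
  if (!noiseless) {
    scale <- peak_counts / max(model)
    model <- model * scale
    amplitudes <- amplitudes * scale
    counts <- with_seed(seed, matrix(stats::rpois(length(model), model),
                                     nrow = n_channels))
  } else {
    counts <- model
  }
  data <- tidyr::expand_grid(wavelength = wavelengths, time = time) |>
    dplyr::arrange(.data$time, .data$wavelength)
  data$counts <- as.vector(t(counts))
  list(
    data = data,
    truth = list(lifetimes = lifetimes, amplitudes = amplitudes,
                 wavelengths = wavelengths, irf_fwhm = irf_fwhm,
                 channel_width = channel_width, n_channels = n_channels,
                 t0 = t0, peak_counts = peak_counts,
                 seed = if (noiseless) NA_integer_ else seed)
  )
}

#' Default decay-associated amplitude spectra for the generator
#'
#' Gaussian spectral bands: the fastest component carries a positive
#' short-wavelength band and, when more than one component is present,
#' a negative long-wavelength lobe (the rise signature of downhill
#' energy transfer); slower components carry broad positive bands.
#'
#' @param lifetimes Lifetime vector (row count of the result).
#' @param wavelengths Wavelength axis, nm.
#' @return Amplitude matrix, component x wavelength.
#' @export
default_das <- function(lifetimes, wavelengths) {
  band <- function(center, width, amp) amp * exp(-((wavelengths - center) / width)^2)
  n <- length(lifetimes)
  t(vapply(seq_len(n), function(i) {
    if (i == 1 && n > 1) {
      band(685, 8, 1) - band(700, 8, 0.35)
    } else {
      band(688 + 4 * i, 10, 0.8)
    }
  }, numeric(length(wavelengths))))
}

#' Generate synthetic P700 oxidation traces
#'
#' Replicate traces of the min-max-normalisable form
#' `1 - exp(-t / tau)` after light onset at `t = 0`, preceded by a zero
#' baseline, with additive Gaussian noise. Ground truth is returned
#' alongside.
#'
#' @param tau Ground-truth oxidation time constant (caller's time unit).
#' @param noise_sd Gaussian noise standard deviation, as a fraction of
#'   the trace range.
#' @param n_replicates Number of technical replicates.
#' @param seed Integer seed.
#' @param t_max Trace end time; the baseline spans `[-0.1 t_max, 0]`.
#' @param n_points Samples per replicate.
#' @return A list with `data` (tibble `replicate`, `time`, `signal`)
#'   and `truth` (list with `tau`, `rate`, `noise_sd`, `seed`).
#' @export
make_p700_trace <- function(tau, noise_sd = 0.02, n_replicates = 8, seed = 0,
                            t_max = 6 * tau, n_points = 240) {
  stopifnot(tau > 0, noise_sd >= 0, n_replicates >= 1)
  time <- seq(-0.1 * t_max, t_max, length.out = n_points)
  clean <- ifelse(time >= 0, 1 - exp(-time / tau), 0)
  data <- with_seed(seed, purrr::map_dfr(seq_len(n_replicates), function(r) {
    tibble::tibble(replicate = r, time = time,
                   signal = clean + stats::rnorm(length(time), sd = noise_sd))
  }))
  list(data = data,
       truth = list(tau = tau, rate = 1 / tau, noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed))
}

# Evaluate expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
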