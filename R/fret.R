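#' Published pigment-pair rate table
#'
#' Loads the packaged transcription of the published table of calculated
#' transfer rates between Lhcp and PSI-core pigment pairs (pair label,
#' rate in ps^-1, Mg-Mg distance in Angstrom, orientation factor, and a
#' flag marking Chl a - Chl a pairs). Pair labels are parsed into donor
#' and acceptor species so the species-class of each row is available
#' for calibration.
#'
#' @param path TSV with columns `pair`, `k_fret`, `R`, `kappa_sq`,
#'   `chl_a_pair`.
#' @return A tibble with the printed columns plus `donor`, `acceptor`,
#'   `donor_species`, `acceptor_species`, and `class`.
#' @examples
#' read_pair_table()
#' @export
read_pair_table <- function(path = system.file("extdata", "table5.tsv",
                                               package = "pigmentnet")) {
  raw <- readr::read_tsv(path, col_types = "cdddc", progress = FALSE)
  ends <- strsplit(raw$pair, "\\s*->\\s*")
  out <- dplyr::mutate(raw,
    donor = purrr::map_chr(ends, 1),
    acceptor = purrr::map_chr(ends, 2),
    donor_species = label_species(.data$donor),
    acceptor_species = label_species(.data$acceptor),
    class = species_class(.data$donor_species, .data$acceptor_species)
  )
  stopifnot(identical(out$chl_a_pair == "Yes",
                      out$donor_species == "chl_a" & out$acceptor_species == "chl_a"))
  out
}

label_species <- function(label) {
  dplyr::case_when(
    grepl("^Mdp", label) ~ "mdp",
    grepl("^a", label) ~ "chl_a",
    grepl("^b", label) ~ "chl_b",
    .default = NA_character_
  )
}

#' Unordered species-pair class
#'
#' Coupling constants are defined per unordered pair of pigment species:
#' `"chl_a:chl_a"`, `"chl_a:chl_b"`, `"chl_a:mdp"`, etc. Direction does
#' not enter (under the equal-excited-state-energy approximation the
#' same constant serves both transfer directions).
#'
#' @param donor_species,acceptor_species Character vectors.
#' @return Character vector of class keys.
#' @export
species_class <- function(donor_species, acceptor_species) {
  purrr::map2_chr(donor_species, acceptor_species,
                  ~ paste(sort(c(.x, .y)), collapse = ":"))
}

#' Calibrate species-class coupling constants
#'
#' In the simplified Forster treatment all spectral and dipole-strength
#' factors for a given pair of pigment species are absorbed into a single
#' constant `C` (Angstrom^6 ps^-1) so that `k = C * kappa^2 / R^6`.
#' `C` is never published directly; it is recovered from a printed rate
#' table. The default estimator averages the per-row implied constant
#' `k R^6 / kappa^2` (arithmetic any reader can audit row by row); a
#' least-squares alternative minimises `sum((k - C kappa^2 / R^6)^2)`
#' per class.
#'
#' Rows with printed rates below `min_rate` are excluded: at two-decimal
#' rounding such rates carry almost no information about `C`. Classes
#' calibrated from a single row are flagged `low_confidence`.
#'
#' @param rows Pair-table tibble (e.g. from [read_pair_table()]) with
#'   columns `k_fret`, `R`, `kappa_sq` and either `class` or both
#'   species columns.
#' @param estimator `"mean_implied"` (default) or `"least_squares"`.
#' @param min_rate Minimum printed rate for a row to inform calibration.
#' @param exclude Character vector of pair labels (`"donor -> acceptor"`)
#'   to leave out, e.g. for leave-one-out validation.
#' @return A tibble `class`, `C`, `n_rows`, `low_confidence`.
#' @examples
#' calibrate_coupling(read_pair_table())
#' @export
calibrate_coupling <- function(rows, estimator = c("mean_implied", "least_squares"),
                               min_rate = 0.05, exclude = character()) {
  estimator <- match.arg(estimator)
  if (!"class" %in% names(rows)) {
    rows$class <- species_class(rows$donor_species, rows$acceptor_species)
  }
  if (!"pair" %in% names(rows)) rows$pair <- paste(rows$donor, "->", rows$acceptor)
  use <- dplyr::filter(rows, .data$k_fret >= min_rate, !(.data$pair %in% exclude))
  if (nrow(use) == 0) {
    abort("no rows left to calibrate from", class = "pigmentnet_data_error")
  }
  if (any(use$kappa_sq <= 0) || any(use$R <= 0)) {
    abort("calibration rows require kappa_sq > 0 and R > 0",
          class = "pigmentnet_data_error")
  }
  use |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      C = if (estimator == "mean_implied") {
        mean(.data$k_fret * .data$R^6 / .data$kappa_sq)
      } else {
        # weighted normal equation of the one-parameter linear model k = C * x
        x <- .data$kappa_sq / .data$R^6
        sum(.data$k_fret * x) / sum(x^2)
      },
      n_rows = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(low_confidence = .data$n_rows < 2)
}

#' Simplified Forster transfer rate
#'
#' `k = C * kappa^2 / R^6`, with `C` the species-class coupling constant
#' in Angstrom^6 ps^-1, `R` the Mg-Mg distance in Angstrom and
#' `kappa^2` the orientation factor. Vectorised.
#'
#' @param R Distance(s), Angstrom.
#' @param kappa_sq Orientation factor(s).
#' @param C Coupling constant(s), Angstrom^6 ps^-1.
#' @return Rate(s) in ps^-1.
#' @export
fret_rate <- function(R, kappa_sq, C) {
  stopifnot(all(R > 0), all(kappa_sq >= 0), all(C > 0))
  C * kappa_sq / R^6
}

lookup_constant <- function(constants, class) {
  idx <- match(class, constants$class)
  if (anyNA(idx)) {
    abort(paste0("no coupling constant configured for class: ",
                 paste(unique(class[is.na(idx)]), collapse = ", ")),
          class = "pigmentnet_config_error")
  }
  constants$C[idx]
}

#' Transfer-rate table for a grouped structure
#'
#' Computes `k = C * kappa^2 / R^6` for every inter-complex pigment pair
#' within the distance cutoff. Pairs whose species class has no
#' calibrated constant raise an explicit error rather than receiving a
#' silent default.
#'
#' @param sites Grouped structure tibble (see [assign_complexes()]).
#' @param constants Coupling-constant tibble from [calibrate_coupling()].
#' @param cutoff Distance cutoff in Angstrom.
#' @param intra Keep pairs within a single complex too (default drops
#'   them, mirroring the inter-complex focus of transfer-network
#'   analysis).
#' @return A tibble of [pair_geometries()] columns plus `class`,
#'   `k_fret` (ps^-1, full precision) and `is_chl_a_pair`, sorted by
#'   descending rate.
#' @export
rate_table <- function(sites, constants, cutoff = 25, intra = FALSE) {
  geo <- pair_geometries(sites, cutoff = cutoff)
  if (!intra) {
    geo <- dplyr::filter(geo, .data$donor_complex != .data$acceptor_complex)
  }
  if (nrow(geo) == 0) {
    return(dplyr::mutate(geo, class = character(0), k_fret = double(0),
                         is_chl_a_pair = logical(0)))
  }
  geo |>
    dplyr::mutate(
      class = species_class(.data$donor_species, .data$acceptor_species),
      k_fret = fret_rate(.data$R, .data$kappa_sq,
                         lookup_constant(constants, .data$class)),
      is_chl_a_pair = .data$donor_species == "chl_a" &
        .data$acceptor_species == "chl_a"
    ) |>
    dplyr::arrange(dplyr::desc(.data$k_fret), .data$R, .data$donor, .data$acceptor)
}

#' Self-consistency check of a printed pair table
#'
#' Recomputes every row of a printed rate table from class constants
#' calibrated on that same table (leave-one-out for the checked row) and
#' reports the discrepancy. Rows whose printed rate cannot be reconciled
#' with `k = C kappa^2 / R^6` within `tol` are flagged as anomalous
#' rather than force-fitted.
#'
#' @param rows Pair table from [read_pair_table()].
#' @param tol Agreement tolerance in ps^-1 (default 0.015, half a unit
#'   in the last printed digit plus calibration scatter).
#' @param min_rate Calibration threshold passed to
#'   [calibrate_coupling()].
#' @return `rows` plus `k_pred`, `residual`, `anomalous`. Rows of
#'   classes with fewer than two calibration rows have `k_pred = NA`.
#' @export
pair_table_consistency <- function(rows, tol = 0.015, min_rate = 0.05) {
  rows <- dplyr::mutate(rows, k_pred = NA_real_)
  for (i in seq_len(nrow(rows))) {
    cls <- rows$class[i]
    cal <- tryCatch(
      calibrate_coupling(rows, min_rate = min_rate, exclude = rows$pair[i]),
      pigmentnet_data_error = function(e) NULL
    )
    if (is.null(cal) || !cls %in% cal$class) next
    if (cal$low_confidence[cal$class == cls]) next
    rows$k_pred[i] <- fret_rate(rows$R[i], rows$kappa_sq[i],
                                cal$C[cal$class == cls])
  }
  dplyr::mutate(rows,
    residual = .data$k_fret - .data$k_pred,
    anomalous = !is.na(.data$k_pred) & abs(.data$residual) > tol
  )
}

#' Default coupling constants from the packaged pair table
#'
#' Calibrates every species class appearing in the packaged rate table.
#' Classes with at least one informative row (printed rate at or above
#' `min_rate`) are calibrated from those rows; classes whose only rows
#' fall below the threshold (the single Mdp pair, for instance) are
#' calibrated from all their rows and flagged `low_confidence`.
#'
#' @inheritParams calibrate_coupling
#' @return A tibble `class`, `C`, `n_rows`, `low_confidence`.
#' @export
default_coupling_constants <- function(rows = read_pair_table(),
                                       estimator = "mean_implied",
                                       min_rate = 0.05) {
  main <- calibrate_coupling(rows, estimator = estimator, min_rate = min_rate)
  missing_cls <- setdiff(unique(rows$class[rows$k_fret > 0]), main$class)
  if (length(missing_cls)) {
    extra <- calibrate_coupling(
      dplyr::filter(rows, .data$class %in% missing_cls, .data$k_fret > 0),
      estimator = estimator, min_rate = 0
    )
    extra$low_confidence <- TRUE
    main <- dplyr::bind_rows(main, extra)
  }
  dplyr::arrange(main, .data$class)
}
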