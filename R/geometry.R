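#' Mg-Mg distance between two pigment sites
#'
#' Euclidean distance between the central magnesium atoms of two
#' chlorophyll-family sites, in Angstrom. This is the standard distance
#' coordinate of pigment-pair analyses.
#'
#' @param a,b Single-row site records (as returned by [read_structure()]).
#' @return Distance in Angstrom.
#' @export
mg_distance <- function(a, b) {
  check_geometric(a)
  check_geometric(b)
  sqrt(sum((site_mg(a) - site_mg(b))^2))
}

site_mg <- function(s) c(s$mg_x[1], s$mg_y[1], s$mg_z[1])

check_geometric <- function(s) {
  if (!isTRUE(s$has_mg[1]) || anyNA(site_mg(s))) {
    abort(paste0("site ", s$site_id[1], " has no Mg position"),
          class = "pigmentnet_data_error")
  }
  invisible(s)
}

#' Qy transition-dipole unit vector of a pigment site
#'
#' Unit vector along the configured dipole atom pair (by default the
#' N-B to N-D ring nitrogens of the chlorin macrocycle, the conventional
#' Qy axis). The overall sign of the vector is immaterial for the
#' orientation factor.
#'
#' @param site Single-row site record.
#' @return Numeric length-3 unit vector.
#' @export
transition_dipole <- function(site) {
  v <- c(site$d2_x[1] - site$d1_x[1],
         site$d2_y[1] - site$d1_y[1],
         site$d2_z[1] - site$d1_z[1])
  if (anyNA(v)) {
    abort(paste0("site ", site$site_id[1], " is missing dipole atoms"),
          class = "pigmentnet_data_error")
  }
  n <- sqrt(sum(v^2))
  if (n == 0) {
    abort(paste0("site ", site$site_id[1], " has coincident dipole atoms"),
          class = "pigmentnet_data_error")
  }
  v / n
}

#' Forster orientation factor kappa squared
#'
#' For donor and acceptor transition-dipole unit vectors `d_hat`,
#' `a_hat` and the unit vector `r_hat` joining the two pigments,
#' `kappa = d.a - 3 (d.r)(a.r)` in the point-dipole approximation, and
#' the function returns `kappa^2`, which lies in `[0, 4]` and is
#' invariant to flipping the sign of any of the three vectors.
#'
#' @param d_hat,a_hat,r_hat Unit vectors (length 3), or matrices with one
#'   unit vector per row for vectorised evaluation.
#' @param tol Tolerance on the unit-norm requirement.
#' @return `kappa^2`, a number in `[0, 4]` (or a vector thereof).
#' @examples
#' kappa_squared(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)) # head-to-tail: 4
#' kappa_squared(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0)) # parallel, perpendicular: 1
#' @export
kappa_squared <- function(d_hat, a_hat, r_hat, tol = 1e-8) {
  d <- rbind(d_hat); a <- rbind(a_hat); r <- rbind(r_hat)
  for (m in list(d, a, r)) {
    if (any(abs(rowSums(m^2) - 1) > tol)) {
      abort("kappa_squared requires unit-norm input vectors",
            class = "pigmentnet_data_error")
    }
  }
  kappa <- rowSums(d * a) - 3 * rowSums(d * r) * rowSums(a * r)
  unname(kappa^2)
}

#' Geometry of a single pigment pair
#'
#' Bundles the Mg-Mg distance and the orientation factor for an ordered
#' pigment pair. Both quantities are symmetric under swapping donor and
#' acceptor.
#'
#' @param a,b Single-row site records.
#' @return A one-row tibble with `donor`, `acceptor`, `R`, `kappa_sq`.
#' @export
pair_geometry <- function(a, b) {
  if (identical(a$site_id[1], b$site_id[1])) {
    abort("pair_geometry requires two distinct sites",
          class = "pigmentnet_data_error")
  }
  R <- mg_distance(a, b)
  if (R == 0) {
    abort("sites have identical Mg positions", class = "pigmentnet_data_error")
  }
  r_hat <- (site_mg(b) - site_mg(a)) / R
  k2 <- kappa_squared(transition_dipole(a), transition_dipole(b), r_hat)
  tibble::tibble(donor = a$site_id[1], acceptor = b$site_id[1],
                 R = R, kappa_sq = k2)
}

#' All pairwise pigment geometries within a distance cutoff
#'
#' Enumerates pigment pairs (chlorophyll-family sites with an Mg
#' position) whose Mg-Mg distance is at most `cutoff` and computes the
#' distance and orientation factor for each. Each unordered pair appears
#' once, ordered by the site order of the input (chain, then residue
#' number); the geometric fields are direction-independent.
#'
#' @param sites Structure tibble from [read_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 25, generous
#'   margin above the largest interfacial pair distances of interest).
#' @return A tibble `donor`, `acceptor`, `donor_species`,
#'   `acceptor_species`, `donor_complex`, `acceptor_complex`, `R`,
#'   `kappa_sq`.
#' @export
pair_geometries <- function(sites, cutoff = 25) {
  geo <- dplyr::filter(sites, .data$family == "chlorophyll", .data$has_mg)
  n <- nrow(geo)
  if (n < 2) {
    return(tibble::tibble(donor = character(), acceptor = character(),
                          donor_species = character(), acceptor_species = character(),
                          donor_complex = character(), acceptor_complex = character(),
                          R = double(), kappa_sq = double()))
  }
  mg <- as.matrix(geo[, c("mg_x", "mg_y", "mg_z")])
  dip <- as.matrix(geo[, c("d2_x", "d2_y", "d2_z")]) -
    as.matrix(geo[, c("d1_x", "d1_y", "d1_z")])
  dip <- dip / sqrt(rowSums(dip^2))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  dv <- mg[j, , drop = FALSE] - mg[i, , drop = FALSE]
  R <- sqrt(rowSums(dv^2))
  keep <- R <= cutoff & R > 0
  i <- i[keep]; j <- j[keep]; R <- R[keep]
  r_hat <- dv[keep, , drop = FALSE] / R
  k2 <- kappa_squared(dip[i, , drop = FALSE], dip[j, , drop = FALSE], r_hat)
  tibble::tibble(
    donor = geo$site_id[i], acceptor = geo$site_id[j],
    donor_species = geo$species[i], acceptor_species = geo$species[j],
    donor_complex = geo$complex[i], acceptor_complex = geo$complex[j],
    R = R, kappa_sq = k2
  ) |> dplyr::arrange(.data$R)
}
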