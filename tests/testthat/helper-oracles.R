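# Independent brute-force oracle for the orientation factor: explicit
# dot-product arithmetic, coded separately from the package routine.
kappa_sq_oracle <- function(d, a, r) {
  dot <- function(u, v) u[1] * v[1] + u[2] * v[2] + u[3] * v[3]
  k <- dot(d, a) - 3 * dot(d, r) * dot(a, r)
  k * k
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Build a structure tibble directly (no file round-trip), with explicit
# Mg positions and dipole axes.
make_sites <- function(mg, axes, species = rep("chl_a", nrow(mg)),
                       chain = LETTERS[seq_len(nrow(mg))],
                       resnum = rep(101L, nrow(mg)),
                       complex = rep("ungrouped", nrow(mg))) {
  axes <- axes / sqrt(rowSums(axes^2))
  tibble::tibble(
    site_id = site_label(species, resnum, chain),
    code = "CLA", species = species, family = "chlorophyll",
    chain = chain, resnum = resnum, complex = complex, has_mg = TRUE,
    mg_x = mg[, 1], mg_y = mg[, 2], mg_z = mg[, 3],
    d1_x = mg[, 1] - axes[, 1], d1_y = mg[, 2] - axes[, 2],
    d1_z = mg[, 3] - axes[, 3],
    d2_x = mg[, 1] + axes[, 1], d2_y = mg[, 2] + axes[, 2],
    d2_z = mg[, 3] + axes[, 3]
  )
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
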