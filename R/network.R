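#' Interfacial pigment pairs between complexes
#'
#' Restricts a rate table to pairs whose donor and acceptor belong to
#' different complexes and orders it for bridge ranking: descending
#' rate, ties broken by ascending distance, then lexicographic donor and
#' acceptor labels. Pairs involving ungrouped chains can be kept or
#' dropped.
#'
#' @param rates Rate table from [rate_table()].
#' @param drop_ungrouped Drop pairs with an `"ungrouped"` end (default
#'   TRUE).
#' @param cutoff Optional stricter distance cutoff, Angstrom.
#' @return The filtered, sorted rate table.
#' @export
interfacial_pairs <- function(rates, drop_ungrouped = TRUE, cutoff = NULL) {
  out <- dplyr::filter(rates, .data$donor_complex != .data$acceptor_complex)
  if (drop_ungrouped) {
    out <- dplyr::filter(out, .data$donor_complex != "ungrouped",
                         .data$acceptor_complex != "ungrouped")
  }
  if (!is.null(cutoff)) out <- dplyr::filter(out, .data$R <= cutoff)
  dplyr::arrange(out, dplyr::desc(.data$k_fret), .data$R,
                 .data$donor, .data$acceptor)
}

#' Flag pairs with low orientation factor
#'
#' Pairs with `kappa^2` strictly below the threshold (0.7 by default)
#' are marked as low-orientation: even at short distance their transfer
#' efficiency is negligible because the transition dipoles are
#' unfavourably aligned. The boundary value itself is not flagged.
#'
#' @param pairs Tibble with a `kappa_sq` column.
#' @param threshold Strict lower bound on `kappa^2` (default 0.7).
#' @return `pairs` with an added logical `low_orientation` column.
#' @export
flag_low_orientation <- function(pairs, threshold = 0.7) {
  dplyr::mutate(pairs, low_orientation = .data$kappa_sq < threshold)
}

#' Top transfer bridges
#'
#' Ranks interfacial pairs by rate and returns the strongest `n`.
#' Optionally restricts to Chl a - Chl a pairs (Chl b pigments are
#' poor inter-complex bridges) and/or drops low-orientation pairs.
#'
#' @param pairs Rate or interfacial-pair tibble.
#' @param n Number of pairs to return; if fewer are available all are
#'   returned.
#' @param chl_a_only Restrict to Chl a - Chl a pairs (default FALSE).
#' @param drop_low_orientation Drop pairs with `kappa^2` below
#'   `threshold` first (default FALSE).
#' @param threshold Orientation-factor threshold used when filtering.
#' @return The top-`n` rows, sorted by descending rate with the
#'   [interfacial_pairs()] tie-breakers.
#' @export
top_transfer_pairs <- function(pairs, n = 3, chl_a_only = FALSE,
                               drop_low_orientation = FALSE, threshold = 0.7) {
  if (chl_a_only && "is_chl_a_pair" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, .data$is_chl_a_pair)
  }
  if (drop_low_orientation) {
    pairs <- dplyr::filter(pairs, .data$kappa_sq >= threshold)
  }
  pairs |>
    dplyr::arrange(dplyr::desc(.data$k_fret), .data$R,
                   .data$donor, .data$acceptor) |>
    head(n)
}

#' Assign chlorophylls to stromal and lumenal layers
#'
#' Antenna chlorophylls sit in two roughly planar tiers near the
#' stromal and lumenal membrane faces. Given the Mg positions of a
#' complex (or any subset), the membrane normal is estimated as the
#' principal component of the Mg point cloud along which a deterministic
#' 1-D two-means split (Lloyd iterations from min/max initial centres)
#' separates the points best, measured by between-cluster over total sum
#' of squares. The partition is invariant under rigid rotation and
#' translation of the structure.
#'
#' Layer names are assigned by projection order along the chosen axis
#' (with the axis sign fixed so its largest-magnitude loading is
#' positive): the higher-projection group is labelled `"stromal"`. In an
#' arbitrarily oriented model frame the two names may be swapped
#' relative to the true membrane sidedness; the partition itself is the
#' meaningful output.
#'
#' @param sites Structure tibble; only chlorophyll-family sites with Mg
#'   positions are used.
#' @param min_separation Minimum acceptable between/total sum-of-squares
#'   ratio; below it the point cloud has no two-layer structure and an
#'   ambiguity error is raised.
#' @return A tibble `site_id`, `species`, `layer` with
#'   `layer` in `{"stromal", "lumenal"}`.
#' @export
assign_layers <- function(sites, min_separation = 0.5) {
  geo <- dplyr::filter(sites, .data$family == "chlorophyll", .data$has_mg)
  if (nrow(geo) < 2) {
    abort("layer assignment needs at least two chlorophyll sites",
          class = "pigmentnet_data_error")
  }
  mg <- as.matrix(geo[, c("mg_x", "mg_y", "mg_z")])
  pc <- prcomp(mg, center = TRUE, scale. = FALSE)
  best <- NULL
  for (ax in seq_len(ncol(pc$rotation))) {
    proj <- pc$x[, ax]
    if (diff(range(proj)) == 0) next
    split <- two_means_1d(proj)
    if (is.null(best) || split$score > best$score) {
      best <- c(split, list(axis = ax, proj = proj))
    }
  }
  if (is.null(best) || best$score < min_separation) {
    abort("ambiguous layer geometry: no axis separates the Mg positions into two layers",
          class = "pigmentnet_data_error")
  }
  axis_vec <- pc$rotation[, best$axis]
  flip <- sign(axis_vec[which.max(abs(axis_vec))])
  proj <- best$proj * flip
  upper <- if (flip > 0) best$cluster == which.max(best$centers) else
    best$cluster == which.min(best$centers)
  tibble::tibble(
    site_id = geo$site_id,
    species = geo$species,
    layer = ifelse(upper, "stromal", "lumenal")
  )
}

# Deterministic 1-D two-means: centres start at the extremes, Lloyd
# iterations until stable. Returns cluster ids, centres, and the
# between/total sum-of-squares ratio.
two_means_1d <- function(x, max_iter = 100) {
  centers <- range(x)
  cluster <- rep(1L, length(x))
  for (iter in seq_len(max_iter)) {
    new_cluster <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    if (identical(new_cluster, cluster) && iter > 1) break
    cluster <- new_cluster
    centers <- c(mean(x[cluster == 1L]), mean(x[cluster == 2L]))
  }
  tot <- sum((x - mean(x))^2)
  betw <- sum(tabulate(cluster, 2) * (centers - mean(x))^2)
  list(cluster = cluster, centers = centers,
       score = if (tot > 0) betw / tot else 0)
}

#' Export a transfer network as a DOT graph
#'
#' Writes the pair list as an undirected graphviz DOT file, with edge
#' labels carrying the rate (ps^-1) and nodes grouped by complex.
#'
#' @param pairs Rate-table tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_dot <- function(pairs, path) {
  lines <- c("graph transfer_network {")
  nodes <- unique(c(pairs$donor, pairs$acceptor))
  lines <- c(lines, sprintf('  "%s";', nodes))
  if (nrow(pairs)) {
    lines <- c(lines, sprintf('  "%s" -- "%s" [label="%.2f"];',
                              pairs$donor, pairs$acceptor, pairs$k_fret))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Plot a transfer-pair overview
#'
#' Scatter of orientation factor against Mg-Mg distance, sized by rate,
#' with the low-orientation threshold drawn as a horizontal line.
#'
#' @param pairs Rate-table tibble.
#' @param threshold Orientation-factor threshold to draw.
#' @return A ggplot object.
#' @export
plot_pair_map <- function(pairs, threshold = 0.7) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$R, .data$kappa_sq,
                                      size = .data$k_fret)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "Mg-Mg distance (Å)",
                  y = expression(kappa^2),
                  size = expression(k[FRET] ~ (ps^-1))) +
    ggplot2::theme_minimal()
}
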