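fake_rates <- function(k, R = seq_along(k) + 10, donor_complex = "T1",
                       acceptor_complex = "PSI", kappa_sq = 1,
                       is_chl_a_pair = TRUE) {
  n <- length(k)
  tibble::tibble(
    donor = sprintf("a%03d_A", seq_len(n)),
    acceptor = sprintf("a%03d_B", 100 + seq_len(n)),
    donor_species = ifelse(is_chl_a_pair, "chl_a", "chl_b"),
    acceptor_species = "chl_a",
    donor_complex = rep_len(donor_complex, n),
    acceptor_complex = rep_len(acceptor_complex, n),
    R = R, kappa_sq = rep_len(kappa_sq, n), k_fret = k,
    is_chl_a_pair = rep_len(is_chl_a_pair, n)
  )
}

test_that("interfacial pairs keep only cross-complex edges, sorted by rate", {
  rt <- dplyr::bind_rows(
    fake_rates(c(0.3, 0.1)),
    fake_rates(0.5, donor_complex = "T1", acceptor_complex = "T1"),
    fake_rates(0.2, donor_complex = "ungrouped")
  )
  out <- interfacial_pairs(rt)
  expect_equal(out$k_fret, c(0.3, 0.1))
  expect_true(all(out$donor_complex != out$acceptor_complex))
  kept <- interfacial_pairs(rt, drop_ungrouped = FALSE)
  expect_equal(nrow(kept), 3)
  # all pigments in one complex -> empty list
  expect_equal(nrow(interfacial_pairs(fake_rates(0.4, donor_complex = "X",
                                                 acceptor_complex = "X"))), 0)
})

test_that("ranking is a total order stable under input permutation", {
  set.seed(5)
  rt <- fake_rates(k = c(0.2, 0.2, 0.2, 0.1), R = c(15, 12, 12, 9))
  rt$acceptor[2] <- "a050_B"  # tie in k and R broken lexicographically
  sorted <- interfacial_pairs(rt)
  expect_equal(sorted$k_fret, c(0.2, 0.2, 0.2, 0.1))
  expect_equal(sorted$R[1:3], c(12, 12, 15))
  expect_equal(sorted$acceptor[1], "a050_B")
  for (i in 1:5) {
    perm <- rt[sample(nrow(rt)), ]
    expect_identical(interfacial_pairs(perm), sorted)
  }
})

test_that("the interface list is invariant to complex relabeling", {
  rt <- dplyr::bind_rows(fake_rates(c(0.3, 0.1)),
                         fake_rates(0.5, donor_complex = "A", acceptor_complex = "A"))
  relabeled <- rt |>
    dplyr::mutate(donor_complex = paste0("grp_", donor_complex),
                  acceptor_complex = paste0("grp_", acceptor_complex))
  expect_equal(interfacial_pairs(rt)$donor,
               interfacial_pairs(relabeled)$donor)
})

test_that("low-orientation flag uses a strict threshold", {
  pairs <- fake_rates(c(0.0, 0.29, 0.1), kappa_sq = 1)
  pairs$kappa_sq <- c(0.01, 0.95, 0.7)
  flagged <- flag_low_orientation(pairs)
  expect_equal(flagged$low_orientation, c(TRUE, FALSE, FALSE))
  expect_equal(flag_low_orientation(pairs, threshold = 0.71)$low_orientation,
               c(TRUE, FALSE, TRUE))
})

test_that("top transfer pairs from the printed table give the three known bridges", {
  tab <- read_pair_table()
  pairs <- tab |>
    dplyr::rename(is_chl_a_pair = "chl_a_pair") |>
    dplyr::mutate(is_chl_a_pair = is_chl_a_pair == "Yes")
  top <- top_transfer_pairs(pairs, n = 3, chl_a_only = TRUE)
  expect_setequal(top$pair, c("a612_W -> a201_K", "a611_R -> a302_H",
                              "a612_R -> a610_Lhca6"))
  expect_equal(top$pair[1], "a612_W -> a201_K")  # 0.29 ps^-1 leads
  # n beyond availability returns everything, no error
  expect_equal(nrow(top_transfer_pairs(pairs, n = 99, chl_a_only = TRUE)),
               sum(pairs$is_chl_a_pair))
  expect_equal(nrow(top_transfer_pairs(pairs[0, ], n = 3)), 0)
  # matches an independently sorted reference
  ref <- pairs[order(-pairs$k_fret, pairs$R, pairs$donor, pairs$acceptor), ]
  expect_equal(top_transfer_pairs(pairs, n = 5)$pair, ref$pair[1:5])
})

test_that("two-slab point clouds are split into the constructed layers", {
  spec <- toy_monomer_spec(separation = 15)
  sites <- read_structure(make_toy_structure(spec))
  layers <- assign_layers(sites)
  expect_equal(sort(as.integer(table(layers$layer))), c(7L, 7L))
  # membership matches the construction: resnums 601-607 on one side
  side <- layers$layer[match(site_label(spec$species, spec$resnum, spec$chain),
                             layers$site_id)]
  expect_equal(length(unique(side[1:7])), 1)
  expect_equal(length(unique(side[8:14])), 1)
  expect_false(side[1] == side[8])
  # stromal slab composition: 5 chl_a, 1 chl_b, 1 mdp
  strom <- dplyr::count(dplyr::filter(layers, layer == side[1]), species)
  expect_equal(strom$n[strom$species == "chl_a"], 5)
  expect_equal(strom$n[strom$species == "chl_b"], 1)
  expect_equal(strom$n[strom$species == "mdp"], 1)
})

test_that("layer partition is invariant under rigid motion", {
  set.seed(61)
  spec <- toy_monomer_spec(separation = 12)
  sites <- read_structure(make_toy_structure(spec))
  base <- assign_layers(sites)
  for (i in 1:5) {
    Q <- random_rotation()
    shift <- stats::rnorm(3, sd = 50)
    mg <- as.matrix(sites[, c("mg_x", "mg_y", "mg_z")]) %*% t(Q)
    moved <- sites
    moved$mg_x <- mg[, 1] + shift[1]
    moved$mg_y <- mg[, 2] + shift[2]
    moved$mg_z <- mg[, 3] + shift[3]
    rot <- assign_layers(moved)
    same <- identical(rot$layer, base$layer)
    swapped <- identical(rot$layer,
                         ifelse(base$layer == "stromal", "lumenal", "stromal"))
    expect_true(same || swapped)
  }
})

test_that("degenerate layer geometry raises an ambiguity error", {
  one <- make_sites(rbind(c(0, 0, 0)), rbind(c(1, 0, 0)))
  expect_error(assign_layers(one), class = "pigmentnet_data_error")
  # a single tight blob has no two-layer structure at the required separation
  set.seed(71)
  blob <- make_sites(matrix(stats::rnorm(60, sd = 1), 20, 3),
                     t(replicate(20, random_unit())),
                     chain = sprintf("C%02d", 1:20))
  expect_error(assign_layers(blob, min_separation = 0.95),
               class = "pigmentnet_data_error")
})

test_that("DOT export writes every edge with its rate", {
  pairs <- fake_rates(c(0.29, 0.17))
  path <- tempfile(fileext = ".dot")
  export_dot(pairs, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("--", lines, fixed = TRUE)), 2)
  expect_true(any(grepl("0.29", lines, fixed = TRUE)))
})
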