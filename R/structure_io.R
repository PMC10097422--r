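#' Read pigment and cofactor sites from a coordinate model
#'
#' Parses a macromolecular coordinate file (PDB or mmCIF), identifies
#' cofactor residues by their ligand codes, and returns one row per
#' cofactor instance. For chlorophyll-family residues the central Mg
#' position and the two atoms defining the Qy transition-dipole axis are
#' extracted; the default convention takes the axis from the N-B to the
#' N-D ring nitrogen of the chlorin macrocycle.
#'
#' Chlorophyll-family residues that lack an Mg atom are retained with
#' `has_mg = FALSE` (and a warning) so that inventories stay complete,
#' but they are excluded from all geometric computations.
#'
#' @param path Coordinate file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param ligand_map Tibble mapping ligand codes to species, see
#'   [default_ligand_map()].
#' @param dipole_atoms Character vector of length 2 naming the atoms that
#'   define the Qy axis of chlorophyll-family pigments.
#' @return A tibble with one row per recognised cofactor residue and
#'   columns `site_id`, `code`, `species`, `family`, `chain`, `resnum`,
#'   `complex` (initially `"ungrouped"`), `has_mg`, Mg coordinates
#'   `mg_x/mg_y/mg_z` and dipole-atom coordinates `d1_*`, `d2_*`
#'   (all in the deposited model frame, Angstrom). Rows are ordered by
#'   chain then residue number so the result is independent of record
#'   order in the file.
#' @seealso [count_cofactors()], [assign_complexes()], [pair_geometries()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           ligand_map = default_ligand_map(),
                           dipole_atoms = c("NB", "ND")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("coordinate file not found: ", path), class = "pigmentnet_data_error")
  }
  if (nrow(ligand_map) == 0) {
    abort("ligand map is empty", class = "pigmentnet_config_error")
  }
  if (length(dipole_atoms) != 2 || anyDuplicated(dipole_atoms)) {
    abort("dipole_atoms must be two distinct atom names", class = "pigmentnet_config_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)$atom
    else bio3d::read.cif(path, verbose = FALSE)$atom,
    error = function(e) {
      abort(paste0("failed to parse ", format, " file ", path, ": ",
                   conditionMessage(e)), class = "pigmentnet_data_error")
    }
  )
  atoms <- tibble::as_tibble(atoms)
  atoms <- dplyr::filter(atoms, .data$resid %in% ligand_map$code)
  if (nrow(atoms) == 0) {
    return(empty_structure())
  }
  atoms <- dplyr::left_join(atoms,
                            dplyr::rename(ligand_map, resid = "code"),
                            by = "resid")
  atoms$chain[is.na(atoms$chain)] <- ""
  sites <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid,
                    .data$species, .data$family) |>
    dplyr::summarise(
      mg = list(locate_atom(dplyr::pick(dplyr::everything()), "MG", element = "MG")),
      d1 = list(locate_atom(dplyr::pick(dplyr::everything()), dipole_atoms[1])),
      d2 = list(locate_atom(dplyr::pick(dplyr::everything()), dipole_atoms[2])),
      .groups = "drop"
    )
  out <- tibble::tibble(
    site_id = site_label(sites$species, sites$resno, sites$chain, sites$resid),
    code = sites$resid,
    species = sites$species,
    family = sites$family,
    chain = sites$chain,
    resnum = sites$resno,
    complex = "ungrouped",
    has_mg = sites$family == "chlorophyll" & !purrr::map_lgl(sites$mg, ~ anyNA(.x)),
    mg_x = purrr::map_dbl(sites$mg, 1), mg_y = purrr::map_dbl(sites$mg, 2),
    mg_z = purrr::map_dbl(sites$mg, 3),
    d1_x = purrr::map_dbl(sites$d1, 1), d1_y = purrr::map_dbl(sites$d1, 2),
    d1_z = purrr::map_dbl(sites$d1, 3),
    d2_x = purrr::map_dbl(sites$d2, 1), d2_y = purrr::map_dbl(sites$d2, 2),
    d2_z = purrr::map_dbl(sites$d2, 3)
  )
  no_mg <- out$family == "chlorophyll" & !out$has_mg
  if (any(no_mg)) {
    warn(paste0("chlorophyll site(s) without Mg excluded from geometry: ",
                paste(out$site_id[no_mg], collapse = ", ")))
  }
  if (anyDuplicated(out$site_id)) {
    abort("duplicate site_id in structure (chain/resnum collision)",
          class = "pigmentnet_data_error")
  }
  dplyr::arrange(out, .data$chain, .data$resnum)
}

empty_structure <- function() {
  tibble::tibble(
    site_id = character(), code = character(), species = character(),
    family = character(), chain = character(), resnum = integer(),
    complex = character(), has_mg = logical(),
    mg_x = double(), mg_y = double(), mg_z = double(),
    d1_x = double(), d1_y = double(), d1_z = double(),
    d2_x = double(), d2_y = double(), d2_z = double()
  )
}

locate_atom <- function(df, name, element = NULL) {
  hit <- which(df$elety == name)
  if (!length(hit) && !is.null(element) && "elesy" %in% names(df)) {
    ele <- toupper(trimws(as.character(df$elesy)))
    cand <- which(ele == element)
    if (length(cand) == 1) hit <- cand
  }
  if (!length(hit)) return(c(NA_real_, NA_real_, NA_real_))
  c(df$x[hit[1]], df$y[hit[1]], df$z[hit[1]])
}

#' Render a pigment site label
#'
#' Labels follow the convention of published pair tables: a species
#' letter (`a` for Chl a, `b` for Chl b, `Mdp` for the divinyl
#' pheoporphyrin), the residue number, an underscore, and the chain,
#' e.g. `"a612_W"`. Non-chlorophyll cofactors use their lowercased
#' ligand code in place of the letter.
#'
#' @param species,resnum,chain,code Vectors describing the sites.
#' @return Character vector of labels.
#' @export
site_label <- function(species, resnum, chain, code = species) {
  prefix <- dplyr::case_match(species,
    "chl_a" ~ "a", "chl_b" ~ "b", "mdp" ~ "Mdp",
    .default = tolower(code)
  )
  paste0(prefix, resnum, "_", chain)
}

#' Count cofactors by species
#'
#' Tallies the cofactor inventory of a parsed structure, optionally per
#' assigned complex. The chlorophyll-family total is the sum of the
#' Chl a, Chl b, and Mdp counts.
#'
#' @param sites Structure tibble from [read_structure()].
#' @param by_complex Also group counts by the `complex` column.
#' @return A tibble with columns (`complex`,) `species`, `family`, `n`.
#' @examples
#' sites <- read_structure(make_toy_structure(toy_pair_spec(16.24, 0.95)))
#' count_cofactors(sites)
#' @export
count_cofactors <- function(sites, by_complex = FALSE) {
  keys <- c(if (by_complex) "complex", "species", "family")
  sites |>
    dplyr::count(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Chlorophyll b / a ratio
#'
#' The Chl b to Chl a molar ratio of an inventory, a standard descriptor
#' of antenna composition (e.g. 5 Chl b : 8 Chl a = 0.625 for a single
#' Lhcp monomer).
#'
#' @param counts Either a counts tibble from [count_cofactors()] or a
#'   structure tibble from [read_structure()].
#' @return A single number, `n(chl_b) / n(chl_a)`.
#' @export
chl_ba_ratio <- function(counts) {
  if (!"n" %in% names(counts)) counts <- count_cofactors(counts)
  n_of <- function(sp) sum(counts$n[counts$species == sp])
  na <- n_of("chl_a")
  if (na == 0) {
    abort("chl_b/chl_a ratio undefined: no Chl a in inventory",
          class = "pigmentnet_data_error")
  }
  n_of("chl_b") / na
}

#' Assign chains to named complexes
#'
#' Attaches a `complex` label to every site according to a chain
#' grouping table (e.g. chains S, T, U form "Trimer 1"). Chains absent
#' from the grouping are labelled `"ungrouped"`.
#'
#' @param sites Structure tibble from [read_structure()].
#' @param grouping Tibble with columns `chain`, `complex`, or a named
#'   character vector `c(S = "Trimer 1", ...)`.
#' @return The sites tibble with its `complex` column filled in.
#' @export
assign_complexes <- function(sites, grouping) {
  grouping <- as_grouping(grouping)
  sites$complex <- NULL
  out <- dplyr::left_join(sites, grouping, by = "chain")
  out$complex[is.na(out$complex)] <- "ungrouped"
  dplyr::relocate(out, "complex", .after = "resnum")
}

as_grouping <- function(grouping) {
  if (is.character(grouping) && !is.null(names(grouping))) {
    grouping <- tibble::tibble(chain = names(grouping), complex = unname(grouping))
  }
  if (!all(c("chain", "complex") %in% names(grouping))) {
    abort("grouping must have columns chain and complex",
          class = "pigmentnet_config_error")
  }
  if (anyDuplicated(grouping$chain)) {
    abort("grouping assigns a chain to more than one complex",
          class = "pigmentnet_config_error")
  }
  tibble::as_tibble(grouping[c("chain", "complex")])
}

#' Chain grouping of the supercomplex deposition
#'
#' The default grouping used for the PSI-LHCI-Lhcp supercomplex model:
#' chains A-O are the PSI core subunits (PsaA-PsaO), chains S/T/U form
#' Trimer 1, P/Q/R Trimer 2 (Q is the phosphorylated Lhcp1), and V/W/X
#' Trimer 3. The LHCI belt chains are deposition-specific and left to a
#' user-supplied grouping file.
#'
#' @param path TSV with columns `chain`, `complex`.
#' @return A grouping tibble.
#' @export
default_grouping <- function(path = system.file("extdata", "grouping_7yca.tsv",
                                                package = "pigmentnet")) {
  read_grouping(path)
}

#' @rdname default_grouping
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("grouping file not found: ", path), class = "pigmentnet_config_error")
  }
  as_grouping(readr::read_tsv(path, col_types = "cc", progress = FALSE))
}

#' Write a pigment inventory TSV
#'
#' @param sites Structure tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pigment_inventory <- function(sites, path) {
  inv <- dplyr::select(sites, "site_id", "species", "chain", "resnum",
                       "complex", "mg_x", "mg_y", "mg_z")
  readr::write_tsv(inv, path, progress = FALSE)
  invisible(path)
}
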