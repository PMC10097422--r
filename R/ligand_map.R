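#' Ligand-code to pigment-species mapping
#'
#' Coordinate depositions identify cofactors by three-letter chemical
#' component codes. A ligand map translates those codes into the species
#' vocabulary used throughout the package (`chl_a`, `chl_b`, `mdp`,
#' `car_*`, ...) and assigns each species to a family:
#' `"chlorophyll"` (chlorin macrocycles with a central Mg),
#' `"carotenoid"`, or `"other"` (quinones, iron-sulfur clusters, lipids).
#'
#' The default map covers chlorophyll a (`CLA`), chlorophyll b (`CHL`),
#' magnesium 2,4-divinylpheoporphyrin a5 monomethyl ester (`DVP`, often
#' called Mdp), the common carotenoid codes (beta-carotene `BCR`,
#' violaxanthin `XAT`, neoxanthin `NEX`, lutein `LUT`, prasinoxanthin
#' `PRX`, dihydrolutein `DLT`), phylloquinone `PQN`, the Fe4S4 cluster
#' `SF4`, and common thylakoid lipid codes. Because deposition dialects
#' vary (in particular for prasinophyte-specific pigments), the map is a
#' plain TSV that users can extend or replace.
#'
#' @param path TSV file with columns `code`, `species`, `family`. The
#'   default reads the map packaged under `extdata/ligand_map.tsv`.
#' @return A tibble with columns `code`, `species`, `family`.
#' @examples
#' default_ligand_map()
#' @export
default_ligand_map <- function(path = system.file("extdata", "ligand_map.tsv",
                                                  package = "pigmentnet")) {
  read_ligand_map(path)
}

#' @rdname default_ligand_map
#' @export
read_ligand_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("ligand map file not found: ", path), class = "pigmentnet_config_error")
  }
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("code", "species", "family")
  if (!all(required %in% names(map))) {
    abort("ligand map must have columns code, species, family",
          class = "pigmentnet_config_error")
  }
  if (anyDuplicated(map$code)) {
    abort("ligand map assigns a code to more than one species",
          class = "pigmentnet_config_error")
  }
  bad <- setdiff(unique(map$family), c("chlorophyll", "carotenoid", "other"))
  if (length(bad)) {
    abort(paste0("unknown ligand family: ", paste(bad, collapse = ", ")),
          class = "pigmentnet_config_error")
  }
  tibble::as_tibble(map[required])
}
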