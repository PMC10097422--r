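#' Read a pipeline configuration file
#'
#' Configuration is a small YAML key-value file. Recognised keys (all
#' optional, with packaged defaults): `ligand_map` and `grouping`
#' (paths to TSVs), `calibration` (path to a printed pair-table TSV),
#' `cutoff` (Angstrom), `kappa_sq_threshold`, `min_rate`, `seed`,
#' `out_dir`. Paths are resolved relative to the config file.
#'
#' @param path Config file; `NULL` returns the defaults.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- list(
    ligand_map = system.file("extdata", "ligand_map.tsv", package = "pigmentnet"),
    grouping = system.file("extdata", "grouping_7yca.tsv", package = "pigmentnet"),
    calibration = system.file("extdata", "table5.tsv", package = "pigmentnet"),
    cutoff = 25, kappa_sq_threshold = 0.7, min_rate = 0.05,
    seed = 0, out_dir = "."
  )
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "pigmentnet_config_error")
    }
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
            class = "pigmentnet_config_error")
    }
    for (key in c("ligand_map", "grouping", "calibration")) {
      if (!is.null(user[[key]]) && !file.exists(user[[key]])) {
        rel <- file.path(dirname(path), user[[key]])
        if (file.exists(rel)) user[[key]] <- rel
      }
    }
    cfg[names(user)] <- user
  }
  for (num in c("cutoff", "kappa_sq_threshold", "min_rate")) {
    if (!is.numeric(cfg[[num]]) || cfg[[num]] <= 0) {
      abort(paste0("config field ", num, " must be a positive number"),
            class = "pigmentnet_config_error")
    }
  }
  for (key in c("ligand_map", "grouping", "calibration")) {
    if (!file.exists(cfg[[key]])) {
      abort(paste0("config file refers to missing path: ", cfg[[key]]),
            class = "pigmentnet_config_error")
    }
  }
  cfg
}

#' Run the structure-to-network pipeline
#'
#' Executes extract -> geometry -> calibrate -> rates -> network on a
#' coordinate file and writes a report bundle to `out_dir`:
#' `inventory.tsv` (pigment inventory), `rates.tsv` (pair rates, with
#' rates also given rounded to two decimals as reported in print),
#' `network.tsv` (interfacial pairs with low-orientation flags),
#' `network.dot` (graph export), and `summary.json` (counts, constants,
#' top pairs, configuration echo and package version). Reruns with the
#' same inputs produce byte-identical outputs.
#'
#' @param structure_path Coordinate file (PDB or mmCIF).
#' @param config Configuration list from [read_pipeline_config()].
#' @param out_dir Output directory (overrides the config value).
#' @param top_n Number of top bridges in the summary.
#' @return Invisibly, a list with the `inventory`, `rates`, `network`
#'   tibbles, the `constants`, and the output `paths`.
#' @export
run_pipeline <- function(structure_path, config = read_pipeline_config(),
                         out_dir = config$out_dir, top_n = 3) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }
  ligand_map <- stage("config", read_ligand_map(config$ligand_map))
  grouping <- stage("config", read_grouping(config$grouping))
  pair_tab <- stage("calibrate", read_pair_table(config$calibration))
  constants <- stage("calibrate",
                     default_coupling_constants(pair_tab,
                                                min_rate = config$min_rate))
  sites <- stage("extract",
                 read_structure(structure_path, ligand_map = ligand_map))
  sites <- stage("extract", assign_complexes(sites, grouping))
  rates <- stage("rates", rate_table(sites, constants, cutoff = config$cutoff))
  network <- stage("network",
                   interfacial_pairs(rates) |>
                     flag_low_orientation(config$kappa_sq_threshold))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    inventory = file.path(out_dir, "inventory.tsv"),
    rates = file.path(out_dir, "rates.tsv"),
    network = file.path(out_dir, "network.tsv"),
    dot = file.path(out_dir, "network.dot"),
    summary = file.path(out_dir, "summary.json")
  )
  write_pigment_inventory(sites, paths$inventory)
  readr::write_tsv(dplyr::mutate(rates, k_fret_2dp = round(.data$k_fret, 2)),
                   paths$rates, progress = FALSE)
  readr::write_tsv(network, paths$network, progress = FALSE)
  export_dot(network, paths$dot)
  summary <- list(
    structure = basename(structure_path),
    pigmentnet_version = as.character(utils::packageVersion("pigmentnet")),
    config = config[c("cutoff", "kappa_sq_threshold", "min_rate")],
    counts = count_cofactors(sites),
    constants = constants,
    top_pairs = top_transfer_pairs(network, n = top_n)
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(inventory = sites, rates = rates, network = network,
                 constants = constants, paths = paths))
}
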