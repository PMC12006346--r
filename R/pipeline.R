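#' Run configuration
#'
#' Reads and validates the single YAML (or list) configuration driving
#' [run_pipeline()]. Required fields: `network` (SBML/JSON path),
#' `expression` (list with `matrix`, `genes`, `cells`, `labels` paths),
#' `medium` (CSV path), `output_dir`. Optional fields with defaults:
#' `pathway_keys` (CSV path; toy defaults when absent), `discretization`
#' (list, see [discretize()]), `epsilon` (1e-4), `o2_glucose_ratio` (2),
#' `min_cells` (50), `require_shared` (TRUE), `floor_fraction` (0.1),
#' `exact_threshold` (25), `seed` (1, recorded in metadata).
#'
#' @param config YAML file path or a list with the fields above.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(pathway_keys = NULL, discretization = list(),
                   epsilon = 1e-4, o2_glucose_ratio = 2, min_cells = 50,
                   require_shared = TRUE, floor_fraction = 0.1,
                   exact_threshold = 25, seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  need <- c("network", "expression", "medium", "output_dir")
  miss <- need[!need %in% names(config)]
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  paths <- c(config$network, config$medium,
             unlist(config$expression[c("matrix", "genes", "cells",
                                        "labels")]),
             config$pathway_keys)
  for (p in paths) if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(config$epsilon > 0, config$o2_glucose_ratio > 0,
            config$min_cells >= 1, config$floor_fraction >= 0,
            config$floor_fraction <= 1)
  class(config) <- "run_config"
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Serialize a multi-cell model
#'
#' Writes the model network in the package's JSON dialect with a
#' `multicell` extension block (cell types, weights, biomass map,
#' condition, provenance).
#'
#' @param model a `multicell_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multicell_model <- function(model, path) {
  tmp <- tempfile(fileext = ".json")
  write_network_json(model$network, tmp)
  doc <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  unlink(tmp)
  doc$multicell <- list(
    cell_types = as.list(model$cell_types),
    weights = as.list(model$weights),
    biomass_reaction = as.list(model$biomass_reaction),
    condition = model$condition,
    provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_multicell_model
#' @export
read_multicell_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$multicell)) stop("not a multicell model file: ", path)
  net <- read_network_json(path)
  mc <- doc$multicell
  structure(list(network = net,
                 cell_types = unlist(mc$cell_types),
                 weights = unlist(mc$weights),
                 biomass_reaction = unlist(mc$biomass_reaction),
                 condition = mc$condition,
                 provenance = mc$provenance),
            class = "multicell_model")
}

#' Run the full multi-cell modeling pipeline
#'
#' One call per data set: reads the generic network, counts and medium,
#' retains cell types, and per condition builds core sets, the multi-cell
#' model, solves the weighted-biomass FBA with minimal-cardinality fluxes,
#' and writes every report plus a metadata JSON into a hash-named run
#' directory. Deterministic given the config.
#'
#' @param config a config list/path accepted by [read_run_config()].
#' @return (invisibly) named list of per-condition result lists (`model`,
#'   `weighted`, `solution`, `reports`, `dir`).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  chash <- config_hash(config)
  network <- read_network(config$network)
  expr <- read_expression(config$expression$matrix, config$expression$genes,
                          config$expression$cells, config$expression$labels)
  medium <- read_medium(config$medium,
                        o2_glucose_ratio = config$o2_glucose_ratio)
  keys <- default_pathway_keys(config$pathway_keys)
  strata <- filter_cell_types(expr, min_cells = config$min_cells,
                              require_shared = config$require_shared)
  if (!nrow(strata)) stop("no cell type passes the retention rule")
  run_dir <- file.path(config$output_dir, paste0("run_", substr(chash, 1, 12)))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  out <- list()
  for (cond in unique(strata$condition)) {
    cdir <- file.path(run_dir, cond)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    cs <- build_core_sets(expr, network,
                          strata[strata$condition == cond, , drop = FALSE],
                          params = config$discretization)
    model <- build_multicell_model(network, cs, epsilon = config$epsilon,
                                   medium = medium)
    model <- apply_medium(model, medium)
    weighted <- maximize_weighted_biomass(model,
                                          floor_fraction =
                                            config$floor_fraction)
    solution <- minimal_cardinality_flux(model, weighted,
                                         exact_threshold =
                                           config$exact_threshold)
    write_multicell_model(model, file.path(cdir, "model.json"))
    write_report(tibble::tibble(reaction = names(solution$fluxes),
                                flux = unname(solution$fluxes)),
                 file.path(cdir, "fluxes.tsv"))
    med_rep <- medium_exchange_report(solution, model)
    write_report(med_rep, file.path(cdir, "medium_exchange.tsv"))
    med_species <- medium_exchange_base(
      grep("^EX_", model$network$rxns$id, value = TRUE))
    ic <- do.call(rbind, lapply(med_species, function(s)
      intercellular_exchange_report(solution, model, s)))
    write_report(ic, file.path(cdir, "intercellular_exchange.tsv"))
    pfs <- do.call(rbind, lapply(names(keys), function(p) {
      scopes <- c("model", model$cell_types)
      tibble::tibble(pathway = p, scope = scopes,
                     flux_sum = vapply(scopes, function(s)
                       pathway_flux_sum(solution, model, keys[[p]], s),
                       numeric(1)))
    }))
    write_report(pfs, file.path(cdir, "pathway_flux_sum.tsv"))
    meta <- list(
      config = unclass(config), config_hash = chash,
      condition = cond,
      input_hashes = list(
        network = unname(tools::md5sum(config$network)),
        matrix = unname(tools::md5sum(config$expression$matrix)),
        medium = unname(tools::md5sum(config$medium))),
      thresholds = lapply(cs, function(x)
        c(list(cell_type = x$cell_type), x$thresholds)),
      n_cells = stats::setNames(as.list(model$weights),
                                names(model$weights)),
      objective_value = solution$objective_value,
      per_type_max_biomass = as.list(weighted$per_type_max_biomass),
      support_size = solution$support_size,
      solver = solution$solver_metadata,
      package_version = as.character(utils::packageVersion("multicellfba")))
    jsonlite::write_json(meta, file.path(cdir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out[[cond]] <- list(model = model, weighted = weighted,
                        solution = solution,
                        reports = list(medium = med_rep, intercellular = ic,
                                       pathway = pfs),
                        dir = cdir)
  }
  invisible(out)
}

read_run_dir <- function(dir) {
  if (!file.exists(file.path(dir, "metadata.json"))) {
    stop("not a pipeline run directory (no metadata.json): ", dir)
  }
  list(meta = jsonlite::fromJSON(file.path(dir, "metadata.json"),
                                 simplifyVector = TRUE),
       model = read_multicell_model(file.path(dir, "model.json")),
       pathway = utils::read.delim(file.path(dir, "pathway_flux_sum.tsv"),
                                   stringsAsFactors = FALSE),
       medium = utils::read.delim(file.path(dir, "medium_exchange.tsv"),
                                  stringsAsFactors = FALSE),
       intercellular = utils::read.delim(
         file.path(dir, "intercellular_exchange.tsv"),
         stringsAsFactors = FALSE))
}

#' Compare two pipeline runs
#'
#' Aligns two completed per-condition run directories built from the same
#' generic reconstruction: reaction-content Jaccard similarity, per-pathway
#' FluxSum deltas, and medium exchange-rate deltas (run B minus run A).
#'
#' @param run_a,run_b per-condition run directories written by
#'   [run_pipeline()].
#' @return list with `jaccard` (scalar), `pathway_delta`,
#'   `exchange_delta` tibbles.
#' @export
compare_conditions <- function(run_a, run_b) {
  a <- read_run_dir(run_a)
  b <- read_run_dir(run_b)
  ha <- a$meta$input_hashes$network
  hb <- b$meta$input_hashes$network
  if (!identical(ha, hb)) {
    stop("runs derive from different generic networks (hash mismatch)")
  }
  jac <- jaccard_similarity(a$model$network$rxns$id, b$model$network$rxns$id)
  pw <- merge(a$pathway, b$pathway, by = c("pathway", "scope"),
              suffixes = c("_a", "_b"), all = TRUE)
  pw[is.na(pw)] <- 0
  pw$delta <- pw$flux_sum_b - pw$flux_sum_a
  me <- merge(a$medium[, c("metabolite", "rate")],
              b$medium[, c("metabolite", "rate")],
              by = "metabolite", suffixes = c("_a", "_b"), all = TRUE)
  me[is.na(me)] <- 0
  me$delta <- me$rate_b - me$rate_a
  list(jaccard = jac,
       pathway_delta = tibble::as_tibble(pw),
       exchange_delta = tibble::as_tibble(me))
}

#' Run the demonstration scenario end to end
#'
#' Generates the lactate-shuttle fixtures ([scenario_lactate_shuttle()]),
#' writes them to disk, runs the pipeline on them, and returns the run
#' results. The `disrupted` variant simulates the respiration-deficient
#' neuron program.
#'
#' @param dir working directory for fixtures and outputs.
#' @param seed simulation seed.
#' @param disrupted use the respiration-deficient neuron program.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(dir = tempfile("multicellfba_demo"), seed = 1,
                     disrupted = FALSE) {
  sc <- scenario_lactate_shuttle(seed = seed, disrupted = disrupted)
  fix <- write_scenario_fixtures(sc, file.path(dir, "fixtures"))
  config <- list(
    network = unname(fix[["network"]]),
    expression = list(matrix = unname(fix[["matrix"]]),
                      genes = unname(fix[["genes"]]),
                      cells = unname(fix[["cells"]]),
                      labels = unname(fix[["labels"]])),
    medium = unname(fix[["medium"]]),
    min_cells = 1, require_shared = FALSE,
    seed = seed,
    output_dir = file.path(dir, "runs"))
  run_pipeline(config)
}
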