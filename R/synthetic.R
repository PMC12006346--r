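#' Toy central-carbon metabolic network
#'
#' A ~33-reaction, hand-checkable stand-in for a genome-scale human
#' reconstruction covering the energy pathways the multi-cell analysis
#' scores: glucose uptake and glycolysis (lumped lower glycolysis), lactate
#' dehydrogenase and monocarboxylate transport, pyruvate oxidation and a
#' four-step TCA cycle, an NADH shuttle, a two-step OXPHOS (electron
#' transport producing a proton-motive proxy, ATP synthase consuming it),
#' fatty-acid oxidation from linoleate, acetate release/uptake, ketone-body
#' (3-hydroxybutyrate) synthesis/oxidation, thymidine uptake, and one
#' biomass-maintenance reaction consuming ATP plus a trace of thymidine.
#' Compartments: cytoplasm `c`, mitochondria `m`, extracellular boundary
#' `e`. GPR rules reference human gene symbols so simulated cell-type
#' programs map onto reactions.
#'
#' Stoichiometric coefficients are fixed, documented constants chosen for
#' clean hand-verifiable optima rather than literature P/O ratios: each
#' mitochondrial NADH yields 10 proton units, ATP synthase converts 4
#' proton units per ATP, so one NADH buys exactly 2.5 ATP against 0.5 O2 —
#' 5 ATP per O2 for every NADH-producing route. Full glucose oxidation
#' therefore yields 32 ATP (2 substrate-level + 12 NADH), fermentation 2.
#'
#' @param config optional list; `bound` overrides the default flux bound
#'   magnitude (1000 a.u.).
#' @return a flux-consistent `metabolic_network`.
#' @export
make_toy_network <- function(config = list()) {
  B <- config$bound %||% 1000
  rev <- c(-B, B)
  irr <- c(0, B)
  rxn <- function(stoich, bounds, gpr = "", subsystem = NA_character_) {
    list(stoich = stoich, lower = bounds[1], upper = bounds[2], gpr = gpr,
         subsystem = subsystem)
  }
  rl <- list(
    ## glycolysis
    GLCt = rxn(c("glc_D[e]" = -1, "glc_D[c]" = 1), irr, "SLC2A1",
               "glycolysis"),
    HEX1 = rxn(c("glc_D[c]" = -1, "atp[c]" = -1, "g6p[c]" = 1,
                 "adp[c]" = 1), irr, "HK1 or HK2", "glycolysis"),
    PYK = rxn(c("g6p[c]" = -1, "adp[c]" = -3, "nad[c]" = -2, "pyr[c]" = 2,
                "atp[c]" = 3, "nadh[c]" = 2), irr, "GAPDH and PKM",
              "glycolysis"),
    LDH_L = rxn(c("pyr[c]" = -1, "nadh[c]" = -1, "lac_L[c]" = 1,
                  "nad[c]" = 1), rev, "LDHA or LDHB", "glycolysis"),
    L_LACt = rxn(c("lac_L[c]" = -1, "lac_L[e]" = 1), rev,
                 "SLC16A1 or SLC16A7", "transport"),
    ## pyruvate oxidation + TCA
    PYRt_m = rxn(c("pyr[c]" = -1, "pyr[m]" = 1), irr, "MPC1", "transport"),
    PDH = rxn(c("pyr[m]" = -1, "nad[m]" = -1, "accoa[m]" = 1,
                "nadh[m]" = 1), irr, "PDHA1", "TCA"),
    CS = rxn(c("accoa[m]" = -1, "oaa[m]" = -1, "cit[m]" = 1), irr, "CS",
             "TCA"),
    ICDH = rxn(c("cit[m]" = -1, "nad[m]" = -1, "akg[m]" = 1,
                 "nadh[m]" = 1), irr, "IDH3A", "TCA"),
    AKGD = rxn(c("akg[m]" = -1, "nad[m]" = -1, "succ[m]" = 1,
                 "nadh[m]" = 1), irr, "OGDH", "TCA"),
    SUCOAA = rxn(c("succ[m]" = -1, "nad[m]" = -2, "oaa[m]" = 1,
                   "nadh[m]" = 2), irr, "SDHA and MDH2", "TCA"),
    ## NADH shuttle + OXPHOS
    NADHSH = rxn(c("nadh[c]" = -1, "nad[m]" = -1, "nad[c]" = 1,
                   "nadh[m]" = 1), irr, "GOT1 and GOT2", "OXPHOS"),
    O2t = rxn(c("o2[e]" = -1, "o2[m]" = 1), irr, "", "OXPHOS"),
    ETC = rxn(c("nadh[m]" = -1, "o2[m]" = -0.5, "nad[m]" = 1, "h[m]" = 10),
              irr, "NDUFA1 and SDHA", "OXPHOS"),
    ATPS = rxn(c("h[m]" = -4, "adp[c]" = -1, "atp[c]" = 1), irr, "ATP5F1A",
               "OXPHOS"),
    ## acetate branch
    ACOUT = rxn(c("pyr[c]" = -1, "ac[c]" = 1), irr, "ACOT12", "acetate"),
    ACS = rxn(c("ac[c]" = -1, "atp[c]" = -2, "accoa[c]" = 1,
                "adp[c]" = 2), irr, "ACSS2", "acetate"),
    ACt = rxn(c("ac[c]" = -1, "ac[e]" = 1), rev, "SLC16A3", "transport"),
    ACCOAtm = rxn(c("accoa[c]" = -1, "accoa[m]" = 1), irr, "CRAT",
                  "transport"),
    ## fatty-acid oxidation
    FATP = rxn(c("lnlc[e]" = -1, "lnlc[c]" = 1), irr, "SLC27A1",
               "transport"),
    FAO = rxn(c("lnlc[c]" = -1, "atp[c]" = -1, "nad[m]" = -2,
                "accoa[m]" = 2, "nadh[m]" = 2, "adp[c]" = 1), irr,
              "CPT1A and ACADVL", "FAO"),
    ## ketone bodies
    KETO = rxn(c("accoa[m]" = -2, "nadh[m]" = -1, "bhb[m]" = 1,
                 "nad[m]" = 1), rev, "BDH1", "ketone"),
    BHBtm = rxn(c("bhb[m]" = -1, "bhb[c]" = 1), rev, "", "transport"),
    BHBt = rxn(c("bhb[c]" = -1, "bhb[e]" = 1), rev, "SLC16A6", "transport"),
    ## biomass support
    THMDt = rxn(c("thymd[e]" = -1, "thymd[c]" = 1), irr, "SLC29A1",
                "transport"),
    biomass_maintenance = rxn(c("atp[c]" = -1, "thymd[c]" = -0.002,
                                "adp[c]" = 1), irr, "", "biomass"),
    ## environment exchanges
    `EX_glc_D[e]` = rxn(c("glc_D[e]" = -1), rev, "", "exchange"),
    `EX_lac_L[e]` = rxn(c("lac_L[e]" = -1), rev, "", "exchange"),
    `EX_ac[e]` = rxn(c("ac[e]" = -1), rev, "", "exchange"),
    `EX_bhb[e]` = rxn(c("bhb[e]" = -1), rev, "", "exchange"),
    `EX_o2[e]` = rxn(c("o2[e]" = -1), rev, "", "exchange"),
    `EX_thymd[e]` = rxn(c("thymd[e]" = -1), rev, "", "exchange"),
    `EX_lnlc[e]` = rxn(c("lnlc[e]" = -1), rev, "", "exchange")
  )
  mets <- sort(unique(unlist(lapply(rl, function(r) names(r$stoich)))))
  S <- matrix(0, length(mets), length(rl),
              dimnames = list(mets, names(rl)))
  for (j in seq_along(rl)) S[names(rl[[j]]$stoich), j] <- rl[[j]]$stoich
  metabolic_network(
    data.frame(id = mets, name = sub("\\[.*", "", mets),
               compartment = met_compartment(mets),
               stringsAsFactors = FALSE),
    data.frame(id = names(rl),
               lower = vapply(rl, `[[`, numeric(1), "lower"),
               upper = vapply(rl, `[[`, numeric(1), "upper"),
               gpr = vapply(rl, `[[`, character(1), "gpr"),
               subsystem = vapply(rl, `[[`, character(1), "subsystem"),
               stringsAsFactors = FALSE),
    S)
}

#' Cell-type expression program
#'
#' Parameters of one simulated cell-type population: per-gene mean
#' expression on the `log2(1 + count)` scale at the reference library size,
#' a negative-binomial size parameter (larger = closer to Poisson), a
#' dropout probability applied independently per gene and cell, the number
#' of cells, and the mean library size (UMI per cell).
#'
#' @param label cell-type label.
#' @param means named numeric vector, `log2(1 + expected count)` per gene.
#' @param dispersion NB size parameter (default 2).
#' @param dropout_rate probability in `[0, 1)` of zeroing an observation
#'   (default 0.3).
#' @param n_cells number of cells (default 300).
#' @param library_size mean UMI per cell used to scale per-cell depth
#'   (default 1500).
#' @return object of class `cell_type_program`.
#' @export
cell_type_program <- function(label, means, dispersion = 2,
                              dropout_rate = 0.3, n_cells = 300,
                              library_size = 1500) {
  stopifnot(n_cells >= 1, dropout_rate >= 0, dropout_rate < 1,
            dispersion > 0, !is.null(names(means)))
  structure(list(label = label, means = means, dispersion = dispersion,
                 dropout_rate = dropout_rate, n_cells = as.integer(n_cells),
                 library_size = library_size),
            class = "cell_type_program")
}

#' Simulate single-cell UMI counts from cell-type programs
#'
#' Per gene and cell, counts are negative-binomial with mean
#' `(2^m_g - 1) * f_j` — `m_g` the program mean, `f_j` a lognormal
#' per-cell depth factor with unit mean — and the program's size
#' parameter, then independently zeroed with the dropout probability.
#' Reproducible given the seed.
#'
#' @param programs list of [cell_type_program()] objects sharing one gene
#'   set.
#' @param seed integer RNG seed.
#' @param condition condition label assigned to every simulated cell.
#' @return an `expression_matrix`.
#' @export
simulate_counts <- function(programs, seed = 1, condition = "baseline") {
  genes <- names(programs[[1]]$means)
  for (p in programs) {
    if (!identical(names(p$means), genes)) {
      stop("programs must share one ordered gene set")
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  blocks <- list()
  types <- character(0)
  for (p in programs) {
    mu <- pmax(2^p$means - 1, 0)
    f <- stats::rlnorm(p$n_cells, meanlog = -0.3^2 / 2, sdlog = 0.3)
    M <- matrix(stats::rnbinom(length(genes) * p$n_cells,
                               mu = outer(mu, f), size = p$dispersion),
                nrow = length(genes))
    if (p$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(M)) < p$dropout_rate, nrow = nrow(M))
      M[drop] <- 0L
    }
    blocks[[length(blocks) + 1L]] <- M
    types <- c(types, rep(p$label, p$n_cells))
  }
  counts <- do.call(cbind, blocks)
  cells <- sprintf("cell_%05d", seq_len(ncol(counts)))
  expression_matrix(counts, genes, cells, cell_type = types,
                    condition = rep(condition, ncol(counts)))
}

## gene panel of the toy study: network genes + markers + inert genes
toy_gene_panel <- function() {
  c("SLC2A1", "HK1", "HK2", "GAPDH", "PKM", "LDHA", "LDHB", "SLC16A1",
    "SLC16A7", "MPC1", "PDHA1", "CS", "IDH3A", "OGDH", "SDHA", "MDH2",
    "GOT1", "GOT2", "NDUFA1", "ATP5F1A", "ACOT12", "ACSS2", "SLC16A3",
    "CRAT", "SLC27A1", "CPT1A", "ACADVL", "BDH1", "SLC16A6", "SLC29A1",
    "GFAP", "S100B", "AQP4", "SLC1A3", "VIM", "SOX9", "HES5", "ATF5",
    "MAP2", "MAPT", "SYT1", "TH", "NR4A2", "KCNJ6", "CALB1", "GAD1",
    "GAD2", "LMX1B", "SOX6", "RBFOX3", "ACTB", "B2M", "RPL13A", "TUBB4A",
    "EEF1A1", "HMGB2", "XBP1", "PAX2", "SOX10", "PDGFRA")
}

#' Lactate-shuttle simulation scenario
#'
#' Builds the full input bundle for an end-to-end run that should recover
#' the astrocyte-neuron lactate shuttle: the toy network, simulated counts
#' for a glycolytic astrocyte-like program (high glucose uptake,
#' glycolysis, LDHA and lactate export genes; low OXPHOS) and an oxidative
#' neuron-like program (high TCA/OXPHOS, lactate importer SLC16A7 and
#' shuttle genes; low hexokinase/pyruvate kinase), and a closed glucose
#' medium with the oxygen bound tied to glucose. Under these programs the
#' astrocyte-like type can only make ATP by fermenting glucose (exporting
#' lactate) and the neuron-like type can only make ATP by oxidizing
#' medium lactate, so the exchange report shows astrocyte lactate
#' production (negative rate) and neuron lactate uptake (positive).
#'
#' The `disrupted` variant models respiratory dysfunction with glycolytic
#' compensation: the neuron program loses its OXPHOS genes and gains the
#' glycolytic ones, shifting the neuron-type glycolytic FluxSum upward.
#'
#' @param seed integer RNG seed for the count simulation.
#' @param disrupted logical; use the respiration-deficient neuron program.
#' @param n_cells cells per type (default 300).
#' @param glucose_bound maximal glucose uptake (default 10 a.u.).
#' @param o2_glucose_ratio oxygen:glucose uptake-bound ratio (default 2).
#' @return list with `network`, `expression`, `medium`, and `expected`
#'   (qualitative signs of the lactate exchange rows).
#' @export
scenario_lactate_shuttle <- function(seed = 1, disrupted = FALSE,
                                     n_cells = 300, glucose_bound = 10,
                                     o2_glucose_ratio = 2) {
  panel <- toy_gene_panel()
  lowv <- 0.3
  base <- stats::setNames(rep(lowv, length(panel)), panel)
  hk <- c("ACTB", "B2M", "RPL13A", "EEF1A1")  # housekeeping
  astro_hi <- c("SLC2A1", "HK2", "GAPDH", "PKM", "LDHA", "SLC16A1",
                "GFAP", "S100B", "AQP4", "SLC1A3", "VIM", "SOX9", hk)
  neuron_hi <- c("SLC16A7", "LDHB", "MPC1", "PDHA1", "CS", "IDH3A", "OGDH",
                 "SDHA", "MDH2", "GOT1", "GOT2", "NDUFA1", "ATP5F1A",
                 "BDH1", "SLC27A1", "CPT1A", "ACADVL",
                 "MAP2", "MAPT", "SYT1", "RBFOX3", hk)
  if (disrupted) {
    ## respiratory-complex loss plus failing lactate import, compensated by
    ## a glycolytic program — the neuron type must ferment its own glucose
    neuron_hi <- setdiff(neuron_hi,
                         c("NDUFA1", "ATP5F1A", "SDHA", "SLC16A7", "LDHB"))
    neuron_hi <- c(neuron_hi, "SLC2A1", "HK2", "GAPDH", "PKM")
  }
  astro <- base; astro[astro_hi] <- 5
  neuron <- base; neuron[neuron_hi] <- 5
  programs <- list(
    cell_type_program("astrocyte_like", astro, n_cells = n_cells),
    cell_type_program("neuron_like", neuron, n_cells = n_cells))
  condition <- if (disrupted) "disrupted" else "baseline"
  expr <- simulate_counts(programs, seed = seed, condition = condition)
  medium <- medium_definition(c(glc_D = glucose_bound),
                              o2_glucose_ratio = o2_glucose_ratio)
  list(network = make_toy_network(),
       expression = expr,
       medium = medium,
       expected = list(astrocyte_like = -1, neuron_like = +1,
                       metabolite = "lac_L"))
}

#' Write a scenario as plain-text fixture files
#'
#' Emits the MatrixMarket counts triplet, gene/cell id files, the label
#' TSV, the network (JSON and SBML), and the medium CSV into a directory —
#' the file bundle the pipeline reads.
#'
#' @param scenario result of [scenario_lactate_shuttle()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_scenario_fixtures <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "counts.mtx"),
             genes = file.path(dir, "genes.txt"),
             cells = file.path(dir, "cells.txt"),
             labels = file.path(dir, "labels.tsv"),
             network = file.path(dir, "network.json"),
             network_sbml = file.path(dir, "network.xml"),
             medium = file.path(dir, "medium.csv"))
  expr <- scenario$expression
  Matrix::writeMM(expr$counts, paths[["matrix"]])
  writeLines(expr$gene_ids, paths[["genes"]])
  writeLines(expr$cell_ids, paths[["cells"]])
  utils::write.table(
    data.frame(cell_id = expr$cell_ids, cell_type = expr$cell_type,
               condition = expr$condition),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(scenario$network, paths[["network"]], "json")
  write_network(scenario$network, paths[["network_sbml"]], "sbml")
  med <- scenario$medium
  utils::write.table(
    data.frame(metabolite = names(med$entries),
               bound = unname(med$entries)),
    paths[["medium"]], sep = ",", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
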