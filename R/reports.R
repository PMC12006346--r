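#' FluxSum: metabolite turnover in a flux solution
#'
#' The FluxSum of a metabolite is the sum of its producing (incoming)
#' fluxes, `sum_j max(S_ij * v_j, 0)` — at steady state this equals the
#' consuming sum and estimates the metabolite's turnover.
#'
#' @param solution a `flux_solution`.
#' @param model a `multicell_model` or `metabolic_network` the solution was
#'   computed on.
#' @param metabolite metabolite id (may be a vector; values are summed per
#'   id and returned as a named vector).
#' @return non-negative numeric, one value per requested metabolite.
#' @export
flux_sum <- function(solution, model, metabolite) {
  net <- if (inherits(model, "multicell_model")) model$network else model
  i <- match(metabolite, net$mets$id)
  if (anyNA(i)) {
    stop("unknown metabolite: ",
         paste(metabolite[is.na(i)], collapse = ", "))
  }
  v <- solution$fluxes[net$rxns$id]
  S <- net$S
  out <- vapply(i, function(ii) {
    prod <- as.numeric(S[ii, ]) * v
    sum(pmax(prod, 0))
  }, numeric(1))
  stats::setNames(out, metabolite)
}

#' Pathway keys for FluxSum aggregation
#'
#' A pathway key names the metabolites whose FluxSum values are summed to
#' score a pathway's activity. `default_pathway_keys()` returns the set
#' shipped for the toy central-carbon network (base ids without cell-type
#' namespace): glycolysis (cytosolic glucose, glucose-6-phosphate,
#' pyruvate — upstream intermediates, so lactate turnover from imported
#' lactate does not masquerade as glycolytic activity), TCA (citrate,
#' alpha-ketoglutarate, succinate), OXPHOS (mitochondrial NADH,
#' proton-motive proxy, ATP), FAO (cytosolic and mitochondrial acetyl-CoA).
#' For a real reconstruction supply your own key table.
#'
#' @param path optional CSV with columns `pathway`, `metabolite` to read
#'   keys from instead.
#' @return named list: pathway name to character vector of metabolite ids.
#' @export
default_pathway_keys <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("pathway", "metabolite") %in% names(tab))) {
      stop("pathway key table needs columns 'pathway' and 'metabolite'")
    }
    return(split(tab$metabolite, tab$pathway))
  }
  list(
    glycolysis = c("glc_D[c]", "g6p[c]", "pyr[c]"),
    TCA = c("cit[m]", "akg[m]", "succ[m]"),
    OXPHOS = c("nadh[m]", "h[m]", "atp[c]"),
    FAO = c("accoa[c]", "accoa[m]")
  )
}

#' Pathway FluxSum
#'
#' Sums the FluxSum of a pathway's key metabolites, either over the whole
#' model or restricted to one cell type's namespace (metabolites and
#' reactions of that type). Key metabolites are given as base ids
#' (`"pyr[c]"`); for a cell-type scope they are resolved to
#' `"pyr[c]_<type>"`.
#'
#' @param solution a `flux_solution`.
#' @param model a `multicell_model`.
#' @param key character vector of base metabolite ids (one pathway's key).
#' @param scope `"model"` for the whole model or one of the model's cell
#'   types.
#' @return numeric scalar.
#' @export
pathway_flux_sum <- function(solution, model, key, scope = "model") {
  if (!length(key)) stop("empty pathway key")
  stopifnot(inherits(model, "multicell_model"))
  net <- model$network
  if (identical(scope, "model")) {
    ids <- unlist(lapply(model$cell_types, function(t)
      paste0(key, "_", t)), use.names = FALSE)
  } else {
    if (!scope %in% model$cell_types) stop("unknown scope: ", scope)
    ids <- paste0(key, "_", scope)
  }
  ids <- intersect(ids, net$mets$id)
  if (!length(ids)) return(0)
  sum(flux_sum(solution, model, ids))
}

#' Medium uptake/secretion report
#'
#' One row per medium species with nonzero environment-exchange flux.
#' Sign convention: positive rates are uptake into the multi-cell system,
#' negative rates are secretion into the environment.
#'
#' @param solution a `flux_solution`.
#' @param model a `multicell_model`.
#' @param tol fluxes with absolute value below `tol` are omitted.
#' @return tibble with columns `metabolite`, `scope` (`"medium"`), `rate`,
#'   `direction`.
#' @export
medium_exchange_report <- function(solution, model, tol = 1e-9) {
  net <- model$network
  ex <- which(grepl("^EX_", net$rxns$id))
  v <- solution$fluxes[net$rxns$id[ex]]
  keep <- abs(v) > tol
  ## exchange flux is positive out of the system; report uptake as positive
  rate <- -v[keep]
  tibble::tibble(
    metabolite = medium_exchange_base(net$rxns$id[ex][keep]),
    scope = "medium",
    rate = unname(rate),
    direction = ifelse(rate > 0, "uptake", "secretion"))
}

#' Inter-cellular exchange report for one metabolite
#'
#' Splits the flow of a shared-medium metabolite between the cell types:
#' per type the net transport flux toward the medium, reported with the
#' convention negative = production/release by that type, positive =
#' uptake; the final row gives the medium balance (positive = net
#' secretion into the environment). Rows sum to zero by mass balance of
#' the medium species.
#'
#' @param solution a `flux_solution`.
#' @param model a `multicell_model`.
#' @param metabolite base metabolite id of the medium species (e.g.
#'   `"lac_L"`).
#' @return tibble with columns `metabolite`, `scope` (cell type or
#'   `"medium"`), `rate`, `direction`.
#' @export
intercellular_exchange_report <- function(solution, model, metabolite) {
  net <- model$network
  med_id <- paste0(metabolite, "[u]")
  if (!med_id %in% net$mets$id) {
    stop("no medium species for metabolite: ", metabolite)
  }
  ## transports are the non-exchange reactions touching the medium species;
  ## each belongs to the cell type whose namespace its other metabolite has
  i <- match(med_id, net$mets$id)
  touching <- which(net$S[i, ] != 0 & !grepl("^EX_", net$rxns$id))
  rows <- lapply(model$cell_types, function(t) {
    suffix <- paste0("_", t)
    v <- 0
    for (j in touching) {
      others <- net$mets$id[which(net$S[, j] != 0)]
      if (any(endsWith(setdiff(others, med_id), suffix))) {
        ## net production of the medium species by this transport
        v <- v + net$S[i, j] * unname(solution$fluxes[net$rxns$id[j]])
      }
    }
    tibble::tibble(metabolite = metabolite, scope = t, rate = -v,
                   direction = if (-v < 0) "production" else "uptake")
  })
  ex_id <- paste0("EX_", med_id)
  vex <- if (ex_id %in% net$rxns$id) unname(solution$fluxes[ex_id]) else 0
  rows <- c(rows, list(tibble::tibble(
    metabolite = metabolite, scope = "medium", rate = vex,
    direction = if (vex >= 0) "secretion" else "uptake")))
  do.call(rbind, rows)
}

#' Write a report tibble as TSV
#'
#' Deterministic serialization (fixed column order, no row names, full
#' precision) so identical inputs give byte-identical files.
#'
#' @param report a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
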