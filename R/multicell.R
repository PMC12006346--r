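#' Multiplicate a generic network per cell type around a shared medium
#'
#' Every metabolite and internal reaction of the generic network is
#' duplicated once per cell type with the type label appended
#' (`"lac_L[c]"` for type `"astro"` becomes `"lac_L[c]_astro"`). Each
#' generic exchange reaction on a boundary metabolite `x[e]` is replaced by
#' one transport per cell type, `x[e]_type <-> x[u]`, plus a single shared
#' environment exchange `x[u] -> (out)` in the medium compartment `u`.
#' Transports inherit the generic exchange's bounds, so secretion and
#' uptake are both possible whenever the generic exchange was reversible.
#' GPR rules are copied unchanged.
#'
#' @param generic a `metabolic_network` with identifiable exchange
#'   reactions.
#' @param cell_types character labels, at least one; labels become id
#'   suffixes and must be unique.
#' @param boundary compartment tag(s) of the generic boundary (default
#'   `"e"`).
#' @param medium_tag compartment tag of the shared medium (default `"u"`).
#' @return a `metabolic_network` with `length(cell_types)` namespaced
#'   copies wired to one medium compartment.
#' @export
expand_model <- function(generic, cell_types, boundary = "e",
                         medium_tag = "u") {
  stopifnot(length(cell_types) >= 1)
  cell_types <- as.character(cell_types)
  if (anyDuplicated(cell_types)) stop("duplicate cell type label")
  exch <- is_exchange_reaction(generic, boundary)
  if (!any(exch)) stop("generic network has no identifiable exchange reaction")
  S <- generic$S
  mets <- generic$mets
  rxns <- generic$rxns
  ex_j <- which(exch)
  in_j <- which(!exch)
  ex_met <- vapply(ex_j, function(j) mets$id[which(S[, j] != 0)], character(1))
  med_of <- function(mid) sub("\\[[^][]+\\]", paste0("[", medium_tag, "]"), mid)
  med_ids <- med_of(ex_met)

  new_mets <- list()
  new_rxns <- list()
  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)
  met_idx <- new.env(parent = emptyenv())
  nmet <- 0L
  add_met <- function(id, name, compartment) {
    if (!is.null(met_idx[[id]])) return(met_idx[[id]])
    nmet <<- nmet + 1L
    met_idx[[id]] <- nmet
    new_mets[[nmet]] <<- data.frame(id = id, name = name,
                                    compartment = compartment,
                                    formula = NA_character_,
                                    stringsAsFactors = FALSE)
    nmet
  }
  nrx <- 0L
  add_rxn <- function(id, stoich_ids, coef, lower, upper, gpr, subsystem) {
    nrx <<- nrx + 1L
    new_rxns[[nrx]] <<- data.frame(id = id, lower = lower, upper = upper,
                                   gpr = gpr, subsystem = subsystem,
                                   stringsAsFactors = FALSE)
    trip_i <<- c(trip_i, vapply(stoich_ids, function(s) met_idx[[s]],
                                integer(1)))
    trip_j <<- c(trip_j, rep(nrx, length(coef)))
    trip_x <<- c(trip_x, coef)
    nrx
  }

  for (t in cell_types) {
    suffix <- paste0("_", t)
    ids_t <- paste0(mets$id, suffix)
    if (any(ids_t %in% mets$id) || any(ids_t %in% med_ids)) {
      stop("namespace collision for cell type ", t)
    }
    for (i in seq_len(nrow(mets))) {
      add_met(ids_t[i], paste0(mets$name[i], " (", t, ")"),
              mets$compartment[i])
    }
    for (j in in_j) {
      i <- which(S[, j] != 0)
      add_rxn(paste0(rxns$id[j], suffix), ids_t[i], S[i, j],
              rxns$lower[j], rxns$upper[j], rxns$gpr[j], rxns$subsystem[j])
    }
  }
  ## shared medium species + per-type transports + one environment exchange
  for (k in seq_along(ex_j)) {
    j <- ex_j[k]
    add_met(med_ids[k], paste0(mets$name[match(ex_met[k], mets$id)],
                               " (medium)"), medium_tag)
  }
  for (t in cell_types) {
    suffix <- paste0("_", t)
    for (k in seq_along(ex_j)) {
      j <- ex_j[k]
      tr_id <- paste0(sub("^EX_", "TR_", rxns$id[j]), suffix)
      add_rxn(tr_id, c(paste0(ex_met[k], suffix), med_ids[k]), c(-1, 1),
              rxns$lower[j], rxns$upper[j], rxns$gpr[j], rxns$subsystem[j])
    }
  }
  for (k in seq_along(ex_j)) {
    j <- ex_j[k]
    add_rxn(paste0("EX_", med_ids[k]), med_ids[k], -1,
            rxns$lower[j], rxns$upper[j], "", rxns$subsystem[j])
  }

  mets_df <- do.call(rbind, new_mets)
  rxns_df <- do.call(rbind, new_rxns)
  Snew <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                               dims = c(nrow(mets_df), nrow(rxns_df)))
  metabolic_network(mets_df, rxns_df, Snew, genes = generic$genes)
}

## stable content hash of a network (via its canonical JSON serialization)
network_hash <- function(network) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_network_json(network, tmp)
  unname(tools::md5sum(tmp))
}

#' Build a condition-specific multi-cell population model
#'
#' The model-building step: the generic reconstruction is reduced to its
#' flux-consistent part, multiplicated per retained cell type around a
#' shared medium compartment ([expand_model()]), and completed with the
#' FASTCORE extraction ([extract_core_subnetwork()]) around the union of
#' the per-type namespaced core reactions. The biomass-maintenance reaction
#' of each cell type and every medium environment exchange are always part
#' of the core, so each type can sustain maintenance flux and medium
#' components stay reachable; core reactions that cannot carry flux in the
#' assembled model are dropped with a warning (a missing biomass reaction
#' is an error naming the cell type).
#'
#' @param generic a `metabolic_network`.
#' @param coresets list of `core_set` objects (see [build_core_sets()]),
#'   all belonging to one condition.
#' @param epsilon flux-activation threshold, see [fastcore].
#' @param biomass_id id of the biomass-maintenance reaction in `generic`;
#'   by default the single reaction whose id contains "biomass".
#' @param medium optional `medium_definition`; when given, only the
#'   environment exchanges of actual medium components (entries, special
#'   bounds, oxygen) are forced into the core — other medium species keep
#'   their exchanges only if the extraction needs them. Without a medium
#'   every environment exchange joins the core.
#' @return a `multicell_model`: list with `network` (the extracted
#'   `metabolic_network`), `cell_types`, `weights` (cluster cell counts),
#'   `biomass_reaction` (per-type reaction id), `condition`, `provenance`.
#' @export
build_multicell_model <- function(generic, coresets, epsilon = 1e-4,
                                  biomass_id = NULL, medium = NULL) {
  conds <- unique(vapply(coresets, function(x) x$condition, character(1)))
  if (length(conds) != 1) {
    stop("core sets span several conditions: ", paste(conds, collapse = ", "))
  }
  types <- vapply(coresets, function(x) x$cell_type, character(1))
  if (anyDuplicated(types)) stop("duplicate cell type among core sets")
  weights <- stats::setNames(as.integer(vapply(coresets, function(x)
    as.numeric(x$n_cells), numeric(1))), types)
  if (is.null(biomass_id)) {
    cand <- grep("biomass", generic$rxns$id, ignore.case = TRUE, value = TRUE)
    if (length(cand) != 1) {
      stop("cannot identify a unique biomass reaction; pass biomass_id")
    }
    biomass_id <- cand
  }
  gen_hash <- network_hash(generic)

  cons <- find_consistent_subnetwork(generic, epsilon)
  if (!(biomass_id %in% cons$consistent_reactions)) {
    stop("biomass reaction ", biomass_id,
         " is not flux-consistent in the generic network")
  }
  generic_c <- subnetwork(generic, cons$consistent_reactions)

  expanded <- expand_model(generic_c, types)
  biomass_map <- stats::setNames(paste0(biomass_id, "_", types), types)
  core <- character(0)
  for (cs in coresets) {
    keep <- intersect(cs$core_reactions, generic_c$rxns$id)
    core <- c(core, paste0(keep, "_", cs$cell_type))
  }
  core <- intersect(core, expanded$rxns$id)   # exchanges became transports
  med_ex <- expanded$rxns$id[grepl("^EX_", expanded$rxns$id)]
  if (!is.null(medium)) {
    comps <- unique(c(names(medium$entries), names(medium$special_bounds),
                      medium$oxygen_id))
    med_ex <- med_ex[medium_exchange_base(med_ex) %in% comps]
  }
  core <- unique(c(core, unname(biomass_map), med_ex))

  cons2 <- find_consistent_subnetwork(expanded, epsilon)
  lost_bio <- setdiff(biomass_map, cons2$consistent_reactions)
  if (length(lost_bio)) {
    stop("biomass-maintenance reaction cannot be activated for cell type: ",
         paste(names(biomass_map)[biomass_map %in% lost_bio],
               collapse = ", "))
  }
  lost <- setdiff(core, cons2$consistent_reactions)
  if (length(lost)) {
    warning(length(lost),
            " core reaction(s) are not activatable in the assembled model ",
            "and were dropped")
    core <- setdiff(core, lost)
  }
  cons_net <- subnetwork(expanded, cons2$consistent_reactions)
  kept <- extract_core_subnetwork(cons_net, core, epsilon)
  ## medium plumbing: every medium species reachable in the extracted model
  ## keeps its environment exchange, so secretion routes always exist
  all_ex <- intersect(expanded$rxns$id[grepl("^EX_", expanded$rxns$id)],
                      cons_net$rxns$id)
  for (exr in setdiff(all_ex, kept)) {
    i <- which(cons_net$S[, match(exr, cons_net$rxns$id)] != 0)
    touching <- which(cons_net$S[i, ] != 0 &
                        !grepl("^EX_", cons_net$rxns$id))
    if (any(cons_net$rxns$id[touching] %in% kept)) kept <- c(kept, exr)
  }
  kept <- sort(kept)
  final <- subnetwork(cons_net, kept)

  structure(list(network = final,
                 cell_types = types,
                 weights = weights,
                 biomass_reaction = biomass_map,
                 condition = conds,
                 provenance = list(generic_hash = gen_hash,
                                   epsilon = epsilon,
                                   built = format(Sys.time(), tz = "UTC"))),
            class = "multicell_model")
}

#' @export
print.multicell_model <- function(x, ...) {
  cat(sprintf("multicell_model (%s): %d cell types, %d reactions, %d metabolites\n",
              x$condition, length(x$cell_types), nrow(x$network$rxns),
              nrow(x$network$mets)))
  w <- paste(sprintf("%s=%d", names(x$weights), x$weights), collapse = ", ")
  cat("weights:", w, "\n")
  invisible(x)
}

#' Jaccard similarity of two models' reaction sets
#'
#' `|A intersect B| / |A union B|` over reaction ids: 0 for disjoint models,
#' 1 for identical reaction content. Models must derive from the same
#' generic reconstruction and cell-type label set for their namespaced ids
#' to be comparable.
#'
#' @param a,b `multicell_model` objects (or plain character vectors of
#'   reaction ids).
#' @return numeric in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  ra <- if (inherits(a, "multicell_model")) a$network$rxns$id else a
  rb <- if (inherits(b, "multicell_model")) b$network$rxns$id else b
  if (inherits(a, "multicell_model") && inherits(b, "multicell_model")) {
    if (!setequal(a$cell_types, b$cell_types)) {
      stop("models have different cell-type namespaces and are not comparable")
    }
  }
  u <- length(union(ra, rb))
  if (u == 0) return(1)
  length(intersect(ra, rb)) / u
}

#' Per-cell-type sub-model sizes
#'
#' Counts the reactions (internal plus medium transports) and metabolites in
#' each cell type's namespace of a multi-cell model.
#'
#' @param model a `multicell_model`.
#' @return tibble with columns `cell_type`, `n_reactions`, `n_metabolites`.
#' @export
submodel_sizes <- function(model) {
  net <- model$network
  out <- lapply(model$cell_types, function(t) {
    suffix <- paste0("_", t)
    nr <- sum(endsWith(net$rxns$id, suffix))
    nm <- sum(endsWith(net$mets$id, suffix))
    tibble::tibble(cell_type = t, n_reactions = nr, n_metabolites = nm)
  })
  do.call(rbind, out)
}

#' Reactions belonging to one cell type's namespace
#' @param model a `multicell_model`.
#' @param cell_type one of `model$cell_types`.
#' @return character vector of reaction ids (internal + transports).
#' @export
submodel_reactions <- function(model, cell_type) {
  if (!cell_type %in% model$cell_types) {
    stop("unknown cell type: ", cell_type)
  }
  ids <- model$network$rxns$id
  ids[endsWith(ids, paste0("_", cell_type))]
}
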