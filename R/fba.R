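#' Flux balance analysis over a metabolic network
#'
#' Maximizes (or minimizes) the flux of one reaction, or a named linear
#' combination of reactions, subject to steady state `S v = 0` and the
#' network's flux bounds.
#'
#' @param network a `metabolic_network`.
#' @param objective reaction id, or named numeric vector of objective
#'   coefficients over reaction ids.
#' @param maximize direction (default maximize).
#' @param extra_lower,extra_upper optional named bound overrides applied on
#'   top of the network bounds.
#' @return list with `objective`, `fluxes` (named), `status`.
#' @export
optimize_flux <- function(network, objective, maximize = TRUE,
                          extra_lower = NULL, extra_upper = NULL) {
  n <- nrow(network$rxns)
  rid <- network$rxns$id
  obj <- numeric(n)
  if (is.character(objective)) {
    j <- match(objective, rid)
    if (anyNA(j)) stop("unknown objective reaction: ",
                       paste(objective[is.na(j)], collapse = ", "))
    obj[j] <- 1
  } else {
    j <- match(names(objective), rid)
    if (anyNA(j)) stop("unknown objective reaction: ",
                       paste(names(objective)[is.na(j)], collapse = ", "))
    obj[j] <- objective
  }
  lb <- network$rxns$lower
  ub <- network$rxns$upper
  if (!is.null(extra_lower)) {
    j <- match(names(extra_lower), rid)
    if (anyNA(j)) stop("bound override for unknown reaction")
    lb[j] <- extra_lower
  }
  if (!is.null(extra_upper)) {
    j <- match(names(extra_upper), rid)
    if (anyNA(j)) stop("bound override for unknown reaction")
    ub[j] <- extra_upper
  }
  res <- lp_solve(obj, as.matrix(network$S), rep(0, nrow(network$S)),
                  NULL, lb, ub, maximize = maximize)
  list(objective = res$objective,
       fluxes = stats::setNames(res$x, rid),
       status = res$status)
}

#' Medium definition
#'
#' Maps medium components to maximal uptake bounds: concentrations are
#' identified numerically with bounds in arbitrary units (no volumetric
#' rescaling). Oxygen is not listed directly; its uptake bound is always
#' `o2_glucose_ratio` times the glucose uptake bound (default 2, the
#' culture-medium convention; 5 corresponds to the physiological brain
#' oxygen:glucose ratio). `special_bounds` holds components whose uptake is
#' pinned to a fixed value to permit biomass production (default: thymidine
#' and linoleate at 1).
#'
#' @param entries named numeric vector (metabolite base id, without
#'   compartment suffix, to maximal uptake bound) or a data.frame with
#'   columns `metabolite`, `bound`.
#' @param o2_glucose_ratio positive scalar (default 2).
#' @param special_bounds named numeric vector of pinned uptake bounds.
#' @param glucose_id,oxygen_id base metabolite ids used to locate the
#'   glucose and oxygen exchanges.
#' @return object of class `medium_definition`.
#' @export
medium_definition <- function(entries, o2_glucose_ratio = 2,
                              special_bounds = c(thymd = 1, lnlc = 1),
                              glucose_id = "glc_D", oxygen_id = "o2") {
  if (is.data.frame(entries)) {
    entries <- stats::setNames(as.numeric(entries$bound), entries$metabolite)
  }
  stopifnot(o2_glucose_ratio > 0, all(entries >= 0),
            is.null(special_bounds) || all(special_bounds >= 0))
  if (!glucose_id %in% names(entries)) {
    stop("medium must list the glucose component '", glucose_id, "'")
  }
  structure(list(entries = entries,
                 o2_glucose_ratio = o2_glucose_ratio,
                 special_bounds = special_bounds,
                 glucose_id = glucose_id, oxygen_id = oxygen_id),
            class = "medium_definition")
}

#' Read a medium definition from a CSV/TSV table
#'
#' Expects columns `metabolite` and `bound` (maximal uptake, a.u.).
#'
#' @param path file path; delimiter inferred from the extension.
#' @param ... passed to [medium_definition()].
#' @return a `medium_definition`.
#' @export
read_medium <- function(path, ...) {
  if (!file.exists(path)) stop("medium file does not exist: ", path)
  tab <- if (grepl("\\.tsv$", path)) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("metabolite", "bound") %in% names(tab))) {
    stop("medium table needs columns 'metabolite' and 'bound': ", path)
  }
  medium_definition(tab, ...)
}

## "EX_glc_D[u]" -> "glc_D"
medium_exchange_base <- function(ids) {
  sub("\\[[^][]+\\]$", "", sub("^EX_", "", ids))
}

#' Constrain a multi-cell model with a medium definition
#'
#' Closed-medium convention: every environment exchange of a listed medium
#' component gets its maximal uptake bound from the medium table; every
#' unlisted medium species gets uptake bound 0 (secretion stays
#' unrestricted). The oxygen uptake bound is then set to
#' `o2_glucose_ratio` times the glucose uptake bound, overriding any listed
#' value, and the `special_bounds` components are pinned last.
#'
#' @param model a `multicell_model`.
#' @param medium a `medium_definition`.
#' @return the constrained `multicell_model` (medium recorded in
#'   `model$medium`).
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "multicell_model"),
            inherits(medium, "medium_definition"))
  net <- model$network
  ex <- which(grepl("^EX_", net$rxns$id))
  base <- medium_exchange_base(net$rxns$id[ex])
  glc <- ex[base == medium$glucose_id]
  o2 <- ex[base == medium$oxygen_id]
  if (!length(glc)) stop("glucose exchange missing from model: EX_",
                         medium$glucose_id, "[u]")
  if (!length(o2)) stop("oxygen exchange missing from model: EX_",
                        medium$oxygen_id, "[u]")
  ## uptake = negative exchange flux, so the uptake bound acts on `lower`
  for (k in seq_along(ex)) {
    b <- medium$entries[base[k]]
    net$rxns$lower[ex[k]] <- if (!is.na(b)) -b else 0
  }
  glc_bound <- unname(medium$entries[medium$glucose_id])
  net$rxns$lower[o2] <- -medium$o2_glucose_ratio * glc_bound
  for (nm in names(medium$special_bounds)) {
    j <- ex[base == nm]
    if (length(j)) net$rxns$lower[j] <- -medium$special_bounds[[nm]]
  }
  model$network <- net
  model$medium <- medium
  model
}

#' Weighted biomass-maintenance FBA with per-type floors
#'
#' Two-stage scheme. Stage 1 maximizes each cell type's biomass-maintenance
#' flux alone (no floors), recording the per-type maximum. Stage 2 imposes
#' a floor of `floor_fraction` (default 10%) of each type's solo maximum
#' and maximizes the sum of biomass fluxes weighted by the cluster cell
#' counts. The floors guarantee every cell type a minimal maintenance share
#' of the medium; the weights let large clusters draw proportionally more.
#'
#' @param model a medium-constrained `multicell_model`.
#' @param floor_fraction fraction of the solo maximum each type must keep
#'   (default 0.1).
#' @return list with `objective_value` (stage-2 optimum),
#'   `per_type_max_biomass`, `floors`, `fluxes` (stage-2 solution),
#'   `weights`.
#' @export
maximize_weighted_biomass <- function(model, floor_fraction = 0.1) {
  stopifnot(inherits(model, "multicell_model"))
  net <- model$network
  bio <- model$biomass_reaction
  miss <- setdiff(bio, net$rxns$id)
  if (length(miss)) stop("biomass reaction missing from model: ",
                         paste(miss, collapse = ", "))
  per_max <- stats::setNames(numeric(length(bio)), names(bio))
  for (t in names(bio)) {
    r <- optimize_flux(net, bio[[t]], maximize = TRUE)
    if (r$status != "optimal") {
      stop("biomass maximization failed for cell type ", t,
           " (status ", r$status, ")")
    }
    per_max[t] <- r$objective
  }
  floors <- floor_fraction * per_max
  obj <- stats::setNames(as.numeric(model$weights[names(bio)]), bio)
  r2 <- optimize_flux(net, obj, maximize = TRUE,
                      extra_lower = stats::setNames(floors, bio))
  if (r2$status != "optimal") {
    stop("weighted biomass FBA infeasible under the 10% maintenance floors; ",
         "a medium component cannot support all cell types jointly ",
         "(floors: ", paste(sprintf("%s=%.4g", names(floors), floors),
                            collapse = ", "), ")")
  }
  list(objective_value = r2$objective,
       per_type_max_biomass = per_max,
       floors = floors,
       fluxes = r2$fluxes,
       weights = model$weights)
}

#' Minimal-cardinality flux distribution at a fixed objective
#'
#' Among flux vectors attaining the weighted-biomass objective (within a
#' relative tolerance) and respecting the per-type maintenance floors,
#' selects one minimizing the number of reactions carrying flux (the zero
#' norm). Models up to `exact_threshold` reactions are solved exactly by a
#' mixed-integer program; larger models use iteratively reweighted 1-norm
#' minimization (a standard zero-norm surrogate) with a fixed reweighting
#' schedule, which is deterministic and in practice lands within one
#' reaction of the exact support on small models.
#'
#' @param model a medium-constrained `multicell_model`.
#' @param weighted result of [maximize_weighted_biomass()] on the same
#'   model (supplies the fixed objective and the floors).
#' @param exact_threshold largest model size (reactions) for the exact MILP
#'   route (default 25).
#' @param objective_tol relative tolerance when fixing the objective
#'   (default 1e-6).
#' @param method `"auto"`, `"exact"` or `"heuristic"`.
#' @return a `flux_solution`: list with `fluxes`, `objective_value`,
#'   `per_type_max_biomass`, `support_size`, `solver_metadata`.
#' @export
minimal_cardinality_flux <- function(model, weighted,
                                     exact_threshold = 25,
                                     objective_tol = 1e-6,
                                     method = c("auto", "exact",
                                                "heuristic")) {
  method <- match.arg(method)
  net <- model$network
  n <- nrow(net$rxns)
  rid <- net$rxns$id
  S <- as.matrix(net$S)
  m <- nrow(S)
  lb <- net$rxns$lower
  ub <- net$rxns$upper
  bio <- model$biomass_reaction
  jb <- match(bio, rid)
  lb[jb] <- pmax(lb[jb], weighted$floors[names(bio)])
  wrow <- numeric(n)
  wrow[jb] <- as.numeric(model$weights[names(bio)])
  target <- weighted$objective_value * (1 - objective_tol) -
    1e-9 * max(1, abs(weighted$objective_value))
  if (method == "auto") method <- if (n <= exact_threshold) "exact"
    else "heuristic"

  supp_tol <- 1e-6
  if (method == "exact") {
    ## v plus binary indicators y; |v_i| > 0 forces y_i = 1
    A <- rbind(cbind(S, matrix(0, m, n)),
               cbind(diag(n), diag(-pmax(ub, 0) - (ub == 0))),
               cbind(diag(n), diag(-pmin(lb, 0) + (lb == 0))),
               c(wrow, rep(0, n)))
    ## rows 2: v_i - ub_i * y_i <= 0 ; rows 3: v_i - lb_i * y_i >= 0
    sense <- c(rep("=", m), rep("<=", n), rep(">=", n), ">=")
    rhs <- c(rep(0, m + 2 * n), target)
    res <- milp_solve(obj = c(rep(0, n), rep(1, n)),
                      A = A, rhs = rhs, sense = sense,
                      lower = c(lb, rep(0, n)), upper = c(ub, rep(1, n)),
                      binary = n + seq_len(n), maximize = FALSE)
    if (res$status != "optimal") {
      stop("cardinality MILP failed: status ", res$status)
    }
    v <- res$x[seq_len(n)]
  } else {
    ## iteratively reweighted 1-norm with fixed schedule
    w <- rep(1, n)
    reg <- 1e-3
    v <- NULL
    for (it in 1:5) {
      A <- rbind(cbind(S, matrix(0, m, n)),
                 cbind(diag(n), diag(n)),      # v + z >= 0
                 cbind(-diag(n), diag(n)),     # z - v >= 0
                 c(wrow, rep(0, n)))
      big <- max(abs(c(lb, ub)))
      res <- lp_solve(obj = c(rep(0, n), w), A = A,
                      rhs = c(rep(0, m + 2 * n), target),
                      sense = c(rep("=", m), rep(">=", 2 * n), ">="),
                      lower = c(lb, rep(0, n)),
                      upper = c(ub, rep(big, n)),
                      maximize = FALSE)
      if (res$status != "optimal") {
        stop("cardinality heuristic LP failed: status ", res$status)
      }
      v <- res$x[seq_len(n)]
      w <- 1 / (abs(v) + reg)
    }
  }
  ## polish: pin the zero set and re-maximize the objective on the chosen
  ## support, so the reported solution attains the stage-2 optimum exactly
  zero <- abs(v) <= supp_tol
  lb2 <- lb; ub2 <- ub
  lb2[zero] <- 0; ub2[zero] <- 0
  res <- lp_solve(obj = wrow, A = rbind(S, wrow),
                  rhs = c(rep(0, m), target),
                  sense = c(rep("=", m), ">="),
                  lower = lb2, upper = ub2, maximize = TRUE)
  if (res$status == "optimal") v <- res$x
  v[abs(v) <= supp_tol] <- 0
  fluxes <- stats::setNames(v, rid)
  structure(list(fluxes = fluxes,
                 objective_value = sum(wrow * v),
                 per_type_max_biomass = weighted$per_type_max_biomass,
                 floors = weighted$floors,
                 support_size = sum(abs(v) > supp_tol),
                 solver_metadata = list(method = method,
                                        objective_tol = objective_tol,
                                        support_tol = supp_tol,
                                        target = target)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: objective %.6g, support %d/%d reactions (%s)\n",
              x$objective_value, x$support_size, length(x$fluxes),
              x$solver_metadata$method))
  invisible(x)
}

#' Minimal substrate uptake sustaining a fixed objective
#'
#' Minimizes the uptake flux of one medium exchange subject to the weighted
#' biomass objective staying at (or above) `fixed_objective` and all other
#' constraints, answering questions like "how much oxygen does the model
#' need at its optimum".
#'
#' @param model a medium-constrained `multicell_model`.
#' @param substrate_exchange_id environment exchange reaction id (e.g.
#'   `"EX_o2[u]"`).
#' @param weighted result of [maximize_weighted_biomass()] (fixes the
#'   objective and floors).
#' @param objective_tol relative tolerance on the fixed objective.
#' @return list with `min_uptake` (a.u.) and `ratio_to_glucose_bound`
#'   (relative to the glucose uptake bound when a medium is attached,
#'   otherwise `NA`).
#' @export
minimal_substrate_requirement <- function(model, substrate_exchange_id,
                                          weighted, objective_tol = 1e-6) {
  net <- model$network
  rid <- net$rxns$id
  j <- match(substrate_exchange_id, rid)
  if (is.na(j)) stop("unknown exchange reaction: ", substrate_exchange_id)
  bio <- model$biomass_reaction
  jb <- match(bio, rid)
  wrow <- numeric(length(rid))
  wrow[jb] <- as.numeric(model$weights[names(bio)])
  target <- weighted$objective_value * (1 - objective_tol) -
    1e-9 * max(1, abs(weighted$objective_value))
  lbv <- stats::setNames(pmax(net$rxns$lower[jb],
                              weighted$floors[names(bio)]), bio)
  S <- as.matrix(net$S)
  obj <- numeric(length(rid)); obj[j] <- 1
  lb <- net$rxns$lower; ub <- net$rxns$upper
  lb[jb] <- lbv
  ## maximize the exchange flux = minimize uptake (uptake is negative flux)
  res <- lp_solve(obj, rbind(S, wrow), c(rep(0, nrow(S)), target),
                  c(rep("=", nrow(S)), ">="), lb, ub, maximize = TRUE)
  if (res$status != "optimal") {
    stop("substrate minimization failed: status ", res$status)
  }
  up <- max(0, -res$objective)
  ratio <- NA_real_
  if (!is.null(model$medium)) {
    glc_bound <- unname(model$medium$entries[model$medium$glucose_id])
    if (is.finite(glc_bound) && glc_bound > 0) ratio <- up / glc_bound
  }
  list(min_uptake = up, ratio_to_glucose_bound = ratio)
}
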