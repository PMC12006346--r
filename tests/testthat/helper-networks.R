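# Builders and independent oracles shared across the suite.

# Build a metabolic_network from a list of named stoichiometry vectors.
mk_net <- function(rxns_list, lower = NULL, upper = NULL, gpr = NULL,
                   compartment = NULL) {
  mets <- sort(unique(unlist(lapply(rxns_list, names))))
  S <- matrix(0, length(mets), length(rxns_list),
              dimnames = list(mets, names(rxns_list)))
  for (j in seq_along(rxns_list)) S[names(rxns_list[[j]]), j] <- rxns_list[[j]]
  n <- length(rxns_list)
  if (is.null(lower)) lower <- rep(0, n)
  if (is.null(upper)) upper <- rep(10, n)
  if (is.null(gpr)) gpr <- rep("", n)
  comp <- if (is.null(compartment)) {
    cmp <- multicellfba:::met_compartment(mets)
    ifelse(nzchar(cmp), cmp, "c")
  } else compartment
  metabolic_network(
    data.frame(id = mets, compartment = comp, stringsAsFactors = FALSE),
    data.frame(id = names(rxns_list), lower = lower, upper = upper,
               gpr = gpr, stringsAsFactors = FALSE),
    S)
}

# Linear chain R1 -> ... -> Rn through n-1 metabolites (source/sink at ends).
mk_chain <- function(n = 4, lower = NULL, upper = NULL) {
  rl <- list()
  rl[["R1"]] <- c(M1 = 1)
  if (n > 2) for (j in 2:(n - 1)) {
    rl[[paste0("R", j)]] <- stats::setNames(c(-1, 1),
                                            paste0("M", c(j - 1, j)))
  }
  rl[[paste0("R", n)]] <- stats::setNames(-1, paste0("M", n - 1))
  mk_net(rl, lower = lower, upper = upper)
}

# Diamond: src -> M; two 2-reaction routes M -> N; N -> sink.
mk_diamond <- function() {
  mk_net(list(src = c(M = 1),
              a1 = c(M = -1, X = 1), a2 = c(X = -1, N = 1),
              b1 = c(M = -1, Y = 1), b2 = c(Y = -1, N = 1),
              snk = c(N = -1)))
}

# Random small network with some exchanges and reversible reactions.
mk_random_net <- function(n_mets = 4, n_rxns = 8, p_rev = 0.4) {
  mets <- paste0("m", seq_len(n_mets))
  rl <- list()
  for (j in seq_len(n_rxns)) {
    k <- sample(1:2, 1)
    picks <- sample(mets, min(k + 1, n_mets))
    st <- c(1, -1, sample(c(-1, 1), max(0, length(picks) - 2),
                          replace = TRUE))
    rl[[paste0("r", j)]] <- stats::setNames(st[seq_along(picks)], picks)
  }
  for (e in sample(mets, sample(seq_len(n_mets), 1))) {
    rl[[paste0("EX_", e)]] <- stats::setNames(1, e)
  }
  n <- length(rl)
  rev <- stats::runif(n) < p_rev
  mk_net(rl, lower = ifelse(rev, -10, 0), upper = rep(10, n))
}

# Brute-force consistency oracle: a reaction is consistent iff its flux can
# reach +eps or -eps in two dedicated LPs.
oracle_consistent <- function(network, epsilon = 1e-4) {
  ids <- network$rxns$id
  keep <- vapply(ids, function(r) {
    mx <- optimize_flux(network, r, maximize = TRUE)
    mn <- optimize_flux(network, r, maximize = FALSE)
    (mx$status == "optimal" && mx$objective >= epsilon * 0.99) ||
      (mn$status == "optimal" && mn$objective <= -epsilon * 0.99)
  }, logical(1))
  sort(ids[keep])
}

# Exhaustive minimal consistent supersets of a core (tiny networks only):
# enumerate all reaction subsets containing the core whose induced
# subnetwork is fully flux-consistent, and return the minimum cardinality.
oracle_min_superset_size <- function(network, core, epsilon = 1e-4) {
  ids <- network$rxns$id
  rest <- setdiff(ids, core)
  best <- Inf
  for (sz in 0:length(rest)) {
    if (length(core) + sz >= best) break
    combs <- utils::combn(rest, sz, simplify = FALSE)
    for (add in combs) {
      sel <- c(core, add)
      sub <- subnetwork(network, sel)
      cons <- oracle_consistent(sub, epsilon)
      if (length(cons) == length(sel)) {
        best <- min(best, length(sel))
        break
      }
    }
  }
  best
}

# A minimal flux_solution object for report-only tests.
mk_solution <- function(fluxes) {
  structure(list(fluxes = fluxes,
                 objective_value = NA_real_,
                 support_size = sum(abs(fluxes) > 1e-6),
                 solver_metadata = list(method = "fixed")),
            class = "flux_solution")
}

# One full scenario run (shared by several test files).
run_scenario <- function(seed = 1, disrupted = FALSE, method = "auto") {
  sc <- scenario_lactate_shuttle(seed = seed, disrupted = disrupted)
  strata <- filter_cell_types(sc$expression, min_cells = 1,
                              require_shared = FALSE)
  cs <- build_core_sets(sc$expression, sc$network, strata)
  mc <- build_multicell_model(sc$network, cs, medium = sc$medium)
  mc <- apply_medium(mc, sc$medium)
  wb <- maximize_weighted_biomass(mc)
  sol <- minimal_cardinality_flux(mc, wb, method = method)
  list(scenario = sc, coresets = cs, model = mc, weighted = wb,
       solution = sol)
}

# Steady-state / bounds checks on a solution.
expect_valid_solution <- function(sol, model, tol = 1e-6) {
  net <- model$network
  v <- sol$fluxes[net$rxns$id]
  resid <- as.numeric(net$S %*% v)
  expect_lt(max(abs(resid)), tol)
  expect_true(all(v >= net$rxns$lower - tol))
  expect_true(all(v <= net$rxns$upper + tol))
}
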