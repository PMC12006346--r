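test_that("flux_sum sums producing fluxes only", {
  # chain A -> B -> C carrying flux v, plus a second producer of C
  net <- mk_net(list(r1 = c(A = 1), r2 = c(A = -1, B = 1),
                     r3 = c(B = -1, C = 1), r4 = c(D = 1),
                     r5 = c(D = -1, C = 1), r6 = c(C = -1)))
  sol <- mk_solution(c(r1 = 3, r2 = 3, r3 = 3, r4 = 4, r5 = 4, r6 = 7))
  expect_equal(unname(flux_sum(sol, net, "B")), 3)   # single producer
  expect_equal(unname(flux_sum(sol, net, "C")), 7)   # 3 + 4 producers
  # steady state: producing equals consuming for internal metabolites
  consuming <- sum(pmax(-as.numeric(net$S["C", ]) * sol$fluxes, 0))
  expect_equal(unname(flux_sum(sol, net, "C")), consuming)
  expect_error(flux_sum(sol, net, "Z"), "unknown metabolite")
})

test_that("pathway flux sums respect scope and partition over cell types", {
  out <- run_scenario(seed = 2, method = "heuristic")
  keys <- default_pathway_keys()
  for (key in keys) {
    whole <- pathway_flux_sum(out$solution, out$model, key, "model")
    parts <- vapply(out$model$cell_types, function(t)
      pathway_flux_sum(out$solution, out$model, key, t), numeric(1))
    expect_equal(whole, sum(parts), tolerance = 1e-9)
  }
  # singleton key equals the plain flux_sum of that metabolite
  one <- pathway_flux_sum(out$solution, out$model, "pyr[c]",
                          "astrocyte_like")
  expect_equal(one, unname(flux_sum(out$solution, out$model,
                                    "pyr[c]_astrocyte_like")))
  # a purely glycolytic type shows no fatty-acid oxidation turnover
  expect_equal(pathway_flux_sum(out$solution, out$model, keys$FAO,
                                "astrocyte_like"), 0)
  expect_error(pathway_flux_sum(out$solution, out$model, character()),
               "empty pathway key")
})

test_that("medium report uses uptake-positive convention and drops zeros", {
  out <- run_scenario(seed = 2, method = "heuristic")
  rep <- medium_exchange_report(out$solution, out$model)
  expect_equal(rep$rate[rep$metabolite == "glc_D"], 10)
  expect_equal(rep$direction[rep$metabolite == "glc_D"], "uptake")
  lac <- rep$rate[rep$metabolite == "lac_L"]
  expect_lt(lac, 0)                     # secretion is negative
  # zero-flux species are omitted
  v <- out$solution$fluxes
  zero_ex <- names(v)[grepl("^EX_", names(v)) & abs(v) <= 1e-9]
  expect_false(any(multicellfba:::medium_exchange_base(zero_ex) %in%
                     rep$metabolite))
})

test_that("intercellular rows follow the figure sign convention and balance", {
  # constructed toy: astro releases 8, neuron takes 5, medium accumulates 3
  gen <- mk_net(list(LACt = c("lac[c]" = -1, "lac[e]" = 1),
                     SRC = c("lac[c]" = 1), SNK = c("lac[c]" = -1),
                     `EX_lac[e]` = c("lac[e]" = -1)),
                lower = c(-10, 0, 0, -10))
  ex <- expand_model(gen, c("astro", "neuron"))
  model <- structure(list(network = ex,
                          cell_types = c("astro", "neuron"),
                          weights = c(astro = 1L, neuron = 1L),
                          biomass_reaction = c(astro = "none"),
                          condition = "toy"),
                     class = "multicell_model")
  v <- stats::setNames(rep(0, nrow(ex$rxns)), ex$rxns$id)
  v[c("SRC_astro", "LACt_astro", "TR_lac[e]_astro")] <- 8
  v[c("TR_lac[e]_neuron", "LACt_neuron")] <- -5
  v["SNK_neuron"] <- 5
  v["EX_lac[u]"] <- 3
  expect_equal(max(abs(as.numeric(ex$S %*% v))), 0)  # steady by design
  sol <- mk_solution(v)
  rep <- intercellular_exchange_report(sol, model, "lac")
  expect_equal(rep$rate[rep$scope == "astro"], -8)
  expect_equal(rep$rate[rep$scope == "neuron"], 5)
  expect_equal(rep$rate[rep$scope == "medium"], 3)
  expect_equal(sum(rep$rate), 0)
  expect_equal(rep$direction, c("production", "uptake", "secretion"))
  # untouched metabolite gives all-zero rows
  sol0 <- mk_solution(stats::setNames(rep(0, nrow(ex$rxns)), ex$rxns$id))
  rep0 <- intercellular_exchange_report(sol0, model, "lac")
  expect_equal(rep0$rate, c(0, 0, 0))
  expect_error(intercellular_exchange_report(sol, model, "pyruvate"),
               "no medium species")
})

test_that("exchange balance holds for every medium species of a real run", {
  out <- run_scenario(seed = 4, method = "heuristic")
  species <- multicellfba:::medium_exchange_base(
    grep("^EX_", out$model$network$rxns$id, value = TRUE))
  for (s in species) {
    rep <- intercellular_exchange_report(out$solution, out$model, s)
    expect_lt(abs(sum(rep$rate)), 1e-6)
  }
})

test_that("report serialization is byte-stable", {
  out <- run_scenario(seed = 2, method = "heuristic")
  rep <- medium_exchange_report(out$solution, out$model)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_report(rep, f1)
  write_report(medium_exchange_report(out$solution, out$model), f2)
  expect_identical(readLines(f1), readLines(f2))
})
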