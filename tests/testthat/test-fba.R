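# Shared-glucose generic for medium/FBA tests: biomass converts one glucose
# into one unit of maintenance, so solo maxima equal the glucose bound.
mk_fba_generic <- function() {
  mk_net(
    list(GLCt = c("glc_D[e]" = -1, "glc_D[c]" = 1),
         O2t = c("o2[e]" = -1, "o2[c]" = 1),
         OXSINK = c("o2[c]" = -1),
         biomass = c("glc_D[c]" = -1),
         `EX_glc_D[e]` = c("glc_D[e]" = -1),
         `EX_o2[e]` = c("o2[e]" = -1)),
    lower = c(0, 0, 0, 0, -1000, -1000),
    upper = rep(1000, 6),
    gpr = c("GLUT", "", "", "", "", ""))
}

build_two_type <- function(weights = c(9, 1)) {
  gen <- mk_fba_generic()
  cs <- list(
    structure(list(condition = "WT", cell_type = "big",
                   core_genes = "GLUT", core_reactions = "GLCt",
                   n_cells = weights[1], thresholds = list()),
              class = "core_set"),
    structure(list(condition = "WT", cell_type = "small",
                   core_genes = "GLUT", core_reactions = "GLCt",
                   n_cells = weights[2], thresholds = list()),
              class = "core_set"))
  build_multicell_model(gen, cs)
}

test_that("medium bounds follow the closed-medium and oxygen-ratio rules", {
  mc <- build_two_type()
  med <- medium_definition(c(glc_D = 10), o2_glucose_ratio = 2,
                           special_bounds = NULL)
  m2 <- apply_medium(mc, med)
  rx <- m2$network$rxns
  expect_equal(rx$lower[rx$id == "EX_glc_D[u]"], -10)
  expect_equal(rx$lower[rx$id == "EX_o2[u]"], -20)
  med5 <- medium_definition(c(glc_D = 10), o2_glucose_ratio = 5,
                            special_bounds = NULL)
  m5 <- apply_medium(mc, med5)
  expect_equal(m5$network$rxns$lower[rx$id == "EX_o2[u]"], -50)
  # oxygen ratio overrides a listed oxygen value
  medo <- medium_definition(c(glc_D = 10, o2 = 1), o2_glucose_ratio = 2,
                            special_bounds = NULL)
  mo <- apply_medium(mc, medo)
  expect_equal(mo$network$rxns$lower[rx$id == "EX_o2[u]"], -20)
  # secretion of unlisted species stays open while uptake closes
  expect_true(all(m2$network$rxns$upper[grepl("^EX_", rx$id)] > 0))
  expect_error(medium_definition(c(fruct = 10)), "glucose")
})

test_that("weighted FBA reduces to plain FBA for a single type", {
  gen <- mk_fba_generic()
  cs <- list(structure(list(condition = "WT", cell_type = "only",
                            core_genes = "GLUT", core_reactions = "GLCt",
                            n_cells = 1L, thresholds = list()),
                       class = "core_set"))
  mc <- build_multicell_model(gen, cs)
  mc <- apply_medium(mc, medium_definition(c(glc_D = 7),
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  expect_equal(wb$objective_value, 7, tolerance = 1e-9)
  expect_equal(unname(wb$per_type_max_biomass["only"]), 7)
})

test_that("floors guarantee 10% to each type and weights take the rest", {
  # two identical types share 10 glucose; hand LP: maximize 9*b1 + 1*b2
  # with b1 + b2 <= 10 and floors b_i >= 1 gives b = (9, 1)
  mc <- build_two_type(c(9, 1))
  mc <- apply_medium(mc, medium_definition(c(glc_D = 10),
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  expect_equal(unname(wb$per_type_max_biomass), c(10, 10))
  expect_equal(unname(wb$floors), c(1, 1))
  expect_equal(wb$objective_value, 9 * 9 + 1 * 1, tolerance = 1e-8)
  b <- wb$fluxes[mc$biomass_reaction]
  expect_equal(unname(b), c(9, 1), tolerance = 1e-8)
})

test_that("a zero-weight type still gets its 10% maintenance floor", {
  mc <- build_two_type(c(1, 1))
  mc$weights <- stats::setNames(c(1L, 0L), names(mc$weights))
  mc <- apply_medium(mc, medium_definition(c(glc_D = 10),
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  b <- stats::setNames(wb$fluxes[mc$biomass_reaction],
                       names(mc$biomass_reaction))
  expect_gte(unname(b["small"]), 0.1 * wb$per_type_max_biomass[["small"]] -
               1e-8)
})

test_that("stage-2 optimum lies between the floor and relaxation bounds", {
  out <- run_scenario(seed = 3, method = "heuristic")
  w <- as.numeric(out$model$weights)
  mx <- as.numeric(out$weighted$per_type_max_biomass)
  expect_lte(out$weighted$objective_value, sum(w * mx) + 1e-6)
  expect_gte(out$weighted$objective_value, sum(w * 0.1 * mx) - 1e-6)
})

test_that("cardinality minimization keeps one diamond route active", {
  # two equivalent 2-reaction routes between glucose and biomass
  gen <- mk_net(
    list(GLCt = c("glc_D[e]" = -1, "glc_D[c]" = 1),
         r1a = c("glc_D[c]" = -1, "x[c]" = 1),
         r1b = c("x[c]" = -1, "p[c]" = 1),
         r2a = c("glc_D[c]" = -1, "y[c]" = 1),
         r2b = c("y[c]" = -1, "p[c]" = 1),
         biomass = c("p[c]" = -1),
         O2t = c("o2[e]" = -1, "o2[c]" = 1),
         OXSINK = c("o2[c]" = -1),
         `EX_glc_D[e]` = c("glc_D[e]" = -1),
         `EX_o2[e]` = c("o2[e]" = -1)),
    lower = c(rep(0, 8), -1000, -1000), upper = rep(1000, 10),
    gpr = c("GLUT", "RA", "RA", "RB", "RB", "", "", "", "", ""))
  core_genes <- c("GLUT", "RA", "RB")   # both routes stay in the model
  cs <- list(structure(list(condition = "WT", cell_type = "t",
                            core_genes = core_genes,
                            core_reactions =
                              map_core_reactions(gen, core_genes),
                            n_cells = 1L, thresholds = list()),
                       class = "core_set"))
  mc <- build_multicell_model(gen, cs)
  mc <- apply_medium(mc, medium_definition(c(glc_D = 5),
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  for (method in c("exact", "heuristic")) {
    sol <- minimal_cardinality_flux(mc, wb, method = method)
    v <- sol$fluxes
    route1 <- abs(v[["r1a_t"]]) > 1e-6
    route2 <- abs(v[["r2a_t"]]) > 1e-6
    expect_true(xor(route1, route2))
    expect_equal(sol$objective_value, wb$objective_value,
                 tolerance = 1e-6)
    expect_valid_solution(sol, mc)
  }
})

test_that("a bounded futile cycle detached from the objective carries no flux", {
  gen <- mk_net(
    list(GLCt = c("glc_D[e]" = -1, "glc_D[c]" = 1),
         biomass = c("glc_D[c]" = -1),
         cyc1 = c("a[c]" = -1, "b[c]" = 1),
         cyc2 = c("b[c]" = -1, "a[c]" = 1),
         O2t = c("o2[e]" = -1, "o2[c]" = 1),
         OXSINK = c("o2[c]" = -1),
         `EX_glc_D[e]` = c("glc_D[e]" = -1),
         `EX_o2[e]` = c("o2[e]" = -1)),
    lower = c(0, 0, -50, -50, 0, 0, -1000, -1000),
    upper = c(1000, 1000, 50, 50, 1000, 1000, 1000, 1000),
    gpr = c("GLUT", "", "CYC", "CYC", "", "", "", ""))
  cs <- list(structure(list(condition = "WT", cell_type = "t",
                            core_genes = c("GLUT", "CYC"),
                            core_reactions =
                              map_core_reactions(gen, c("GLUT", "CYC")),
                            n_cells = 1L, thresholds = list()),
                       class = "core_set"))
  mc <- build_multicell_model(gen, cs)
  mc <- apply_medium(mc, medium_definition(c(glc_D = 5),
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  sol <- minimal_cardinality_flux(mc, wb, method = "exact")
  expect_equal(unname(abs(sol$fluxes[c("cyc1_t", "cyc2_t")])), c(0, 0))
})

test_that("minimal substrate requirement matches stoichiometric hand counts", {
  # biomass requires 3 O2 per glucose; glucose bound 10 fully used -> 30
  gen <- mk_net(
    list(GLCt = c("glc_D[e]" = -1, "glc_D[c]" = 1),
         O2t = c("o2[e]" = -1, "o2[c]" = 1),
         biomass = c("glc_D[c]" = -1, "o2[c]" = -3),
         `EX_glc_D[e]` = c("glc_D[e]" = -1),
         `EX_o2[e]` = c("o2[e]" = -1)),
    lower = c(0, 0, 0, -1000, -1000), upper = rep(1000, 5),
    gpr = c("GLUT", "", "", "", ""))
  cs <- list(structure(list(condition = "WT", cell_type = "t",
                            core_genes = "GLUT", core_reactions = "GLCt",
                            n_cells = 1L, thresholds = list()),
                       class = "core_set"))
  mc <- build_multicell_model(gen, cs)
  mc <- apply_medium(mc, medium_definition(c(glc_D = 10),
                                           o2_glucose_ratio = 4,
                                           special_bounds = NULL))
  wb <- maximize_weighted_biomass(mc)
  expect_equal(wb$objective_value, 10, tolerance = 1e-8)
  ms <- minimal_substrate_requirement(mc, "EX_o2[u]", wb)
  expect_equal(ms$min_uptake, 30, tolerance = 1e-5)
  expect_equal(ms$ratio_to_glucose_bound, 3, tolerance = 1e-5)
  # the minimum never exceeds the bound actually granted
  expect_lte(ms$min_uptake, 40 + 1e-9)
  # a fermentative objective needs no oxygen at all
  mcf <- build_two_type(c(1, 1))
  mcf <- apply_medium(mcf, medium_definition(c(glc_D = 10),
                                             special_bounds = NULL))
  wbf <- maximize_weighted_biomass(mcf)
  msf <- minimal_substrate_requirement(mcf, "EX_o2[u]", wbf)
  expect_equal(msf$min_uptake, 0)
})

test_that("raising the oxygen ratio never lowers the weighted optimum", {
  gen <- mk_fba_generic()
  cs <- list(structure(list(condition = "WT", cell_type = "t",
                            core_genes = "GLUT", core_reactions = "GLCt",
                            n_cells = 1L, thresholds = list()),
                       class = "core_set"))
  mc0 <- build_multicell_model(gen, cs)
  prev <- -Inf
  for (ratio in c(1, 2, 5)) {
    m <- apply_medium(mc0, medium_definition(c(glc_D = 10),
                                             o2_glucose_ratio = ratio,
                                             special_bounds = NULL))
    wb <- maximize_weighted_biomass(m)
    expect_gte(wb$objective_value, prev - 1e-9)
    prev <- wb$objective_value
  }
})
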