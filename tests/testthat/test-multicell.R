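# A small generic network with cross-feeding structure: glucose can be
# fermented to lactate (glyc half) or lactate can be oxidized (oxid half).
mk_generic <- function() {
  B <- 10
  mk_net(
    list(GLCt = c("glc[e]" = -1, "glc[c]" = 1),
         GLYC = c("glc[c]" = -1, "atp[c]" = 2, "lac[c]" = 2),
         LACt = c("lac[c]" = -1, "lac[e]" = 1),
         OXID = c("lac[c]" = -1, "o2[c]" = -1, "atp[c]" = 5),
         O2t = c("o2[e]" = -1, "o2[c]" = 1),
         biomass = c("atp[c]" = -1),
         `EX_glc[e]` = c("glc[e]" = -1),
         `EX_lac[e]` = c("lac[e]" = -1),
         `EX_o2[e]` = c("o2[e]" = -1)),
    lower = c(0, 0, -B, 0, 0, 0, -B, -B, -B),
    upper = rep(B, 9),
    gpr = c("GLUT", "PFK", "MCT", "OXPH", "", "", "", "", ""))
}

mk_cs <- function(cell_type, core_genes, generic, n_cells = 10,
                  condition = "WT") {
  structure(list(condition = condition, cell_type = cell_type,
                 core_genes = core_genes,
                 core_reactions = map_core_reactions(generic, core_genes),
                 n_cells = as.integer(n_cells),
                 thresholds = list()), class = "core_set")
}

test_that("expansion counts follow k*i internal + k*e transports + e exchanges", {
  gen <- mk_generic()
  e <- sum(is_exchange_reaction(gen))
  i <- nrow(gen$rxns) - e
  one <- expand_model(gen, "t1")
  expect_equal(nrow(one$rxns), i + e + e)
  expect_equal(nrow(one$mets), nrow(gen$mets) + e)
  two <- expand_model(gen, c("t1", "t2"))
  expect_equal(nrow(two$rxns), 2 * i + 2 * e + e)
  expect_equal(nrow(two$mets), 2 * nrow(gen$mets) + e)
})

test_that("expansion namespaces metabolites and shares medium species", {
  gen <- mk_generic()
  ex <- expand_model(gen, c("astro", "neuro"))
  expect_true("lac[c]_astro" %in% ex$mets$id)
  expect_true("lac[u]" %in% ex$mets$id)
  expect_equal(sum(ex$mets$id == "lac[u]"), 1)
  expect_true("EX_lac[u]" %in% ex$rxns$id)
  # GPRs are copied unchanged into each namespace
  expect_equal(ex$rxns$gpr[ex$rxns$id == "GLYC_astro"], "PFK")
  expect_error(expand_model(gen, c("a", "a")), "duplicate cell type")
})

test_that("no reaction couples two cell-type namespaces directly", {
  gen <- mk_generic()
  ex <- expand_model(gen, c("a", "b"))
  suffix_of <- function(mid) {
    if (endsWith(mid, "_a")) "a" else if (endsWith(mid, "_b")) "b" else "u"
  }
  for (j in seq_len(nrow(ex$rxns))) {
    mets <- ex$mets$id[which(ex$S[, j] != 0)]
    spaces <- setdiff(unique(vapply(mets, suffix_of, character(1))), "u")
    expect_lte(length(spaces), 1)
  }
})

test_that("a cross-feeding core yields producer and consumer wired via medium", {
  gen <- mk_generic()
  cs <- list(mk_cs("glyco", c("GLUT", "PFK", "MCT"), gen),
             mk_cs("oxid", c("MCT", "OXPH"), gen))
  mc <- build_multicell_model(gen, cs)
  ids <- mc$network$rxns$id
  expect_true(all(c("GLYC_glyco", "OXID_oxid") %in% ids))
  expect_false("OXID_glyco" %in% ids)   # oxidation only in the consumer
  expect_false("GLYC_oxid" %in% ids)    # glycolysis only in the producer
  # lactate transports in both types, one shared medium exchange set
  expect_true(all(c("TR_lac[e]_glyco", "TR_lac[e]_oxid") %in% ids))
  # the assembled model is flux-consistent as-is
  expect_length(find_consistent_subnetwork(mc$network)$removed_reactions, 0)
})

test_that("a type with empty core keeps only biomass support", {
  gen <- mk_generic()
  cs <- list(mk_cs("glyco", c("GLUT", "PFK", "MCT"), gen),
             mk_cs("idle", character(), gen))
  mc <- build_multicell_model(gen, cs)
  idle <- submodel_reactions(mc, "idle")
  # biomass forced in; its minimal support is ATP generation from lactate
  # or glucose, not the whole namespace
  expect_true("biomass_idle" %in% idle)
  expect_lt(length(idle), length(submodel_reactions(mc, "glyco")) + 4)
})

test_that("core sets spanning conditions are rejected", {
  gen <- mk_generic()
  cs <- list(mk_cs("a", "GLUT", gen, condition = "WT"),
             mk_cs("b", "GLUT", gen, condition = "PD"))
  expect_error(build_multicell_model(gen, cs), "several conditions")
})

test_that("jaccard similarity follows set arithmetic", {
  a <- paste0("r", 1:6)
  b <- paste0("r", 4:9)
  expect_equal(jaccard_similarity(a, b), 3 / 9)
  expect_equal(jaccard_similarity(a, a), 1)
  expect_equal(jaccard_similarity(a, paste0("q", 1:3)), 0)
  expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
  gen <- mk_generic()
  cs1 <- list(mk_cs("a", c("GLUT", "PFK", "MCT"), gen))
  cs2 <- list(mk_cs("b", c("GLUT", "PFK", "MCT"), gen))
  m1 <- build_multicell_model(gen, cs1)
  m2 <- build_multicell_model(gen, cs2)
  expect_error(jaccard_similarity(m1, m2), "not comparable")
})

test_that("submodel sizes partition the model", {
  gen <- mk_generic()
  cs <- list(mk_cs("glyco", c("GLUT", "PFK", "MCT"), gen),
             mk_cs("oxid", c("MCT", "OXPH"), gen))
  mc <- build_multicell_model(gen, cs)
  sz <- submodel_sizes(mc)
  n_medium_ex <- sum(grepl("^EX_", mc$network$rxns$id))
  expect_equal(sum(sz$n_reactions) + n_medium_ex, nrow(mc$network$rxns))
  n_medium_species <- sum(mc$network$mets$compartment == "u")
  expect_equal(sum(sz$n_metabolites) + n_medium_species,
               nrow(mc$network$mets))
})
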