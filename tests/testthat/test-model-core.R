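# Metabolic-model container, GPR evaluation, reversibility splitting and
# metabolite/gene neighborhoods.

test_that("model validation enforces the container invariants", {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"), compartment = "c")
  rxns <- data.frame(id = "R1", name = "r", lb = 0, ub = 10, reversible = FALSE,
                     gpr = "", subsystem = "s")
  expect_error(
    metabolic_model(mets, rxns, list(R1 = c(Z_c = -1))), "undeclared")
  expect_error(
    metabolic_model(rbind(mets, mets[1, ]), rxns, list(R1 = c(A_c = -1))),
    "duplicate")
  expect_error(
    metabolic_model(data.frame(id = "A_x", name = "A", compartment = "x"),
                    rxns, list(R1 = c(A_x = -1))), "compartment")
  bad <- rxns; bad$lb <- 5; bad$ub <- 1
  expect_error(metabolic_model(mets, bad, list(R1 = c(A_c = -1))), "lb > ub")
})

test_that("GPR evaluation follows the and/or rules and missing-gene policy", {
  vals <- c(g1 = 5, g2 = 7, g3 = 4)
  expect_equal(evaluate_gpr("g1 or g2", vals), 7)
  expect_equal(evaluate_gpr("g1 and g2", vals), 5)
  expect_equal(evaluate_gpr("(g1 and g2) or g3", c(g1 = 2, g2 = 8, g3 = 4)), 4)
  # missing gene contributes no evidence rather than zero
  expect_equal(evaluate_gpr("g1 and gX", vals), 5)
  expect_true(is.na(evaluate_gpr("gX and gY", vals)))
  expect_true(is.na(evaluate_gpr("", vals)))
  # configurable rules
  expect_equal(evaluate_gpr("g1 and g2", vals, and_rule = function(x) mean(x)), 6)
  expect_error(evaluate_gpr("g1 and (g2", vals), "malformed")
})

test_that("GPR evaluation is invariant to operand order", {
  set.seed(1)
  for (i in 1:20) {
    genes <- paste0("g", 1:4)
    vals <- stats::setNames(runif(4, 0, 10), genes)
    perm <- sample(genes)
    e1 <- evaluate_gpr(sprintf("(%s and %s) or (%s and %s)",
                               genes[1], genes[2], genes[3], genes[4]), vals)
    e2 <- evaluate_gpr(sprintf("(%s and %s) or (%s and %s)",
                               genes[2], genes[1], genes[4], genes[3]), vals)
    expect_equal(e1, e2)
  }
})

test_that("split_reversible mirrors stoichiometry and maps fluxes back", {
  m <- build_toy_sphingolipid_model()
  sp <- split_reversible(m)
  n_rev <- sum(m$rxns$lb < 0)
  expect_equal(nrow(sp$rxns), nrow(m$rxns) + n_rev)
  expect_true(all(sp$rxns$lb >= 0))
  # S * (merged fluxes) == S_split * v_split for random flux vectors
  S <- as.matrix(model_S(m)); Ssp <- as.matrix(model_S(sp))
  set.seed(7)
  for (i in 1:5) {
    v_split <- stats::setNames(runif(nrow(sp$rxns), 0, 3), sp$rxns$id)
    v <- merge_split_fluxes(v_split, sp)
    expect_equal(as.vector(S %*% v[colnames(S)]),
                 as.vector(Ssp %*% v_split[colnames(Ssp)]), tolerance = 1e-12)
  }
  # splitting an already irreversible model is the identity
  sp2 <- split_reversible(sp)
  expect_identical(sp2$rxns$id, sp$rxns$id)
  expect_identical(sp2$stoich, sp$stoich)
})

test_that("metabolite neighborhoods collect GPR genes and obey the currency list", {
  m <- build_toy_sphingolipid_model()
  # glucosylceramide in the cytosol: synthesized by GCS; transports carry no GPR
  expect_equal(metabolite_gene_neighborhood(m, "glcCer_c"), "g_GCS")
  # ceramide in the ER touches DES (production) and GalCS + transport
  expect_setequal(metabolite_gene_neighborhood(m, "cer_r"),
                  c("g_DES", "g_GALCS"))
  # currency exclusion: sugars act as donors in the toy model
  expect_identical(metabolite_gene_neighborhood(m, "glc_c"), character(0))
  expect_identical(
    metabolite_gene_neighborhood(m, "glc_c", currency = character(0)), "g_GCS")
  # metabolite participating only in GPR-less reactions
  expect_identical(metabolite_gene_neighborhood(m, "ser_e"), character(0))
  expect_error(metabolite_gene_neighborhood(m, "nope"), "unknown metabolite")
})

test_that("boundary classification and display names follow conventions", {
  m <- build_toy_sphingolipid_model()
  bd <- boundary_reactions(m)
  expect_setequal(bd$type[grepl("^EX_", bd$rxn)], "exchange")
  expect_true(all(bd$type[grepl("demand$|^DM_", bd$rxn)] == "demand"))
  expect_equal(met_display(c("glcCer_c", "cer_g", "foo")),
               c("glcCer[c]", "cer[g]", "foo"))
})
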