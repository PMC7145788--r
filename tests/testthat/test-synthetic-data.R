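# Toy network and cohort simulators: structure, determinism, planted truth.

test_that("toy sphingolipid model has the required structure", {
  m <- build_toy_sphingolipid_model()
  expect_true(nrow(m$rxns) >= 35 && nrow(m$rxns) <= 60)
  expect_setequal(unique(m$mets$compartment), c("c", "g", "r", "l", "e"))
  enzymes <- c("SPT", "KSR", "CERS", "DES", "SMS", "SMASE", "GCS", "GCDASE",
               "GALCS", "GALCDASE", "LACCERS", "CDASE", "SK", "S1PL", "CK",
               "C1PP")
  expect_true(all(enzymes %in% m$rxns$id))
  # each enzyme step carries a distinct single-gene GPR
  gprs <- m$rxns$gpr[match(enzymes, m$rxns$id)]
  expect_true(all(nzchar(gprs)))
  expect_equal(anyDuplicated(gprs), 0)
  expect_true(all(lengths(lapply(gprs, gpr_genes)) == 1))
  # uptakes and demands
  expect_true(all(c("EX_ser", "EX_palm", "EX_glc", "EX_gal", "EX_cho")
                  %in% m$rxns$id))
  expect_true(all(c("DM_sm", "glcCer_demand", "DM_lacCer", "DM_galCer",
                    "digalCer_demand", "DM_s1pdeg") %in% m$rxns$id))
})

test_that("toy model is flux-consistent and loses glucosylceramide without glucose", {
  m <- build_toy_sphingolipid_model()
  expect_gt(fba(m, "glcCer_demand", parsimonious = FALSE)$objval, 0)
  fc <- flux_consistency(m)
  expect_length(fc$blocked, 0)
  m2 <- build_toy_sphingolipid_model(drop_reactions = c("EX_glc", "T_glc"))
  expect_equal(fba(m2, "glcCer_demand", parsimonious = FALSE)$objval, 0)
  # an infeasible topology is refused when consistency checking is on
  expect_error(build_toy_sphingolipid_model(drop_reactions = c("EX_glc", "T_glc"),
                                            check_consistency = TRUE),
               "not flux-consistent")
})

test_that("internal metabolites are balanced or drained", {
  m <- build_toy_sphingolipid_model()
  S <- as.matrix(model_S(m))
  bd <- boundary_reactions(m)
  for (i in seq_len(nrow(S))) {
    met <- rownames(S)[i]
    ok <- (any(S[i, ] > 0) && any(S[i, ] < 0)) || met %in% bd$met
    expect_true(ok, label = paste("metabolite", met, "balanced or drained"))
  }
})

test_that("cohort design encodes group sizes and seroconversion medians", {
  d <- cohort_design(seed = 5)
  expect_equal(as.integer(table(d$subjects$group)[c("CTRL", "P1Ab", "PT1D")]),
               c(10L, 27L, 34L))
  expect_true(all(is.na(d$subjects$seroconversion_age[d$subjects$group == "CTRL"])))
  # medians across many draws approximate 24 (P1Ab) and 14 (PT1D) months
  sero <- do.call(rbind, lapply(1:30, function(s) {
    x <- cohort_design(seed = s)$subjects
    data.frame(p1ab = median(x$seroconversion_age[x$group == "P1Ab"]),
               pt1d = median(x$seroconversion_age[x$group == "PT1D"]))
  }))
  expect_equal(mean(sero$p1ab), 24, tolerance = 0.2)
  expect_equal(mean(sero$pt1d), 14, tolerance = 0.15)
  expect_error(cohort_design(group_sizes = c(CTRL = 1, P1Ab = 5, PT1D = 5)),
               "at least 2")
  expect_error(cohort_design(missingness_rate = 0.6), "missingness_rate")
})

test_that("generators are reproducible and seeds matter", {
  d <- cohort_design(seed = 3)
  a <- simulate_metabolomics(d, seed = 10)
  b <- simulate_metabolomics(d, seed = 10)
  c3 <- simulate_metabolomics(d, seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c3$values))
  m <- build_toy_sphingolipid_model()
  e1 <- simulate_expression(m, seed = 4)
  e2 <- simulate_expression(m, seed = 4)
  expect_identical(e1$values, e2$values)
})

test_that("zero missingness yields the complete subject-by-age grid", {
  d <- cohort_design(missingness_rate = 0, seed = 2)
  om <- simulate_metabolomics(d, seed = 2)
  expect_equal(nrow(om$values), nrow(d$subjects) * length(d$ages))
})

test_that("null expression gives uniform p-values; planted GCS effect is detectable", {
  m <- build_toy_sphingolipid_model()
  des <- expression_design(c(CTRL = 25, PT1D = 25), seed = 1)
  om <- simulate_expression(m, des, effects = data.frame(), seed = 21)
  oml <- log2_normalize(om)
  ctr <- two_sample_contrast(oml, "PT1D", "CTRL")
  expect_gt(stats::ks.test(ctr$p, "punif")$p.value, 0.01)
  # power: GCS doubled in PT1D, n = 25/group, log2 sd 0.5 -> FDR < 0.05 hit
  hits <- vapply(1:50, function(s) {
    om <- simulate_expression(m, des,
                              effects = data.frame(gene = "g_GCS",
                                                   group = "PT1D",
                                                   log2_effect = 1),
                              noise_sd = 0.5, seed = s)
    ctr <- two_sample_contrast(log2_normalize(om), "PT1D", "CTRL")
    ctr$fdr[ctr$feature == "g_GCS"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted ceramide decrease is recovered across seeds", {
  hits <- vapply(1:50, function(s) {
    d <- cohort_design(seed = s * 17L)
    om <- simulate_metabolomics(d, seed = s * 17L + 1L)
    ctr <- two_sample_contrast(log2_normalize(om), "PT1D", "CTRL", age_bin = 36)
    ctr$log2FC[ctr$feature == "Cer(d18:1/24:0)"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the planted registry travels with the data", {
  d <- cohort_design(seed = 1)
  om <- simulate_metabolomics(d, seed = 1)
  eff <- attr(om, "effects")
  expect_true(all(c("feature", "group", "age", "log2_effect") %in% names(eff)))
  expect_true("Cer(d18:1/24:0)" %in% eff$feature)
  expect_true(all(eff$feature %in% om$feature_meta$feature))
})

test_that("random toy networks are reproducible and well-formed", {
  n1 <- random_toy_network(8, seed = 3)
  n2 <- random_toy_network(8, seed = 3)
  expect_identical(n1$stoich, n2$stoich)
  expect_false(identical(random_toy_network(8, seed = 4)$stoich, n1$stoich))
  expect_equal(nrow(n1$rxns), 8)
  expect_true(all(n1$rxns$lb == 0))
})
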