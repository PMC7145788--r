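# Flux balance analysis, parsimonious fluxes and subsystem summaries.

test_that("FBA finds the bottleneck optimum on a chain and zero on a closed model", {
  m <- chain_model(src_ub = 10)
  st <- fba(m, "SINK")
  expect_equal(st$status, "optimal")
  expect_equal(st$objval, 10)
  expect_lte(mass_balance_residual(m, st), 1e-9)
  # closing the source zeroes every objective
  closed <- m
  closed$rxns$ub[closed$rxns$id == "SRC"] <- 0
  expect_equal(fba(closed, "SINK")$objval, 0)
})

test_that("toy-model glucosylceramide optimum equals the hand-derived capacity", {
  m <- build_toy_sphingolipid_model(uptake = 10)
  # each ceramide consumes two palmitates (SPT + CerS); palmitate uptake 10
  # caps de novo ceramide at 5, which also caps cytosolic glucosylceramide
  st <- fba(m, "glcCer_demand")
  expect_equal(st$objval, 5)
  expect_lte(mass_balance_residual(m, st), 1e-9)
  # raising palmitate availability moves the bottleneck to the next substrate
  m2 <- m
  m2$rxns$lb[m2$rxns$id == "EX_palm"] <- -20
  expect_equal(fba(m2, "glcCer_demand")$objval, 10)
})

test_that("FBA optimum is invariant to reaction order and reversibility splitting", {
  m <- build_toy_sphingolipid_model()
  ref <- fba(m, "glcCer_demand", parsimonious = FALSE)$objval
  # permuted columns
  set.seed(1)
  perm <- sample(nrow(m$rxns))
  mp <- metabolic_model(m$mets, m$rxns[perm, ], m$stoich[m$rxns$id[perm]],
                        id = m$id)
  expect_equal(fba(mp, "glcCer_demand", parsimonious = FALSE)$objval, ref)
  # split model
  sp <- split_reversible(m)
  expect_equal(fba(sp, "glcCer_demand", parsimonious = FALSE)$objval, ref)
})

test_that("parsimonious FBA yields a deterministic, loop-free optimal vertex", {
  m <- build_toy_sphingolipid_model()
  s1 <- fba(m, "glcCer_demand", parsimonious = TRUE)
  s2 <- fba(m, "glcCer_demand", parsimonious = TRUE)
  expect_identical(s1$flux, s2$flux)
  expect_equal(s1$objval, fba(m, "glcCer_demand", parsimonious = FALSE)$objval)
  # the kinase/phosphatase futile cycles carry no parsimonious flux
  expect_equal(unname(s1$flux["SK"] + s1$flux["S1PPASE"]), 0, tolerance = 1e-9)
  expect_lte(mass_balance_residual(m, s1), 1e-9)
})

test_that("infeasible and unbounded statuses are reported, not solved", {
  m <- chain_model()
  m$rxns$lb[m$rxns$id == "SINK"] <- 50  # demands more than the source allows
  expect_equal(fba(m, "SINK")$status, "infeasible")
  expect_error(fba(chain_model(), "nope"), "not in model")
})

test_that("subsystem deltas are zero on identical fluxes and track scaling", {
  m <- build_toy_sphingolipid_model()
  st <- fba(m, "glcCer_demand")
  d0 <- subsystem_flux_deltas(st, st, m)
  expect_true(all(d0$delta == 0))
  st2 <- st
  st2$flux <- 2 * st$flux
  d2 <- subsystem_flux_deltas(st, st2, m)
  active <- d2$flux_A > 0
  expect_equal(d2$rel_change[active], rep(1, sum(active)))
})

test_that("switching the glucosylceramide objective on raises transport fluxes", {
  m <- build_toy_sphingolipid_model()
  # objective off: the parsimonious optimum at zero demand is the quiescent state
  off <- fba(m, "glcCer_demand", sense = "min")
  expect_equal(unname(max(abs(off$flux))), 0, tolerance = 1e-9)
  on <- fba(m, "glcCer_demand")
  deltas <- subsystem_flux_deltas(off, on, m)
  tr <- deltas[grepl("^Transport", deltas$subsystem), ]
  expect_gt(sum(tr$delta), 0)
})

test_that("glycoceramide optimization tabulates pruned objectives as zero", {
  m <- build_toy_sphingolipid_model()
  # a context model without the glyco branch
  ctrl <- subset_model(m, setdiff(m$rxns$id,
                                  c("GCS", "DGALCS", "glcCer_demand",
                                    "digalCer_demand", "T_glcCer_c_g",
                                    "T_glcCer_c_l", "LACCERS", "DM_lacCer",
                                    "GCDASE")))
  res <- optimize_glycoceramide_production(list(CTRL = ctrl, PT1D = m),
                                           template = m)
  expect_equal(res$optimum[res$group == "CTRL" &
                             res$objective == "glcCer_demand"], 0)
  expect_true(res$pruned[res$group == "CTRL" &
                           res$objective == "glcCer_demand"])
  pt <- res$optimum[res$group == "PT1D" & res$objective == "glcCer_demand"]
  expect_gt(pt, 0)
  # identical models give ratio 1
  res2 <- optimize_glycoceramide_production(list(CTRL = m, PT1D = m),
                                            template = m)
  expect_equal(res2$ratio_vs_reference[res2$group == "PT1D"], c(1, 1))
})
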