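# Reaction scoring, metabolite evidence, exchange constraints and the INIT
# extraction.

toy_expression <- function(model, gene_log2, groups = "CTRL") {
  # one group, deterministic expression at the given per-gene log2 levels
  vals <- matrix(2^gene_log2, nrow = 2, ncol = length(gene_log2), byrow = TRUE,
                 dimnames = list(NULL, names(gene_log2)))
  meta <- data.frame(sample_id = c("s1", "s2"), subject = c("s1", "s2"),
                     group = groups, sex = "F", age_months = NA_real_,
                     seroconversion_age = NA_real_)
  omics_matrix(vals, meta)
}

test_that("reaction weights follow log2(e/tau) with clipping", {
  m <- chain_model()
  # genes: gAB on reaction AB; tau is the median of gene group means
  ex <- toy_expression(m, c(gAB = 3, gZZ1 = 2, gZZ2 = 4))
  # tau = median(2^3, 2^2, 2^4) = 8 -> e(AB) = 8 -> w = 0
  sc <- score_reactions(m, ex, "CTRL")
  expect_equal(sc$weight[sc$reaction == "AB"], 0, tolerance = 1e-12)
  # no-GPR reactions have no evidence and weight 0
  expect_true(all(is.na(sc$expression_level[sc$reaction %in% c("SRC", "SINK")])))
  expect_true(all(sc$weight[sc$reaction %in% c("SRC", "SINK")] == 0))
  # e = 4 tau -> w = 2
  sc2 <- score_reactions(m, ex, "CTRL", tau = 2^1)
  expect_equal(sc2$weight[sc2$reaction == "AB"], 2, tolerance = 1e-12)
  # extreme ratios clip at w_max
  sc3 <- score_reactions(m, ex, "CTRL", tau = 2^30, w_max = 5)
  expect_equal(sc3$weight[sc3$reaction == "AB"], -5)
})

test_that("metabolite evidence maps detected features, flags ambiguity", {
  m <- build_toy_sphingolipid_model()
  ev <- expect_warning(
    metabolite_evidence_from_metabolomics(m, c("HexCer(d18:1/16:0)")),
    "ambiguous")
  expect_true(all(ev$present[ev$metabolite %in% c("glcCer_c", "galCer_r")]))
  expect_false(any(ev$present[!ev$metabolite %in% c("glcCer_c", "galCer_r")]))
  # empty detected set -> nothing present
  ev2 <- metabolite_evidence_from_metabolomics(m, character(0))
  expect_false(any(ev2$present))
  # unmapped features are reported
  expect_message(
    ev3 <- metabolite_evidence_from_metabolomics(m, c("mystery_feature")),
    "not mappable")
  expect_identical(attr(ev3, "unmapped"), "mystery_feature")
})

test_that("exchange bounds open only evidenced or medium uptakes, idempotently", {
  m <- build_toy_sphingolipid_model()
  ev <- data.frame(metabolite = c("glc_c"), present = TRUE)
  con <- exchange_bounds_from_metabolomics(m, ev, default_uptake = 10,
                                           media = c("ser", "palm"))
  lb <- stats::setNames(con$rxns$lb, con$rxns$id)
  expect_equal(unname(lb[c("EX_glc", "EX_ser", "EX_palm")]), rep(-10, 3))
  expect_equal(unname(lb[c("EX_gal", "EX_cho")]), c(0, 0))
  # secretion stays open
  expect_true(all(con$rxns$ub[grepl("^EX_", con$rxns$id)] > 0))
  con2 <- exchange_bounds_from_metabolomics(con, ev, default_uptake = 10,
                                            media = c("ser", "palm"))
  expect_identical(con$rxns, con2$rxns)
})

test_that("init_extract keeps everything when all weights are positive", {
  m <- split_reversible(build_toy_sphingolipid_model())
  sc <- data.frame(reaction = m$rxns$id, weight = 1)
  cm <- init_extract(m, sc)
  expect_setequal(cm$included, m$rxns$id)
})

test_that("a negative bridge outweighing its ends empties the chain", {
  # uptake(+1) -> conversion(-3) -> sink(+1): connectivity forces the bridge,
  # 1 - 3 + 1 < 0, so the optimum is the empty network
  m <- chain_model()
  w <- c(SRC = 1, AB = -3, SINK = 1)
  sc <- data.frame(reaction = names(w), weight = unname(w))
  cm <- init_extract(m, sc)
  expect_length(cm$included, 0)
  expect_equal(cm$objective, 0)
  # oracle agrees over all 2^3 subsets
  oracle <- enum_init_optimum(m, w[m$rxns$id])
  expect_equal(cm$objective, oracle$objective)
  # with a milder bridge (-1.5) the chain survives
  w2 <- c(SRC = 1, AB = -1.5, SINK = 1)
  cm2 <- init_extract(m, data.frame(reaction = names(w2), weight = unname(w2)))
  expect_setequal(cm2$included, m$rxns$id)
  expect_equal(cm2$objective,
               enum_init_optimum(m, w2[m$rxns$id])$objective)
})

test_that("init_extract matches exhaustive enumeration on random networks", {
  for (s in 1:6) {
    net <- random_toy_network(sample(5:9, 1), seed = s)
    set.seed(s + 100)
    w <- runif(nrow(net$rxns), -5, 5)
    sc <- data.frame(reaction = net$rxns$id, weight = w)
    cm <- init_extract(net, sc)
    oracle <- enum_init_optimum(net, w)
    expect_equal(cm$objective, oracle$objective, tolerance = 1e-6)
  }
})

test_that("raising an excluded reaction's weight never drops an included one", {
  net <- random_toy_network(7, seed = 5)
  set.seed(50)
  w <- runif(nrow(net$rxns), -3, 3)
  sc <- data.frame(reaction = net$rxns$id, weight = w)
  cm <- init_extract(net, sc)
  excl <- setdiff(net$rxns$id, cm$included)
  for (r in excl[seq_len(min(3, length(excl)))]) {
    w2 <- w; w2[net$rxns$id == r] <- w2[net$rxns$id == r] + 4
    cm2 <- init_extract(net, data.frame(reaction = net$rxns$id, weight = w2))
    expect_gte(cm2$objective, cm$objective - 1e-9)
  }
})

test_that("metabolite evidence pulls a production path in despite negative weights", {
  m <- chain_model()  # SRC -> A -> B -> SINK
  sc <- data.frame(reaction = m$rxns$id, weight = c(0, -1, 0))
  # without evidence: nothing worth including
  cm0 <- init_extract(m, sc)
  expect_equal(cm0$objective, 0)
  # with evidence for B (kappa = 20): the path is forced, x_B = 1
  ev <- data.frame(metabolite = "B_c", present = TRUE)
  cm <- init_extract(m, sc, ev)
  expect_true(all(c("SRC", "AB") %in% cm$included))
  expect_equal(unname(cm$x["B_c"]), 1)
  expect_equal(cm$objective, 20 - 1, tolerance = 1e-6)
  # every included reaction carries at least eps flux (extracted model)
  st <- fba(cm$model, "SRC", parsimonious = FALSE)
  expect_equal(st$status, "optimal")
})

test_that("extraction requires a split model and errors on infeasible MILPs", {
  m <- build_toy_sphingolipid_model()
  sc <- data.frame(reaction = m$rxns$id, weight = 1)
  expect_error(init_extract(m, sc), "split")
  sp <- split_reversible(m)
  expect_error(init_extract(sp, sc[1:3, ]), "cover all reactions")
})

test_that("planted GCS up-regulation separates PT1D and CTRL context models", {
  m <- build_toy_sphingolipid_model()
  sp <- split_reversible(m)
  base <- stats::setNames(rep(3, length(m$genes)), m$genes)
  lo <- base; lo["g_GCS"] <- 1.5   # under-expressed in CTRL
  hi <- base; hi["g_GCS"] <- 4.5   # induced in PT1D
  ev_ctrl <- data.frame(metabolite = "cer_c", present = TRUE)
  ev_pt1d <- data.frame(metabolite = c("cer_c", "glcCer_c"), present = TRUE)
  sc_ctrl <- score_reactions(sp, toy_expression(m, lo), "CTRL", tau = 2^3)
  sc_pt1d <- score_reactions(sp, toy_expression(m, hi), "CTRL", tau = 2^3)
  cm_ctrl <- init_extract(sp, sc_ctrl, ev_ctrl)
  cm_pt1d <- init_extract(sp, sc_pt1d, ev_pt1d)
  expect_false("GCS" %in% cm_ctrl$included)
  expect_true("GCS" %in% cm_pt1d$included)
})
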