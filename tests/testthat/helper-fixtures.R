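# Shared fixtures: tiny analytic networks and independent oracles used to
# validate the LP/MILP layer, ORA and the INIT extraction.

# Linear chain source(<=10) -> A -> B -> sink.
chain_model <- function(src_ub = 10) {
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("SRC", "AB", "SINK"),
                     name = c("uptake", "conversion", "sink"),
                     lb = 0, ub = c(src_ub, 1000, 1000), reversible = FALSE,
                     gpr = c("", "gAB", ""), subsystem = "chain",
                     stringsAsFactors = FALSE)
  stoich <- list(SRC = c(A_c = 1), AB = c(A_c = -1, B_c = 1), SINK = c(B_c = -1))
  metabolic_model(mets, rxns, stoich, id = "chain")
}

# Independent INIT oracle: exhaustive enumeration over all reaction subsets
# with an LP feasibility check (every included reaction must carry >= eps
# flux jointly; excluded reactions are clamped to zero). No metabolite
# evidence term. Returns the optimal objective and one optimal subset.
enum_init_optimum <- function(model, weights, eps = 1e-3) {
  S <- as.matrix(model_S(model))
  n <- nrow(model$rxns)
  ub <- model$rxns$ub
  best <- 0  # empty network is always feasible with objective 0
  best_set <- integer(0)
  feasible <- function(idx) {
    inc <- seq_len(n) %in% idx
    # quick necessary condition: iteratively drop impossible supports
    repeat {
      if (!any(inc)) return(length(idx) == 0)
      Ssub <- S[, inc, drop = FALSE]
      prod_ok <- rowSums(Ssub > 0) > 0
      cons_ok <- rowSums(Ssub < 0) > 0
      # a metabolite touched with production but no consumption (or vice
      # versa) blocks all its reactions
      bad_met <- which(xor(prod_ok, cons_ok))
      if (!length(bad_met)) break
      bad_rxn <- which(inc & colSums(abs(S[bad_met, , drop = FALSE])) > 0)
      if (!length(bad_rxn)) break
      inc[bad_rxn] <- FALSE
    }
    if (!identical(which(inc), sort(idx))) return(FALSE)
    r <- solve_lp(numeric(n), S, rep("=", nrow(S)), rep(0, nrow(S)),
                  lb = ifelse(inc, eps, 0), ub = ifelse(inc, ub, 0),
                  maximize = TRUE)
    r$status == "optimal"
  }
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0)
    val <- sum(weights[idx])
    if (val <= best + 1e-12) next
    if (feasible(idx)) { best <- val; best_set <- idx }
  }
  list(objective = best, included = model$rxns$id[best_set])
}

# Hand-rolled BH step-up, independent of stats::p.adjust.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper tail: enumerate all size-n draws from a
# universe of size N containing K marked elements; fraction with >= k marks.
hyper_enum <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- draws <= K  # elements 1..K are the pathway members
  mean(colSums(marked) >= k)
}
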