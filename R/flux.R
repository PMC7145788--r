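# Flux balance analysis and flux summaries on (context) models.

#' Flux balance analysis
#'
#' Solves `max/min v_obj` subject to `S v = 0`, `lb <= v <= ub`. With
#' `parsimonious = TRUE`, a second stage fixes the optimal objective value and
#' minimizes the total absolute flux (pFBA), which makes the returned flux
#' vector reproducible in the presence of alternate optima.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @param parsimonious run the pFBA second stage (default TRUE).
#' @return a `flux_state`: list with `flux` (named vector), `objective`,
#'   `objval` and `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @export
fba <- function(model, objective, sense = c("max", "min"), parsimonious = TRUE) {
  sense <- match.arg(sense)
  if (!objective %in% model$rxns$id) stop("objective reaction not in model: ", objective)
  S <- as.matrix(model_S(model))
  n <- nrow(model$rxns)
  obj <- as.numeric(model$rxns$id == objective)
  r1 <- solve_lp(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                 lb = model$rxns$lb, ub = model$rxns$ub,
                 maximize = sense == "max")
  if (r1$status != "optimal")
    return(structure(list(flux = NULL, objective = objective,
                          objval = NA_real_, status = r1$status),
                     class = "flux_state"))
  v <- r1$x
  if (parsimonious) {
    # minimize sum(v+ + v-) with v = v+ - v-, at the fixed optimum
    A2 <- cbind(S, -S)
    A2 <- rbind(A2, c(obj, -obj))
    dirs <- c(rep("=", nrow(S)), "=")
    rhs <- c(rep(0, nrow(S)), r1$objval)
    lbp <- c(pmax(model$rxns$lb, 0), pmax(-model$rxns$ub, 0))
    ubp <- c(pmax(model$rxns$ub, 0), pmax(-model$rxns$lb, 0))
    r2 <- solve_lp(rep(1, 2 * n), A2, dirs, rhs, lb = lbp, ub = ubp,
                   maximize = FALSE)
    if (r2$status == "optimal") v <- r2$x[seq_len(n)] - r2$x[n + seq_len(n)]
  }
  structure(list(flux = stats::setNames(v, model$rxns$id), objective = objective,
                 objval = r1$objval, status = "optimal"),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> objective ", x$objective, " (", x$status, ")\n", sep = "")
  if (x$status == "optimal") {
    cat("  optimum: ", format(x$objval), "\n", sep = "")
    act <- sum(abs(x$flux) > 1e-9)
    cat("  active reactions: ", act, " of ", length(x$flux), "\n", sep = "")
  }
  invisible(x)
}

#' Mass-balance residual of a flux state
#'
#' @param model the model the fluxes refer to.
#' @param state a `flux_state`.
#' @return max-norm of `S v`.
#' @export
mass_balance_residual <- function(model, state) {
  if (state$status != "optimal") return(NA_real_)
  max(abs(as.vector(model_S(model) %*% state$flux[model$rxns$id])))
}

# Maximal achievable flux through one reaction in one direction.
fva_bound <- function(S, lb, ub, idx, maximize) {
  obj <- numeric(length(lb)); obj[idx] <- 1
  r <- solve_lp(obj, S, rep("=", nrow(S)), rep(0, nrow(S)), lb = lb, ub = ub,
                maximize = maximize)
  if (r$status != "optimal") NA_real_ else r$objval
}

#' Per-reaction flux consistency check
#'
#' A reaction is consistent if it can carry at least `eps` absolute flux in
#' some steady state (FVA-style per-reaction optimization in both directions).
#'
#' @param model a `metabolic_model`.
#' @param eps flux threshold.
#' @return list with `consistent` and `blocked` reaction id vectors and the
#'   per-reaction attainable `max_abs_flux`.
#' @export
flux_consistency <- function(model, eps = 1e-6) {
  S <- as.matrix(model_S(model))
  lb <- model$rxns$lb; ub <- model$rxns$ub
  mx <- vapply(seq_len(nrow(model$rxns)), function(i) {
    hi <- fva_bound(S, lb, ub, i, TRUE)
    if (!is.na(hi) && hi >= eps) return(hi)
    lo <- fva_bound(S, lb, ub, i, FALSE)
    max(abs(c(hi, lo)), na.rm = TRUE)
  }, numeric(1))
  names(mx) <- model$rxns$id
  list(consistent = model$rxns$id[mx >= eps],
       blocked = model$rxns$id[mx < eps],
       max_abs_flux = mx)
}

#' Optimize glycoceramide production across context models
#'
#' For each group's context model, maximizes the glucosylceramide demand
#' (production of glucosylceramide from ceramide and glucose) and the
#' digalactosylceramide demand, and tabulates optima and ratios versus the
#' reference group. An objective reaction pruned from an extracted model is
#' reported as flux 0 with `pruned = TRUE` rather than as an error.
#'
#' @param context_models named list of `metabolic_model`s (one per group).
#' @param objectives demand reaction ids.
#' @param template optional template model from which a missing objective
#'   demand is re-added when its metabolite survived extraction (extraction
#'   routinely prunes inactive demands; the optimization question is whether
#'   the network *can* produce the metabolite).
#' @param reference group name used as the ratio denominator.
#' @return data.frame (group, objective, optimum, pruned, ratio_vs_reference).
#' @export
optimize_glycoceramide_production <- function(context_models,
                                              objectives = c("glcCer_demand",
                                                             "digalCer_demand"),
                                              template = NULL,
                                              reference = "CTRL") {
  rows <- list()
  for (g in names(context_models)) {
    mdl <- context_models[[g]]
    for (objctv in objectives) {
      if (!objctv %in% mdl$rxns$id && !is.null(template) &&
          objctv %in% template$rxns$id) {
        met <- names(template$stoich[[objctv]])
        if (all(met %in% mdl$mets$id)) {
          rrow <- template$rxns[template$rxns$id == objctv, , drop = FALSE]
          mdl <- metabolic_model(mdl$mets, rbind(mdl$rxns, rrow),
                                 c(mdl$stoich,
                                   stats::setNames(template$stoich[objctv], objctv)),
                                 id = mdl$id, currency = model_currency(mdl))
        }
      }
      if (!objctv %in% mdl$rxns$id) {
        rows[[length(rows) + 1L]] <- data.frame(group = g, objective = objctv,
                                                optimum = 0, pruned = TRUE)
      } else {
        st <- fba(mdl, objctv, "max", parsimonious = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, objective = objctv,
          optimum = if (st$status == "optimal") st$objval else 0,
          pruned = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  ref <- out[out$group == reference, c("objective", "optimum")]
  out$ratio_vs_reference <- out$optimum /
    ifelse(ref$optimum[match(out$objective, ref$objective)] > 0,
           ref$optimum[match(out$objective, ref$objective)], NA_real_)
  out
}

#' Flux change summary per metabolic subsystem
#'
#' Compares two flux states over the reactions their models share: total
#' absolute flux per subsystem in each state, absolute and relative change.
#'
#' @param fluxA,fluxB `flux_state` objects.
#' @param modelA model of `fluxA` (supplies subsystem annotation).
#' @param modelB model of `fluxB`; defaults to `modelA`.
#' @return data.frame sorted by decreasing absolute change.
#' @export
subsystem_flux_deltas <- function(fluxA, fluxB, modelA, modelB = modelA) {
  if (fluxA$status != "optimal" || fluxB$status != "optimal")
    stop("both flux states must be optimal")
  shared <- intersect(names(fluxA$flux), names(fluxB$flux))
  sub <- modelA$rxns$subsystem[match(shared, modelA$rxns$id)]
  a <- abs(fluxA$flux[shared]); b <- abs(fluxB$flux[shared])
  agg <- function(x) tapply(x, sub, sum)
  ta <- agg(a); tb <- agg(b)
  out <- data.frame(subsystem = names(ta),
                    flux_A = as.numeric(ta), flux_B = as.numeric(tb),
                    delta = as.numeric(tb - ta),
                    rel_change = ifelse(ta > 0, (tb - ta) / ta,
                                        ifelse(tb > 0, Inf, 0)),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta)), , drop = FALSE]
}
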