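# Context-specific model extraction: expression-based reaction confidence
# scores, metabolomics-derived metabolite evidence and exchange constraints,
# and the INIT-style mixed-integer extraction itself.

#' Score reactions from a group's expression data
#'
#' Per-gene group means (linear scale) are aggregated through each reaction's
#' GPR (AND -> `and_rule`, OR -> `or_rule`); the confidence weight is
#' `w = log2(e / tau)` clipped to `[-w_max, w_max]`, where `tau` is the
#' evidence threshold (default: median of the per-gene group means over all
#' groups). Reactions without gene evidence get weight 0.
#'
#' @param model a `metabolic_model`.
#' @param expression an `omics_matrix` (samples x genes) with group labels.
#' @param group group whose context is being scored.
#' @param tau evidence threshold on the expression scale (NULL = median of
#'   the gene-by-group mean matrix).
#' @param w_max weight clip.
#' @param and_rule,or_rule GPR combination rules.
#' @return data.frame (reaction, expression_level, weight); reactions with
#'   no evidence have `NA` expression and weight 0.
#' @export
score_reactions <- function(model, expression, group, tau = NULL, w_max = 5,
                            and_rule = min, or_rule = max) {
  meta <- expression$sample_meta
  if (!group %in% meta$group) stop("group not present in expression data: ", group)
  gmeans <- vapply(unique(meta$group), function(g)
    colMeans(expression$values[meta$group == g, , drop = FALSE]),
    numeric(ncol(expression$values)))
  if (is.null(tau)) tau <- stats::median(gmeans)
  gv <- gmeans[, group]
  names(gv) <- colnames(expression$values)
  e <- vapply(model$rxns$gpr, function(g)
    evaluate_gpr(g, gv, and_rule = and_rule, or_rule = or_rule), numeric(1))
  w <- ifelse(is.na(e), 0, pmin(pmax(log2(pmax(e, 1e-300) / tau), -w_max), w_max))
  data.frame(reaction = model$rxns$id, expression_level = unname(e),
             weight = unname(w), stringsAsFactors = FALSE)
}

#' Features detected in a group (for metabolite evidence)
#'
#' A feature counts as detected when its group-mean log2 intensity at the
#' given age bin is significantly above the detection limit: the one-sided
#' lower confidence bound of the mean, `mean - z_conf * se`, must exceed the
#' limit. The margin makes detection robust in small groups, where a handful
#' of samples can push a below-limit feature's plain mean over the line.
#'
#' @param om a log2-normalized `omics_matrix`.
#' @param group group label.
#' @param age_bin age bin (months), NULL for all samples of the group.
#' @param limit detection limit on the log2 scale.
#' @param conf one-sided confidence level of the detection call.
#' @return character vector of detected feature names.
#' @export
detected_features <- function(om, group, age_bin = NULL,
                              limit = DETECTION_LIMIT_LOG2, conf = 0.95) {
  require_log2(om)
  meta <- om$sample_meta
  sel <- meta$group == group
  if (!is.null(age_bin)) {
    bins <- assign_age_bins(meta)
    sel <- sel & meta$sample_id %in% bins$sample_id[bins$bin == age_bin]
  }
  if (sum(sel) < 2) stop("need at least 2 samples for group ", group)
  vals <- om$values[sel, , drop = FALSE]
  m <- colMeans(vals)
  se <- apply(vals, 2, stats::sd) / sqrt(nrow(vals))
  colnames(om$values)[m - stats::qnorm(conf) * se > limit]
}

#' Default mapping from the synthetic feature panel to toy-model metabolites
#'
#' Hexosylceramide features are chemically ambiguous between glucosyl- and
#' galactosylceramide and map to both (each mapped id is marked present).
#'
#' @return data.frame (feature, met_id).
#' @export
default_feature_mapping <- function() {
  rbind(
    data.frame(feature = c("Cer(d18:1/24:0)", "Cer(d18:1/22:0)"),
               met_id = "cer_c", stringsAsFactors = FALSE),
    expand.grid(feature = c("HexCer(d18:1/16:0)", "HexCer(d18:1/22:0)",
                            "HexCer(d18:1/24:0)"),
                met_id = c("glcCer_c", "galCer_r"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(feature = c("LacCer(d18:1/12:0)", "LacCer(d18:1/14:0)",
                           "LacCer(d18:1/16:0)"),
               met_id = "lacCer_g", stringsAsFactors = FALSE),
    data.frame(feature = c("serine", "glucose", "galactose"),
               met_id = c("ser_c", "glc_c", "gal_c"), stringsAsFactors = FALSE))
}

#' Metabolite evidence from detected metabolomics features
#'
#' @param model a `metabolic_model`.
#' @param detected_feature_names features detected (e.g. from
#'   [detected_features()]).
#' @param mapping data.frame (feature, met_id); a feature mapping to several
#'   ids marks all of them present (with a warning).
#' @return data.frame (metabolite, present) over all mapped model
#'   metabolites; unmapped detected features are listed in the `"unmapped"`
#'   attribute (and messaged).
#' @export
metabolite_evidence_from_metabolomics <- function(model, detected_feature_names,
                                                  mapping = default_feature_mapping()) {
  bad <- setdiff(unique(mapping$met_id), model$mets$id)
  if (length(bad)) stop("mapping targets unknown metabolite(s): ",
                        paste(bad, collapse = ", "))
  det <- unique(detected_feature_names)
  unmapped <- setdiff(det, mapping$feature)
  if (length(unmapped))
    message(length(unmapped), " detected feature(s) not mappable to the model")
  hits <- mapping[mapping$feature %in% det, , drop = FALSE]
  ambiguous <- unique(hits$feature[duplicated(hits$feature)])
  if (length(ambiguous))
    warning("ambiguous feature mapping (all targets marked present): ",
            paste(ambiguous, collapse = ", "))
  present_ids <- unique(hits$met_id)
  out <- data.frame(metabolite = unique(mapping$met_id),
                    present = unique(mapping$met_id) %in% present_ids,
                    stringsAsFactors = FALSE)
  structure(out, unmapped = unmapped)
}

#' Constrain exchange reactions from metabolite evidence
#'
#' Uptake (negative lower bound) is permitted only for exchanges of
#' evidenced metabolites or whitelisted medium components; all other uptakes
#' are closed. Secretion stays open. Applying the overlay twice is a no-op.
#'
#' @param model a `metabolic_model`.
#' @param evidence data.frame (metabolite, present).
#' @param default_uptake uptake magnitude for permitted exchanges.
#' @param media base metabolite ids always permitted (basal medium).
#' @return the model with adjusted exchange bounds; the overlay is recorded
#'   in the `"exchange_overlay"` attribute.
#' @export
exchange_bounds_from_metabolomics <- function(model, evidence,
                                              default_uptake = 10,
                                              media = c("ser", "palm", "glc",
                                                        "gal", "cho")) {
  bd <- boundary_reactions(model)
  ex <- bd[bd$type == "exchange", , drop = FALSE]
  present_base <- met_base(evidence$metabolite[evidence$present])
  overlay <- data.frame(rxn = ex$rxn,
                        lb = ifelse(met_base(ex$met) %in% c(present_base, media),
                                    -default_uptake, 0),
                        stringsAsFactors = FALSE)
  idx <- match(overlay$rxn, model$rxns$id)
  model$rxns$lb[idx] <- overlay$lb
  model$rxns$reversible[idx] <- overlay$lb < 0
  attr(model, "exchange_overlay") <- overlay
  model
}

#' INIT-style context-specific model extraction
#'
#' Solves the mixed-integer program
#' `max sum_i w_i y_i + kappa * sum_j x_j` subject to `S v = b`,
#' `b_j in [0, b_max]` for evidenced metabolites (0 otherwise),
#' `eps * y_i <= v_i <= M_i * y_i`, `eps * x_j <= b_j <= b_max * x_j`,
#' `y, x` binary, on an irreversibility-split model. Production of an
#' evidenced metabolite (`x_j = 1`) earns the bonus `kappa`; reaction
#' inclusion earns its confidence weight. After the solve, a feasibility
#' re-solve verifies that every included reaction carries at least `eps`
#' flux in the extracted network.
#'
#' @param model an irreversible `metabolic_model` (see [split_reversible()]).
#' @param scores data.frame (reaction, weight) from [score_reactions()].
#' @param evidence data.frame (metabolite, present) from
#'   [metabolite_evidence_from_metabolomics()]; may be empty.
#' @param eps minimal flux of an included reaction.
#' @param big_M flux upper bound in the indicator coupling.
#' @param kappa evidence bonus per produced evidenced metabolite.
#' @param b_max maximal accumulation rate of an evidenced metabolite.
#' @param node_limit branch-and-bound node budget.
#' @return object of class `context_model`: list with `model` (the extracted
#'   subnetwork), `included`, `included_orig` (original reaction ids if the
#'   input carried a split map), `y`, `b`, `x`, `objective`, `status`,
#'   `nodes`.
#' @export
init_extract <- function(model, scores, evidence = NULL, eps = 1e-3,
                         big_M = 1000, kappa = 20, b_max = 100,
                         node_limit = 200000L) {
  if (any(model$rxns$lb < 0))
    stop("init_extract requires an irreversibility-split model")
  n <- nrow(model$rxns)
  w <- scores$weight[match(model$rxns$id, scores$reaction)]
  if (any(is.na(w))) stop("scores must cover all reactions")
  S <- as.matrix(model_S(model))
  m <- nrow(S)
  ev_ids <- character(0)
  if (!is.null(evidence) && nrow(evidence))
    ev_ids <- intersect(evidence$metabolite[evidence$present], model$mets$id)
  nev <- length(ev_ids)
  evrow <- match(ev_ids, model$mets$id)
  Bev <- -diag(m)[, evrow, drop = FALSE]  # accumulation columns
  vub <- pmin(model$rxns$ub, big_M)
  # Only scored reactions (w != 0) carry inclusion binaries; a reaction
  # without expression evidence contributes nothing to the objective and its
  # inclusion is read off the optimal flux pattern afterwards (with a joint
  # eps-feasibility re-solve). Indicator coupling uses per-reaction bounds
  # tightened by an FVA pass, which also fixes never-active reactions to 0.
  # The coupling bound is additionally capped near the total boundary
  # exchange capacity: indicator constraints only ever force eps-scale flux,
  # and internal loops can always be deflated below any cap, so fluxes above
  # that scale are never required - while a loose big-M makes the LP
  # relaxation nearly blind to negative-weight reactions on loops.
  scored <- which(abs(w) > 1e-12)
  bd <- boundary_reactions(model)
  coef <- vapply(bd$rxn, function(r) unname(model$stoich[[r]][1]), numeric(1))
  uptake_rxns <- bd$rxn[bd$type == "exchange" & coef > 0]
  cap_in <- sum(vub[match(uptake_rxns, model$rxns$id)])
  cap_M <- max(1, 100 * eps, 2 * cap_in)
  Mi <- pmin(vub, cap_M)
  Sfull <- cbind(S, Bev)
  for (i in scored) {
    o <- numeric(n + nev); o[i] <- 1
    r <- solve_lp(o, Sfull, rep("=", m), rep(0, m),
                  lb = numeric(n + nev), ub = c(vub, rep(b_max, nev)),
                  maximize = TRUE)
    Mi[i] <- if (r$status == "optimal") min(Mi[i], r$objval + 1e-9) else 0
  }
  blocked <- scored[Mi[scored] < eps]
  scored <- setdiff(scored, blocked)
  ns <- length(scored)
  # variables: v (n), b (nev), y (ns), x (nev)
  nv <- n + nev + ns + nev
  iv <- seq_len(n); ib <- n + seq_len(nev)
  iy <- n + nev + seq_len(ns); ix <- n + nev + ns + seq_len(nev)
  A <- matrix(0, m + 2 * ns + 2 * nev, nv)
  A[seq_len(m), c(iv, ib)] <- Sfull
  dirs <- rep("=", m); rhs <- numeric(m + 2 * ns + 2 * nev)
  rr <- m
  for (k in seq_len(ns)) {
    i <- scored[k]
    A[rr + 1L, c(iv[i], iy[k])] <- c(1, -Mi[i])
    A[rr + 2L, c(iv[i], iy[k])] <- c(1, -eps)
    dirs <- c(dirs, "<=", ">="); rr <- rr + 2L
  }
  for (j in seq_len(nev)) {
    A[rr + 1L, c(ib[j], ix[j])] <- c(1, -b_max)
    A[rr + 2L, c(ib[j], ix[j])] <- c(1, -eps)
    dirs <- c(dirs, "<=", ">="); rr <- rr + 2L
  }
  obj <- numeric(nv); obj[iy] <- w[scored]; obj[ix] <- kappa
  lb <- numeric(nv)
  # v of scored reactions and all b are bounded through their indicator rows;
  # leaving their direct bounds open keeps the tableau small
  vub_lp <- vub; vub_lp[scored] <- Inf
  ub <- c(vub_lp, rep(Inf, nev), rep(1, ns), rep(1, nev))
  ub[iv][blocked] <- 0
  sol <- solve_milp(obj, A, dirs, rhs, lb, ub, binary = c(iy, ix),
                    maximize = TRUE, node_limit = node_limit)
  if (sol$status == "infeasible") {
    hint <- if (all(model$rxns$lb >= 0) &&
                !any(boundary_reactions(model)$type == "exchange"))
      " (no exchange reactions; nothing can carry flux)" else ""
    stop("INIT MILP infeasible", hint)
  }
  if (sol$status == "node_limit")
    stop("INIT solve hit the node limit (gap ", format(sol$gap),
         "); raise node_limit or simplify the instance")
  y <- stats::setNames(numeric(n), model$rxns$id)
  y[scored] <- round(sol$x[iy])
  x <- stats::setNames(if (nev) round(sol$x[ix]) else numeric(0), ev_ids)
  b <- stats::setNames(if (nev) sol$x[ib] else numeric(0), ev_ids)
  # Inclusion of unscored (zero-weight) reactions: with scored decisions and
  # evidence indicators fixed, maximize sum(min(v_i, eps)) over the unscored
  # reactions ("epsilon spreading"). The maximizer concentrates flux onto
  # routes that carry at least eps, which defines a clean inclusion set.
  unscored <- setdiff(seq_len(n), scored)
  ulive <- unscored[vub[unscored] > 0]
  nt <- length(ulive)
  lb2 <- numeric(n + nev); ub2 <- c(vub, rep(b_max, nev))
  lb2[scored] <- ifelse(y[scored] == 1, eps, 0)
  ub2[scored] <- ifelse(y[scored] == 1, vub[scored], 0)
  if (nev) {
    lb2[n + seq_len(nev)] <- ifelse(x == 1, eps, 0)
    ub2[n + seq_len(nev)] <- ifelse(x == 1, b_max, 0)
  }
  if (nt) {
    A2 <- cbind(Sfull, matrix(0, m, nt))
    Tcons <- matrix(0, nt, n + nev + nt)
    Tcons[cbind(seq_len(nt), ulive)] <- -1
    Tcons[cbind(seq_len(nt), n + nev + seq_len(nt))] <- 1
    A2 <- rbind(A2, Tcons)
    spread <- solve_lp(c(numeric(n + nev), rep(1, nt)), A2,
                       c(rep("=", m), rep("<=", nt)), numeric(m + nt),
                       lb = c(lb2, numeric(nt)), ub = c(ub2, rep(eps, nt)),
                       maximize = TRUE)
    if (spread$status != "optimal")
      stop("post-hoc consistency check failed: scored inclusion set is not ",
           "jointly feasible")
    vopt <- spread$x[seq_len(n)]
    y[ulive] <- as.numeric(vopt[ulive] >= eps * (1 - 1e-6))
  }
  included <- names(y)[y == 1]
  # post-hoc consistency: all included reactions must carry >= eps together
  if (length(included)) {
    chk <- init_eps_check(model$rxns$id, included, Sfull, m, nev, vub, b_max, eps)
    if (chk$status != "optimal")
      stop("post-hoc consistency check failed: included set cannot carry ",
           "flux >= eps jointly")
  }
  nodes_used <- sol$nodes
  map <- attr(model, "split_map")
  included_orig <- if (!is.null(map))
    unique(map$orig[map$fwd %in% included |
                      (!is.na(map$rev) & map$rev %in% included)]) else included
  sub <- if (length(included)) subset_model(model, included) else NULL
  if (!is.null(sub)) attr(sub, "split_map") <- map
  structure(list(model = sub, included = included,
                 included_orig = included_orig, y = y, b = b, x = x,
                 objective = sol$objval, status = "optimal",
                 nodes = nodes_used),
            class = "context_model")
}

init_eps_check <- function(rxn_ids, included, Sfull, m, nev, vub, b_max, eps) {
  inc <- rxn_ids %in% included
  solve_lp(numeric(ncol(Sfull)), Sfull, rep("=", m), rep(0, m),
           lb = c(ifelse(inc, eps, 0), rep(0, nev)),
           ub = c(ifelse(inc, vub, 0), rep(b_max, nev)),
           maximize = TRUE)
}

#' @export
print.context_model <- function(x, ...) {
  cat("<context_model> ", length(x$included), " reactions included",
      " (objective ", format(x$objective), ", ", x$nodes, " nodes)\n", sep = "")
  invisible(x)
}
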