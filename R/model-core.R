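# Core data model for stoichiometric metabolic networks: construction and
# validation, GPR rules, reversibility splitting and the metabolite/gene
# adjacency used by reporter-metabolite analysis.

VALID_COMPARTMENTS <- c("c", "g", "r", "l", "m", "e")

# Currency species connect most of a network and are excluded from reporter
# neighborhoods by default; matching is on the compartment-less base id.
DEFAULT_CURRENCY <- c("h2o", "h", "atp", "adp", "pi",
                      "nad", "nadh", "nadp", "nadph", "coa")

#' Construct a metabolic model
#'
#' @param mets data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`. Compartments use the single-letter convention
#'   c (cytosol), g (Golgi), r (endoplasmic reticulum), l (lysosome),
#'   m (mitochondrion), e (extracellular).
#' @param rxns data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `reversible`, `gpr` (boolean AND/OR expression over gene ids, possibly
#'   empty) and `subsystem`.
#' @param stoich named list (one entry per reaction id) of named numeric
#'   vectors of signed stoichiometric coefficients keyed by metabolite id.
#' @param id model identifier.
#' @param currency character vector of base metabolite ids treated as
#'   currency species for neighborhood queries.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(mets, rxns, stoich, id = "model",
                            currency = DEFAULT_CURRENCY) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- ""
  if (is.null(rxns$reversible)) rxns$reversible <- rxns$lb < 0
  model <- structure(
    list(id = id, mets = mets, rxns = rxns, stoich = stoich[rxns$id],
         genes = sort(unique(unlist(lapply(rxns$gpr, gpr_genes))))),
    class = "metabolic_model", currency = currency)
  validate_model(model)
  model
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, compartment codes, declared species in all
#' stoichiometries, bound sanity (`lb <= ub`, irreversible implies
#' `lb >= 0`), non-empty stoichiometries and single-metabolite stoichiometry
#' for boundary (exchange/demand) reactions flagged as such.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
  badc <- setdiff(unique(mets$compartment), VALID_COMPARTMENTS)
  if (length(badc)) stop("unknown compartment code(s): ", paste(badc, collapse = ", "))
  if (!setequal(names(model$stoich), rxns$id))
    stop("stoichiometry list does not match reaction ids")
  for (rid in rxns$id) {
    st <- model$stoich[[rid]]
    if (!length(st)) stop("reaction ", rid, " has empty stoichiometry")
    unk <- setdiff(names(st), mets$id)
    if (length(unk)) stop("reaction ", rid, " references undeclared metabolite(s): ",
                          paste(unk, collapse = ", "))
    if (any(st == 0)) stop("reaction ", rid, " has zero stoichiometric coefficient")
  }
  if (any(rxns$lb > rxns$ub)) stop("reaction with lb > ub: ",
    paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  irrev_neg <- !rxns$reversible & rxns$lb < 0
  if (any(irrev_neg)) stop("irreversible reaction with negative lb: ",
    paste(rxns$id[irrev_neg], collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$mets),
      "  reactions: ", nrow(x$rxns),
      "  genes: ", length(x$genes), "\n", sep = "")
  cat("  compartments: ", paste(sort(unique(x$mets$compartment)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return sparse `Matrix` S with metabolites as rows and reactions as columns.
#' @export
model_S <- function(model) {
  i <- integer(0); j <- integer(0); xval <- numeric(0)
  midx <- stats::setNames(seq_len(nrow(model$mets)), model$mets$id)
  for (k in seq_along(model$stoich)) {
    st <- model$stoich[[k]]
    i <- c(i, midx[names(st)]); j <- c(j, rep(k, length(st))); xval <- c(xval, st)
  }
  Matrix::sparseMatrix(i = i, j = j, x = xval,
                       dims = c(nrow(model$mets), nrow(model$rxns)),
                       dimnames = list(model$mets$id, model$rxns$id))
}

model_currency <- function(model) attr(model, "currency") %||% DEFAULT_CURRENCY

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Base id and bracketed display name of metabolites
#'
#' Metabolite ids follow the `<base>_<compartment>` convention; reports use
#' the bracket notation `base[c]`.
#'
#' @param met_ids character vector of metabolite ids.
#' @return character vector.
#' @export
met_display <- function(met_ids) {
  base <- sub("_([cgrlme])$", "", met_ids)
  comp <- ifelse(grepl("_([cgrlme])$", met_ids),
                 sub("^.*_([cgrlme])$", "\\1", met_ids), "")
  ifelse(comp == "", base, paste0(base, "[", comp, "]"))
}

met_base <- function(met_ids) sub("_([cgrlme])$", "", met_ids)

#' Boundary reactions of a model
#'
#' A boundary reaction has a single-metabolite stoichiometry: exchanges when
#' the metabolite is extracellular, demand/sink reactions otherwise.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with reaction id, metabolite id and type
#'   (`"exchange"` or `"demand"`).
#' @export
boundary_reactions <- function(model) {
  single <- vapply(model$stoich, function(s) length(s) == 1L, logical(1))
  rid <- model$rxns$id[single]
  mid <- vapply(model$stoich[single], names, character(1))
  comp <- model$mets$compartment[match(mid, model$mets$id)]
  data.frame(rxn = rid, met = mid,
             type = ifelse(comp == "e", "exchange", "demand"),
             stringsAsFactors = FALSE)
}

# ---- GPR rules --------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := gene | '(' expr ')'`; AND/OR are case-insensitive. An empty
#' string parses to `NULL` (no gene association).
#'
#' @param gpr rule string.
#' @return nested list tree with nodes `list(op = "and"|"or", args = ...)` and
#'   gene-id character leaves, or `NULL`.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR rule: ", gpr)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("malformed GPR rule (unbalanced parentheses): ", gpr)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) stop("malformed GPR rule: ", gpr)
    t
  }
  tree <- parse_expr()
  if (pos <= length(toks)) stop("malformed GPR rule (trailing tokens): ", gpr)
  tree
}

#' Genes referenced by a GPR rule
#' @param gpr rule string or parsed tree.
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr)) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR rule against gene-level values
#'
#' AND nodes are combined with `and_rule` (default `min`, isozyme-limiting),
#' OR nodes with `or_rule` (default `max`). Genes missing from `gene_values`
#' contribute no evidence: they are dropped from their node rather than being
#' treated as zero. A rule whose genes are all missing, or an empty rule,
#' evaluates to `NA` ("no evidence").
#'
#' @param gpr rule string or parsed tree.
#' @param gene_values named numeric vector of per-gene values.
#' @param and_rule,or_rule combining functions.
#' @return numeric value or `NA_real_`.
#' @export
evaluate_gpr <- function(gpr, gene_values, and_rule = min, or_rule = max) {
  tree <- if (is.character(gpr) && length(gpr) == 1L && !is.list(gpr)) parse_gpr(gpr) else gpr
  eval_node <- function(node) {
    if (is.null(node)) return(NA_real_)
    if (is.character(node)) {
      v <- gene_values[node]
      return(if (is.na(names(v)) || is.na(v)) NA_real_ else unname(v))
    }
    vals <- vapply(node$args, eval_node, numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$op == "and") and_rule(vals) else or_rule(vals)
  }
  eval_node(tree)
}

# Render a parsed GPR tree back to its canonical string form.
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (tree$op == "and") " and " else " or ")
}

# ---- reversibility splitting ------------------------------------------------

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' (`<id>__fwd`, bounds `[0, max(0, ub)]`) and a backward copy with mirrored
#' stoichiometry (`<id>__rev`, bounds `[0, -lb]`). The mapping back to the
#' original reactions is kept in the `"split_map"` attribute. Models that are
#' already irreversible are returned unchanged (with an identity map).
#'
#' @param model a `metabolic_model`.
#' @return split `metabolic_model`.
#' @export
split_reversible <- function(model) {
  rxns <- model$rxns
  needs <- rxns$lb < 0
  map <- data.frame(orig = rxns$id,
                    fwd = ifelse(needs, paste0(rxns$id, "__fwd"), rxns$id),
                    rev = ifelse(needs, paste0(rxns$id, "__rev"), NA_character_),
                    stringsAsFactors = FALSE)
  if (!any(needs)) {
    attr(model, "split_map") <- map
    return(model)
  }
  new_rxns <- list(); new_stoich <- list()
  for (k in seq_len(nrow(rxns))) {
    r <- rxns[k, ]
    if (!needs[k]) {
      new_rxns[[length(new_rxns) + 1L]] <- r
      new_stoich[[r$id]] <- model$stoich[[r$id]]
    } else {
      f <- r; f$id <- paste0(r$id, "__fwd"); f$lb <- 0; f$ub <- max(0, r$ub); f$reversible <- FALSE
      b <- r; b$id <- paste0(r$id, "__rev"); b$lb <- 0; b$ub <- -r$lb; b$reversible <- FALSE
      new_rxns[[length(new_rxns) + 1L]] <- f
      new_rxns[[length(new_rxns) + 1L]] <- b
      new_stoich[[f$id]] <- model$stoich[[r$id]]
      new_stoich[[b$id]] <- -model$stoich[[r$id]]
    }
  }
  out <- metabolic_model(model$mets, do.call(rbind, new_rxns), new_stoich,
                         id = model$id, currency = model_currency(model))
  attr(out, "split_map") <- map
  out
}

#' Map fluxes on a split model back to net fluxes on the original reactions
#'
#' @param v named flux vector on the split model.
#' @param split_model model returned by [split_reversible()] (or its
#'   `"split_map"` attribute).
#' @return named numeric vector of net fluxes (forward minus backward).
#' @export
merge_split_fluxes <- function(v, split_model) {
  map <- if (is.data.frame(split_model)) split_model else attr(split_model, "split_map")
  if (is.null(map)) stop("no split map available")
  fwd <- ifelse(is.na(v[map$fwd]), 0, v[map$fwd])
  rev <- ifelse(is.na(map$rev), 0, ifelse(is.na(v[map$rev]), 0, v[map$rev]))
  stats::setNames(as.numeric(fwd) - as.numeric(rev), map$orig)
}

# ---- neighborhoods ----------------------------------------------------------

#' Genes adjacent to a metabolite in the network
#'
#' Union of the genes in the GPRs of every reaction in which the metabolite
#' participates (as substrate or product). Currency metabolites return an
#' empty set by policy.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite id.
#' @param currency base ids excluded as currency species.
#' @return character vector of gene ids.
#' @export
metabolite_gene_neighborhood <- function(model, metabolite_id,
                                         currency = model_currency(model)) {
  if (!metabolite_id %in% model$mets$id)
    stop("unknown metabolite id: ", metabolite_id)
  if (tolower(met_base(metabolite_id)) %in% tolower(currency)) return(character(0))
  part <- vapply(model$stoich, function(s) metabolite_id %in% names(s), logical(1))
  sort(unique(unlist(lapply(model$rxns$gpr[part], gpr_genes))))
}

#' Restrict a model to a subset of reactions
#'
#' @param model a `metabolic_model`.
#' @param rxn_ids reactions to keep.
#' @param drop_orphans drop metabolites no longer used (default TRUE).
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, rxn_ids, drop_orphans = TRUE) {
  keep <- model$rxns$id %in% rxn_ids
  rxns <- model$rxns[keep, , drop = FALSE]
  stoich <- model$stoich[rxns$id]
  mets <- model$mets
  if (drop_orphans) {
    used <- unique(unlist(lapply(stoich, names)))
    mets <- mets[mets$id %in% used, , drop = FALSE]
  }
  metabolic_model(mets, rxns, stoich, id = model$id,
                  currency = model_currency(model))
}

#' Export reaction and metabolite tables as TSV
#'
#' @param model a `metabolic_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_model_tables <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eqn <- vapply(model$rxns$id, function(rid) {
    st <- model$stoich[[rid]]
    lhs <- st[st < 0]; rhs <- st[st > 0]
    fmt <- function(s) paste(ifelse(abs(s) == 1, names(s),
                                    paste(abs(s), names(s))), collapse = " + ")
    paste(fmt(lhs), if (model$rxns$reversible[model$rxns$id == rid]) "<=>" else "-->", fmt(rhs))
  }, character(1))
  rt <- cbind(model$rxns, equation = eqn)
  fr <- file.path(dir, "reactions.tsv"); fm <- file.path(dir, "metabolites.tsv")
  utils::write.table(rt, fr, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$mets, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fr, fm))
}
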