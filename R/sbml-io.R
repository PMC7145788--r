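# SBML Level 3 Version 1 (+ FBC v2) reader/writer for the minimal dialect
# used throughout the package: compartments, species, per-reaction flux-bound
# parameters, gene-product associations, and subsystems carried in reaction
# notes as a "SUBSYSTEM:" paragraph (the convention COBRA tools understand).

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.17g", x)

#' Write a model as SBML (L3v1 core + FBC v2)
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  mets <- model$mets; rxns <- model$rxns
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" version=\"1\"",
                   " fbc:required=\"false\">"), SBML_CORE_NS, SBML_FBC_NS),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", xml_escape(model$id)),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
            sort(unique(mets$compartment))),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  formula_attr <- ifelse(is.na(mets$formula) | !nzchar(mets$formula), "",
                         sprintf(" fbc:chemicalFormula=\"%s\"", xml_escape(mets$formula)))
  out <- c(out, sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\"",
                               " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
                               " constant=\"false\"%s/>"),
                        mets$id, xml_escape(mets$name), mets$compartment, formula_attr),
           "    </listOfSpecies>",
           "    <listOfParameters>",
           sprintf("      <parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
                   rxns$id, num_attr(rxns$lb)),
           sprintf("      <parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
                   rxns$id, num_attr(rxns$ub)),
           "    </listOfParameters>")
  if (length(model$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf("      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
                     model$genes, model$genes),
             "    </fbc:listOfGeneProducts>")
  }
  out <- c(out, "    <listOfReactions>")
  for (k in seq_len(nrow(rxns))) {
    r <- rxns[k, ]
    st <- model$stoich[[r$id]]
    out <- c(out, sprintf(paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\"",
                                 " fast=\"false\" fbc:lowerFluxBound=\"lb_%s\"",
                                 " fbc:upperFluxBound=\"ub_%s\">"),
                          r$id, xml_escape(r$name), tolower(as.character(r$reversible)),
                          r$id, r$id))
    if (nzchar(r$subsystem))
      out <- c(out,
               "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
               sprintf("          <p>SUBSYSTEM: %s</p>", xml_escape(r$subsystem)),
               "        </body></notes>")
    st <- st[order(names(st))]  # canonical species order for stable output
    sub <- st[st < 0]; prod <- st[st > 0]
    if (length(sub)) out <- c(out, "        <listOfReactants>",
      sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
              names(sub), num_attr(-as.numeric(sub))),
      "        </listOfReactants>")
    if (length(prod)) out <- c(out, "        <listOfProducts>",
      sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
              names(prod), num_attr(as.numeric(prod))),
      "        </listOfProducts>")
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree))
      out <- c(out, "        <fbc:geneProductAssociation>",
               gpa_xml(tree, indent = 10L),
               "        </fbc:geneProductAssociation>")
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

gpa_xml <- function(tree, indent) {
  pad <- strrep(" ", indent)
  if (is.character(tree))
    return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>", pad, tree))
  tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
  c(sprintf("%s<%s>", pad, tag),
    unlist(lapply(tree$args, gpa_xml, indent = indent + 2L)),
    sprintf("%s</%s>", pad, tag))
}

#' Read a model from SBML (L3v1 core + FBC v2)
#'
#' Parses the minimal dialect written by [write_sbml()] and the common subset
#' of FBC-annotated models: species/compartments, flux-bound parameters,
#' reversibility, gene-product associations and SUBSYSTEM notes. Unknown SBML
#' package namespaces are ignored with a warning. Reactions citing undeclared
#' species fail model validation.
#'
#' @param path SBML file.
#' @param currency currency list to attach to the model.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, currency = DEFAULT_CURRENCY) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns_all <- xml2::xml_ns(doc)
  known <- c(SBML_CORE_NS, SBML_FBC_NS, "http://www.w3.org/1999/xhtml")
  unknown <- setdiff(unique(unname(ns_all)), known)
  if (length(unknown))
    warning("ignoring unknown SBML package namespace(s): ",
            paste(unknown, collapse = ", "))
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mdl, "xml_missing")) stop("SBML parse error: no <model> element in ", path)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) stop("SBML parse error: no <species> elements in ", path)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = vapply(sp, function(s) {
      a <- xml2::xml_attrs(s)
      f <- a[grep("(^|:)chemicalFormula$", names(a))]
      if (length(f)) unname(f[1]) else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("SBML parse error: no <reaction> elements in ", path)
  rxn_rows <- list(); stoich <- list()
  for (r in rx) {
    a <- xml2::xml_attrs(r)
    rid <- unname(a[["id"]])
    rev <- identical(tolower(unname(a[grep("^reversible$", names(a))])), "true")
    lbref <- a[grep("(^|:)lowerFluxBound$", names(a))]
    ubref <- a[grep("(^|:)upperFluxBound$", names(a))]
    lb <- if (length(lbref) && unname(lbref[1]) %in% names(parval)) parval[[unname(lbref[1])]]
          else if (rev) -1000 else 0
    ub <- if (length(ubref) && unname(ubref[1]) %in% names(parval)) parval[[unname(ubref[1])]]
          else 1000
    reac <- xml2::xml_find_all(r, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(r, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    st <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                            xml2::xml_attr(reac, "species")),
            stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                            xml2::xml_attr(prod, "species")))
    st <- tapply(st, names(st), sum)  # merge duplicated species refs
    st <- st[st != 0]
    gpa <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else deparse_gpr(read_gpa(gpa))
    notes <- xml2::xml_find_all(r, ".//*[local-name()='p']")
    subsystem <- ""
    for (p in notes) {
      txt <- xml2::xml_text(p)
      if (grepl("^\\s*SUBSYSTEM:", txt))
        subsystem <- trimws(sub("^\\s*SUBSYSTEM:", "", txt))
    }
    rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
      id = rid,
      name = if (!is.null(a[["name"]])) unname(a[["name"]]) else rid,
      lb = lb, ub = ub, reversible = rev, gpr = gpr, subsystem = subsystem,
      stringsAsFactors = FALSE)
    stoich[[rid]] <- stats::setNames(as.numeric(st), names(st))
  }
  metabolic_model(mets, do.call(rbind, rxn_rows), stoich, id = model_id,
                  currency = currency)
}

read_gpa <- function(node) {
  lname <- xml2::xml_name(node)
  if (lname == "geneProductRef") {
    a <- xml2::xml_attrs(node)
    g <- a[grep("(^|:)geneProduct$", names(a))]
    return(unname(g[1]))
  }
  if (lname %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = lname, args = lapply(kids, read_gpa)))
  }
  # container element: descend to its single child
  kids <- xml2::xml_children(node)
  if (length(kids) != 1L) stop("malformed geneProductAssociation")
  read_gpa(kids[[1]])
}
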