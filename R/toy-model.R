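# Toy genome-scale model of sphingolipid metabolism. The network follows the
# canonical human pathway map: de novo synthesis in the ER (SPT -> KSR ->
# CerS -> DES), sphingomyelin synthesis/breakdown (SMS in the Golgi, SMase and
# ceramidase in the lysosome), the glycosphingolipid branch (GCS, LacCer
# synthase, GalCS, the corresponding glycosidases, digalactosylceramide
# synthesis) and the signalling branch (SK, S1P lyase/phosphatase, CK, C1PP),
# plus uptake of serine, palmitate, glucose, galactose and a choline head-group
# donor. Enzymatic steps carry single-gene GPRs; transport, exchange and
# demand reactions are unannotated, as is common for vesicular/spontaneous
# lipid movement in metabolic reconstructions.

SUBSYS <- list(
  denovo = "Sphingolipid metabolism (de novo)",
  sm = "Sphingolipid metabolism (sphingomyelin)",
  glyco = "Sphingolipid metabolism (glycosphingolipid)",
  salvage = "Sphingolipid metabolism (salvage)",
  signal = "Sphingolipid signalling",
  gpl = "Glycerophospholipid metabolism",
  t_ex = "Transport, extracellular",
  t_er = "Transport, ER",
  t_golgi = "Transport, Golgi",
  t_lyso = "Transport, lysosomal",
  boundary = "Exchange/demand")

#' Build the toy sphingolipid network
#'
#' @param uptake maximal uptake rate for medium metabolites (flux units);
#'   exchange lower bounds are `-uptake`.
#' @param ub_max default upper flux bound for internal reactions.
#' @param drop_reactions reaction ids to remove (to emulate alternative
#'   topologies); removal that leaves blocked reactions raises an error when
#'   `check_consistency` is on.
#' @param check_consistency verify that every reaction can carry flux
#'   (FVA-style per-reaction optimization) and error otherwise.
#' @return a `metabolic_model` with compartments c/g/r/l/e, single-gene GPRs
#'   on all enzyme steps and demand reactions `glcCer_demand` /
#'   `digalCer_demand` for the two glycoceramide objectives.
#' @export
build_toy_sphingolipid_model <- function(uptake = 10, ub_max = 1000,
                                         drop_reactions = character(),
                                         check_consistency = FALSE) {
  M <- function(id, name, comp) data.frame(id = id, name = name, compartment = comp,
                                           stringsAsFactors = FALSE)
  mets <- rbind(
    M("ser_e", "L-serine", "e"), M("palm_e", "palmitate", "e"),
    M("glc_e", "D-glucose", "e"), M("gal_e", "D-galactose", "e"),
    M("cho_e", "choline head-group donor", "e"),
    M("ser_c", "L-serine", "c"), M("palm_c", "palmitate", "c"),
    M("glc_c", "D-glucose", "c"), M("gal_c", "D-galactose", "c"),
    M("cho_c", "choline head-group donor", "c"),
    M("cer_c", "ceramide", "c"), M("glcCer_c", "glucosylceramide", "c"),
    M("digalCer_c", "digalactosylceramide", "c"),
    M("sph_c", "sphingosine", "c"), M("s1p_c", "sphingosine-1-phosphate", "c"),
    M("s1pdeg_c", "S1P breakdown products", "c"),
    M("c1p_c", "ceramide-1-phosphate", "c"), M("pc_c", "phosphatidylcholine", "c"),
    M("ser_r", "L-serine", "r"), M("palm_r", "palmitate", "r"),
    M("gal_r", "D-galactose", "r"),
    M("kdhSph_r", "3-ketodihydrosphinganine", "r"),
    M("dhSph_r", "dihydrosphingosine", "r"), M("dhCer_r", "dihydroceramide", "r"),
    M("cer_r", "ceramide", "r"), M("galCer_r", "galactosylceramide", "r"),
    M("cer_g", "ceramide", "g"), M("pc_g", "phosphatidylcholine", "g"),
    M("sm_g", "sphingomyelin", "g"), M("dag_g", "diacylglycerol", "g"),
    M("glcCer_g", "glucosylceramide", "g"), M("gal_g", "D-galactose", "g"),
    M("lacCer_g", "lactosylceramide", "g"),
    M("sm_l", "sphingomyelin", "l"), M("cer_l", "ceramide", "l"),
    M("cho_l", "phosphocholine", "l"), M("sph_l", "sphingosine", "l"),
    M("glcCer_l", "glucosylceramide", "l"), M("galCer_l", "galactosylceramide", "l"),
    M("glc_l", "D-glucose", "l"), M("gal_l", "D-galactose", "l"))

  rxn <- function(id, name, stoich, subsystem, gene = "", lb = 0, ub = ub_max) {
    list(row = data.frame(id = id, name = name, lb = lb, ub = ub,
                          reversible = lb < 0, gpr = gene, subsystem = subsystem,
                          stringsAsFactors = FALSE),
         st = stoich)
  }
  ex <- function(met) rxn(paste0("EX_", sub("_e$", "", met)),
                          paste("exchange of", sub("_e$", "", met)),
                          stats::setNames(-1, met), SUBSYS$boundary,
                          lb = -uptake, ub = ub_max)
  tr <- function(id, from, to, subsystem)
    rxn(id, paste("transport", from, "->", to), stats::setNames(c(-1, 1), c(from, to)),
        subsystem)
  enz <- function(id, name, subs, prods, gene, subsystem)
    rxn(id, name, c(stats::setNames(rep(-1, length(subs)), subs),
                    stats::setNames(rep(1, length(prods)), prods)),
        subsystem, gene = gene)
  dm <- function(id, met) rxn(id, paste("demand of", met), stats::setNames(-1, met),
                              SUBSYS$boundary)

  defs <- list(
    ex("ser_e"), ex("palm_e"), ex("glc_e"), ex("gal_e"), ex("cho_e"),
    tr("T_ser", "ser_e", "ser_c", SUBSYS$t_ex),
    tr("T_palm", "palm_e", "palm_c", SUBSYS$t_ex),
    tr("T_glc", "glc_e", "glc_c", SUBSYS$t_ex),
    tr("T_gal", "gal_e", "gal_c", SUBSYS$t_ex),
    tr("T_cho", "cho_e", "cho_c", SUBSYS$t_ex),
    tr("T_ser_r", "ser_c", "ser_r", SUBSYS$t_er),
    tr("T_palm_r", "palm_c", "palm_r", SUBSYS$t_er),
    tr("T_gal_r", "gal_c", "gal_r", SUBSYS$t_er),
    tr("T_cer_r_c", "cer_r", "cer_c", SUBSYS$t_er),
    tr("T_galCer_r_l", "galCer_r", "galCer_l", SUBSYS$t_er),
    tr("T_cer_c_g", "cer_c", "cer_g", SUBSYS$t_golgi),
    tr("T_pc_g", "pc_c", "pc_g", SUBSYS$t_golgi),
    tr("T_glcCer_c_g", "glcCer_c", "glcCer_g", SUBSYS$t_golgi),
    tr("T_gal_g", "gal_c", "gal_g", SUBSYS$t_golgi),
    tr("T_sm_g_l", "sm_g", "sm_l", SUBSYS$t_golgi),
    tr("T_glcCer_c_l", "glcCer_c", "glcCer_l", SUBSYS$t_lyso),
    tr("T_sph_l_c", "sph_l", "sph_c", SUBSYS$t_lyso),
    tr("T_glc_l_c", "glc_l", "glc_c", SUBSYS$t_lyso),
    tr("T_gal_l_c", "gal_l", "gal_c", SUBSYS$t_lyso),
    enz("SPT", "serine palmitoyltransferase", c("ser_r", "palm_r"), "kdhSph_r",
        "g_SPT", SUBSYS$denovo),
    enz("KSR", "3-ketodihydrosphinganine reductase", "kdhSph_r", "dhSph_r",
        "g_KSR", SUBSYS$denovo),
    enz("CERS", "ceramide synthase", c("dhSph_r", "palm_r"), "dhCer_r",
        "g_CERS", SUBSYS$denovo),
    enz("DES", "dihydroceramide desaturase", "dhCer_r", "cer_r",
        "g_DES", SUBSYS$denovo),
    enz("SMS", "sphingomyelin synthase", c("cer_g", "pc_g"), c("sm_g", "dag_g"),
        "g_SMS", SUBSYS$sm),
    enz("SMASE", "sphingomyelinase", "sm_l", c("cer_l", "cho_l"),
        "g_SMASE", SUBSYS$sm),
    enz("CDASE", "ceramidase", "cer_l", "sph_l", "g_CDASE", SUBSYS$salvage),
    enz("CERS2", "ceramide synthase (salvage)", c("sph_c", "palm_c"), "cer_c",
        "g_CERS2", SUBSYS$salvage),
    enz("GCS", "glucosylceramide synthase", c("cer_c", "glc_c"), "glcCer_c",
        "g_GCS", SUBSYS$glyco),
    enz("GCDASE", "glucosylceramidase", "glcCer_l", c("cer_l", "glc_l"),
        "g_GCDASE", SUBSYS$glyco),
    enz("GALCS", "galactosylceramide synthase", c("cer_r", "gal_r"), "galCer_r",
        "g_GALCS", SUBSYS$glyco),
    enz("GALCDASE", "galactosylceramidase", "galCer_l", c("cer_l", "gal_l"),
        "g_GALCDASE", SUBSYS$glyco),
    enz("LACCERS", "lactosylceramide synthase", c("glcCer_g", "gal_g"), "lacCer_g",
        "g_LACCERS", SUBSYS$glyco),
    enz("DGALCS", "digalactosylceramide synthase", c("cer_c", "gal_c"), "digalCer_c",
        "g_DGALCS", SUBSYS$glyco),
    enz("SK", "sphingosine kinase", "sph_c", "s1p_c", "g_SK", SUBSYS$signal),
    enz("S1PPASE", "sphingosine-1-phosphate phosphatase", "s1p_c", "sph_c",
        "g_S1PPASE", SUBSYS$signal),
    enz("S1PL", "sphingosine-1-phosphate lyase", "s1p_c", "s1pdeg_c",
        "g_S1PL", SUBSYS$signal),
    enz("CK", "ceramide kinase", "cer_c", "c1p_c", "g_CK", SUBSYS$signal),
    enz("C1PP", "ceramide-1-phosphate phosphatase", "c1p_c", "cer_c",
        "g_C1PP", SUBSYS$signal),
    enz("PCS", "phosphatidylcholine synthesis", "cho_c", "pc_c",
        "g_PCS", SUBSYS$gpl),
    dm("DM_sm", "sm_g"),
    dm("glcCer_demand", "glcCer_c"),
    dm("DM_lacCer", "lacCer_g"),
    dm("DM_galCer", "galCer_r"),
    dm("digalCer_demand", "digalCer_c"),
    dm("DM_s1pdeg", "s1pdeg_c"),
    dm("DM_dag", "dag_g"),
    dm("DM_cho_l", "cho_l"))

  rxns <- do.call(rbind, lapply(defs, `[[`, "row"))
  stoich <- stats::setNames(lapply(defs, `[[`, "st"), rxns$id)
  if (length(drop_reactions)) {
    unknown <- setdiff(drop_reactions, rxns$id)
    if (length(unknown)) stop("cannot drop unknown reaction(s): ",
                              paste(unknown, collapse = ", "))
    keep <- !(rxns$id %in% drop_reactions)
    rxns <- rxns[keep, , drop = FALSE]
    stoich <- stoich[rxns$id]
    used <- unique(unlist(lapply(stoich, names)))
    mets <- mets[mets$id %in% used, , drop = FALSE]
  }
  model <- metabolic_model(mets, rxns, stoich, id = "toy_sphingolipid",
                           currency = c(DEFAULT_CURRENCY, "glc", "gal"))
  if (check_consistency) {
    blocked <- flux_consistency(model)$blocked
    if (length(blocked))
      stop("requested topology is not flux-consistent; blocked reaction(s): ",
           paste(blocked, collapse = ", "))
  }
  model
}
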