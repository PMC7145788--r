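# End-to-end pipeline: synthetic data (or user inputs) -> QC -> differential
# contrasts -> pathway ORA -> reaction scoring -> INIT extraction -> reporter
# metabolites -> flux analysis, with a hashed output manifest for
# reproducibility checks.

PIPELINE_STAGES <- c("simulate", "qc", "contrast", "ora", "score", "extract",
                     "reporters", "flux")

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param output_dir run directory.
#' @return nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L, output_dir = "immunogem_run") {
  list(
    synthetic = TRUE,
    seed = as.integer(seed),
    output_dir = output_dir,
    inputs = list(metabolomics = NULL, metadata = NULL, expression = NULL,
                  expression_meta = NULL, model = NULL, pathways = NULL),
    cohort = list(group_sizes = list(CTRL = 10L, P1Ab = 27L, PT1D = 34L),
                  ages = c(12, 24, 36), missingness_rate = 0.35),
    expression = list(group_sizes = list(CTRL = 15L, P1Ab = 15L, PT1D = 51L),
                      glyco_genes = c("g_GCS", "g_GALCS", "g_LACCERS", "g_DGALCS"),
                      glyco_baseline_shift_log2 = log2(0.35),
                      glyco_effect_log2 = log2(2.8)),
    thresholds = list(p = 0.05, fdr = 0.05, vip = 1.0, rc = 0.05,
                      auc = 0.65, rho = 0.70),
    plsda = list(n_components = 2L, keep_per_component = 20L,
                 folds = 5L, repeats = 10L),
    gem = list(tau = NULL, w_max = 5, kappa = 20, eps = 1e-3, big_M = 1000,
               b_max = 100, default_uptake = 10,
               detection_limit = DETECTION_LIMIT_LOG2, modelling_age = 36))
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see [default_config()]).
#' @return list with `ok` (logical), `errors` and `warnings` (character
#'   vectors). Threshold values diverging from the published analysis
#'   defaults produce warnings, not errors.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  th <- config$thresholds
  chk_range <- function(x, lo, hi, nm) {
    if (is.null(x) || !is.numeric(x) || x < lo || x > hi)
      errors <<- c(errors, sprintf("%s must be in [%g, %g]", nm, lo, hi))
  }
  chk_range(th$p, 0, 1, "thresholds$p")
  chk_range(th$fdr, 0, 1, "thresholds$fdr")
  chk_range(th$auc, 0, 1, "thresholds$auc")
  chk_range(th$rho, -1, 1, "thresholds$rho")
  if (is.null(th$vip) || th$vip < 0) errors <- c(errors, "thresholds$vip must be >= 0")
  if (is.null(th$rc) || th$rc < 0) errors <- c(errors, "thresholds$rc must be >= 0")
  defaults <- list(p = 0.05, fdr = 0.05, vip = 1.0, rc = 0.05, auc = 0.65,
                   rho = 0.70)
  for (nm in names(defaults)) {
    if (!is.null(th[[nm]]) && is.numeric(th[[nm]]) &&
        abs(th[[nm]] - defaults[[nm]]) > 1e-12)
      warnings <- c(warnings, sprintf(
        "thresholds$%s = %g differs from the reference analysis default %g",
        nm, th[[nm]], defaults[[nm]]))
  }
  gem <- config$gem
  for (nm in c("w_max", "kappa", "eps", "big_M", "b_max", "default_uptake")) {
    if (is.null(gem[[nm]]) || gem[[nm]] <= 0)
      errors <- c(errors, sprintf("gem$%s must be positive", nm))
  }
  if (isTRUE(config$synthetic)) {
    if (is.null(config$seed)) errors <- c(errors, "synthetic runs need a fixed seed")
    mr <- config$cohort$missingness_rate
    if (is.null(mr) || mr < 0 || mr >= 0.5)
      errors <- c(errors, "cohort$missingness_rate must be in [0, 0.5)")
  } else {
    for (nm in c("metabolomics", "metadata", "expression", "model")) {
      p <- config$inputs[[nm]]
      if (is.null(p)) errors <- c(errors, sprintf("inputs$%s is required", nm))
      else if (!file.exists(p)) errors <- c(errors, sprintf("inputs$%s not found: %s", nm, p))
    }
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (or ingest), qc, contrast, ora, score,
#' extract, reporters and flux, writing each stage's tables (TSV), models
#' (SBML) and a manifest (JSON: stage, parameters, output file hashes) under
#' `config$output_dir`. Reruns with the same configuration and seed are
#' bit-identical.
#'
#' @param config configuration list; see [default_config()].
#' @param stages stages to run (a prefix of the stage list; later stages
#'   depend on earlier ones within the same call).
#' @return the run directory, invisibly; the manifest is attached as the
#'   `"manifest"` attribute.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = PIPELINE_STAGES) {
  val <- validate_config(config)
  if (!val$ok) stop("invalid configuration:\n  ",
                    paste(val$errors, collapse = "\n  "))
  for (w in val$warnings) warning(w, call. = FALSE)
  stages <- PIPELINE_STAGES[seq_len(max(match(stages, PIPELINE_STAGES)))]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  env <- new.env()
  for (st in stages) {
    outputs <- tryCatch(
      switch(st,
             simulate = stage_simulate(config, env),
             qc = stage_qc(config, env),
             contrast = stage_contrast(config, env),
             ora = stage_ora(config, env),
             score = stage_score(config, env),
             extract = stage_extract(config, env),
             reporters = stage_reporters(config, env),
             flux = stage_flux(config, env)),
      error = function(e) stop("pipeline stage '", st, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest[[st]] <- list(stage = st,
                           outputs = as.list(tools::md5sum(sort(unname(outputs)))))
  }
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(list(stages = manifest,
                            seed = config$seed,
                            config_hash = unname(tools::md5sum(
                              write_config_for_hash(config)))),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  structure(invisible(config$output_dir), manifest = manifest)
}

write_config_for_hash <- function(config) {
  p <- file.path(config$output_dir, "config.yaml")
  cfg <- config
  yaml::write_yaml(cfg, p)
  p
}

derive_seed <- function(config, offset) (config$seed * 1000L + offset) %% 2147483647L

stage_simulate <- function(config, env) {
  dir <- config$output_dir
  if (isTRUE(config$synthetic)) {
    env$model <- build_toy_sphingolipid_model(
      uptake = config$gem$default_uptake)
    gs <- unlist(config$cohort$group_sizes)
    env$design <- cohort_design(group_sizes = gs,
                                ages = config$cohort$ages,
                                missingness_rate = config$cohort$missingness_rate,
                                seed = derive_seed(config, 1L))
    env$metab <- simulate_metabolomics(env$design,
                                       seed = derive_seed(config, 2L))
    ex <- config$expression
    shift <- stats::setNames(rep(ex$glyco_baseline_shift_log2,
                                 length(ex$glyco_genes)), ex$glyco_genes)
    effects <- data.frame(gene = ex$glyco_genes, group = "PT1D",
                          log2_effect = ex$glyco_effect_log2,
                          stringsAsFactors = FALSE)
    env$expr <- simulate_expression(env$model,
                                    expression_design(unlist(ex$group_sizes),
                                                      seed = derive_seed(config, 3L)),
                                    effects = effects, baseline_shift = shift,
                                    seed = derive_seed(config, 4L))
    truth <- list(metabolomics_effects = attr(env$metab, "effects"),
                  sero_effects = attr(env$metab, "sero_effects"),
                  expression_effects = effects)
    f_truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    env$model <- read_sbml(config$inputs$model)
    vals <- as.matrix(utils::read.delim(config$inputs$metabolomics,
                                        row.names = 1, check.names = FALSE))
    meta <- utils::read.delim(config$inputs$metadata, stringsAsFactors = FALSE)
    env$metab <- omics_matrix(vals, meta[match(rownames(vals), meta$sample_id), ])
    evals <- as.matrix(utils::read.delim(config$inputs$expression,
                                         row.names = 1, check.names = FALSE))
    emeta <- utils::read.delim(config$inputs$expression_meta,
                               stringsAsFactors = FALSE)
    env$expr <- omics_matrix(t(evals), emeta[match(colnames(evals),
                                                   emeta$sample_id), ])
    f_truth <- NULL
  }
  f_model <- file.path(dir, "model.sbml")
  write_sbml(env$model, f_model)
  f_met <- write_tsv(cbind(sample_id = env$metab$sample_meta$sample_id,
                           as.data.frame(env$metab$values, check.names = FALSE)),
                     file.path(dir, "metabolomics.tsv"))
  f_meta <- write_tsv(env$metab$sample_meta, file.path(dir, "sample_meta.tsv"))
  f_expr <- write_tsv(cbind(gene = colnames(env$expr$values),
                            as.data.frame(t(env$expr$values), check.names = FALSE)),
                      file.path(dir, "expression.tsv"))
  f_emeta <- write_tsv(env$expr$sample_meta, file.path(dir, "expression_meta.tsv"))
  c(f_model, f_met, f_meta, f_expr, f_emeta,
    if (!is.null(f_truth)) f_truth)
}

stage_qc <- function(config, env) {
  dir <- config$output_dir
  env$metab_log <- log2_normalize(env$metab)
  env$expr_log <- log2_normalize(env$expr)
  kinds <- unique(env$metab$feature_meta$kind)
  flags <- lapply(kinds, function(k) {
    sub <- subset_features(env$metab_log, env$metab$feature_meta$kind == k)
    out <- pca_outlier_check(sub)
    if (length(out)) data.frame(kind = k, sample_id = out) else NULL
  })
  flags <- do.call(rbind, flags)
  if (is.null(flags)) flags <- data.frame(kind = character(0),
                                          sample_id = character(0))
  f_out <- write_tsv(flags, file.path(dir, "qc_outliers.tsv"))
  ev <- variance_explained(env$metab_log)
  f_ev <- write_tsv(cbind(feature = rownames(ev$per_feature),
                          as.data.frame(ev$per_feature, check.names = FALSE)),
                    file.path(dir, "qc_explained_variation.tsv"))
  f_evs <- write_tsv(data.frame(term = names(ev$summary),
                                median_ev_pct = as.numeric(ev$summary)),
                     file.path(dir, "qc_explained_variation_summary.tsv"))
  bins <- assign_age_bins(env$metab$sample_meta,
                          target_ages = config$cohort$ages %||% c(12, 24, 36))
  env$bins <- bins
  f_bins <- write_tsv(bins, file.path(dir, "qc_age_bins.tsv"))
  c(f_out, f_ev, f_evs, f_bins)
}

pipeline_contrast_pairs <- function() {
  list(c("P1Ab", "CTRL"), c("PT1D", "CTRL"), c("PT1D", "P1Ab"))
}

stage_contrast <- function(config, env) {
  dir <- config$output_dir
  th <- config$thresholds
  pl <- config$plsda
  ages <- config$cohort$ages %||% c(12, 24, 36)
  meta <- env$metab_log$sample_meta
  fm <- env$metab$feature_meta
  all_rows <- list()
  cseed <- 0L
  bins <- assign_age_bins(meta, ages)
  for (pair in pipeline_contrast_pairs()) {
    for (age in ages) {
      for (k in unique(fm$kind)) {
        subl <- subset_features(env$metab_log, fm$kind == k)
        ctr <- tryCatch(
          two_sample_contrast(subl, pair[1], pair[2], age_bin = age,
                              p_threshold = th$p),
          error = function(e) {
            # a group with < 2 samples in this bin is not testable; skip
            if (grepl("at least 2 samples", conditionMessage(e))) NULL
            else stop(e)
          })
        if (is.null(ctr)) next
        insel <- meta$group %in% pair &
          meta$sample_id %in% bins$sample_id[bins$bin == age]
        X <- subl$values[insel, , drop = FALSE]
        labs <- factor(meta$group[insel], levels = rev(pair))
        cseed <- cseed + 1L
        fit <- plsda_fit(X, labs, n_components = pl$n_components,
                         keep_per_component = pl$keep_per_component)
        auc <- cv_auc(X, labs, n_components = pl$n_components,
                      keep_per_component = pl$keep_per_component,
                      folds = pl$folds, repeats = pl$repeats,
                      seed = derive_seed(config, 10L + cseed))
        res <- select_altered_features(ctr, vip_scores(fit), coef(fit), auc,
                                       thresholds = th)
        res$contrast <- paste(pair, collapse = "_vs_")
        res$age <- age
        res$kind <- k
        all_rows[[length(all_rows) + 1L]] <- res
      }
    }
  }
  contrasts <- do.call(rbind, all_rows)
  env$contrasts <- contrasts
  f_con <- write_tsv(contrasts, file.path(dir, "contrasts.tsv"))
  paired <- list()
  for (g in c("P1Ab", "PT1D")) {
    pc <- paired_seroconversion_contrast(env$metab_log, g)
    pc$group <- g
    paired[[g]] <- pc
  }
  env$paired <- do.call(rbind, paired)
  f_pair <- write_tsv(env$paired, file.path(dir, "paired_seroconversion.tsv"))
  tot <- do.call(rbind, lapply(ages, function(a) {
    an <- group_totals_anova(env$metab_log, a)
    data.frame(age = a, F = an$F, p = an$p, degenerate = an$degenerate)
  }))
  f_tot <- write_tsv(tot, file.path(dir, "totals_anova.tsv"))
  c(f_con, f_pair, f_tot)
}

#' Pathway definitions for the synthetic feature panel
#'
#' Chemical-class-based metabolite sets with a within-class path graph
#' (members in panel order), standing in for a curated pathway database.
#'
#' @param feature_meta the simulator's feature table.
#' @return named list of `pathway_set` objects.
#' @export
synthetic_pathways <- function(feature_meta) {
  cls2pw <- c(TG = "Triacylglycerol metabolism",
              CE = "Cholesterol ester metabolism",
              PC = "Glycerophospholipid metabolism",
              LPC = "Glycerophospholipid metabolism",
              PE = "Glycerophospholipid metabolism",
              PI = "Glycerophospholipid metabolism",
              SM = "Sphingolipid metabolism",
              Cer = "Sphingolipid metabolism",
              HexCer = "Sphingolipid metabolism",
              LacCer = "Sphingolipid metabolism",
              "amino acid" = "Amino acid metabolism",
              "sugar derivative" = "Central carbon metabolism",
              "hydroxy/organic acid" = "Central carbon metabolism",
              "fatty acid" = "Fatty acid biosynthesis",
              polar = "Miscellaneous polar metabolites")
  pw_names <- unique(cls2pw[feature_meta$class])
  sets <- lapply(pw_names, function(nm) {
    members <- feature_meta$feature[cls2pw[feature_meta$class] == nm]
    edges <- if (length(members) > 1)
      data.frame(from = members[-length(members)], to = members[-1],
                 stringsAsFactors = FALSE) else NULL
    pathway_set(nm, members, edges)
  })
  stats::setNames(sets, pw_names)
}

stage_ora <- function(config, env) {
  dir <- config$output_dir
  pathways <- if (!is.null(config$inputs$pathways))
    read_gmt(config$inputs$pathways) else synthetic_pathways(env$metab$feature_meta)
  universe <- unique(unlist(lapply(pathways, `[[`, "members")))
  universe <- intersect(colnames(env$metab$values), universe)
  rows <- list()
  for (key in unique(paste(env$contrasts$contrast, env$contrasts$age))) {
    sub <- env$contrasts[paste(env$contrasts$contrast, env$contrasts$age) == key, ]
    hits <- intersect(sub$feature[sub$basis != "none"], universe)
    res <- hypergeom_ora(hits, pathways, universe,
                         fdr_threshold = config$thresholds$fdr)
    res$contrast <- sub$contrast[1]; res$age <- sub$age[1]
    rows[[key]] <- res
  }
  env$ora <- do.call(rbind, rows)
  rownames(env$ora) <- NULL
  f <- write_tsv(env$ora, file.path(dir, "ora.tsv"))
  f_gmt <- file.path(dir, "pathways.gmt")
  write_gmt(pathways, f_gmt)
  c(f, f_gmt)
}

pipeline_groups <- function() c("CTRL", "P1Ab", "PT1D")

stage_score <- function(config, env) {
  dir <- config$output_dir
  gem <- config$gem
  env$evidence <- list(); env$constrained <- list(); env$scores <- list()
  outs <- character(0)
  for (g in pipeline_groups()) {
    det <- detected_features(env$metab_log, g, age_bin = gem$modelling_age,
                             limit = gem$detection_limit)
    ev <- suppressWarnings(suppressMessages(
      metabolite_evidence_from_metabolomics(env$model, det)))
    con <- exchange_bounds_from_metabolomics(env$model, ev,
                                             default_uptake = gem$default_uptake)
    split <- split_reversible(con)
    sc <- score_reactions(split, env$expr, g, tau = gem$tau,
                          w_max = gem$w_max)
    env$evidence[[g]] <- ev; env$constrained[[g]] <- split
    env$scores[[g]] <- sc
    outs <- c(outs,
              write_tsv(ev, file.path(dir, sprintf("evidence_%s.tsv", g))),
              write_tsv(sc, file.path(dir, sprintf("scores_%s.tsv", g))))
  }
  outs
}

stage_extract <- function(config, env) {
  dir <- config$output_dir
  gem <- config$gem
  env$context <- list()
  outs <- character(0)
  incl <- list()
  for (g in pipeline_groups()) {
    cm <- init_extract(env$constrained[[g]], env$scores[[g]],
                       env$evidence[[g]], eps = gem$eps, big_M = gem$big_M,
                       kappa = gem$kappa, b_max = gem$b_max)
    env$context[[g]] <- cm
    f <- file.path(dir, sprintf("context_%s.sbml", g))
    if (!is.null(cm$model)) write_sbml(cm$model, f)
    outs <- c(outs, f)
    incl[[g]] <- data.frame(group = g,
                            reaction = names(cm$y), included = as.integer(cm$y),
                            weight = env$scores[[g]]$weight[
                              match(names(cm$y), env$scores[[g]]$reaction)],
                            stringsAsFactors = FALSE)
  }
  outs <- c(outs, write_tsv(do.call(rbind, incl),
                            file.path(dir, "inclusion_report.tsv")))
  outs
}

stage_reporters <- function(config, env) {
  dir <- config$output_dir
  rows <- list()
  rseed <- 0L
  for (pair in pipeline_contrast_pairs()) {
    deg <- two_sample_contrast(env$expr_log, pair[1], pair[2])
    gs <- data.frame(gene = deg$feature, p = deg$p, log2FC = deg$log2FC,
                     stringsAsFactors = FALSE)
    for (mode in c("up", "down")) {
      rseed <- rseed + 1L
      z <- gene_zscores(gs, mode = mode)
      rep <- reporter_scores(env$model, z,
                             seed = derive_seed(config, 100L + rseed),
                             mode = mode)
      rep$contrast <- paste(pair, collapse = "_vs_")
      rows[[length(rows) + 1L]] <- rep
    }
  }
  env$reporters <- do.call(rbind, rows)
  write_tsv(env$reporters, file.path(dir, "reporters.tsv"))
}

stage_flux <- function(config, env) {
  dir <- config$output_dir
  cms <- lapply(env$context, `[[`, "model")
  env$flux_table <- optimize_glycoceramide_production(cms, template = env$model)
  f1 <- write_tsv(env$flux_table, file.path(dir, "flux_objectives.tsv"))
  # subsystem response to switching the glucosylceramide objective on, in the
  # group whose context model can produce it
  outs <- f1
  pt <- cms[["PT1D"]]
  if (!is.null(pt)) {
    tmpl <- env$model
    add_dm <- function(mdl, objctv) {
      if (objctv %in% mdl$rxns$id) return(mdl)
      met <- names(tmpl$stoich[[objctv]])
      if (!all(met %in% mdl$mets$id)) return(NULL)
      metabolic_model(mdl$mets,
                      rbind(mdl$rxns, tmpl$rxns[tmpl$rxns$id == objctv, ]),
                      c(mdl$stoich, stats::setNames(tmpl$stoich[objctv], objctv)),
                      id = mdl$id, currency = model_currency(mdl))
    }
    ptd <- add_dm(pt, "glcCer_demand")
    if (!is.null(ptd)) {
      # objective off = quiescent parsimonious state, on = maximal production
      off <- fba(ptd, "glcCer_demand", sense = "min")
      on <- fba(ptd, "glcCer_demand")
      if (off$status == "optimal" && on$status == "optimal") {
        deltas <- subsystem_flux_deltas(off, on, ptd)
        deltas$comparison <- "PT1D: glcCer objective on vs off"
        outs <- c(outs, write_tsv(deltas, file.path(dir, "subsystem_deltas.tsv")))
      }
    }
  }
  outs
}
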