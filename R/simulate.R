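# Synthetic cohort and omics generators with planted ground truth. The
# defaults emulate the structure of a longitudinal PBMC metabolomics cohort:
# three clinical groups (autoantibody-negative controls CTRL, seroconverted
# non-progressors P1Ab, progressors to type 1 diabetes PT1D), samples at 12,
# 24 and 36 months of age, ~150 lipid and ~70 polar-metabolite features, and
# an expression cohort covering the toy network's genes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort design with per-subject seroconversion ages
#'
#' Seroconversion ages are drawn log-normally so that the P1Ab median is
#' about 24 months and the PT1D median about 14 months, enabling paired
#' before/after contrasts; controls never seroconvert.
#'
#' @param group_sizes named vector of subjects per group.
#' @param ages sampling ages in months (strictly increasing).
#' @param missingness_rate fraction of subject-by-age samples absent
#'   (in `[0, 0.5)`).
#' @param seed RNG seed for the seroconversion-age and sex draws.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(CTRL = 10, P1Ab = 27, PT1D = 34),
                          ages = c(12, 24, 36),
                          missingness_rate = 0.35, seed = 1L) {
  if (any(group_sizes < 2)) stop("each group needs at least 2 subjects")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  if (missingness_rate < 0 || missingness_rate >= 0.5)
    stop("missingness_rate must be in [0, 0.5)")
  subjects <- with_seed(seed, {
    rows <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      sero <- switch(g,
        CTRL = rep(NA_real_, n),
        P1Ab = pmin(pmax(round(exp(stats::rnorm(n, log(24), 0.6))), 3), 48),
        PT1D = pmin(pmax(round(exp(stats::rnorm(n, log(14), 0.35))), 3), 36),
        rep(NA_real_, n))
      data.frame(subject = sprintf("%s_%02d", g, seq_len(n)), group = g,
                 sex = sample(c("M", "F"), n, replace = TRUE),
                 seroconversion_age = sero, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  structure(list(group_sizes = group_sizes, ages = ages,
                 missingness_rate = missingness_rate, seed = seed,
                 subjects = subjects),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", nrow(x$subjects), " subjects (",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "), ages ", paste(x$ages, collapse = "/"),
      " months, missingness ", x$missingness_rate, "\n", sep = "")
  invisible(x)
}

#' Samples-by-features intensity container
#'
#' @param values numeric matrix of non-negative raw intensities, samples in
#'   rows, features in columns.
#' @param sample_meta data.frame aligned 1:1 with rows (subject, group,
#'   age_months, ...).
#' @param feature_meta data.frame aligned with columns (feature, class, ...).
#' @return object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, sample_meta, feature_meta = NULL) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("raw intensities must be non-negative")
  if (nrow(values) != nrow(sample_meta))
    stop("sample_meta rows must align with value rows")
  if (!is.null(feature_meta) && ncol(values) != nrow(feature_meta))
    stop("feature_meta rows must align with value columns")
  structure(list(values = values, sample_meta = sample_meta,
                 feature_meta = feature_meta),
            class = "omics_matrix")
}

#' Restrict an omics matrix to a subset of features
#'
#' Keeps sample metadata and scale attributes (e.g. the log2 flag).
#'
#' @param om an `omics_matrix`.
#' @param sel logical/integer/character feature selector.
#' @return an `omics_matrix`.
#' @export
subset_features <- function(om, sel) {
  out <- om
  out$values <- om$values[, sel, drop = FALSE]
  if (!is.null(om$feature_meta)) {
    idx <- if (is.character(sel)) match(sel, om$feature_meta$feature) else sel
    out$feature_meta <- om$feature_meta[idx, , drop = FALSE]
  }
  out
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("<omics_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  invisible(x)
}

DETECTION_LIMIT_LOG2 <- 6

#' Default planted group-by-age effects for the metabolomics simulator
#'
#' Encodes the qualitative ground truth the pipeline is expected to recover:
#' a long-chain ceramide persistently decreased in progressors, glycoceramides
#' (hexosyl- and lactosylceramides) increased in progressors at 36 months, and
#' a broad early (12-month) decrease of lipids and polar metabolites in both
#' seroconverted groups, with a transient increase at 24 months.
#'
#' @param feature_meta feature table from [simulate_metabolomics()]'s internal
#'   panel (used to pick the bulk-effect features).
#' @param bulk_fraction fraction of features carrying the early bulk decrease.
#' @param seed seed for the bulk-feature draw.
#' @return data.frame (feature, group, age, log2_effect); `age = NA` means
#'   all ages.
#' @export
default_planted_effects <- function(feature_meta, bulk_fraction = 0.6, seed = 100L) {
  specials <- c("Cer(d18:1/24:0)", "Cer(d18:1/22:0)",
                "HexCer(d18:1/16:0)", "HexCer(d18:1/22:0)", "HexCer(d18:1/24:0)",
                "LacCer(d18:1/12:0)", "LacCer(d18:1/14:0)", "LacCer(d18:1/16:0)")
  eff <- rbind(
    data.frame(feature = "Cer(d18:1/24:0)", group = "PT1D", age = NA_real_,
               log2_effect = -0.8),
    data.frame(feature = "Cer(d18:1/22:0)", group = "PT1D", age = 36,
               log2_effect = -0.6),
    data.frame(feature = c("HexCer(d18:1/16:0)", "HexCer(d18:1/22:0)",
                           "LacCer(d18:1/16:0)"),
               group = "PT1D", age = 36, log2_effect = 1.0))
  bulk <- with_seed(seed, {
    pool <- setdiff(feature_meta$feature, specials)
    sort(sample(pool, round(bulk_fraction * length(pool))))
  })
  rbind(eff,
        data.frame(feature = rep(bulk, 2),
                   group = rep(c("P1Ab", "PT1D"), each = length(bulk)),
                   age = 12, log2_effect = -0.4),
        data.frame(feature = rep(bulk, 2),
                   group = rep(c("P1Ab", "PT1D"), each = length(bulk)),
                   age = 24, log2_effect = 0.3))
}

# Feature panel: ~150 lipid species across the major measured classes plus
# ~70 polar metabolites. Glycoceramides are low-abundance species sitting
# near the detection limit; everything else is comfortably above it.
metabolomics_panel <- function(seed) {
  lipid_classes <- c(TG = 40, PC = 30, LPC = 10, PE = 15, PI = 8, SM = 12,
                     Cer = 10, CE = 17)
  lip <- list()
  with_seed(seed, {
    for (cl in names(lipid_classes)) {
      n <- lipid_classes[[cl]]
      carb <- sample(30:58, n, replace = TRUE)
      dbl <- sample(0:6, n, replace = TRUE)
      nm <- if (cl %in% c("Cer", "SM")) {
        acyl <- sample(c(14, 16, 18, 20, 22, 24), n, replace = TRUE)
        sat <- sample(0:1, n, replace = TRUE)
        sprintf("%s(d18:1/%d:%d)", cl, acyl, sat)
      } else sprintf("%s(%d:%d)", cl, carb, dbl)
      nm <- make.unique(nm, sep = "#")
      lip[[cl]] <- data.frame(feature = nm, class = cl, kind = "lipid",
                              stringsAsFactors = FALSE)
    }
  })
  lip <- do.call(rbind, lip)
  # guarantee the named sentinel species exist exactly once
  sentinels <- data.frame(
    feature = c("Cer(d18:1/24:0)", "Cer(d18:1/22:0)",
                "HexCer(d18:1/16:0)", "HexCer(d18:1/22:0)", "HexCer(d18:1/24:0)",
                "LacCer(d18:1/12:0)", "LacCer(d18:1/14:0)", "LacCer(d18:1/16:0)"),
    class = c("Cer", "Cer", rep("HexCer", 3), rep("LacCer", 3)),
    kind = "lipid", stringsAsFactors = FALSE)
  lip <- lip[!(lip$feature %in% sentinels$feature), , drop = FALSE]
  lip <- rbind(sentinels, lip[seq_len(min(nrow(lip), 150 - nrow(sentinels))), ])
  polar_names <- c(
    "alanine", "glycine", "serine", "threonine", "valine", "leucine",
    "isoleucine", "proline", "phenylalanine", "tyrosine", "tryptophan",
    "methionine", "cysteine", "cystine", "lysine", "histidine", "arginine",
    "glutamine", "asparagine", "glutamic acid", "aspartic acid",
    "glucose", "galactose", "fructose", "mannose", "ribose", "myo-inositol",
    "sucrose", "maltose", "glycerol", "glycerol-3-phosphate",
    "lactic acid", "pyruvic acid", "citric acid", "succinic acid",
    "fumaric acid", "malic acid", "alpha-ketoglutaric acid", "oxalic acid",
    "glycolic acid", "3-hydroxybutyric acid", "2-hydroxybutyric acid",
    "stearic acid", "palmitic acid", "myristic acid", "oleic acid",
    "linoleic acid", "arachidonic acid", "cholesterol", "urea",
    "creatinine", "uric acid", "hypoxanthine", "xanthine", "inosine",
    "uridine", "taurine", "putrescine", "ornithine", "citrulline",
    "phosphoric acid", "ethanolamine", "phosphoethanolamine", "niacinamide",
    "pantothenic acid", "ascorbic acid", "benzoic acid", "hippuric acid",
    "4-hydroxyphenyllactic acid", "indole-3-lactic acid")
  polar_class <- rep("polar", length(polar_names))
  polar_class[1:21] <- "amino acid"
  polar_class[22:31] <- "sugar derivative"
  polar_class[32:42] <- "hydroxy/organic acid"
  polar_class[43:49] <- "fatty acid"
  polar <- data.frame(feature = polar_names, class = polar_class,
                      kind = "polar", stringsAsFactors = FALSE)
  fm <- rbind(lip, polar)
  with_seed(seed + 1L, {
    base <- ifelse(fm$kind == "lipid", stats::rnorm(nrow(fm), 10, 1.5),
                   stats::rnorm(nrow(fm), 9, 1.5))
    # glycoceramides sit just under the detection limit at baseline
    glyco <- fm$class %in% c("HexCer", "LacCer")
    base[glyco] <- DETECTION_LIMIT_LOG2 - 0.6
    fm$baseline_log2 <- base
    fm$age_slope_log2 <- stats::rnorm(nrow(fm), 0, 0.1)
  })
  fm
}

#' Simulate a longitudinal cohort metabolomics matrix with planted effects
#'
#' Intensities are generated on the log2 scale -- feature baseline + a linear
#' age trend + subject random intercept + planted group-by-age effects +
#' residual noise -- and exponentiated, so raw values are positive. Whole
#' subject-by-age samples are removed at the design's missingness rate.
#'
#' @param design a [cohort_design()].
#' @param effects planted effect registry (feature, group, age, log2_effect);
#'   `NULL` for the defaults, `data.frame()` for a null dataset.
#' @param sero_effects optional post-seroconversion effects
#'   (feature, group, log2_effect) applied to samples taken after the
#'   subject's seroconversion age.
#' @param noise_sd residual sd on the log2 scale.
#' @param subject_sd subject random-intercept sd on the log2 scale.
#' @param extra_null_features append this many pure-noise features (class
#'   `"null"`), e.g. for calibration studies.
#' @param seed RNG seed.
#' @return an `omics_matrix`; the planted registry is attached as attribute
#'   `"effects"` (and `"sero_effects"`).
#' @export
simulate_metabolomics <- function(design, effects = NULL, sero_effects = NULL,
                                  noise_sd = 0.5, subject_sd = 0.3,
                                  extra_null_features = 0L, seed = 1L) {
  fm <- metabolomics_panel(seed = 1000L)  # fixed panel; cohort seed varies data
  if (extra_null_features > 0) {
    nf <- with_seed(1001L, data.frame(
      feature = sprintf("null_%04d", seq_len(extra_null_features)),
      class = "null", kind = "null",
      baseline_log2 = stats::rnorm(extra_null_features, 9.5, 1.5),
      age_slope_log2 = 0, stringsAsFactors = FALSE))
    fm <- rbind(fm, nf)
  }
  if (is.null(effects)) effects <- default_planted_effects(fm)
  if (is.null(sero_effects))
    sero_effects <- data.frame(
      feature = c("glutamic acid", "serine"), group = c("P1Ab", "PT1D"),
      log2_effect = c(-0.5, -0.4), stringsAsFactors = FALSE)
  unknown <- setdiff(effects$feature, fm$feature)
  if (length(unknown)) stop("planted effect on unknown feature(s): ",
                            paste(unknown, collapse = ", "))
  sub <- design$subjects
  grid <- expand.grid(subject = sub$subject, age_months = design$ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$age_months), , drop = FALSE]
  grid <- merge(grid, sub, by = "subject", sort = FALSE)
  with_seed(seed, {
    if (design$missingness_rate > 0) {
      keep <- stats::runif(nrow(grid)) >= design$missingness_rate
      grid <- grid[keep, , drop = FALSE]
    }
    grid$sample_id <- sprintf("%s_m%02d", grid$subject, grid$age_months)
    rownames(grid) <- NULL
    intercepts <- stats::setNames(stats::rnorm(nrow(sub), 0, subject_sd), sub$subject)
    nS <- nrow(grid); nF <- nrow(fm)
    logv <- matrix(rep(fm$baseline_log2, each = nS), nS, nF) +
      outer((grid$age_months - design$ages[1]) / 12, fm$age_slope_log2) +
      matrix(intercepts[grid$subject], nS, nF) +
      matrix(stats::rnorm(nS * nF, 0, noise_sd), nS, nF)
    colnames(logv) <- fm$feature
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      rows <- grid$group == e$group &
        (is.na(e$age) | grid$age_months == e$age)
      logv[rows, e$feature] <- logv[rows, e$feature] + e$log2_effect
    }
    if (nrow(sero_effects)) for (k in seq_len(nrow(sero_effects))) {
      e <- sero_effects[k, ]
      rows <- grid$group == e$group & !is.na(grid$seroconversion_age) &
        grid$age_months > grid$seroconversion_age
      logv[rows, e$feature] <- logv[rows, e$feature] + e$log2_effect
    }
    om <- omics_matrix(2^logv, grid[, c("sample_id", "subject", "group", "sex",
                                        "age_months", "seroconversion_age")], fm)
    attr(om, "effects") <- effects
    attr(om, "sero_effects") <- sero_effects
    om
  })
}

#' Default expression-cohort design
#'
#' One array per subject; sizes follow the transcriptomics meta-analysis
#' cohort structure (15 non-progressors, 51 progressors, controls set to 15).
#'
#' @inheritParams cohort_design
#' @export
expression_design <- function(group_sizes = c(CTRL = 15, P1Ab = 15, PT1D = 51),
                              seed = 2L) {
  cohort_design(group_sizes = group_sizes, ages = c(0, 1),
                missingness_rate = 0, seed = seed)
}

#' Simulate a gene-expression matrix over a model's genes
#'
#' Log-normal baseline per gene with planted multiplicative group effects;
#' the default plants a two-fold up-regulation of the glucosylceramide
#' synthase gene in progressors (PT1D).
#'
#' @param model a `metabolic_model` supplying the gene universe.
#' @param design a [cohort_design()] / [expression_design()]; one sample per
#'   subject is generated.
#' @param effects data.frame (gene, group, log2_effect); `NULL` for the
#'   default GCS-doubling, `data.frame()` for none.
#' @param baseline_shift optional named per-gene shift (log2) of the baseline
#'   mean, e.g. to make a pathway branch lowly expressed.
#' @param baseline_mean,baseline_sd log2 baseline distribution across genes.
#' @param noise_sd per-sample residual sd (log2).
#' @param seed RNG seed.
#' @return an `omics_matrix` (samples x genes) with the planted registry in
#'   attribute `"effects"`.
#' @export
simulate_expression <- function(model, design = expression_design(),
                                effects = NULL, baseline_shift = NULL,
                                baseline_mean = 7, baseline_sd = 0.6,
                                noise_sd = 0.5, seed = 1L) {
  genes <- model$genes
  if (is.null(effects))
    effects <- data.frame(gene = "g_GCS", group = "PT1D", log2_effect = 1,
                          stringsAsFactors = FALSE)
  unknown <- setdiff(effects$gene, genes)
  if (length(unknown)) stop("planted effect on unknown gene(s): ",
                            paste(unknown, collapse = ", "))
  sub <- design$subjects
  with_seed(seed, {
    base <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
    names(base) <- genes
    if (!is.null(baseline_shift)) {
      unknown <- setdiff(names(baseline_shift), genes)
      if (length(unknown)) stop("baseline_shift for unknown gene(s): ",
                                paste(unknown, collapse = ", "))
      base[names(baseline_shift)] <- base[names(baseline_shift)] + baseline_shift
    }
    logv <- matrix(rep(base, each = nrow(sub)), nrow(sub), length(genes),
                   dimnames = list(sub$subject, genes)) +
      matrix(stats::rnorm(nrow(sub) * length(genes), 0, noise_sd),
             nrow(sub), length(genes))
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      logv[sub$group == e$group, e$gene] <-
        logv[sub$group == e$group, e$gene] + e$log2_effect
    }
    meta <- data.frame(sample_id = sub$subject, subject = sub$subject,
                       group = sub$group, sex = sub$sex,
                       age_months = NA_real_,
                       seroconversion_age = sub$seroconversion_age,
                       stringsAsFactors = FALSE)
    om <- omics_matrix(2^logv, meta,
                       data.frame(feature = genes, class = "gene",
                                  kind = "expression",
                                  stringsAsFactors = FALSE))
    attr(om, "effects") <- effects
    om
  })
}

#' Random small metabolic network for solver validation
#'
#' Generates an irreversible toy network of at most `n_rxns` reactions:
#' an uptake source, a chain/branch structure over random metabolites and at
#' least one sink. Intended as input for comparing the INIT extraction against
#' exhaustive enumeration; some reactions may be blocked by construction,
#' which the enumeration must handle.
#'
#' @param n_rxns number of reactions (3-12).
#' @param seed RNG seed.
#' @return a `metabolic_model`.
#' @export
random_toy_network <- function(n_rxns, seed) {
  stopifnot(n_rxns >= 3, n_rxns <= 12)
  with_seed(seed, {
    mets <- "m1"
    rxns <- list(); stoich <- list()
    add <- function(id, st) {
      rxns[[length(rxns) + 1L]] <<- data.frame(
        id = id, name = id, lb = 0, ub = 10, reversible = FALSE, gpr = "",
        subsystem = "toy", stringsAsFactors = FALSE)
      stoich[[id]] <<- st
    }
    add("r1", c(m1 = 1))  # uptake/source
    for (k in 2:(n_rxns - 1L)) {
      from <- sample(mets, 1)
      kind <- sample(c("new", "link", "sink"), 1, prob = c(0.5, 0.25, 0.25))
      if (kind == "new" || length(mets) < 2) {
        newm <- paste0("m", length(mets) + 1L)
        mets <- c(mets, newm)
        add(paste0("r", k), stats::setNames(c(-1, 1), c(from, newm)))
      } else if (kind == "link") {
        to <- sample(setdiff(mets, from), 1)
        add(paste0("r", k), stats::setNames(c(-1, 1), c(from, to)))
      } else {
        add(paste0("r", k), stats::setNames(-1, from))
      }
    }
    add(paste0("r", n_rxns), stats::setNames(-1, sample(mets, 1)))  # final sink
    met_df <- data.frame(id = mets, name = mets, compartment = "c",
                         stringsAsFactors = FALSE)
    metabolic_model(met_df, do.call(rbind, rxns), stoich,
                    id = sprintf("random_net_%d", seed))
  })
}
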