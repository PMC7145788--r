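# Univariate statistics on omics matrices: normalization, age binning, PCA
# outlier screening, explained variation, group and paired contrasts,
# correlation maps and FDR control.

is_log2 <- function(om) isTRUE(attr(om, "log2"))

#' Log2-transform an intensity matrix
#'
#' @param om an `omics_matrix` of raw intensities.
#' @param offset added before taking logs so zeros stay finite.
#' @return an `omics_matrix` on the log2 scale (attribute `"log2"` set).
#' @export
log2_normalize <- function(om, offset = 1) {
  if (any(om$values < 0, na.rm = TRUE)) stop("negative intensities")
  out <- om
  out$values <- log2(om$values + offset)
  attr(out, "log2") <- TRUE
  out
}

require_log2 <- function(om) {
  if (!is_log2(om)) stop("this operation expects log2-normalized data; ",
                         "call log2_normalize() first")
  invisible(om)
}

#' Assign samples to target age bins
#'
#' Each sample is mapped to the nearest target age within `window` months
#' (otherwise dropped). When several samples of the same subject fall into
#' one bin, the closest is kept; ties keep the earlier sample.
#'
#' @param sample_meta data.frame with `sample_id`, `subject`, `age_months`.
#' @param target_ages sorted target ages (months).
#' @param window half-width of the matching interval (months).
#' @return data.frame (sample_id, subject, age_months, bin) of retained samples.
#' @export
assign_age_bins <- function(sample_meta, target_ages = c(12, 24, 36), window = 6) {
  if (is.unsorted(target_ages)) stop("target_ages must be sorted")
  d <- abs(outer(sample_meta$age_months, target_ages, "-"))
  nearest <- apply(d, 1, which.min)
  dist <- d[cbind(seq_len(nrow(d)), nearest)]
  keep <- dist <= window
  out <- data.frame(sample_id = sample_meta$sample_id,
                    subject = sample_meta$subject,
                    age_months = sample_meta$age_months,
                    bin = target_ages[nearest],
                    dist = dist, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # per subject x bin keep the closest sample; ties -> earlier age
  out <- out[order(out$subject, out$bin, out$dist, out$age_months), , drop = FALSE]
  out <- out[!duplicated(out[, c("subject", "bin")]), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("sample_id", "subject", "age_months", "bin")]
}

#' PCA-based sample homogeneity check
#'
#' Scores samples on the first `n_components` principal components of the
#' column-centered matrix and flags those outside the Hotelling T-squared
#' ellipse at the given confidence level.
#'
#' @param om an `omics_matrix` (any scale).
#' @param n_components number of score dimensions.
#' @param confidence confidence level of the ellipse (1 flags nothing).
#' @return character vector of flagged sample ids.
#' @export
pca_outlier_check <- function(om, n_components = 2, confidence = 0.95) {
  X <- om$values
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (n_components >= n) stop("fewer samples than components")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  a <- sum(pc$sdev[seq_len(n_components)] > 1e-12)
  if (a == 0) return(character(0))
  scores <- pc$x[, seq_len(a), drop = FALSE]
  lambda <- pc$sdev[seq_len(a)]^2
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  crit <- a * (n - 1) / (n - a) * stats::qf(confidence, a, n - a)
  om$sample_meta$sample_id[t2 > crit]
}

#' Explained variation of clinical covariates per feature
#'
#' Fits, per feature, a linear model on age, sex and clinical group plus
#' their pairwise interactions, and reports each term's sequential
#' (type I) sum of squares as a percentage of the total.
#'
#' @param om a log2-normalized `omics_matrix`.
#' @param covariates main effects to include (subset of age, sex, group).
#' @param interactions include pairwise interactions (default TRUE).
#' @return list with `per_feature` (features x terms EV%% matrix) and
#'   `summary` (median EV%% per term).
#' @export
variance_explained <- function(om, covariates = c("age", "sex", "group"),
                               interactions = TRUE) {
  require_log2(om)
  meta <- om$sample_meta
  df <- data.frame(age = meta$age_months,
                   sex = factor(meta$sex),
                   group = factor(meta$group))[, covariates, drop = FALSE]
  terms <- covariates
  if (interactions && length(covariates) > 1)
    terms <- c(terms, utils::combn(covariates, 2, paste, collapse = ":"))
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  # drop constant covariates (rank-deficient design) with a warning
  const <- vapply(df, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(df)[const], collapse = ", "))
    keep <- !const
    return(variance_explained_inner(om, df[, keep, drop = FALSE],
                                    covariates[keep], interactions))
  }
  variance_explained_inner(om, df, covariates, interactions)
}

variance_explained_inner <- function(om, df, covariates, interactions) {
  terms <- covariates
  if (interactions && length(covariates) > 1)
    terms <- c(terms, utils::combn(covariates, 2, paste, collapse = ":"))
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  feats <- colnames(om$values)
  ev <- matrix(0, length(feats), length(terms),
               dimnames = list(feats, terms))
  for (j in seq_along(feats)) {
    dat <- cbind(y = om$values[, j], df)
    fit <- stats::lm(form, data = dat)
    an <- stats::anova(fit)
    ss <- an[["Sum Sq"]]
    tot <- sum(ss)
    rows <- rownames(an)
    for (t in terms) {
      i <- match(t, rows)
      if (is.na(i)) i <- match(paste(rev(strsplit(t, ":")[[1]]), collapse = ":"), rows)
      if (!is.na(i) && tot > 0) ev[j, t] <- 100 * ss[i] / tot
    }
  }
  list(per_feature = ev, summary = apply(ev, 2, stats::median))
}

# Vectorized two-sample Welch/Student t statistics over matrix columns.
col_t_test <- function(A, B, var_equal = FALSE) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  if (var_equal) {
    sp <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(mA))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  t <- (mA - mB) / se
  degenerate <- !is.finite(se) | se == 0
  t[degenerate & (mA == mB)] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate variance: equal values give p = 1 with a flag, not NaN
  p[degenerate] <- ifelse(mA[degenerate] == mB[degenerate], 1, 0)
  list(estimate = mA - mB, t = t, p = p, df = df, degenerate = degenerate)
}

#' Unpaired two-group contrast per feature
#'
#' Welch (default) or Student two-sample t test on log2 data within one age
#' bin; log2 fold change is mean(A) minus mean(B) (first-named group minus
#' second). Benjamini-Hochberg FDR is computed across features; the
#' univariate selection flag is `p < p_threshold`.
#'
#' @param om a log2-normalized `omics_matrix`.
#' @param groupA,groupB group labels to compare (A minus B).
#' @param age_bin restrict to samples of this age bin (NULL for all); samples
#'   are binned with [assign_age_bins()] when `age_bin` is given.
#' @param var_equal use the pooled-variance Student test.
#' @param p_threshold univariate selection threshold.
#' @return a `contrast_result` data.frame: feature, log2FC, t_stat, p, fdr,
#'   selected_uni, degenerate.
#' @export
two_sample_contrast <- function(om, groupA, groupB, age_bin = NULL,
                                var_equal = FALSE, p_threshold = 0.05) {
  require_log2(om)
  meta <- om$sample_meta
  sel <- meta$group %in% c(groupA, groupB)
  if (!is.null(age_bin)) {
    bins <- assign_age_bins(meta)
    ids <- bins$sample_id[bins$bin == age_bin]
    sel <- sel & meta$sample_id %in% ids
  }
  ga <- sel & meta$group == groupA
  gb <- sel & meta$group == groupB
  if (sum(ga) < 2 || sum(gb) < 2)
    stop("need at least 2 samples per group (", groupA, ": ", sum(ga), ", ",
         groupB, ": ", sum(gb), ")")
  tt <- col_t_test(om$values[ga, , drop = FALSE], om$values[gb, , drop = FALSE],
                   var_equal = var_equal)
  res <- data.frame(feature = colnames(om$values), log2FC = tt$estimate,
                    t_stat = tt$t, p = tt$p, fdr = bh_fdr(tt$p),
                    selected_uni = tt$p < p_threshold,
                    degenerate = tt$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("contrast_result", "data.frame"),
            contrast = c(groupA = groupA, groupB = groupB),
            age_bin = age_bin, n = c(sum(ga), sum(gb)))
}

#' Paired before/after-seroconversion contrast
#'
#' For each subject of the given group with at least one sample before and
#' one at/after their seroconversion age, the per-side means are compared by
#' a paired t test per feature (after minus before). Subjects lacking either
#' side are excluded and reported in the `excluded` attribute.
#'
#' @param om a log2-normalized `omics_matrix`.
#' @param group group label (P1Ab or PT1D).
#' @return a `contrast_result` data.frame (log2FC = mean paired difference).
#' @export
paired_seroconversion_contrast <- function(om, group) {
  require_log2(om)
  meta <- om$sample_meta
  sel <- meta$group == group & !is.na(meta$seroconversion_age)
  subs <- unique(meta$subject[sel])
  before <- list(); after <- list(); excluded <- character(0)
  for (s in subs) {
    rows <- which(meta$subject == s & sel)
    pre <- rows[meta$age_months[rows] < meta$seroconversion_age[rows]]
    post <- rows[meta$age_months[rows] >= meta$seroconversion_age[rows]]
    if (!length(pre) || !length(post)) { excluded <- c(excluded, s); next }
    before[[s]] <- colMeans(om$values[pre, , drop = FALSE])
    after[[s]] <- colMeans(om$values[post, , drop = FALSE])
  }
  if (length(before) < 2)
    stop("fewer than 2 subjects with samples on both sides of seroconversion")
  D <- do.call(rbind, after) - do.call(rbind, before)
  n <- nrow(D)
  m <- colMeans(D); se <- apply(D, 2, stats::sd) / sqrt(n)
  t <- m / se
  degenerate <- !is.finite(se) | se == 0
  t[degenerate & m == 0] <- 0
  p <- 2 * stats::pt(-abs(t), n - 1)
  p[degenerate] <- ifelse(m[degenerate] == 0, 1, 0)
  res <- data.frame(feature = colnames(om$values), log2FC = m, t_stat = t,
                    p = p, fdr = bh_fdr(p), selected_uni = p < 0.05,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("contrast_result", "data.frame"),
            contrast = c(group = group, comparison = "after_vs_before"),
            n_subjects = n, excluded = excluded)
}

#' One-way ANOVA of total signal across groups within an age bin
#'
#' @param om a log2-normalized `omics_matrix`.
#' @param age_bin age bin (months).
#' @param total `"log2"` sums the log2 intensities per sample, `"raw"` sums
#'   raw intensities.
#' @return list with `F`, `p`, `df`, per-group means and a `degenerate` flag
#'   (all totals equal gives p = 1).
#' @export
group_totals_anova <- function(om, age_bin, total = c("log2", "raw")) {
  total <- match.arg(total)
  require_log2(om)
  meta <- om$sample_meta
  bins <- assign_age_bins(meta)
  ids <- bins$sample_id[bins$bin == age_bin]
  sel <- meta$sample_id %in% ids
  groups <- factor(meta$group[sel])
  if (nlevels(groups) < 2) stop("need at least 2 groups in the bin")
  tot <- if (total == "log2") rowSums(om$values[sel, , drop = FALSE])
         else rowSums(2^om$values[sel, , drop = FALSE] - 1)
  if (stats::var(tot) == 0)
    return(list(F = NA_real_, p = 1, df = c(nlevels(groups) - 1,
                                            length(tot) - nlevels(groups)),
                group_means = tapply(tot, groups, mean), degenerate = TRUE))
  an <- stats::anova(stats::lm(tot ~ groups))
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       df = an$Df, group_means = tapply(tot, groups, mean), degenerate = FALSE)
}

#' Spearman correlation map between two paired matrices
#'
#' Rank correlation (average ranks on ties) for every pair of features of two
#' matrices whose samples are paired (e.g. cellular vs plasma levels of the
#' same subjects and ages). P values use the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param omA,omB `omics_matrix` objects.
#' @param pairing two-column data.frame (sample ids in A, sample ids in B)
#'   defining the pairing; `NULL` pairs by identical sample ids.
#' @param rho_threshold,p_threshold significance mask thresholds.
#' @return list with matrices `rho`, `p` and logical `significant`
#'   (featureA x featureB).
#' @export
spearman_map <- function(omA, omB, pairing = NULL,
                         rho_threshold = 0.70, p_threshold = 0.05) {
  if (is.null(pairing)) {
    common <- intersect(omA$sample_meta$sample_id, omB$sample_meta$sample_id)
    pairing <- data.frame(A = common, B = common, stringsAsFactors = FALSE)
  }
  n <- nrow(pairing)
  if (n < 4) stop("need at least 4 paired samples")
  ia <- match(pairing[[1]], omA$sample_meta$sample_id)
  ib <- match(pairing[[2]], omB$sample_meta$sample_id)
  XA <- apply(omA$values[ia, , drop = FALSE], 2, rank)
  XB <- apply(omB$values[ib, , drop = FALSE], 2, rank)
  rho <- stats::cor(XA, XB)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p, significant = rho > rho_threshold & p < p_threshold)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
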