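# Normalization, binning, QC, contrasts, correlations and FDR control.

null_omics <- function(n, p, seed = 1, groups = c("A", "B")) {
  with_seed <- get("with_seed", asNamespace("immunogem"))
  with_seed(seed, {
    vals <- 2^matrix(rnorm(n * p, 10, 1), n, p,
                     dimnames = list(NULL, paste0("f", seq_len(p))))
    meta <- data.frame(sample_id = paste0("s", seq_len(n)),
                       subject = paste0("s", seq_len(n)),
                       group = rep(groups, length.out = n),
                       sex = rep(c("M", "F"), length.out = n),
                       age_months = 12,
                       seroconversion_age = NA_real_)
    omics_matrix(vals, meta)
  })
}

test_that("log2 normalization maps intensities as specified", {
  om <- null_omics(4, 3)
  om$values[1, 1] <- 0
  om$values[2, 1] <- 7
  l <- log2_normalize(om, offset = 1)
  expect_equal(unname(l$values[1, 1]), 0)
  expect_equal(unname(l$values[2, 1]), 3)
  # monotone on every column
  expect_true(all(apply(om$values, 2, order) == apply(l$values, 2, order)))
  om$values[1, 1] <- -1
  expect_error(log2_normalize(om), "negative")
})

test_that("age-bin assignment picks nearest bins, drops strays, keeps closest per child", {
  meta <- data.frame(sample_id = c("a13", "b11", "b13", "c45"),
                     subject = c("A", "B", "B", "C"),
                     age_months = c(13, 11, 13, 45))
  bins <- assign_age_bins(meta, c(12, 24, 36), window = 6)
  expect_equal(bins$bin[bins$sample_id == "a13"], 12)
  # tie at distance 1: earlier sample kept
  expect_equal(bins$sample_id[bins$subject == "B"], "b11")
  # outside every window (the +/-6 windows tile 6..42 months)
  expect_false("c45" %in% bins$sample_id)
})

test_that("PCA outlier check flags a constructed outlier and nothing else", {
  # identical samples -> no structure, no flags
  om <- null_omics(50, 20, seed = 3)
  om$values[] <- 2^10
  expect_length(pca_outlier_check(om), 0)
  # homogeneous jitter -> at most the nominal ~5% of samples flagged
  om$values[] <- 2^(10 + matrix(rnorm(50 * 20, 0, 0.01), 50))
  expect_lte(length(pca_outlier_check(om)), 5)
  # displace one sample 20 pooled sds along the feature-mean direction
  om2 <- null_omics(50, 20, seed = 4)
  l <- log2(om2$values)
  l[7, ] <- l[7, ] + 20 * mean(apply(l, 2, sd))
  om2$values <- 2^l
  flagged <- pca_outlier_check(om2)
  expect_true(om2$sample_meta$sample_id[7] %in% flagged)
  expect_lte(length(flagged), 3)
  # confidence 1 flags nothing
  expect_length(pca_outlier_check(om2, confidence = 1), 0)
  expect_error(pca_outlier_check(null_omics(2, 5)), "at least 3")
})

test_that("explained variation decomposes as sequential sums of squares", {
  n <- 120
  meta <- data.frame(sample_id = paste0("s", 1:n), subject = paste0("s", 1:n),
                     group = rep(c("CTRL", "P1Ab", "PT1D"), length.out = n),
                     sex = rep(c("M", "F"), length.out = n),
                     age_months = rep(c(12, 24, 36), each = n / 3),
                     seroconversion_age = NA_real_)
  vals <- cbind(age_feature = meta$age_months,
                noise = rnorm(n, 10))
  om <- omics_matrix(2^vals, meta,
                     data.frame(feature = colnames(vals), class = "x", kind = "x"))
  oml <- log2_normalize(om, offset = 0)
  # the age-identical feature triggers R's perfect-fit ANOVA warning
  ev <- suppressWarnings(variance_explained(oml))
  # a feature identical to age is fully explained by age
  expect_equal(unname(ev$per_feature["age_feature", "age"]), 100, tolerance = 1e-8)
  expect_true(all(rowSums(ev$per_feature) <= 100 + 1e-8))
  # a pure-noise feature at n = 120 leaves every term small
  expect_true(all(ev$per_feature["noise", ] < 8))
})

test_that("two-sample contrast matches t.test and behaves under symmetry", {
  om <- null_omics(6, 1, seed = 5)
  l <- log2_normalize(om, offset = 0)
  l$values[, 1] <- c(1, 2, 3, 4, 5, 6)
  l$sample_meta$group <- c("A", "A", "A", "B", "B", "B")
  ctr <- two_sample_contrast(l, "A", "B")
  expect_equal(ctr$log2FC, -3)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ctr$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ctr$p, 0.0214, tolerance = 1e-2)
  # label swap negates the fold change, keeps p
  ctr2 <- two_sample_contrast(l, "B", "A")
  expect_equal(ctr2$log2FC, 3)
  expect_equal(ctr2$p, ctr$p)
  # identical values -> degenerate, p = 1
  l$values[, 1] <- 5
  ctr3 <- two_sample_contrast(l, "A", "B")
  expect_equal(ctr3$p, 1)
  expect_true(ctr3$degenerate)
  expect_error(two_sample_contrast(l, "A", "Z"), "at least 2")
})

test_that("vectorized Welch t agrees with stats::t.test across random data", {
  set.seed(11)
  for (i in 1:10) {
    a <- matrix(rnorm(8 * 3), 8); b <- matrix(rnorm(5 * 3, 0.5), 5)
    got <- get("col_t_test", asNamespace("immunogem"))(a, b)
    for (j in 1:3) {
      ref <- t.test(a[, j], b[, j])
      expect_equal(got$p[j], ref$p.value, tolerance = 1e-12)
      expect_equal(got$t[j], unname(ref$statistic), tolerance = 1e-12)
    }
  }
})

test_that("paired seroconversion contrast uses per-subject before/after means", {
  # construct 20 subjects, each one pre and one post sample
  n <- 20
  meta <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                     subject = rep(paste0("p", 1:n), each = 2),
                     group = "PT1D", sex = "F",
                     age_months = rep(c(12, 36), n),
                     seroconversion_age = 20)
  set.seed(8)
  base <- rep(rnorm(n, 10, 0.3), each = 2)
  vals <- matrix(2^(base + rnorm(2 * n, 0, 0.1)), ncol = 1,
                 dimnames = list(NULL, "f1"))
  om <- omics_matrix(vals, meta, data.frame(feature = "f1", class = "x", kind = "x"))
  oml <- log2_normalize(om, offset = 0)
  ctr0 <- paired_seroconversion_contrast(oml, "PT1D")
  # planted post-seroconversion drop of 0.8 is detected
  drop_idx <- meta$age_months > meta$seroconversion_age
  oml2 <- oml
  oml2$values[drop_idx, 1] <- oml$values[drop_idx, 1] - 0.8
  ctr <- paired_seroconversion_contrast(oml2, "PT1D")
  expect_lt(ctr$p, 0.01)
  expect_equal(ctr$log2FC, ctr0$log2FC - 0.8, tolerance = 1e-12)
  # after == before -> t = 0, p = 1
  oml3 <- oml
  oml3$values[] <- rep(base[seq(1, 2 * n, 2)], each = 2)
  ctr3 <- paired_seroconversion_contrast(oml3, "PT1D")
  expect_equal(ctr3$p, 1)
  # a single usable subject is refused
  oml4 <- oml
  oml4$sample_meta$seroconversion_age <- c(20, 20, rep(50, 2 * n - 2))
  expect_error(paired_seroconversion_contrast(oml4, "PT1D"), "fewer than 2")
})

test_that("paired power matches the planted-effect design across seeds", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 20
    meta <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                       subject = rep(paste0("p", 1:n), each = 2),
                       group = "P1Ab", sex = "F",
                       age_months = rep(c(12, 36), n),
                       seroconversion_age = 20)
    base <- rep(rnorm(n, 10, 0.3), each = 2)
    lvals <- base + rnorm(2 * n, 0, 0.3)
    lvals[meta$age_months > 20] <- lvals[meta$age_months > 20] - 0.8
    om <- omics_matrix(matrix(2^lvals, ncol = 1,
                              dimnames = list(NULL, "f1")), meta,
                       data.frame(feature = "f1", class = "x", kind = "x"))
    paired_seroconversion_contrast(log2_normalize(om, offset = 0), "P1Ab")$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group-totals ANOVA separates shifted groups and calibrates under the null", {
  make_om <- function(shift, seed) {
    set.seed(seed)
    n <- 30
    meta <- data.frame(sample_id = paste0("s", 1:n), subject = paste0("s", 1:n),
                       group = rep(c("CTRL", "P1Ab", "PT1D"), each = 10),
                       sex = "F", age_months = 12, seroconversion_age = NA_real_)
    l <- matrix(rnorm(n * 10, 10, 0.5), n)
    l[meta$group == "PT1D", ] <- l[meta$group == "PT1D", ] + shift
    colnames(l) <- paste0("f", 1:10)
    om <- omics_matrix(2^l, meta,
                       data.frame(feature = colnames(l), class = "x", kind = "x"))
    log2_normalize(om, offset = 0)
  }
  # strong shift -> tiny p
  expect_lt(group_totals_anova(make_om(3 * 0.5, 1), 12)$p, 0.001)
  # null: p approximately uniform over seeds
  ps <- vapply(1:60, function(s) group_totals_anova(make_om(0, s), 12)$p,
               numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # degenerate: all totals equal
  om <- make_om(0, 2)
  om$values[] <- 10
  res <- group_totals_anova(om, 12)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("spearman correlation maps respect monotone transforms and hand values", {
  x <- c(1, 2, 3, 4, 5)
  meta <- data.frame(sample_id = paste0("s", 1:5), subject = paste0("s", 1:5),
                     group = "CTRL", sex = "F", age_months = 12,
                     seroconversion_age = NA_real_)
  omA <- omics_matrix(matrix(x, ncol = 1, dimnames = list(NULL, "x")), meta)
  omB <- omics_matrix(matrix(c(1, 3, 2, 5, 4), ncol = 1,
                             dimnames = list(NULL, "y")), meta)
  sm <- spearman_map(omA, omB)
  expect_equal(sm$rho[1, 1], 0.8)
  # monotone increasing / decreasing transforms
  omB$values[, 1] <- 2 * x + 1
  expect_equal(spearman_map(omA, omB)$rho[1, 1], 1)
  omB$values[, 1] <- (6 - x)^3  # strictly decreasing, positive
  expect_equal(spearman_map(omA, omB)$rho[1, 1], -1)
  # invariance of rho under monotone transform of either side
  omB$values[, 1] <- exp(x / 2)
  r1 <- spearman_map(omA, omB)$rho[1, 1]
  omA$values[, 1] <- log(x + 1)
  expect_equal(spearman_map(omA, omB)$rho[1, 1], r1)
  expect_error(spearman_map(subset_features(omA, 1), omB, pairing =
    data.frame(A = paste0("s", 1:3), B = paste0("s", 1:3))), "at least 4")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(c(3, 10, 100, 1000), 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_reference(p), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
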