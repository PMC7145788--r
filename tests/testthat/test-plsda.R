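# Sparse PLS-DA, VIP scores and cross-validated AUC.

make_classes <- function(n_per = 25, p = 50, delta = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c("A", "B"), each = n_per)
  X[y == "B", 1] <- X[y == "B", 1] + delta  # single informative feature
  list(X = X, y = y)
}

test_that("the informative feature dominates coefficients and VIP", {
  d <- make_classes(delta = 3)
  fit <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = 20)
  rc <- coef(fit)
  expect_equal(names(which.max(abs(rc))), "f1")
  vip <- vip_scores(fit)
  expect_gt(vip["f1"], 1)
})

test_that("VIP normalization sum(VIP^2) = p holds on every fit", {
  for (s in 1:5) {
    d <- make_classes(n_per = 15, p = sample(10:60, 1), delta = runif(1, 0, 2),
                      seed = s)
    for (keep in c(5, Inf)) {
      fit <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = keep)
      vip <- vip_scores(fit)
      expect_equal(sum(vip^2), ncol(d$X), tolerance = 1e-8)
    }
  }
})

test_that("single component with equal |weights| gives all VIP = 1", {
  # two duplicated informative features, keep = all, 1 component
  set.seed(3)
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("A", "B"), 20)
  X[y == "B", ] <- X[y == "B", ] + 2
  X[, 2] <- X[, 1]  # duplicate column
  fit <- plsda_fit(X, y, n_components = 1, keep_per_component = Inf)
  vip <- vip_scores(fit)
  expect_equal(unname(vip), c(1, 1), tolerance = 1e-8)
  # duplicated columns receive equal weights up to sign
  expect_equal(abs(fit$W[1, 1]), abs(fit$W[2, 1]), tolerance = 1e-10)
})

test_that("keeping all features recovers ordinary PLS-DA", {
  d <- make_classes()
  f1 <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = Inf)
  f2 <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = ncol(d$X))
  expect_equal(f1$rc, f2$rc, tolerance = 1e-12)
})

test_that("sparsity zeroes all but keep-k weights per component", {
  d <- make_classes()
  fit <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = 7)
  expect_true(all(colSums(fit$W != 0) == 7))
  expect_equal(colSums(fit$W^2), c(1, 1), tolerance = 1e-12)
})

test_that("predictor agrees with mixOmics on dense PLS-DA ordering", {
  # independent cross-check: rank agreement of discriminant coefficients
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  d <- make_classes(n_per = 20, p = 12, delta = 2.5, seed = 7)
  fit <- plsda_fit(d$X, d$y, n_components = 2, keep_per_component = Inf)
  mo <- mixOmics::plsda(d$X, factor(d$y), ncomp = 2)
  vip_mo <- mixOmics::vip(mo)[, 2]
  vip_us <- vip_scores(fit)
  # the informative feature is the top-VIP feature in both implementations
  expect_equal(names(which.max(vip_mo)), names(which.max(vip_us)))
  expect_gt(cor(vip_mo, vip_us, method = "spearman"), 0.8)
})

test_that("n_components beyond the rank is refused", {
  d <- make_classes(n_per = 3, p = 4)
  expect_error(plsda_fit(d$X, d$y, n_components = 6), "rank")
})

test_that("cross-validated AUC hits 1 on separated classes and is symmetric", {
  # separation on many coordinates so the discriminant direction is clean
  set.seed(2)
  X <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("A", "B"), 25)
  X[y == "B", 1:5] <- X[y == "B", 1:5] + 6
  auc <- cv_auc(X, y, folds = 5, repeats = 3, seed = 1)
  expect_equal(auc, 1.0)
  # for fixed scores, inverting the positive class maps AUC to 1 - AUC
  auc_fun <- get("auc_from_scores", asNamespace("immunogem"))
  sc <- rnorm(50)
  expect_equal(auc_fun(sc, y == "B"), 1 - auc_fun(sc, y == "A"),
               tolerance = 1e-12)
})

test_that("null labels give chance-level AUC and small classes reduce folds", {
  set.seed(5)
  X <- matrix(rnorm(200 * 30), 200, 30)
  y <- rep(c("A", "B"), each = 100)
  auc <- cv_auc(X, y, folds = 5, repeats = 5, seed = 3)
  expect_gte(auc, 0.4); expect_lte(auc, 0.6)
  sub <- c(1:3, 101:140)  # only 3 members of class A
  expect_warning(cv_auc(X[sub, ], y[sub], folds = 5, repeats = 2, seed = 1),
                 "reducing folds")
})

test_that("selection combines multivariate and univariate evidence", {
  ctr <- structure(data.frame(feature = c("a", "b", "c"),
                              log2FC = c(1, -0.2, 0.8),
                              t_stat = 0, p = c(0.01, 0.03, 0.2),
                              fdr = 0.1, selected_uni = c(TRUE, TRUE, FALSE),
                              degenerate = FALSE),
                   class = c("contrast_result", "data.frame"))
  vip <- c(a = 1.2, b = 0.5, c = 1.2)
  rc <- c(a = 0.06, b = 0.2, c = 0.06)
  res <- select_altered_features(ctr, vip, rc, auc = 0.7)
  expect_equal(res$basis, c("multi+uni", "uni-only", "none"))
})
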