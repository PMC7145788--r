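# Sparse PLS discriminant analysis (NIPALS PLS1 on a centered class
# indicator with per-component keep-k sparsity), VIP scores, cross-validated
# AUC and the combined multivariate/univariate feature-selection rule.

#' Fit a (sparse) PLS-DA model
#'
#' NIPALS PLS1 against the centered 0/1 class indicator. Sparsity follows the
#' keep-k convention: each component's weight vector retains the
#' `keep_per_component` largest absolute weights, zeroes the rest and is
#' renormalized; keeping all features recovers ordinary PLS-DA.
#'
#' @param x numeric matrix (samples x features) or an `omics_matrix`.
#' @param labels two-level factor/character class labels.
#' @param n_components number of latent components.
#' @param keep_per_component features retained per component (`Inf` for all).
#' @param scale autoscale columns to unit variance (constant columns are left
#'   centered only).
#' @return object of class `plsda_model` with weights `W`, loadings `P`,
#'   scores `T`, per-component explained class variance `ssy`, and `rc`, the
#'   regression coefficients of the final linear predictor.
#' @export
plsda_fit <- function(x, labels, n_components = 2, keep_per_component = 20,
                      scale = TRUE) {
  X <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("plsda_fit requires exactly 2 classes")
  y <- as.numeric(labels == levels(labels)[2])
  n <- nrow(X); pft <- ncol(X)
  if (n_components > min(n - 1, pft)) stop("n_components exceeds matrix rank")
  mu <- colMeans(X)
  sdv <- if (scale) apply(X, 2, stats::sd) else rep(1, pft)
  sdv[sdv == 0] <- 1
  Xc <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ybar <- mean(y)
  yc <- y - ybar
  W <- matrix(0, pft, n_components); P <- matrix(0, pft, n_components)
  Tm <- matrix(0, n, n_components); Cc <- numeric(n_components)
  ssy <- numeric(n_components)
  Xd <- Xc; yd <- yc
  keep <- min(keep_per_component, pft)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    if (sqrt(sum(w^2)) < 1e-12) stop("n_components exceeds matrix rank")
    if (keep < pft) {
      thr <- sort(abs(w), decreasing = TRUE)[keep]
      w[abs(w) < thr] <- 0
    }
    w <- w / sqrt(sum(w^2))
    t <- as.vector(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) stop("n_components exceeds matrix rank")
    p <- as.vector(crossprod(Xd, t)) / tt
    cc <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - cc * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; Cc[a] <- cc
    ssy[a] <- cc^2 * tt
  }
  # coefficients of the final predictor on the (centered, scaled) X scale
  B <- W %*% solve(crossprod(P, W), Cc)
  rc <- as.vector(B)
  structure(list(W = W, P = P, T = Tm, C = Cc, ssy = ssy, rc = rc,
                 center = mu, scalev = sdv, ybar = ybar,
                 levels = levels(labels), n_components = n_components,
                 keep_per_component = keep_per_component,
                 features = colnames(X)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", x$n_components, " component(s), keep ",
      x$keep_per_component, " per component, ", length(x$rc), " features\n",
      "  classes: ", paste(x$levels, collapse = " vs "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.plsda_model <- function(object, ...) {
  stats::setNames(object$rc, object$features)
}

#' Predict continuous class scores from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix or `omics_matrix` with the training features.
#' @param ... unused.
#' @return numeric vector of scores (larger means more like the second class
#'   level).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "omics_matrix")) newdata$values else as.matrix(newdata)
  Xc <- sweep(sweep(X, 2, object$center), 2, object$scalev, "/")
  as.vector(Xc %*% (object$W %*% solve(crossprod(object$P, object$W), object$C))) +
    object$ybar
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a ssy_a (w_ja / ||w_a||)^2 / sum_a ssy_a )` with
#' `p` features and `ssy_a` the class variance explained by component `a`;
#' `sum_j VIP_j^2 = p` exactly.
#'
#' @param model a fitted `plsda_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  W <- model$W
  wnorm2 <- colSums(W^2)
  wnorm2[wnorm2 == 0] <- 1
  num <- (W^2 %*% (model$ssy / wnorm2))
  vip <- sqrt(nrow(W) * num / sum(model$ssy))
  stats::setNames(as.vector(vip), model$features)
}

auc_from_scores <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of the PLS-DA predictor
#'
#' Stratified k-fold cross-validation, repeated; the AUC is computed per test
#' fold (both classes are present under stratification) and averaged over
#' folds and repeats, so fold-specific score offsets cannot distort the
#' ranking.
#'
#' @param x matrix or `omics_matrix`.
#' @param labels two-level labels.
#' @param n_components,keep_per_component,scale passed to [plsda_fit()].
#' @param folds number of folds (reduced with a warning if a class is
#'   smaller).
#' @param repeats number of repeated fold assignments.
#' @param seed RNG seed for fold assignment.
#' @return mean cross-validated AUC (numeric scalar).
#' @export
cv_auc <- function(x, labels, n_components = 2, keep_per_component = 20,
                   scale = TRUE, folds = 5, repeats = 10, seed = 1L) {
  X <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("cv_auc requires exactly 2 classes")
  nmin <- min(table(labels))
  if (nmin < folds) {
    warning("smallest class has ", nmin, " members; reducing folds to ", nmin)
    folds <- nmin
  }
  if (folds < 2) stop("cannot cross-validate with fewer than 2 folds")
  pos <- labels == levels(labels)[2]
  with_seed(seed, {
    aucs <- vapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fold_aucs <- vapply(seq_len(folds), function(f) {
        test <- fold == f
        ncomp <- min(n_components, sum(!test) - 1)
        fit <- plsda_fit(X[!test, , drop = FALSE], labels[!test],
                         n_components = ncomp,
                         keep_per_component = keep_per_component, scale = scale)
        auc_from_scores(predict(fit, X[test, , drop = FALSE]), pos[test])
      }, numeric(1))
      mean(fold_aucs)
    }, numeric(1))
    mean(aucs)
  })
}

#' Combine univariate and multivariate evidence into a selection basis
#'
#' A feature is selected `"multi+uni"` when the model AUC passes its
#' threshold and the feature's VIP, |RC| and univariate p all pass theirs;
#' `"uni-only"` when only the univariate test passes; `"none"` otherwise.
#'
#' @param contrast a `contrast_result` from [two_sample_contrast()].
#' @param vip named VIP vector from [vip_scores()].
#' @param rc named regression-coefficient vector from `coef()` of the fitted
#'   model.
#' @param auc model cross-validated AUC (scalar).
#' @param thresholds list with `p`, `vip`, `rc`, `auc`.
#' @return the contrast with columns `vip`, `rc`, `auc`, `selected_multi`
#'   and `basis` added.
#' @export
select_altered_features <- function(contrast, vip, rc, auc,
                                    thresholds = list(p = 0.05, vip = 1,
                                                      rc = 0.05, auc = 0.65)) {
  ord <- contrast$feature
  contrast$vip <- as.numeric(vip[ord])
  contrast$rc <- as.numeric(rc[ord])
  contrast$auc <- auc
  uni <- contrast$p < thresholds$p
  multi <- auc >= thresholds$auc & contrast$vip > thresholds$vip &
    abs(contrast$rc) > thresholds$rc
  contrast$selected_multi <- multi & uni
  contrast$basis <- ifelse(multi & uni, "multi+uni",
                           ifelse(uni, "uni-only", "none"))
  contrast
}
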