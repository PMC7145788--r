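# Reporter-metabolite analysis: aggregate gene-level differential-expression
# significance onto the metabolites of a network, with a Monte-Carlo
# background correction per neighborhood size.

#' Convert gene p-values to Z scores
#'
#' `mode = "combined"` uses the two-sided p directly
#' (`Z = qnorm(1 - p)`); directional modes convert to one-sided p in the
#' requested direction (`p/2` when the change is in that direction,
#' `1 - p/2` otherwise) before the inverse-normal transform. P values are
#' clamped to `[p_floor, 1 - p_floor]` to keep the quantile finite on both
#' tails.
#'
#' @param gene_stats data.frame with `gene`, `p` and (for directional modes)
#'   `log2FC`.
#' @param mode `"combined"`, `"up"` or `"down"`.
#' @param p_floor lower p bound.
#' @return named numeric vector of Z scores.
#' @export
gene_zscores <- function(gene_stats, mode = c("combined", "up", "down"),
                         p_floor = 1e-15) {
  mode <- match.arg(mode)
  p <- gene_stats$p
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("gene p-values must be in (0, 1]")
  if (mode != "combined") {
    if (is.null(gene_stats$log2FC)) stop("directional modes need log2FC")
    dirsign <- if (mode == "up") 1 else -1
    p <- ifelse(sign(gene_stats$log2FC) * dirsign >= 0, p / 2, 1 - p / 2)
  }
  p <- pmax(pmin(p, 1 - p_floor), p_floor)
  stats::setNames(stats::qnorm(1 - p), gene_stats$gene)
}

#' Reporter metabolite scores
#'
#' For each non-currency metabolite with scored neighborhood genes G
#' (see [metabolite_gene_neighborhood()]), aggregates
#' `z_raw = sum(Z_g) / sqrt(k)`, `k = |G|`, and corrects against the mean and
#' sd of the same statistic over `n_background` random size-k draws (with
#' replacement) from the full scored-gene pool:
#' `z_corrected = (z_raw - mu_k) / sigma_k`; `p = 1 - Phi(z_corrected)`, BH
#' FDR across metabolites.
#'
#' @param model a `metabolic_model`.
#' @param gene_z named Z-score vector from [gene_zscores()].
#' @param n_background background draws per neighborhood size.
#' @param seed RNG seed for the background sampling.
#' @param mode label recorded in the result (`"up"`, `"down"`, `"combined"`).
#' @return data.frame (metabolite in bracket notation, met_id, k, z_raw,
#'   z_corrected, p, fdr, mode) sorted by decreasing z_corrected; metabolites
#'   with empty scored neighborhoods are skipped and listed in the
#'   `"skipped"` attribute.
#' @export
reporter_scores <- function(model, gene_z, n_background = 10000L, seed = 1L,
                            mode = "combined") {
  pool <- gene_z[!is.na(gene_z)]
  if (!length(pool)) stop("no scored genes")
  # vectorized neighborhoods (equivalent to metabolite_gene_neighborhood per
  # metabolite, but parsing each GPR once)
  genes_by_rxn <- lapply(model$rxns$gpr, gpr_genes)
  trip <- Matrix::summary(model_S(model))
  rxns_by_met <- split(trip$j, factor(trip$i, levels = seq_len(nrow(model$mets))))
  currency <- tolower(model_currency(model))
  hoods <- lapply(seq_len(nrow(model$mets)), function(i) {
    if (tolower(met_base(model$mets$id[i])) %in% currency)
      return(character(0))
    intersect(unique(unlist(genes_by_rxn[rxns_by_met[[i]]])), names(pool))
  })
  names(hoods) <- model$mets$id
  k <- lengths(hoods)
  skipped <- model$mets$id[k == 0]
  mets <- model$mets$id[k > 0]
  if (!length(mets)) stop("no metabolite has scored neighborhood genes")
  kk <- k[mets]
  z_raw <- vapply(mets, function(m) sum(pool[hoods[[m]]]) / sqrt(length(hoods[[m]])),
                  numeric(1))
  bg <- with_seed(seed, {
    ks <- sort(unique(kk))
    stats::setNames(lapply(ks, function(ksize) {
      draws <- matrix(sample(pool, n_background * ksize, replace = TRUE),
                      n_background, ksize)
      agg <- rowSums(draws) / sqrt(ksize)
      c(mu = mean(agg), sigma = stats::sd(agg))
    }), as.character(ks))
  })
  mu <- vapply(as.character(kk), function(s) bg[[s]]["mu"], numeric(1))
  sigma <- vapply(as.character(kk), function(s) bg[[s]]["sigma"], numeric(1))
  # a degenerate background (all pool scores equal) carries no evidence
  dev <- z_raw - mu
  z_corr <- ifelse(sigma > 1e-12, dev / sigma,
                   ifelse(abs(dev) < 1e-9, 0, sign(dev) * Inf))
  p <- stats::pnorm(z_corr, lower.tail = FALSE)
  out <- data.frame(metabolite = met_display(mets), met_id = mets,
                    k = as.integer(kk), z_raw = z_raw, z_corrected = z_corr,
                    p = p, fdr = bh_fdr(p), mode = mode,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$z_corrected, out$met_id), ]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}
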