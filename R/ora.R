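# Metabolite pathway over-representation analysis (one-sided hypergeometric
# with BH control) and topology-based pathway impact scores.

#' Construct a pathway set
#'
#' @param name pathway name.
#' @param members metabolite ids.
#' @param edges optional two-column matrix/data.frame of undirected edges
#'   between members (the pathway's own graph, used for impact scores).
#' @return object of class `pathway_set`.
#' @export
pathway_set <- function(name, members, edges = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("pathway must have members: ", name)
  if (!is.null(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    bad <- setdiff(unique(c(edges[[1]], edges[[2]])), members)
    if (length(bad)) stop("graph nodes outside pathway members: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(name = name, members = members, edges = edges),
            class = "pathway_set")
}

#' Read pathway sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. An optional edge-list
#' TSV (`pathway<TAB>from<TAB>to`) attaches within-pathway graphs.
#'
#' @param path GMT file.
#' @param edges_path optional edge-list TSV.
#' @return named list of `pathway_set` objects.
#' @export
read_gmt <- function(path, edges_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- NULL
  if (!is.null(edges_path)) {
    edges <- utils::read.delim(edges_path, header = TRUE,
                               stringsAsFactors = FALSE)
  }
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    e <- if (!is.null(edges)) {
      sel <- edges[[1]] == f[1]
      if (any(sel)) edges[sel, 2:3] else NULL
    } else NULL
    pathway_set(f[1], f[-(1:2)], e)
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write pathway sets to GMT (and optional edge list)
#' @param pathways list of `pathway_set`.
#' @param path GMT output file.
#' @param edges_path optional edge-list TSV output.
#' @export
write_gmt <- function(pathways, path, edges_path = NULL) {
  lines <- vapply(pathways, function(p)
    paste(c(p$name, "na", p$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  if (!is.null(edges_path)) {
    ed <- do.call(rbind, lapply(pathways, function(p) {
      if (is.null(p$edges)) return(NULL)
      data.frame(pathway = p$name, from = p$edges[[1]], to = p$edges[[2]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided (upper tail) hypergeometric test per pathway after intersecting
#' each pathway with the measured universe; BH FDR across pathways; impact
#' scores where a pathway graph is available.
#'
#' @param hits character vector of significant metabolite ids (subset of
#'   `universe`).
#' @param pathways list of `pathway_set` objects.
#' @param universe all measured, pathway-mappable metabolite ids.
#' @param fdr_threshold flag threshold.
#' @return data.frame (pathway, k, K, n, N, p, fdr, significant, pis) sorted
#'   by p. `pis` is `NA` for pathways without a graph.
#' @export
hypergeom_ora <- function(hits, pathways, universe, fdr_threshold = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(hits)
  extra <- setdiff(hits, universe)
  if (length(extra)) stop("hits outside the universe: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe); n <- length(hits)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$members, universe)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw$name, k = k, K = K, n = n, N = N, p = p,
               pis = pathway_impact(pw, hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p, out$pathway), c("pathway", "k", "K", "n", "N", "p", "fdr",
                                   "significant", "pis")]
}

#' Pathway impact score
#'
#' Ratio of summed relative betweenness centrality of hit members to that of
#' all members, computed on the pathway's own (undirected) graph. Returns 1
#' when every member is hit, 0 when none is (or when no member is central),
#' and `NA` when the pathway has no graph.
#'
#' @param pathway a `pathway_set` with a graph.
#' @param hits significant metabolite ids.
#' @return numeric in `[0, 1]`, or `NA` if the pathway has no graph.
#' @export
pathway_impact <- function(pathway, hits) {
  if (is.null(pathway$edges)) return(NA_real_)
  g <- igraph::graph_from_data_frame(pathway$edges, directed = FALSE,
                                     vertices = pathway$members)
  cent <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  denom <- sum(cent)
  if (denom == 0) return(if (all(pathway$members %in% hits)) 1 else 0)
  hit_members <- intersect(pathway$members, hits)
  if (setequal(hit_members, pathway$members)) return(1)
  sum(cent[hit_members]) / denom
}
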