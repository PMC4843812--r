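#' Stability ranking of candidate genes
#'
#' The unit aggregated by the consensus: one algorithm's ordinal ranking
#' of the candidate genes (ties allowed, competition style: a two-way tie
#' at the top is 1, 1, 3), optionally with the underlying statistic.
#'
#' @param algorithm label, e.g. `"genorm"`, `"normfinder"`,
#'   `"bestkeeper"`, `"rnaseq_cv"` or `"external"`.
#' @param ranks named integer-ish vector mapping every gene to a rank
#'   >= 1.
#' @param statistic optional named numeric vector of the per-gene
#'   statistic behind the ranks.
#' @return An object of class `stability_ranking`.
#' @export
stability_ranking <- function(algorithm, ranks, statistic = NULL) {
  if (is.null(names(ranks)) || anyDuplicated(names(ranks)))
    stop("'ranks' must be uniquely named by gene")
  if (any(!is.finite(ranks)) || any(ranks < 1))
    stop("ranks must be finite and >= 1")
  structure(list(algorithm = as.character(algorithm),
                 genes = names(ranks),
                 ranks = stats::setNames(as.numeric(ranks), names(ranks)),
                 statistic = statistic),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  ord <- names(sort(x$ranks))
  cat("Stability ranking [", x$algorithm, "]: ",
      paste(ord, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Competition ranks from a statistic
#'
#' Converts per-gene scores to ordinal ranks. With `ascending = TRUE`
#' (the case for M, SV and the BestKeeper SD) a lower score is a better
#' (smaller) rank. Ties receive the same rank and the next rank is
#' skipped ("1, 1, 3").
#'
#' @param scores named finite numeric vector.
#' @param ascending if `FALSE`, higher scores rank better.
#' @param algorithm label stored on the result.
#' @return A [stability_ranking()].
#' @examples
#' ranks_from_scores(c(a = 0.2, b = 0.2, c = 0.5))$ranks  # 1 1 3
#' @export
ranks_from_scores <- function(scores, ascending = TRUE,
                              algorithm = "scores") {
  if (any(!is.finite(scores))) stop("non-finite score(s)")
  s <- if (ascending) scores else -scores
  r <- rank(s, ties.method = "min")
  stability_ranking(algorithm, stats::setNames(r, names(scores)),
                    statistic = scores)
}

# coerce fitted objects to their stability_ranking
.as_ranking <- function(x) {
  if (inherits(x, "stability_ranking")) return(x)
  if (!is.null(x$ranking) && inherits(x$ranking, "stability_ranking"))
    return(x$ranking)
  stop("cannot extract a stability_ranking from object of class ",
       paste(class(x), collapse = "/"))
}

#' Geometric-mean consensus of stability rankings
#'
#' Aggregates two or more per-algorithm rankings over the same gene set
#' into a comprehensive ranking: each gene's score is the geometric mean
#' of its per-algorithm ordinal ranks and genes are ordered by ascending
#' score. Ties on the geometric mean are broken in favour of the gene
#' whose worst ranks are smaller (its per-algorithm ranks sorted in
#' decreasing order compare lexicographically smaller), then by input
#' gene order.
#'
#' @param rankings list of [stability_ranking()] objects, or fitted
#'   `genorm`/`normfinder`/`bestkeeper` objects (their `$ranking` is
#'   used). All must cover the identical gene set.
#' @param genes optional character vector fixing the input gene order
#'   used for the final tie-break; defaults to the gene order of the
#'   first ranking.
#' @return An object of class `consensus_ranking`: list with `table`
#'   (data frame: gene, per-algorithm ranks, geomean, position), `order`
#'   (genes best first), `geomean` (named vector) and `inputs`.
#' @examples
#' a <- ranks_from_scores(c(g1 = 0.1, g2 = 0.3, g3 = 0.5))
#' b <- ranks_from_scores(c(g1 = 0.4, g2 = 0.2, g3 = 0.9))
#' consensus_rank(list(a, b))$order
#' @export
consensus_rank <- function(rankings, genes = NULL) {
  if (length(rankings) < 2) stop("need >= 2 rankings")
  rankings <- lapply(rankings, .as_ranking)
  gsets <- lapply(rankings, function(r) sort(r$genes))
  if (!all(vapply(gsets[-1], identical, logical(1), gsets[[1]])))
    stop("gene-set mismatch between rankings")
  if (is.null(genes)) genes <- rankings[[1]]$genes
  if (!setequal(genes, rankings[[1]]$genes))
    stop("'genes' must match the rankings' gene set")

  rmat <- sapply(rankings, function(r) r$ranks[genes])
  rownames(rmat) <- genes
  algos <- vapply(rankings, function(r) r$algorithm, character(1))
  colnames(rmat) <- make.unique(algos)

  geomean <- exp(rowMeans(log(rmat)))
  # tie-break: lexicographically smaller sorted-descending rank profile
  prof <- t(apply(rmat, 1, sort, decreasing = TRUE))
  ord <- do.call(order, c(list(geomean),
                          lapply(seq_len(ncol(prof)), function(j) prof[, j]),
                          list(seq_along(genes))))
  pos <- integer(length(genes))
  pos[ord] <- seq_along(genes)
  tab <- data.frame(gene = genes, rmat, geomean = geomean, position = pos,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(table = tab[order(tab$position), ],
                 order = genes[ord],
                 geomean = geomean,
                 inputs = rankings),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Comprehensive (geometric-mean) ranking of ", length(x$order),
      " genes over ", length(x$inputs), " algorithms\n  ", sep = "")
  cat(paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.consensus_ranking <- function(object, ...) object$table

#' @export
plot.consensus_ranking <- function(x, ...) {
  gm <- sort(x$geomean)
  graphics::barplot(gm, las = 2, ylab = "geometric mean of ranks",
                    main = "comprehensive ranking", ...)
  invisible(x)
}

#' Read per-algorithm ranking fixtures
#'
#' Reads rankings stored as CSV with columns `panel`, `algorithm`, `rank`,
#' `gene` (one row per gene per algorithm; tied genes repeat a rank).
#'
#' @param path CSV file path.
#' @param panel panel label to extract.
#' @param algorithms algorithms to extract, in order.
#' @param gene_order optional input gene order for tie-breaking.
#' @return List of [stability_ranking()] objects.
#' @export
read_ranking_fixture <- function(path, panel,
                                 algorithms = c("genorm", "normfinder",
                                                "bestkeeper"),
                                 gene_order = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("panel", "algorithm", "rank", "gene")
  if (!all(need %in% names(df)))
    stop("format error: need columns ", paste(need, collapse = ", "))
  df <- df[df$panel == panel, ]
  if (nrow(df) == 0) stop("unknown panel: ", panel)
  lapply(algorithms, function(a) {
    sub <- df[df$algorithm == a, ]
    if (nrow(sub) == 0) stop("panel ", panel, " has no '", a, "' ranking")
    ranks <- stats::setNames(sub$rank, sub$gene)
    if (!is.null(gene_order)) ranks <- ranks[gene_order]
    stability_ranking(a, ranks)
  })
}
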