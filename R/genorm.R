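#' Pairwise variation between two genes
#'
#' The geNorm building block: the sample standard deviation (n-1
#' denominator) of the log2 expression ratio of two genes across samples.
#' Two perfectly co-regulated (proportional) genes have V = 0.
#'
#' @param q_j,q_k positive numeric vectors of relative quantities of equal
#'   length >= 2.
#' @return V, in log2 units; symmetric in its arguments.
#' @export
pairwise_v <- function(q_j, q_k) {
  if (length(q_j) != length(q_k)) stop("length mismatch")
  if (length(q_j) < 2) stop("need >= 2 samples")
  if (any(q_j <= 0) || any(q_k <= 0)) stop("value error: nonpositive quantities")
  stats::sd(log2(q_j / q_k))
}

#' geNorm expression stability M
#'
#' M of a gene is the arithmetic mean of its pairwise variations
#' [pairwise_v()] against every other gene in the candidate set. Lower M
#' means more stable expression.
#'
#' @param x a `relquant` object or positive genes x samples matrix.
#' @param gene_set genes to evaluate (default: all genes in `x`); must
#'   contain at least 2 genes.
#' @return Named numeric vector of M values over `gene_set`.
#' @export
stability_m <- function(x, gene_set = NULL) {
  q <- .q_matrix(x)
  if (is.null(gene_set)) gene_set <- rownames(q)
  if (length(gene_set) < 2) stop("need >= 2 genes")
  if (!all(gene_set %in% rownames(q)))
    stop("unknown gene(s): ", paste(setdiff(gene_set, rownames(q)), collapse = ", "))
  lq <- log2(q[gene_set, , drop = FALSE])
  k <- length(gene_set)
  # sd over samples of lq[j,] - lq[k,] for all pairs; vectorised via scan
  vmat <- matrix(0, k, k, dimnames = list(gene_set, gene_set))
  for (j in seq_len(k - 1)) {
    d <- lq[(j + 1):k, , drop = FALSE] -
      matrix(lq[j, ], k - j, ncol(lq), byrow = TRUE)
    s <- apply(d, 1, stats::sd)
    vmat[j, (j + 1):k] <- s
    vmat[(j + 1):k, j] <- s
  }
  rowSums(vmat) / (k - 1)
}

#' geNorm stability analysis
#'
#' Ranks candidate reference genes by stepwise elimination: in each round
#' the gene with the highest average expression stability M is removed and
#' M recomputed on the survivors, until two genes remain. geNorm cannot
#' rank the final pair against each other, so both are reported at rank 1.
#' The pairwise variation series V(n/n+1) between normalization factors
#' built from the top n and n+1 genes determines how many reference genes
#' are needed: the smallest n with V(n/n+1) below the cutoff.
#'
#' @param x a `relquant` object or positive genes x samples matrix with at
#'   least 3 genes, 2 samples, and no missing cells.
#' @param m_threshold M value above which a gene is flagged as unstable in
#'   the full candidate set (conventional threshold 1.5).
#' @param v_cutoff cutoff for the pairwise variation series; the
#'   conventional choice is 0.15.
#' @details Elimination ties (equal maximal M) are broken by removing the
#'   later-listed of the tied genes, so results are deterministic in the
#'   input gene order.
#' @return An object of class `genorm` with elements:
#'   \describe{
#'     \item{ranked_genes}{all genes, best first; the first two are the
#'       unordered final pair.}
#'     \item{final_pair}{the two genes remaining after elimination.}
#'     \item{elimination_order}{genes in removal order (least stable
#'       removed first).}
#'     \item{m_trajectory}{list of named M vectors, one per elimination
#'       round, starting from the full set.}
#'     \item{m_values}{first-round M of every gene.}
#'     \item{flagged}{genes whose first-round M exceeds `m_threshold`.}
#'     \item{v_series}{named vector V(n/n+1) for n = 2..k-1.}
#'     \item{recommended_n}{smallest n with V(n/n+1) < `v_cutoff`, or `NA`
#'       when no n qualifies.}
#'     \item{ranking}{a [stability_ranking()] with the final pair tied at
#'       rank 1 (competition ranking 1,1,3,...).}
#'   }
#' @examples
#' set.seed(1)
#' q <- matrix(2^-abs(rnorm(40)), 5, 8,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' genorm(q)
#' @export
genorm <- function(x, m_threshold = 1.5, v_cutoff = 0.15) {
  q <- .q_matrix(x)
  k <- nrow(q)
  if (k < 3) stop("need >= 3 genes")
  if (ncol(q) < 2) stop("need >= 2 samples")
  genes <- rownames(q)

  surviving <- genes
  elim <- character(0)
  traj <- list()
  while (length(surviving) > 2) {
    m <- stability_m(q, surviving)
    traj[[length(traj) + 1L]] <- m
    # remove the later-listed gene among those tied at the maximum
    worst <- surviving[max(which(m == max(m)))]
    elim <- c(elim, worst)
    surviving <- setdiff(surviving, worst)
  }
  traj[[length(traj) + 1L]] <- stability_m(q, surviving)
  final_pair <- surviving
  ranked <- c(final_pair, rev(elim))

  m_full <- traj[[1L]]
  v <- .v_series(q, ranked)
  below <- which(v < v_cutoff)
  rec_n <- if (length(below)) as.integer(names(v)[min(below)]) else NA_integer_

  ranks <- c(1L, 1L, seq_len(k)[-(1:2)])
  names(ranks) <- ranked
  ranking <- stability_ranking("genorm", ranks[genes],
                               statistic = m_full[genes])

  structure(list(ranked_genes = ranked, final_pair = final_pair,
                 elimination_order = elim, m_trajectory = traj,
                 m_values = m_full, flagged = names(m_full)[m_full > m_threshold],
                 v_series = v, recommended_n = rec_n,
                 v_cutoff = v_cutoff, m_threshold = m_threshold,
                 ranking = ranking),
            class = "genorm")
}

#' Normalization factor from the top n reference genes
#'
#' Per-sample geometric mean of the relative quantities of the n
#' best-ranked reference genes.
#'
#' @param x a `relquant` object or positive matrix.
#' @param ranked_genes genes ordered best first.
#' @param n number of genes to combine, 2 <= n <= length(ranked_genes).
#' @return Named numeric vector: one normalization factor per sample.
#' @export
normalization_factor <- function(x, ranked_genes, n) {
  q <- .q_matrix(x)
  if (n < 2 || n > length(ranked_genes)) stop("n out of range [2, k]")
  if (!all(ranked_genes %in% rownames(q)))
    stop("unknown gene(s) in 'ranked_genes'")
  exp(colMeans(log(q[ranked_genes[seq_len(n)], , drop = FALSE])))
}

.v_series <- function(q, ranked) {
  k <- length(ranked)
  if (k < 3) return(stats::setNames(numeric(0), character(0)))
  nf <- sapply(2:k, function(n) normalization_factor(q, ranked, n))
  v <- sapply(seq_len(k - 2), function(i)
    stats::sd(log2(nf[, i] / nf[, i + 1])))
  names(v) <- 2:(k - 1)
  v
}

#' Pairwise variation series V(n/n+1)
#'
#' @inheritParams normalization_factor
#' @param cutoff threshold below which adding another reference gene is
#'   judged unnecessary (default 0.15).
#' @return List with `v_series` (named vector, names are n) and
#'   `recommended_n` (`NA` when no n is below the cutoff).
#' @export
pairwise_variation_series <- function(x, ranked_genes, cutoff = 0.15) {
  q <- .q_matrix(x)
  if (length(ranked_genes) < 3) stop("need >= 3 ranked genes")
  v <- .v_series(q, ranked_genes)
  below <- which(v < cutoff)
  list(v_series = v,
       recommended_n = if (length(below)) as.integer(names(v)[min(below)])
       else NA_integer_)
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability analysis (", length(x$ranked_genes), " genes)\n", sep = "")
  cat("  best pair (tied at rank 1): ",
      paste(x$final_pair, collapse = " / "), "\n", sep = "")
  cat("  ranking: ", paste(x$ranked_genes, collapse = " > "), "\n", sep = "")
  if (length(x$flagged))
    cat("  M > ", x$m_threshold, ": ", paste(x$flagged, collapse = ", "),
        "\n", sep = "")
  cat("  recommended n: ",
      if (is.na(x$recommended_n)) paste0("none (all V >= ", x$v_cutoff, ")")
      else x$recommended_n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.genorm <- function(object, ...) {
  df <- data.frame(gene = names(object$m_values),
                   M = unname(object$m_values),
                   rank = unname(object$ranking$ranks[names(object$m_values)]),
                   flagged = names(object$m_values) %in% object$flagged,
                   stringsAsFactors = FALSE)
  df[order(df$rank, df$gene), ]
}

#' Plot geNorm results
#'
#' Left panel: average expression stability M of the surviving set at each
#' elimination round (least stable genes leave first). Right panel: the
#' pairwise variation series with its cutoff.
#'
#' @param x a `genorm` object.
#' @param ... ignored.
#' @export
plot.genorm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(5, 4, 2, 1))
  on.exit(graphics::par(op))
  avg_m <- sapply(x$m_trajectory, mean)
  remaining <- length(x$ranked_genes) - seq_along(avg_m) + 1L
  graphics::plot(remaining, avg_m, type = "b", xlim = rev(range(remaining)),
                 xlab = "genes remaining", ylab = "average M of surviving set",
                 main = "stepwise exclusion")
  graphics::barplot(x$v_series, ylab = "V(n/n+1)", xlab = "n",
                    main = "pairwise variation")
  graphics::abline(h = x$v_cutoff, lty = 2)
  invisible(x)
}
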