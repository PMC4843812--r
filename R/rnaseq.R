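#' Per-unigene FPKM stability statistics
#'
#' For each unigene, the mean FPKM (MV), the sample standard deviation
#' (SD, n-1 denominator) across conditions, and the coefficient of
#' variation CV = SD/MV used to screen stable candidates from RNA-seq
#' data. Rows with MV = 0 get an undefined (NA) CV and are flagged, not
#' dropped.
#'
#' @param x an [fpkm_table()] with at least 2 conditions.
#' @return Data frame of class `fpkm_stats`: `unigene`, `mv`, `sd`, `cv`,
#'   `cv_defined`.
#' @export
fpkm_stats <- function(x) {
  stopifnot(inherits(x, "fpkm_table"))
  if (ncol(x$fpkm) < 2) stop("need >= 2 conditions")
  mv <- rowMeans(x$fpkm)
  sdv <- apply(x$fpkm, 1, stats::sd)
  cv <- ifelse(mv > 0, sdv / mv, NA_real_)
  out <- data.frame(unigene = x$unigenes, mv = mv, sd = sdv, cv = cv,
                    cv_defined = mv > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fpkm_stats", "data.frame")
  out
}

#' Screen candidate reference genes from FPKM statistics
#'
#' Keeps unigenes with adequate expression (`mv >= min_mv`), low
#' variability (`cv <= max_cv`) and, if given, a credible annotation, and
#' orders them by ascending CV (lowest CV = most stable).
#'
#' @param stats an [fpkm_stats()] data frame.
#' @param min_mv minimum mean FPKM; the "appropriate expression level"
#'   threshold. Default 1 FPKM (an arbitrary but conventional floor).
#' @param max_cv maximum coefficient of variation.
#' @param annotated optional character vector of annotated unigene ids to
#'   restrict to.
#' @return The filtered rows of `stats`, CV-ascending, with a `rank`
#'   column.
#' @export
screen_candidates <- function(stats, min_mv = 1, max_cv = Inf,
                              annotated = NULL) {
  stopifnot(inherits(stats, "fpkm_stats"))
  if (min_mv <= 0 || max_cv <= 0) stop("thresholds must be > 0")
  keep <- stats$cv_defined & stats$mv >= min_mv & stats$cv <= max_cv
  if (!is.null(annotated)) keep <- keep & stats$unigene %in% annotated
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$cv, seq_len(nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Correlation between two stability rankings
#'
#' Pearson correlation of the two rank vectors over a common gene set
#' (equivalently, the Spearman correlation of the underlying statistics),
#' used to compare the qPCR-derived stability ordering with the RNA-seq
#' CV ordering. Kendall's tau is available as a robustness check.
#'
#' @param rank_a,rank_b [stability_ranking()] objects (or fitted objects
#'   carrying one) over identical gene sets.
#' @param method `"pearson"` (on ranks) or `"kendall"`.
#' @return Correlation coefficient in [-1, 1]; `NA` with a warning when a
#'   rank vector has zero variance.
#' @examples
#' a <- stability_ranking("a", c(g1 = 1, g2 = 2, g3 = 3, g4 = 4))
#' b <- stability_ranking("b", c(g1 = 2, g2 = 1, g3 = 3, g4 = 4))
#' ranking_correlation(a, b)  # 0.8
#' @export
ranking_correlation <- function(rank_a, rank_b,
                                method = c("pearson", "kendall")) {
  method <- match.arg(method)
  rank_a <- .as_ranking(rank_a)
  rank_b <- .as_ranking(rank_b)
  if (!setequal(rank_a$genes, rank_b$genes))
    stop("gene-set mismatch between rankings")
  a <- rank_a$ranks[rank_a$genes]
  b <- rank_b$ranks[rank_a$genes]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance rank vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}
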