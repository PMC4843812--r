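#' BestKeeper descriptive stability analysis
#'
#' Computes the BestKeeper descriptive statistics on raw Ct values:
#' per-gene arithmetic and geometric mean Ct, range, the BestKeeper "SD"
#' (mean absolute deviation about the arithmetic mean, in cycles) and CV
#' (SD as a percent of the mean Ct), flags genes whose SD exceeds the
#' acceptability threshold of 1 cycle, builds the BestKeeper index (the
#' per-sample geometric mean Ct over the retained genes) and correlates
#' each gene with it (Pearson r with two-sided p). Genes are ranked by SD,
#' then CV, then input order; excluded genes are still listed, after all
#' acceptable ones.
#'
#' @param x a [ct_table()] (raw Ct, not relative quantities).
#' @param samples optional sample selection as in [ct_subset()].
#' @param sd_threshold exclusion threshold in cycles (default 1).
#' @param sd_method `"mad"` for the BestKeeper convention (mean absolute
#'   deviation, 1/n) or `"sample"` for the n-1 sample SD, for sensitivity
#'   analysis.
#' @param rank_by primary ranking key: `"sd"` (default; the exclusion rule
#'   is stated on SD) or `"cv"`.
#' @return An object of class `bestkeeper` with elements `stats` (data
#'   frame: gene, n, geo_mean, ar_mean, min, max, sd, cv, excluded, r, p,
#'   rank), `excluded`, `index` (per-sample geometric mean Ct over
#'   included genes; `NULL` when fewer than 2 genes are retained),
#'   `ranked_genes` and `ranking` (a [stability_ranking()]).
#' @examples
#' ct <- matrix(c(20, 21, 20, 21, 25, 24, 26, 25), 2, 4, byrow = TRUE,
#'              dimnames = list(c("g1", "g2"), NULL))
#' bestkeeper(ct_table(ct))
#' @export
bestkeeper <- function(x, samples = NULL, sd_threshold = 1,
                       sd_method = c("mad", "sample"),
                       rank_by = c("sd", "cv")) {
  stopifnot(inherits(x, "ct_table"))
  sd_method <- match.arg(sd_method)
  rank_by <- match.arg(rank_by)
  if (!is.null(samples)) x <- ct_subset(x, samples)
  ct <- x$ct
  if (ncol(ct) < 2) stop("need >= 2 samples")
  if (any(is.na(ct))) stop("completeness error: missing Ct cells")

  am <- rowMeans(ct)
  sdv <- if (sd_method == "mad") rowMeans(abs(ct - am))
         else apply(ct, 1, stats::sd)
  stats_df <- data.frame(
    gene = x$genes,
    n = ncol(ct),
    geo_mean = exp(rowMeans(log(ct))),
    ar_mean = am,
    min = apply(ct, 1, min),
    max = apply(ct, 1, max),
    sd = sdv,
    cv = 100 * sdv / am,
    row.names = NULL, stringsAsFactors = FALSE)
  stats_df$excluded <- stats_df$sd > sd_threshold
  excluded <- stats_df$gene[stats_df$excluded]

  included <- stats_df$gene[!stats_df$excluded]
  index <- NULL
  stats_df$r <- NA_real_
  stats_df$p <- NA_real_
  if (length(included) >= 2) {
    index <- bestkeeper_index(x, included)
    for (i in seq_len(nrow(stats_df))) {
      g <- stats_df$gene[i]
      if (ncol(ct) < 3 || stats::sd(ct[g, ]) == 0 || stats::sd(index) == 0)
        next  # correlation needs >= 3 samples and variation
      h <- stats::cor.test(ct[g, ], index)
      stats_df$r[i] <- unname(h$estimate)
      stats_df$p[i] <- h$p.value
    }
  }

  keys <- if (rank_by == "sd") list(stats_df$sd, stats_df$cv)
          else list(stats_df$cv, stats_df$sd)
  ord <- order(stats_df$excluded, keys[[1]], keys[[2]], seq_len(nrow(stats_df)))
  stats_df$rank <- NA_integer_
  stats_df$rank[ord] <- seq_len(nrow(stats_df))
  ranked <- stats_df$gene[ord]

  ranking <- stability_ranking(
    "bestkeeper",
    stats::setNames(stats_df$rank, stats_df$gene),
    statistic = stats::setNames(stats_df$sd, stats_df$gene))

  structure(list(stats = stats_df, excluded = excluded, index = index,
                 ranked_genes = ranked, sd_threshold = sd_threshold,
                 sd_method = sd_method, rank_by = rank_by,
                 ranking = ranking),
            class = "bestkeeper")
}

#' BestKeeper index and per-gene correlations
#'
#' The BestKeeper index is the per-sample geometric mean Ct over the
#' retained candidate genes; genes that track the common expression signal
#' correlate strongly (and positively) with it.
#'
#' @param x a [ct_table()].
#' @param included_genes at least 2 gene symbols to combine.
#' @return Named numeric vector: the index value for every sample.
#' @export
bestkeeper_index <- function(x, included_genes) {
  stopifnot(inherits(x, "ct_table"))
  if (length(included_genes) < 2) stop("need >= 2 included genes")
  if (!all(included_genes %in% x$genes))
    stop("unknown gene(s): ",
         paste(setdiff(included_genes, x$genes), collapse = ", "))
  exp(colMeans(log(x$ct[included_genes, , drop = FALSE])))
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper analysis (", nrow(x$stats), " genes, SD = ",
      if (x$sd_method == "mad") "mean absolute deviation" else "sample SD",
      ")\n", sep = "")
  best <- x$ranked_genes[1]
  b <- x$stats[x$stats$gene == best, ]
  cat(sprintf("  most stable: %s (CV %.2f +/- SD %.2f)\n", best, b$cv, b$sd))
  if (length(x$excluded))
    cat("  excluded (SD > ", x$sd_threshold, "): ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bestkeeper <- function(object, ...) {
  object$stats[order(object$stats$rank), ]
}

#' @export
plot.bestkeeper <- function(x, ...) {
  s <- x$stats[order(x$stats$rank), ]
  bp <- graphics::barplot(s$sd, names.arg = s$gene, las = 2,
                          ylab = "SD (cycles)", main = "BestKeeper", ...)
  graphics::abline(h = x$sd_threshold, lty = 2)
  invisible(x)
}
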