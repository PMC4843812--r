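#' NormFinder model-based stability analysis
#'
#' Decomposes log-scale expression into gene, sample and error terms and
#' scores each candidate by its estimated expression variance; with sample
#' groups (treatments, tissues) it additionally estimates systematic
#' between-group deviations and combines both sources into a stability
#' value (SV). Lower SV = more stable.
#'
#' @section Model:
#' On the log2 scale, `y_ij = alpha_i + beta_j + eps_ij` for gene i and
#' sample j: a gene level, a shared per-sample loading effect, and a
#' gene-specific error with variance `sigma_i^2`. Per-sample centering
#' across genes removes `beta_j`; the residual variance of gene i then
#' mixes its own `sigma_i^2` with the average of all genes' variances.
#' Writing `v_i` for the sample variance over samples of the centered,
#' gene-mean-removed residuals, taking expectations gives
#' `E(v_i) = (1 - 2/k) sigma_i^2 + S/k^2` with `S` the sum of all
#' variances, so the bias-corrected estimator is
#' `sigma2_i = max(0, k/(k-2) * (v_i - sum(v)/(k (k-1))))`
#' and the ungrouped stability value is `SV_i = sqrt(sigma2_i)`. The
#' correction requires k >= 3 genes.
#'
#' In grouped mode the same estimate is formed within each group g (size
#' n_g), giving `sigma2_ig` and group means `a_ig` of the centered values.
#' The gene x group deviations `d_ig = a_ig - mean_g(a_ig)` estimate true
#' inter-group effects with sampling noise `sigma2_ig/n_g`; their common
#' variance is estimated as
#' `gamma2 = max(0, sum(d^2)/((k-1)(G-1)) - mean(sigma2_ig/n_g))`
#' and each deviation is shrunk towards zero,
#' `d~_ig = d_ig * gamma2/(gamma2 + sigma2_ig/n_g)`. The grouped
#' stability value averages the absolute shrunk deviation and its
#' posterior spread over groups:
#' `SV_i = mean_g( |d~_ig| + sqrt( (sigma2_ig/n_g) * gamma2/(gamma2 + sigma2_ig/n_g) ) )`.
#'
#' @param x a `relquant` object or positive genes x samples matrix with
#'   k >= 3 genes and no missing values.
#' @param groups optional sample group labels (character/factor, one per
#'   sample, or a named vector over sample ids); every group needs >= 2
#'   samples. With a single distinct label the analysis falls back to
#'   ungrouped mode.
#' @return An object of class `normfinder` with elements `sv` (named,
#'   log2 units), `sigma2` (gene variance estimates; gene x group matrix
#'   in grouped mode), `d_shrunk` (gene x group shrunk deviations, grouped
#'   mode), `gamma2`, `mode` (`"grouped"`/`"ungrouped"`), and `ranking`
#'   (a [stability_ranking()], lower SV = better).
#' @examples
#' set.seed(1)
#' q <- matrix(2^-abs(rnorm(60, sd = 0.5)), 6, 10,
#'             dimnames = list(paste0("g", 1:6), NULL))
#' normfinder(q)
#' @export
normfinder <- function(x, groups = NULL) {
  q <- .q_matrix(x)
  k <- nrow(q)
  if (k < 3) stop("need >= 3 genes (variance correction divides by k - 2)")
  genes <- rownames(q)
  y <- log2(q)
  z <- sweep(y, 2, colMeans(y))  # remove per-sample loading effect

  if (!is.null(groups)) {
    if (!is.null(names(groups)) && !is.null(colnames(q)))
      groups <- groups[colnames(q)]
    if (length(groups) != ncol(q) || anyNA(groups))
      stop("missing group label(s): 'groups' must label every sample")
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) < 2) groups <- NULL
  }

  if (is.null(groups)) {
    sigma2 <- .nf_sigma2(z)
    sv <- sqrt(sigma2)
    res <- list(sv = sv, sigma2 = sigma2, d_shrunk = NULL, gamma2 = NULL,
                mode = "ungrouped")
  } else {
    G <- nlevels(groups)
    ng <- table(groups)
    if (any(ng < 2)) stop("every group needs >= 2 samples")
    sigma2 <- sapply(levels(groups), function(g)
      .nf_sigma2(z[, groups == g, drop = FALSE]))
    a <- sapply(levels(groups), function(g)
      rowMeans(z[, groups == g, drop = FALSE]))
    d <- a - rowMeans(a)
    noise <- sweep(sigma2, 2, as.numeric(ng), "/")  # sigma2_ig / n_g
    gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(noise))
    denom <- gamma2 + noise
    shrink <- ifelse(denom > 0, gamma2 / denom, 0)
    d_shrunk <- d * shrink
    sv <- rowMeans(abs(d_shrunk) + sqrt(noise * shrink))
    names(sv) <- genes
    res <- list(sv = sv, sigma2 = sigma2, d_shrunk = d_shrunk,
                gamma2 = gamma2, mode = "grouped")
  }
  res$ranking <- stability_ranking("normfinder", ranks_from_scores(res$sv)$ranks,
                                   statistic = res$sv)
  structure(res, class = "normfinder")
}

# bias-corrected per-gene variance from per-sample-centered log values
.nf_sigma2 <- function(z) {
  k <- nrow(z)
  if (ncol(z) < 2) stop("need >= 2 samples per group")
  v <- apply(z, 1, stats::var)
  pmax(k / (k - 2) * (v - sum(v) / (k * (k - 1))), 0)
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder stability analysis (", x$mode, " mode, ",
      length(x$sv), " genes)\n", sep = "")
  best <- names(sort(x$sv))
  cat("  most stable: ", paste(utils::head(best, 3), collapse = ", "),
      "\n  least stable: ", paste(utils::tail(best, 2), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.normfinder <- function(object, ...) {
  df <- data.frame(gene = names(object$sv), sv = unname(object$sv),
                   rank = unname(object$ranking$ranks[names(object$sv)]),
                   stringsAsFactors = FALSE)
  if (object$mode == "grouped") df$gamma2 <- object$gamma2
  df[order(df$rank, df$gene), ]
}

#' @export
plot.normfinder <- function(x, ...) {
  sv <- sort(x$sv)
  graphics::barplot(sv, las = 2, ylab = "stability value (SV)",
                    main = paste0("NormFinder (", x$mode, ")"), ...)
  invisible(x)
}
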