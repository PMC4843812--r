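#' Normalize a target gene against chosen references
#'
#' Computes the relative expression of a target gene normalized by one or
#' more reference genes and reports per-condition fold changes against a
#' control condition (the 2^-ddCt scheme generalised to multi-reference
#' normalization). Per sample, the normalized quantity is the target's
#' relative quantity divided by the geometric mean of the references'
#' relative quantities (the normalization-factor construction); per
#' condition, the fold change is the mean normalized quantity of its
#' biological replicates divided by that of the control condition, so the
#' control is exactly 1.
#'
#' @param x a [ct_table()] (technical replicates collapsed).
#' @param target target gene symbol.
#' @param references character vector of reference gene symbols (one or
#'   more; must not contain the target).
#' @param samples optional sample selection as in [ct_subset()].
#' @param control value of `condition_col` identifying the control
#'   condition (e.g. `0` for the 0 h time point).
#' @param condition_col annotation column defining conditions; default
#'   `"time_point"`.
#' @param base amplification base passed to [delta_ct_transform()].
#' @return An object of class `fold_change_series`: data frame with
#'   `condition`, `fold_change`, `n` (replicates) plus attributes
#'   `target`, `references` and `normalized` (per-sample values).
#' @examples
#' ct <- matrix(c(20, 19, 20, 20, 20, 20), 2, 3, byrow = TRUE,
#'              dimnames = list(c("tgt", "ref"), NULL))
#' tab <- ct_table(ct, data.frame(sample_id = c("a", "b", "c"),
#'                                time_point = c(0, 6, 24)))
#' normalized_expression(tab, "tgt", "ref", control = 0)
#' @export
normalized_expression <- function(x, target, references, samples = NULL,
                                  control, condition_col = "time_point",
                                  base = 2) {
  stopifnot(inherits(x, "ct_table"))
  if (length(references) == 0) stop("empty reference list")
  if (target %in% references) stop("reference equal to target")
  if (!is.null(samples)) x <- ct_subset(x, samples)
  genes <- c(target, references)
  if (!all(genes %in% x$genes))
    stop("unknown gene(s): ", paste(setdiff(genes, x$genes), collapse = ", "))
  cond <- x$samples[[condition_col]]
  if (is.null(cond)) stop("annotation column '", condition_col, "' not found")
  if (!any(cond == control)) stop("control selects no samples")

  rq <- delta_ct_transform(x, base = base)
  q_t <- rq$q[target, ]
  q_r <- exp(colMeans(log(rq$q[references, , drop = FALSE])))
  norm_q <- q_t / q_r

  conds <- unique(cond)
  means <- vapply(conds, function(cc) mean(norm_q[cond == cc]), numeric(1))
  nrep <- vapply(conds, function(cc) sum(cond == cc), integer(1))
  fc <- means / means[match(control, conds)]
  out <- data.frame(condition = conds, fold_change = unname(fc),
                    n = unname(nrep), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "target") <- target
  attr(out, "references") <- references
  attr(out, "normalized") <- norm_q
  class(out) <- c("fold_change_series", "data.frame")
  out
}

#' @export
print.fold_change_series <- function(x, ...) {
  cat("Fold changes of ", attr(x, "target"), " normalized by ",
      paste(attr(x, "references"), collapse = " + "), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normalization bias between two reference choices
#'
#' Per-condition ratio of two fold-change series of the same target under
#' different reference gene sets: a diagnostic of how much an unstable
#' reference distorts (over- or underestimates) apparent expression.
#'
#' @param series_stable,series_unstable [normalized_expression()] results
#'   for the same target over the same conditions.
#' @return Data frame `condition`, `ratio` (unstable-normalized fold
#'   change as seen relative to the stable-normalized one).
#' @export
reference_choice_distortion <- function(series_stable, series_unstable) {
  stopifnot(inherits(series_stable, "fold_change_series"),
            inherits(series_unstable, "fold_change_series"))
  if (!identical(attr(series_stable, "target"),
                 attr(series_unstable, "target")))
    stop("series have different targets")
  if (!identical(series_stable$condition, series_unstable$condition))
    stop("condition mismatch between series")
  data.frame(condition = series_stable$condition,
             ratio = series_unstable$fold_change / series_stable$fold_change,
             row.names = NULL, stringsAsFactors = FALSE)
}
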