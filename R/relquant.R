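#' Relative quantities by the 2^-dCt transform
#'
#' Converts Ct values to relative expression quantities per gene:
#' `q = base^-(Ct - min Ct)`, the minimum taken per gene within the
#' analysed sample set, so that for every gene the best-expressed sample
#' has q = 1 and all quantities lie in (0, 1]. With the default `base = 2`
#' this is exactly the 2^-dCt transform used as input to geNorm and
#' NormFinder; supplying the measured per-gene amplification efficiencies
#' as `base` gives efficiency-corrected quantities.
#'
#' @param x a [ct_table()].
#' @param samples optional sample selection as in [ct_subset()]; the
#'   per-gene minimum is computed within this subset, so each analysis
#'   subset is self-contained.
#' @param base per-cycle amplification factor: a single number in (1, 2]
#'   or a named numeric vector with one entry per gene. Default 2.
#' @return An object of class `relquant`: list with `q` (genes x samples
#'   matrix of relative quantities), `genes`, `samples` (annotations) and
#'   `base`.
#' @examples
#' ct <- ct_table(matrix(c(18, 19, 20), 1, dimnames = list("g1", NULL)))
#' delta_ct_transform(ct)$q  # 1, 0.5, 0.25
#' @export
delta_ct_transform <- function(x, samples = NULL, base = 2) {
  stopifnot(inherits(x, "ct_table"))
  if (!is.null(samples)) x <- ct_subset(x, samples)
  if (ncol(x$ct) < 2) stop("subset selects < 2 samples")
  if (any(is.na(x$ct)))
    stop("completeness error: Ct matrix has missing cells; ",
         "restrict to complete columns first")
  b <- if (length(base) == 1L) rep(base, length(x$genes)) else base[x$genes]
  if (anyNA(b) || any(b <= 1) || any(b > 2))
    stop("value error: base must lie in (1, 2] for every gene")
  dct <- x$ct - apply(x$ct, 1, min)
  q <- b ^ (-dct)
  dimnames(q) <- dimnames(x$ct)
  structure(list(q = q, genes = x$genes, samples = x$samples, base = b),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat("Relative quantities (base^-dCt): ", length(x$genes), " genes x ",
      ncol(x$q), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.relquant <- function(x) dim(x$q)

# internal: accept a relquant or a bare positive matrix
.q_matrix <- function(x) {
  if (inherits(x, "relquant")) return(x$q)
  if (is.matrix(x) && is.numeric(x)) {
    if (any(x <= 0)) stop("value error: quantities must be > 0")
    return(x)
  }
  stop("expected a 'relquant' object or a positive numeric matrix")
}
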