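#' Construct a Ct table
#'
#' A `ct_table` holds quantification-cycle (Ct) values as a genes x samples
#' matrix together with per-sample annotations. It is the raw input of all
#' downstream qPCR stability analyses. Lower Ct means higher transcript
#' abundance; one cycle corresponds roughly to one doubling of template.
#'
#' @param ct numeric matrix of Ct values (cycles) with one row per gene and
#'   one column per sample; rownames are gene symbols.
#' @param samples data frame of sample annotations with at least a
#'   `sample_id` column; recognised optional columns are `subset`, `group`,
#'   `time_point`, `bio_replicate` and `tech_replicate`. One row per column
#'   of `ct`, in the same order. If `NULL`, minimal annotations are built
#'   from the column names of `ct`.
#' @param allow_missing logical; if `FALSE` (default) any missing Ct cell is
#'   an error. Downstream algorithms require complete matrices.
#'
#' @details Ct values must be finite and in (0, 45]; standard protocols run
#'   40-45 cycles, so values above 40 are accepted but reported as
#'   near-floor detections via a message. Gene symbols must be unique.
#'
#' @return An object of class `ct_table`: a list with elements `ct`
#'   (numeric matrix), `genes`, and `samples` (annotation data frame).
#' @seealso [read_ct_table()], [collapse_technical_replicates()],
#'   [summarize_ct()], [delta_ct_transform()]
#' @examples
#' ct <- matrix(c(20, 21, 19, 22, 23, 21), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("ACT", "GAPDH"), c("s1", "s2", "s3")))
#' ct_table(ct)
#' @export
ct_table <- function(ct, samples = NULL, allow_missing = FALSE) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)))
    stop("format error: 'ct' must have gene symbols as rownames")
  if (anyDuplicated(rownames(ct)))
    stop("format error: duplicate gene symbol(s): ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (is.null(colnames(ct)))
    colnames(ct) <- paste0("sample", seq_len(ncol(ct)))

  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(ct), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(samples) || is.null(samples$sample_id))
    stop("'samples' must be a data frame with a 'sample_id' column")
  if (nrow(samples) != ncol(ct))
    stop("'samples' must have one row per column of 'ct' (",
         nrow(samples), " vs ", ncol(ct), ")")
  if (is.null(samples$subset)) samples$subset <- "all"
  if (is.null(samples$bio_replicate)) samples$bio_replicate <- 1L
  if (is.null(samples$tech_replicate)) samples$tech_replicate <- 1L
  if (any(samples$bio_replicate < 1L) || any(samples$tech_replicate < 1L))
    stop("replicate indices must be >= 1")

  key <- paste(samples$sample_id, samples$tech_replicate)
  if (anyDuplicated(key))
    stop("format error: duplicate (sample_id, tech_replicate) pair(s)")
  colnames(ct) <- if (anyDuplicated(samples$sample_id))
    paste(samples$sample_id, samples$tech_replicate, sep = ".") else samples$sample_id

  .validate_ct_values(ct, allow_missing)

  structure(list(ct = ct, genes = rownames(ct), samples = samples),
            class = "ct_table")
}

.validate_ct_values <- function(ct, allow_missing) {
  miss <- which(is.na(ct), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    cells <- paste0("(", rownames(ct)[miss[, 1]], ", ",
                    colnames(ct)[miss[, 2]], ")")
    if (!allow_missing)
      stop("completeness error: missing Ct in cell(s) ",
           paste(utils::head(cells, 10L), collapse = ", "))
    message("Ct table contains ", nrow(miss), " missing cell(s); ",
            "subset analyses will be restricted to complete columns")
  }
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0 | ct > 45), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("value error: Ct outside (0, 45] in cell (",
         rownames(ct)[bad[1, 1]], ", ", colnames(ct)[bad[1, 2]], "): ",
         ct[bad[1, , drop = FALSE]])
  n_hi <- sum(ct > 40, na.rm = TRUE)
  if (n_hi > 0)
    message(n_hi, " Ct value(s) above 40 cycles: near-floor detections")
  invisible(ct)
}

#' @export
print.ct_table <- function(x, ...) {
  cat("Ct table: ", length(x$genes), " genes x ", nrow(x$samples),
      " samples\n", sep = "")
  cat("  subsets: ", paste(unique(x$samples$subset), collapse = ", "), "\n",
      sep = "")
  rng <- range(x$ct, na.rm = TRUE)
  cat(sprintf("  Ct range: %.2f - %.2f cycles\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Subset a Ct table by sample
#'
#' @param x a [ct_table()].
#' @param samples character vector of sample ids, a logical vector over
#'   samples, or the name of a subset label found in `x$samples$subset`.
#' @return A `ct_table` restricted to the selected samples.
#' @export
ct_subset <- function(x, samples) {
  stopifnot(inherits(x, "ct_table"))
  if (is.logical(samples)) {
    keep <- which(samples)
  } else if (all(samples %in% x$samples$subset)) {
    keep <- which(x$samples$subset %in% samples)
  } else {
    keep <- match(samples, x$samples$sample_id)
    if (anyNA(keep))
      stop("unknown sample id(s): ",
           paste(samples[is.na(keep)], collapse = ", "))
  }
  if (length(keep) == 0) stop("empty sample selection")
  ct_table(x$ct[, keep, drop = FALSE],
           x$samples[keep, , drop = FALSE],
           allow_missing = TRUE)
}

.delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a Ct table from CSV/TSV
#'
#' Wide layout: genes as rows, a leading `gene` column and one column per
#' sample (header row of sample ids). Long layout: one record per
#' (gene, sample) with columns `gene`, `sample_id`, `ct` and any of the
#' annotation columns `subset`, `group`, `time_point`, `bio_replicate`,
#' `tech_replicate`.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is given.
#' @param layout `"wide"` or `"long"`.
#' @param samples optional annotation data frame for the wide layout.
#' @param allow_missing passed to [ct_table()].
#' @param delim optional field delimiter override.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, layout = c("wide", "long"), samples = NULL,
                          allow_missing = FALSE, delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (layout == "wide") {
    if (ncol(df) < 2) stop("format error: wide layout needs a gene column plus samples")
    genes <- as.character(df[[1]])
    if (any(is.na(genes) | genes == ""))
      stop("format error: missing gene symbol")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m) &
                     m != "NA", arr.ind = TRUE)
      if (nrow(bad) > 0)
        stop("value error: non-numeric Ct in cell (", genes[bad[1, 1]], ", ",
             colnames(m)[bad[1, 2]], "): '", m[bad[1, , drop = FALSE]], "'")
      m <- array(suppressWarnings(as.numeric(m)), dim(m), dimnames(m))
    }
    rownames(m) <- genes
    ct_table(m, samples, allow_missing = allow_missing)
  } else {
    need <- c("gene", "sample_id", "ct")
    if (!all(need %in% names(df)))
      stop("format error: long layout needs columns ", paste(need, collapse = ", "))
    ann_cols <- intersect(c("subset", "group", "time_point",
                            "bio_replicate", "tech_replicate"), names(df))
    df$.col <- paste(df$sample_id,
                     if ("tech_replicate" %in% ann_cols) df$tech_replicate else 1L)
    cols <- unique(df$.col)
    genes <- unique(df$gene)
    m <- matrix(NA_real_, length(genes), length(cols),
                dimnames = list(genes, cols))
    m[cbind(match(df$gene, genes), match(df$.col, cols))] <- df$ct
    first <- df[!duplicated(df$.col), c("sample_id", ann_cols), drop = FALSE]
    ct_table(m, first, allow_missing = allow_missing)
  }
}

#' Write a Ct table to CSV/TSV
#'
#' @param x a [ct_table()].
#' @param path output file path; delimiter inferred from extension.
#' @param layout `"wide"` or `"long"`.
#' @param delim optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, layout = c("wide", "long"), delim = NULL) {
  stopifnot(inherits(x, "ct_table"))
  layout <- match.arg(layout)
  sep <- .delim_for(path, delim)
  if (layout == "wide") {
    df <- data.frame(gene = x$genes, x$ct, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    ann <- x$samples
    long <- do.call(rbind, lapply(seq_along(x$genes), function(i) {
      cbind(data.frame(gene = x$genes[i], stringsAsFactors = FALSE),
            ann, data.frame(ct = x$ct[i, ]))
    }))
    rownames(long) <- NULL
    utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses technical replicates of each biological sample to a single
#' column by the arithmetic mean of their Ct values (the conventional qPCR
#' aggregation). Biological replicates are kept as separate samples: the
#' stability statistics need biological variation.
#'
#' @param x a [ct_table()] whose annotations carry `tech_replicate`.
#' @param dispersion_warn cycles; technical replicates of one sample
#'   spanning more than this range trigger a warning naming the worst
#'   (gene, sample) cell. Default 0.5 cycles.
#' @return A [ct_table()] with one column per biological sample and the
#'   `tech_replicate` annotation dropped.
#' @export
collapse_technical_replicates <- function(x, dispersion_warn = 0.5) {
  stopifnot(inherits(x, "ct_table"))
  ids <- unique(x$samples$sample_id)
  groups <- lapply(ids, function(id) which(x$samples$sample_id == id))
  if (any(lengths(groups) == 0)) stop("replicate group of size 0")
  m <- sapply(groups, function(j) rowMeans(x$ct[, j, drop = FALSE]))
  m <- matrix(m, nrow = length(x$genes), dimnames = list(x$genes, ids))
  spans <- sapply(groups, function(j) {
    if (length(j) < 2) return(0)
    max(apply(x$ct[, j, drop = FALSE], 1, function(v) diff(range(v))))
  })
  if (any(spans > dispersion_warn)) {
    worst <- which.max(spans)
    warning(sum(spans > dispersion_warn), " sample(s) with technical-replicate ",
            "dispersion > ", dispersion_warn, " cycles (worst: ",
            ids[worst], ", ", sprintf("%.2f", spans[worst]), " cycles)")
  }
  ann <- x$samples[!duplicated(x$samples$sample_id), , drop = FALSE]
  ann$tech_replicate <- NULL
  out <- ct_table(m, ann)
  out$samples$tech_replicate <- NULL
  out
}

#' Per-gene descriptive Ct summary
#'
#' Summarises each gene's Ct distribution across samples (the usual
#' box-plot view of candidate reference genes): mean, sample SD (n-1
#' denominator), minimum, quartiles, median and maximum.
#'
#' @param x a [ct_table()] with at least 2 samples.
#' @return A data frame with one row per gene and columns `gene`, `n`,
#'   `mean`, `sd`, `min`, `q25`, `median`, `q75`, `max`.
#' @export
summarize_ct <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  if (ncol(x$ct) < 2) stop("need >= 2 samples")
  qs <- t(apply(x$ct, 1, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  data.frame(gene = x$genes,
             n = rowSums(!is.na(x$ct)),
             mean = rowMeans(x$ct, na.rm = TRUE),
             sd = apply(x$ct, 1, stats::sd, na.rm = TRUE),
             min = qs[, 1], q25 = qs[, 2], median = qs[, 3],
             q75 = qs[, 4], max = qs[, 5],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a primer/gene metadata table
#'
#' Reads the qPCR primer description table: one row per assay with gene
#' symbol and id, primer sequences, amplicon length (bp), per-cycle
#' amplification efficiency E (dimensionless; 2 = perfect doubling) and
#' the standard-curve R-squared.
#'
#' @param path CSV/TSV file with columns `gene_symbol`, `gene_id`,
#'   `forward_primer`, `reverse_primer`, `amplicon_bp`, `efficiency`,
#'   `r_squared`, and optionally `gene_name`, `arabidopsis_locus` and
#'   `is_candidate_reference`.
#' @param target_genes optional character vector of validation target
#'   symbols; used to infer `is_candidate_reference` when that column is
#'   absent.
#' @param delim optional delimiter override.
#' @return A data frame of class `primer_table`, rows in file order.
#' @details Efficiencies outside (1, 2] are an error. Amplicon lengths
#'   outside the usual 100-250 bp design window are accepted with a
#'   warning.
#' @export
read_primer_table <- function(path, target_genes = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_symbol", "gene_id", "forward_primer", "reverse_primer",
            "amplicon_bp", "efficiency", "r_squared")
  if (!all(need %in% names(df)))
    stop("format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$gene_symbol))
    stop("format error: duplicate gene symbol(s): ",
         paste(unique(df$gene_symbol[duplicated(df$gene_symbol)]), collapse = ", "))
  if (any(df$amplicon_bp <= 0)) stop("value error: amplicon_bp must be > 0")
  bad_e <- df$efficiency <= 1 | df$efficiency > 2
  if (any(bad_e))
    stop("value error: efficiency outside (1, 2] for ",
         paste(df$gene_symbol[bad_e], collapse = ", "))
  if (any(df$r_squared <= 0 | df$r_squared > 1))
    stop("value error: r_squared outside (0, 1]")
  out_rng <- df$amplicon_bp < 100 | df$amplicon_bp > 250
  if (any(out_rng))
    warning("amplicon length outside 100-250 bp for ",
            paste(df$gene_symbol[out_rng], collapse = ", "))
  if (is.null(df$is_candidate_reference)) {
    df$is_candidate_reference <- !(df$gene_symbol %in% target_genes)
  } else {
    df$is_candidate_reference <- as.logical(df$is_candidate_reference)
  }
  class(df) <- c("primer_table", "data.frame")
  df
}

#' Construct an FPKM expression table
#'
#' @param fpkm numeric matrix of FPKM values (>= 0), unigenes as rows
#'   (rownames) and sample/condition labels as columns.
#' @return An object of class `fpkm_table`.
#' @export
fpkm_table <- function(fpkm) {
  if (!is.matrix(fpkm) || !is.numeric(fpkm))
    stop("'fpkm' must be a numeric matrix")
  if (is.null(rownames(fpkm))) stop("format error: unigene ids required as rownames")
  if (anyDuplicated(rownames(fpkm)))
    stop("format error: duplicate unigene id(s)")
  if (any(!is.finite(fpkm)) || any(fpkm < 0))
    stop("value error: FPKM values must be finite and >= 0")
  if (is.null(colnames(fpkm)))
    colnames(fpkm) <- paste0("cond", seq_len(ncol(fpkm)))
  structure(list(fpkm = fpkm, unigenes = rownames(fpkm),
                 conditions = colnames(fpkm)),
            class = "fpkm_table")
}

#' Read an FPKM table from CSV/TSV (unigenes as rows)
#'
#' @param path file path; first column unigene id, remaining columns FPKM
#'   per condition.
#' @param delim optional delimiter override.
#' @return An [fpkm_table()].
#' @export
read_fpkm_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  fpkm_table(m)
}
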