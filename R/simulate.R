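#' Configuration for the synthetic Ct generator
#'
#' Describes one simulated qPCR experiment: a time-course subset with a
#' per-gene baseline Ct, a shared per-sample loading effect, optional
#' gene-by-condition destabilization shifts, and per-gene Gaussian Ct
#' noise. The error model is additive Gaussian on the Ct (cycle) scale,
#' i.e. multiplicative log-normal on abundance -- the standard qPCR noise
#' model. Default baselines span 13-25 cycles, the range observed for
#' typical candidate reference genes.
#'
#' @param n_genes number of candidate genes.
#' @param timepoints condition labels (hours); default the 0/1/6/24 h
#'   time course.
#' @param n_bio_replicates biological replicates per condition (>= 1).
#' @param n_tech_replicates technical replicates per biological sample.
#' @param baseline_ct optional per-gene baseline Ct (cycles); drawn
#'   uniformly from `baseline_range` when `NULL`.
#' @param baseline_range range baselines are drawn from, in cycles.
#' @param loading_sd SD (cycles) of the per-sample loading effect shared
#'   by all genes of a sample (template amount, RT efficiency).
#' @param effects named list mapping gene name to a numeric vector of
#'   per-condition Ct shifts (cycles); genes with non-constant shifts are
#'   designed-unstable.
#' @param noise_sd per-gene Ct noise SD (cycles); scalar or per-gene
#'   vector. Default 0.2 cycles, a typical within-assay spread.
#' @param tech_sd SD of the small independent technical-replicate jitter.
#' @param genes optional gene names.
#' @param subset subset label written into the sample annotations.
#' @param seed optional integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 14, timepoints = c(0, 1, 6, 24),
                             n_bio_replicates = 3, n_tech_replicates = 1,
                             baseline_ct = NULL, baseline_range = c(13, 25),
                             loading_sd = 0.5, effects = list(),
                             noise_sd = 0.2, tech_sd = 0.05,
                             genes = NULL, subset = "treatment",
                             seed = NULL) {
  if (n_bio_replicates < 1 || n_tech_replicates < 1)
    stop("replicate counts must be >= 1")
  if (any(c(loading_sd, noise_sd, tech_sd) < 0)) stop("SDs must be >= 0")
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(n_genes))
  if (length(genes) != n_genes) stop("'genes' length must equal n_genes")
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, n_genes)
  if (length(noise_sd) != n_genes) stop("'noise_sd' must be scalar or per-gene")
  if (!is.null(baseline_ct) && length(baseline_ct) != n_genes)
    stop("'baseline_ct' must have one value per gene")
  if (length(effects) > 0) {
    if (is.null(names(effects)) || !all(names(effects) %in% genes))
      stop("'effects' must be named by gene")
    if (any(lengths(effects) != length(timepoints)))
      stop("each effect vector needs one shift per condition")
  }
  structure(list(n_genes = n_genes, timepoints = timepoints,
                 n_bio_replicates = n_bio_replicates,
                 n_tech_replicates = n_tech_replicates,
                 baseline_ct = baseline_ct, baseline_range = baseline_range,
                 loading_sd = loading_sd, effects = effects,
                 noise_sd = stats::setNames(noise_sd, genes),
                 tech_sd = tech_sd, genes = genes, subset = subset,
                 seed = seed),
            class = "synthetic_config")
}

# population variance (1/n), used for the condition-shift component of the
# true stability score: every condition weighs equally
.popvar <- function(v) mean((v - mean(v))^2)

#' Simulate a Ct table with known ground truth
#'
#' Draws `Ct = baseline + loading + effect(condition) + noise` per gene
#' and biological sample, with an independent small jitter per technical
#' replicate. The loading effect is shared across all genes of a sample,
#' so ratio-based statistics (geNorm M, NormFinder SV) are blind to it
#' while raw-Ct statistics (BestKeeper SD) are not. The returned truth
#' carries the realised parameters and the implied true stability score
#' per gene, `sqrt(noise_sd^2 + popvar(condition shifts))`, whose
#' ascending order is the true stability order.
#'
#' @param config a [synthetic_config()].
#' @return List with `table` (a [ct_table()]) and `truth` (list:
#'   `baseline_ct`, `loading`, `effects`, `noise_sd`, `true_score`,
#'   `true_order`).
#' @examples
#' sim <- simulate_ct(synthetic_config(n_genes = 5, seed = 1))
#' sim$table
#' sim$truth$true_order
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- config$genes
  k <- length(g)
  tp <- config$timepoints
  nb <- config$n_bio_replicates
  nt <- config$n_tech_replicates

  baseline <- config$baseline_ct
  if (is.null(baseline))
    baseline <- stats::runif(k, config$baseline_range[1], config$baseline_range[2])
  names(baseline) <- g

  eff <- matrix(0, k, length(tp), dimnames = list(g, as.character(tp)))
  for (nm in names(config$effects)) eff[nm, ] <- config$effects[[nm]]

  n_bio <- length(tp) * nb
  loading <- stats::rnorm(n_bio, 0, config$loading_sd)
  cond_of <- rep(seq_along(tp), each = nb)

  ann <- data.frame(
    sample_id = paste0(config$subset, "_t", rep(tp, each = nb * nt),
                       "_r", rep(rep(seq_len(nb), each = nt), length(tp)),
                       if (nt > 1) paste0("_", rep(seq_len(nt), nb * length(tp))) else ""),
    subset = config$subset,
    time_point = rep(tp, each = nb * nt),
    bio_replicate = rep(rep(seq_len(nb), each = nt), length(tp)),
    tech_replicate = rep(seq_len(nt), nb * length(tp)),
    stringsAsFactors = FALSE)
  # sample_id identifies the biological sample; tech replicates share it
  ann$sample_id <- paste0(config$subset, "_t", ann$time_point, "_r",
                          ann$bio_replicate)

  ct <- matrix(NA_real_, k, nrow(ann), dimnames = list(g, NULL))
  bio_idx <- (match(ann$time_point, tp) - 1L) * nb + ann$bio_replicate
  bio_noise <- matrix(stats::rnorm(k * n_bio, 0, config$noise_sd), k, n_bio)
  for (col in seq_len(nrow(ann))) {
    b <- bio_idx[col]
    mu <- baseline + loading[b] + eff[, match(ann$time_point[col], tp)] +
      bio_noise[, b]
    ct[, col] <- mu + if (nt > 1) stats::rnorm(k, 0, config$tech_sd) else 0
  }
  ct <- pmin(pmax(ct, 1e-3), 45)

  true_score <- sqrt(config$noise_sd^2 + apply(eff, 1, .popvar))
  list(table = ct_table(ct, ann),
       truth = list(baseline_ct = baseline, loading = loading,
                    effects = eff, noise_sd = config$noise_sd,
                    loading_sd = config$loading_sd,
                    true_score = true_score,
                    true_order = names(sort(true_score))))
}

#' Default benchmark scenario for the stability algorithms
#'
#' The reference synthetic experiment used to benchmark the whole
#' pipeline: 14 candidate genes over a 0/1/6/24 h time course with 3
#' biological replicates (12 samples), a 0.5-cycle shared loading effect,
#' two designed-stable genes (gene01, gene02; noise SD 0.05 cycles), one
#' treatment-responsive gene (gene13; Ct shifts 0/+1/+2/+2 cycles), one
#' high-noise gene (gene14; noise SD 1.5 cycles) and baseline noise of
#' 0.2 cycles elsewhere. A sound analysis should place the two designed-
#' stable genes at the top of the consensus and the two designed-unstable
#' ones at the bottom of every algorithm's ranking.
#'
#' @param seed optional integer seed.
#' @return A [synthetic_config()].
#' @export
benchmark_config <- function(seed = NULL) {
  synthetic_config(
    n_genes = 14, timepoints = c(0, 1, 6, 24), n_bio_replicates = 3,
    loading_sd = 0.5,
    noise_sd = c(0.05, 0.05, rep(0.2, 11), 1.5),
    effects = list(gene13 = c(0, 1, 2, 2)),
    seed = seed)
}

#' Simulate the full multi-subset study design
#'
#' Generates one Ct table spanning the standard design: seven treatment
#' time courses (NaCl, PEG, cold, heat, ABA, MeJA, SNP; 0/1/6/24 h) plus
#' a nine-tissue panel, each with its own loading effects and noise, over
#' a shared set of genes and baselines. The pooled "all samples" subset
#' is the union of all columns.
#'
#' @param n_genes,n_bio_replicates,n_tech_replicates,loading_sd,noise_sd,tech_sd,baseline_range
#'   as in [synthetic_config()], applied to every subset.
#' @param effects named list mapping subset name to a per-gene effects
#'   list (as in [synthetic_config()]).
#' @param genes optional gene names.
#' @param seed optional integer seed.
#' @return List with `table` (combined [ct_table()]), `truth` (per-subset
#'   truth lists) and `subsets` (subset names, excluding the implicit
#'   pooled set).
#' @export
simulate_study <- function(n_genes = 14, n_bio_replicates = 3,
                           n_tech_replicates = 1, loading_sd = 0.5,
                           noise_sd = 0.2, tech_sd = 0.05,
                           baseline_range = c(13, 25), effects = list(),
                           genes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(n_genes))
  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  treatments <- c("NaCl", "PEG", "cold", "heat", "ABA", "MeJA", "SNP")
  tissues <- c("filament", "anther", "column", "petal", "ovary", "stem",
               "root", "bulb", "leaf")
  pieces <- list()
  truth <- list()
  for (tr in treatments) {
    cfg <- synthetic_config(n_genes = n_genes, timepoints = c(0, 1, 6, 24),
                            n_bio_replicates = n_bio_replicates,
                            n_tech_replicates = n_tech_replicates,
                            baseline_ct = baseline, loading_sd = loading_sd,
                            effects = if (tr %in% names(effects)) effects[[tr]] else list(),
                            noise_sd = noise_sd, tech_sd = tech_sd,
                            genes = genes, subset = tr)
    sim <- simulate_ct(cfg)
    pieces[[tr]] <- sim$table
    truth[[tr]] <- sim$truth
  }
  cfg <- synthetic_config(n_genes = n_genes,
                          timepoints = seq_along(tissues),
                          n_bio_replicates = n_bio_replicates,
                          n_tech_replicates = n_tech_replicates,
                          baseline_ct = baseline, loading_sd = loading_sd,
                          effects = if ("tissue" %in% names(effects)) effects[["tissue"]] else list(),
                          noise_sd = noise_sd, tech_sd = tech_sd,
                          genes = genes, subset = "tissue")
  sim <- simulate_ct(cfg)
  sim$table$samples$tissue <- tissues[sim$table$samples$time_point]
  sim$table$samples$time_point <- NULL
  pieces[["tissue"]] <- sim$table
  truth[["tissue"]] <- sim$truth

  ct <- do.call(cbind, lapply(pieces, function(p) p$ct))
  ann <- do.call(rbind, lapply(pieces, function(p) {
    s <- p$samples
    for (col in c("time_point", "tissue"))
      if (is.null(s[[col]])) s[[col]] <- NA
    s[, c("sample_id", "subset", "time_point", "tissue",
          "bio_replicate", "tech_replicate")]
  }))
  rownames(ann) <- NULL
  list(table = ct_table(ct, ann), truth = truth,
       subsets = c(treatments, "tissue"))
}

#' Simulate an FPKM table with requested mean and CV
#'
#' Draws log-normal FPKM values moment-matched to the requested per-
#' unigene mean and coefficient of variation: `sdlog^2 = log(1 + cv^2)`,
#' `meanlog = log(mean) - sdlog^2/2`. A CV of 0 yields constant rows.
#'
#' @param mean positive per-unigene mean FPKM (named vector, names become
#'   unigene ids).
#' @param cv per-unigene CV (>= 0); scalar or vector.
#' @param n_conditions number of columns to draw.
#' @param seed optional integer seed.
#' @return List with `table` (an [fpkm_table()]) and `truth` (data frame
#'   `unigene`, `mean`, `cv`).
#' @export
simulate_fpkm <- function(mean, cv, n_conditions, seed = NULL) {
  if (any(mean <= 0)) stop("invalid moments: means must be > 0")
  if (any(cv < 0)) stop("invalid moments: cv must be >= 0")
  if (n_conditions < 1) stop("need >= 1 condition")
  if (!is.null(seed)) set.seed(seed)
  n <- length(mean)
  if (length(cv) == 1L) cv <- rep(cv, n)
  if (length(cv) != n) stop("'cv' must be scalar or one per unigene")
  ids <- names(mean)
  if (is.null(ids)) ids <- sprintf("unigene%03d", seq_len(n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  m <- matrix(stats::rlnorm(n * n_conditions, rep(meanlog, n_conditions),
                            rep(sdlog, n_conditions)),
              n, n_conditions, dimnames = list(ids, NULL))
  list(table = fpkm_table(m),
       truth = data.frame(unigene = ids, mean = unname(mean),
                          cv = unname(cv), row.names = NULL,
                          stringsAsFactors = FALSE))
}
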