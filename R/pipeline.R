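#' Run the full stability analysis pipeline
#'
#' One-call orchestration of the whole workflow: load (or simulate) a Ct
#' table, collapse technical replicates, and for every analysis subset
#' run geNorm, NormFinder and BestKeeper, aggregate them into the
#' geometric-mean comprehensive ranking, and write tidy CSV outputs plus
#' a run manifest. Optional stages screen an FPKM table and normalize a
#' target gene against chosen references.
#'
#' @param config a configuration list or the path to a YAML file with the
#'   same structure. Recognised entries:
#'   \describe{
#'     \item{seed}{integer seed used for simulation.}
#'     \item{simulate}{list of [simulate_study()] arguments (synthetic
#'       input), or}
#'     \item{input}{list with `ct` (path), `layout`, optional `samples`
#'       annotation CSV path.}
#'     \item{subsets}{subset names to analyse; default all subset labels
#'       present plus the pooled `"all"`.}
#'     \item{parameters}{list: `v_cutoff` (0.15), `m_threshold` (1.5),
#'       `sd_threshold` (1), `base` (2).}
#'     \item{fpkm}{list: `path`, `min_mv`, `max_cv`.}
#'     \item{validation}{list: `target`, `references`, `subset`,
#'       `control`, optional `condition_col`.}
#'   }
#' @param output_dir directory for outputs; created if needed. Overrides
#'   `config$output_dir`.
#' @return A list of class `run_manifest`: configuration digest, input
#'   digests, package version, seed, per-subset result objects and output
#'   paths, warnings log, and status.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  par <- config$parameters %||% list()
  v_cutoff <- par$v_cutoff %||% 0.15
  m_threshold <- par$m_threshold %||% 1.5
  sd_threshold <- par$sd_threshold %||% 1
  base <- par$base %||% 2

  manifest <- list(package_version = as.character(utils::packageVersion("refstab")),
                   seed = config$seed, config_digest = .digest_obj(config),
                   input_digests = character(0), outputs = list(),
                   results = list(), warnings = character(0),
                   status = "running", output_dir = out_dir)
  log_warn <- function(w) manifest$warnings <<- c(manifest$warnings, w)

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$input)) {
      tab <- read_ct_table(config$input$ct,
                           layout = config$input$layout %||% "wide",
                           allow_missing = isTRUE(config$input$allow_missing))
      manifest$input_digests <- tools::md5sum(config$input$ct)
    } else {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- withCallingHandlers(
        do.call(simulate_study, sim_args),
        warning = function(w) { log_warn(conditionMessage(w)); invokeRestart("muffleWarning") })
      tab <- sim$table
      manifest$truth <- sim$truth
    }
    if (any(tab$samples$tech_replicate > 1))
      tab <- withCallingHandlers(
        collapse_technical_replicates(tab),
        warning = function(w) { log_warn(conditionMessage(w)); invokeRestart("muffleWarning") })

    stage <- "design"
    present <- unique(tab$samples$subset)
    subsets <- config$subsets %||% c(present, "all")
    unknown <- setdiff(setdiff(subsets, "all"), present)
    if (length(unknown))
      stop("validation error: unknown subset name(s): ",
           paste(unknown, collapse = ", "))

    for (ss in subsets) {
      stage <- paste0("subset:", ss)
      sub_tab <- if (ss == "all") tab else ct_subset(tab, ss)
      q <- delta_ct_transform(sub_tab, base = base)
      gn <- genorm(q, m_threshold = m_threshold, v_cutoff = v_cutoff)
      nf <- normfinder(q)
      bk <- bestkeeper(sub_tab, sd_threshold = sd_threshold)
      cons <- consensus_rank(list(gn, nf, bk), genes = sub_tab$genes)
      manifest$results[[ss]] <- list(genorm = gn, normfinder = nf,
                                     bestkeeper = bk, consensus = cons,
                                     summary = summarize_ct(sub_tab))
      manifest$outputs[[ss]] <- .write_subset_outputs(
        out_dir, ss, sub_tab, gn, nf, bk, cons)
      if (length(bk$excluded))
        log_warn(paste0(ss, ": BestKeeper excluded (SD > ", sd_threshold,
                        "): ", paste(bk$excluded, collapse = ", ")))
    }

    if (!is.null(config$fpkm)) {
      stage <- "fpkm_screen"
      ft <- read_fpkm_table(config$fpkm$path)
      manifest$input_digests <- c(manifest$input_digests,
                                  tools::md5sum(config$fpkm$path))
      st <- fpkm_stats(ft)
      sc <- screen_candidates(st, min_mv = config$fpkm$min_mv %||% 1,
                              max_cv = config$fpkm$max_cv %||% Inf)
      p <- file.path(out_dir, "fpkm_screen.csv")
      utils::write.csv(sc, p, row.names = FALSE, quote = FALSE)
      manifest$results$fpkm_screen <- sc
      manifest$outputs$fpkm_screen <- p
    }

    if (!is.null(config$validation)) {
      stage <- "validation"
      v <- config$validation
      fc <- normalized_expression(tab, v$target, unlist(v$references),
                                  samples = v$subset, control = v$control,
                                  condition_col = v$condition_col %||% "time_point",
                                  base = base)
      p <- file.path(out_dir, "target_validation.csv")
      df <- cbind(subset = v$subset, as.data.frame(fc),
                  references = paste(unlist(v$references), collapse = "+"))
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      manifest$results$validation <- fc
      manifest$outputs$validation <- p
    }
    "ok"
  }, error = function(e) e)

  if (inherits(result, "error")) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    .write_manifest(manifest)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(result))
  }
  manifest$status <- "ok"
  .write_manifest(manifest)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.write_manifest <- function(manifest) {
  keep <- manifest[c("package_version", "seed", "config_digest",
                     "input_digests", "warnings", "status", "output_dir")]
  keep$failed_stage <- manifest$failed_stage
  keep$outputs <- lapply(manifest$outputs, unname)
  yaml::write_yaml(keep, file.path(manifest$output_dir, "manifest.yaml"))
}

.num <- function(x) formatC(x, digits = 10, format = "g")

.write_subset_outputs <- function(out_dir, ss, tab, gn, nf, bk, cons) {
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(ss, "_", name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
  }
  m_tidy <- do.call(rbind, lapply(seq_along(gn$m_trajectory), function(r) {
    m <- gn$m_trajectory[[r]]
    data.frame(subset = ss, round = r, gene = names(m), M = .num(m),
               stringsAsFactors = FALSE)
  }))
  w(m_tidy, "genorm_m")
  w(data.frame(subset = ss, n = as.integer(names(gn$v_series)),
               value = .num(gn$v_series),
               below_cutoff = gn$v_series < gn$v_cutoff), "v_series")
  w(data.frame(subset = ss, gene = names(nf$sv), statistic = "SV",
               value = .num(nf$sv), rank = unname(nf$ranking$ranks[names(nf$sv)]),
               mode = nf$mode), "normfinder")
  bks <- bk$stats
  num_cols <- c("geo_mean", "ar_mean", "min", "max", "sd", "cv", "r", "p")
  for (cc in num_cols) bks[[cc]] <- .num(bks[[cc]])
  w(cbind(subset = ss, bks), "bestkeeper")
  ctab <- cons$table
  ctab$geomean <- .num(ctab$geomean)
  w(cbind(subset = ss, ctab), "consensus")
  # Table-2-style wide layout: one row per algorithm plus the consensus
  k <- length(cons$order)
  wide <- rbind(genorm = gn$ranked_genes,
                normfinder = names(sort(nf$ranking$ranks)),
                bestkeeper = bk$ranked_genes,
                comprehensive = cons$order)
  wide_df <- data.frame(subset = ss, algorithm = rownames(wide), wide,
                        stringsAsFactors = FALSE, check.names = FALSE)
  colnames(wide_df) <- c("subset", "algorithm", as.character(seq_len(k)))
  w(wide_df, "ranking_table")
  smry <- summarize_ct(tab)
  for (cc in setdiff(names(smry), c("gene", "n"))) smry[[cc]] <- .num(smry[[cc]])
  w(cbind(subset = ss, smry), "ct_summary")
  paths
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("refstab pipeline run (", x$status, ")\n", sep = "")
  cat("  package ", x$package_version, ", seed ",
      x$seed %||% "none", "\n", sep = "")
  cat("  subsets: ", paste(names(x$results), collapse = ", "), "\n", sep = "")
  cat("  outputs under ", x$output_dir, "\n", sep = "")
  if (length(x$warnings))
    cat("  warnings: ", length(x$warnings), "\n", sep = "")
  invisible(x)
}

#' Render a human-readable report from a pipeline run
#'
#' Summarises a [run_pipeline()] manifest: per-subset comprehensive
#' rankings, the recommended number of reference genes (or a note that no
#' pairwise variation fell below the cutoff), BestKeeper exclusions and
#' logged warnings. Regeneration from the same manifest is idempotent.
#'
#' @param manifest a `run_manifest`.
#' @param file optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly when `file` is
#'   given.
#' @export
render_report <- function(manifest, file = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (length(manifest$results) == 0) stop("manifest has no results")
  lines <- c("Reference gene stability report",
             paste0("package refstab ", manifest$package_version,
                    "; seed ", manifest$seed %||% "none"), "")
  subset_names <- setdiff(names(manifest$results),
                          c("fpkm_screen", "validation"))
  for (ss in subset_names) {
    r <- manifest$results[[ss]]
    gn <- r$genorm
    lines <- c(lines, paste0("[", ss, "]"),
               paste0("  comprehensive ranking: ",
                      paste(r$consensus$order, collapse = " > ")),
               paste0("  geNorm best pair: ",
                      paste(gn$final_pair, collapse = "/")),
               if (is.na(gn$recommended_n))
                 paste0("  optimal n: none (lowest V(n/n+1) = ",
                        sprintf("%.3f", min(gn$v_series)), " >= ",
                        gn$v_cutoff, ")")
               else paste0("  optimal n: ", gn$recommended_n,
                           " (V = ", sprintf("%.3f",
                             gn$v_series[as.character(gn$recommended_n)]), ")"),
               if (length(r$bestkeeper$excluded))
                 paste0("  BestKeeper excluded: ",
                        paste(r$bestkeeper$excluded, collapse = ", "))
               else "  BestKeeper excluded: none",
               "")
  }
  if (length(manifest$warnings))
    lines <- c(lines, "Warnings:", paste0("  - ", manifest$warnings))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
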