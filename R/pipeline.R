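config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("rgstab_config_error",
                                             "error", "condition")))
}

pipeline_stages <- c("simulate", "preselect", "stability", "combos")

#' Run the full reference-gene selection pipeline
#'
#' Orchestrates the stages in study order -- simulate (optional),
#' preselect (optional, needs a count matrix), stability + consensus,
#' combinations -- writing one TSV per stage plus a machine-readable JSON
#' run report (input digests, config echo, output digests, package
#' version, seed) that fully determines a re-run. Logs go to standard
#' error; stage outputs are pure functions of (inputs, config, seed).
#'
#' @param config a YAML file path or an equivalent named list. Recognised
#'   keys: `seed` (integer, default 1); `stages` (subset of
#'   `simulate, preselect, stability, combos`); `simulate` (list with
#'   `preset` = `"pti"`, `"pmi"` or `"ngs"`); `ct`, `metadata`, `counts`,
#'   `counts_metadata` (input file paths); `preselect` (list: `k`,
#'   `count_threshold`, `tpm_threshold`, `cv_scope`); `stability` (list:
#'   `algorithms`, `v_threshold`, `use_groups`, `bestkeeper_dispersion`,
#'   `sd_denominator`); `combos` (list: `genes`, `max_size`, `mean_type`);
#'   `out_dir`.
#' @param out_dir output directory (overrides the config key; default
#'   `"."`).
#' @param seed integer; overrides the config `seed` when given.
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a YAML file or a list")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  config$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c(if (!is.null(config$simulate)) "simulate",
      if (!is.null(config$counts) || !is.null(config$simulate)) "preselect",
      "stability", "combos")
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    config_error("unknown stage(s): ", paste(bad, collapse = ", "))

  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(...) message(sprintf("[rgstab +%.1fs] ",
                                           proc.time()[["elapsed"]] - t0), ...)
  run_stage <- function(name, expr) {
    log_msg("stage ", name, " ...")
    tryCatch(expr, rgstab_config_error = function(e) stop(e),
             error = function(e)
               stop("stage ", name, " failed: ", conditionMessage(e),
                    call. = FALSE))
  }

  outputs <- character(0)
  report <- list(package = "rgstab",
                 version = as.character(utils::packageVersion("rgstab")),
                 seed = seed, config = config, stages = stages)

  ct_path <- config$ct
  meta_path <- config$metadata
  counts_path <- config$counts
  counts_meta_path <- config$counts_metadata %||% config$metadata

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      preset <- (config$simulate %||% list())$preset %||% "pti"
      cfg <- switch(preset,
                    pti = sim_config_pti(seed),
                    pmi = sim_config_pmi(seed),
                    ngs = sim_config_ngs(seed),
                    config_error("unknown simulate preset: ", preset))
      ct <- simulate_ct_table(cfg)
      ct_path <- file.path(out_dir, "ct.tsv")
      meta_path <- file.path(out_dir, "samples.tsv")
      write_ct_table(ct, ct_path, meta_path)
      cnt_cfg <- if (preset == "ngs") cfg else sim_config_ngs(seed)
      counts <- simulate_count_matrix(cnt_cfg)
      counts_path <- file.path(out_dir, "counts.tsv")
      counts_meta_path <- file.path(out_dir, "counts_samples.tsv")
      write_expression_matrix(counts, counts_path)
      utils::write.table(data.frame(sample = names(counts$groups),
                                    group = as.character(counts$groups)),
                         counts_meta_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, ct_path, meta_path, counts_path,
                    counts_meta_path)
    })
  }

  inputs <- c(ct = ct_path, metadata = meta_path, counts = counts_path)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  for (p in inputs) if (!file.exists(p))
    config_error("input file not found: ", p)
  report$inputs <- as.list(tools::md5sum(unlist(inputs)))

  if ("preselect" %in% stages) {
    run_stage("preselect", {
      if (is.null(counts_path))
        config_error("preselect stage needs a `counts` input")
      counts <- read_expression_matrix(counts_path, counts_meta_path,
                                       unit = "count")
      pc <- config$preselect %||% list()
      cand <- select_candidates(counts,
                                k = pc$k %||% 5,
                                count_threshold = pc$count_threshold %||% 8000,
                                tpm_threshold = pc$tpm_threshold %||% 5000,
                                cv_scope = pc$cv_scope %||% "samples")
      out <- file.path(out_dir, "candidates.tsv")
      write_candidates(cand, out)
      outputs <- c(outputs, out)
      report$candidates <- attr(cand, "selected")
    })
  }

  fit <- NULL
  if ("stability" %in% stages) {
    run_stage("stability", {
      if (is.null(ct_path))
        config_error("stability stage needs a `ct` input")
      ct <- read_ct_table(ct_path, meta_path)
      sc <- config$stability %||% list()
      fit <- rg_stability(
        ct,
        algorithms = sc$algorithms %||%
          c("genorm", "normfinder", "bestkeeper", "delta_ct"),
        use_groups = sc$use_groups,
        bestkeeper_dispersion = sc$bestkeeper_dispersion %||% "sd",
        v_threshold = sc$v_threshold %||% 0.15,
        sd_denominator = sc$sd_denominator %||% "n-1")
      out <- file.path(out_dir, "stability.tsv")
      write_stability(fit, out,
                      genorm_trace_path = file.path(out_dir,
                                                    "genorm_trace.tsv"),
                      v_series_path = file.path(out_dir, "v_series.tsv"))
      outputs <- c(outputs, out, file.path(out_dir, "genorm_trace.tsv"),
                    file.path(out_dir, "v_series.tsv"))
      report$consensus_top3 <-
        fit$consensus$gene[order(fit$consensus$final_rank)][1:3]
      report$optimal_n <- as.integer(fit$optimal_n)
    })
  }

  if ("combos" %in% stages) {
    run_stage("combos", {
      if (is.null(fit))
        config_error("combos stage needs the stability stage")
      cc <- config$combos %||% list()
      genes <- cc$genes %||%
        fit$consensus$gene[order(fit$consensus$final_rank)][1:3]
      combo <- evaluate_combinations(fit$ct, genes,
                                     max_size = cc$max_size %||% 3,
                                     mean_type = cc$mean_type %||%
                                       "geometric")
      out <- file.path(out_dir, "combinations.tsv")
      write_combinations(combo, out)
      outputs <- c(outputs, out)
      report$best_combination <-
        combo$ranking$gene[which.min(combo$ranking$final_rank)]
    })
  }

  report$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  log_msg("done; report at ", file.path(out_dir, "report.json"))
  invisible(report)
}
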