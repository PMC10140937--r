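# Config-driven orchestration: simulate -> call -> score -> test.
#
# One structured YAML config drives the whole run; every study threshold is a
# config key with the study value as default.  Each stage logs record counts
# (sites read, calls made, calls surviving the depth filter, genes surviving
# the read threshold) so filter attrition is auditable, and a manifest
# records config hash and versions.  Stage failures abort with a condition
# carrying the stage name, which the command-line wrapper maps to per-stage
# exit codes.

STAGE_EXIT_CODES <- c(config = 2L, annotation = 10L, simulate = 20L,
                      call = 30L, score = 40L, test = 50L)

stage_error <- function(stage, parent) {
  stop(structure(class = c("imprintscan_stage_error", "error", "condition"),
                 list(message = sprintf("[%s] %s", stage,
                                        conditionMessage(parent)),
                      call = NULL, stage = stage)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "imprintscan_stage_error")) stop(e)
    stage_error(stage, e)
  })
}

log_msg <- function(cfg, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  if (!is.null(cfg$log_file))
    cat(line, "\n", file = cfg$log_file, append = TRUE, sep = "")
  invisible(line)
}

#' Build a validated run configuration
#'
#' Accepts a YAML file path or a list with the same structure.  Keys:
#' `seed`, `out_dir`, an optional `simulate` block ([sim_config()] fields),
#' or for real data `annotation` (+`annotation_format`), `imprinted_ids`
#' (file with one gene id per line, or vector), `pileups` (named sample ->
#' mpileup path), `read_totals` and `metadata` TSV paths; plus optional
#' `caller` ([caller_params()] fields) and `analysis` ([analysis_params()]
#' fields), `log_file`, and `plot`.
#'
#' @param x path to a YAML config or a list.
#' @param ... overrides applied on top (e.g. `seed = 7`, `out_dir = "out"`).
#' @return object of class `run_config`.
#' @export
run_config <- function(x = list(), ...) {
  with_stage("config", {
    cfg <- if (is.character(x)) {
      if (!file.exists(x)) stopf("config file not found: %s", x)
      yaml::read_yaml(x)
    } else x
    dots <- list(...)
    cfg[names(dots)] <- dots
    cfg$seed <- as.integer(cfg$seed %||% 1L)
    cfg$out_dir <- cfg$out_dir %||% "imprintscan_out"
    cfg$plot <- isTRUE(cfg$plot %||% TRUE)
    cfg$caller <- do.call(caller_params, cfg$caller %||% list())
    ap <- cfg$analysis %||% list()
    keep <- intersect(names(ap), names(formals(analysis_params)))
    cfg$analysis <- do.call(analysis_params, ap[keep])
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      if (!inherits(sim, "sim_config")) {
        sim <- sim[intersect(names(sim), names(formals(sim_config)))]
        if (!is.null(sim$leakage_by_group))
          sim$leakage_by_group <- unlist(sim$leakage_by_group)
        if (is.null(sim$seed)) sim$seed <- cfg$seed
        sim <- do.call(sim_config, sim)
      }
      cfg$simulate <- sim
    } else {
      for (k in c("pileups", "read_totals", "metadata"))
        if (is.null(cfg[[k]]))
          stopf("config needs either a 'simulate' block or '%s'", k)
      if (is.null(cfg$annotation) && is.null(cfg$panel))
        stopf("config needs 'annotation' (+ 'imprinted_ids') or 'panel'")
    }
    structure(cfg, class = "run_config")
  })
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(cfg), function(v)
    if (is.data.frame(v)) as.list(v) else v, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, counts, path) {
  manifest <- list(
    tool = "imprintscan",
    version = as.character(packageVersion("imprintscan")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config_md5 = config_digest(cfg),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_panel <- function(cfg) {
  with_stage("annotation", {
    if (inherits(cfg$panel, "transcript_models")) return(cfg$panel)
    if (is.character(cfg$panel)) {
      m <- load_gene_models(cfg$panel, format = "tsv")
      return(build_panel(m, m$gene_id[m$imprinted])$panel)
    }
    if (!is.null(cfg$simulate)) {
      sp <- synthetic_panel(cfg$simulate)
      return(build_panel(sp$models, sp$imprinted_ids)$panel)
    }
    models <- load_gene_models(cfg$annotation,
                               format = cfg$annotation_format %||% "auto")
    ids <- cfg$imprinted_ids
    if (is.character(ids) && length(ids) == 1L && file.exists(ids))
      ids <- readLines(ids)
    if (is.null(ids)) ids <- models$gene_id[models$imprinted]
    if (!length(ids)) stopf("no imprinted gene ids supplied")
    build_panel(models, ids)$panel
  })
}

#' Run the simulation stage
#'
#' @param cfg a [run_config()] with a `simulate` block.
#' @return the written `sim_cohort`, invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$simulate)) stage_error("simulate",
                                         simpleError("no simulate block"))
  panel <- resolve_panel(cfg)
  with_stage("simulate", {
    sim_dir <- file.path(cfg$out_dir, "sim")
    cohort <- simulate_cohort(cfg$simulate, panel, out_dir = sim_dir)
    log_msg(cfg, "simulate", "%d samples x %d genes -> %s",
            length(cohort$pileups), nrow(panel), sim_dir)
    write_manifest(cfg, list(samples = length(cohort$pileups),
                             panel_genes = nrow(panel)),
                   file.path(sim_dir, "manifest.json"))
    invisible(cohort)
  })
}

#' Run the variant-calling stage over per-sample pileups
#'
#' @param cfg a [run_config()].
#' @param pileups named list of [pileup()] objects or mpileup paths; default
#'   taken from the config.
#' @return named list of `variant_calls` (site-depth-passing only);
#'   per-sample VCF and TSV files are written under `out_dir/calls`.
#' @export
run_call <- function(cfg, pileups = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  with_stage("call", {
    if (is.null(pileups)) pileups <- as.list(unlist(cfg$pileups))
    if (!length(pileups)) stopf("no pileups to call")
    call_dir <- file.path(cfg$out_dir, "calls")
    dir.create(call_dir, showWarnings = FALSE, recursive = TRUE)
    calls <- vector("list", length(pileups))
    names(calls) <- names(pileups)
    for (s in names(pileups)) {
      all_calls <- call_sample(pileups[[s]], cfg$caller,
                               keep_failed_depth = TRUE)
      kept <- all_calls[all_calls$passed_site_depth, , drop = FALSE]
      rownames(kept) <- NULL
      n_sites <- if (inherits(pileups[[s]], "pileup"))
        nrow(pileups[[s]]$sites) else length(readLines(pileups[[s]]))
      log_msg(cfg, "call",
              "%s: %d sites read, %d calls, %d pass site-depth filter",
              s, n_sites, nrow(all_calls), nrow(kept))
      write_variant_calls(kept,
                          vcf_path = file.path(call_dir,
                                               paste0(s, ".vcf")),
                          tsv_path = file.path(call_dir,
                                               paste0(s, ".tsv")))
      calls[[s]] <- kept
    }
    calls
  })
}

#' Run the scoring stage: per-gene SNP summaries
#'
#' @param cfg a [run_config()].
#' @param calls named list of `variant_calls` per sample.
#' @param panel panel table (default resolved from config).
#' @param read_totals read-totals data frame or TSV path.
#' @return `gene_snp_summary` table; written to `out_dir/summaries.tsv`.
#' @export
run_score <- function(cfg, calls, panel = NULL, read_totals = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(panel)) panel <- resolve_panel(cfg)
  with_stage("score", {
    if (is.null(read_totals)) read_totals <- cfg$read_totals
    if (is.character(read_totals)) read_totals <- read_tsv(read_totals)
    summaries <- summarize_cohort(calls, panel, read_totals, cfg$analysis)
    inc <- summaries[summaries$included, , drop = FALSE]
    log_msg(cfg, "score",
            "%d gene x sample rows, %d pass the %d-read threshold",
            nrow(summaries), nrow(inc),
            cfg$analysis$min_transcript_reads)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(summaries, file.path(cfg$out_dir, "summaries.tsv"))
    summaries
  })
}

#' Run the testing stage: ANOVA + Tukey + report files
#'
#' @param cfg a [run_config()].
#' @param summaries `gene_snp_summary` table or TSV path.
#' @param metadata sample sheet or TSV path.
#' @return an `imprint_anova`; tables written under `out_dir`.
#' @export
run_test <- function(cfg, summaries, metadata = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  with_stage("test", {
    if (is.character(summaries)) summaries <- read_summaries(summaries)
    if (is.null(metadata)) metadata <- cfg$metadata
    if (is.character(metadata)) metadata <- read_tsv(metadata)
    fit <- imprinting_anova(summaries, metadata,
                            include_interaction =
                              isTRUE(cfg$include_interaction %||% TRUE),
                            sex_covariate =
                              isTRUE(cfg$sex_covariate %||% TRUE))
    report(summaries, fit, cfg$out_dir, plot = cfg$plot)
    for (ts in names(fit$tissues))
      log_msg(cfg, "test", "tissue %s: %d rows modelled", ts,
              fit$tissues[[ts]]$n)
    fit
  })
}

#' Run the full pipeline
#'
#' annotation -> (simulate | read pileups) -> per-sample calling ->
#' per-gene summaries -> ANOVA/Tukey -> report files, with a manifest in
#' `out_dir`.  Running the stages individually with the same config yields
#' identical outputs.
#'
#' @param cfg a [run_config()] (or anything `run_config()` accepts).
#' @return invisibly, list with `panel`, `calls`, `summaries`, `anova`,
#'   and `out_dir`.
#' @export
run_full <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  panel <- resolve_panel(cfg)
  if (!is.null(cfg$simulate)) {
    cohort <- run_simulate(cfg)
    pileups <- cohort$pileups
    read_totals <- cohort$read_totals
    metadata <- cohort$metadata
  } else {
    pileups <- as.list(unlist(cfg$pileups))
    read_totals <- read_tsv(cfg$read_totals)
    metadata <- read_tsv(cfg$metadata)
  }
  calls <- run_call(cfg, pileups)
  summaries <- run_score(cfg, calls, panel, read_totals)
  fit <- run_test(cfg, summaries, metadata)
  write_manifest(cfg,
                 list(samples = length(pileups),
                      panel_genes = nrow(panel),
                      calls = sum(vapply(calls, nrow, integer(1))),
                      summary_rows = nrow(summaries),
                      included_rows = sum(summaries$included)),
                 file.path(cfg$out_dir, "manifest.json"))
  invisible(list(panel = panel, calls = calls, summaries = summaries,
                 anova = fit, out_dir = cfg$out_dir))
}
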