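# End-to-end orchestration: (real or synthetic) table -> rarefaction ->
# diversity -> KW -> stepwise DA -> family network -> pooled resampling CIs
# -> machine-readable report.  One root seed; every stage derives its own
# substream, so reordering stages never silently changes results.

#' Pipeline configuration
#'
#' Defaults mirror the protocol parameters of the original analysis:
#' per-colony rarefaction to 10,000 reads, 100 pooled in-silico libraries of
#' 10,000 reads with 95% percentile intervals, p < 0.05 for correlation
#' edges, family-level correlations, genus-level tests.
#'
#' @param synthetic generate the input table with [sample_table()]?
#' @param synthetic_config a [synthetic_config()]; default
#'   [default_synthetic_config()] under `seed`.
#' @param effects optional [effect_spec()] list for the generator.
#' @param counts_path,metadata_path input TSVs when `synthetic = FALSE`.
#' @param format count-table dialect for [read_count_table()].
#' @param taxonomy genus-to-family map; default [default_taxonomy()].
#' @param L_sample per-colony rarefaction depth.
#' @param resampling a [resampling_config()].
#' @param f_enter,f_remove stepwise thresholds ([stepwise_da()]).
#' @param correlation_level `"family"` (default) or `"genus"`.
#' @param p_threshold network edge significance threshold.
#' @param outdir run directory (created by [run_pipeline()]).
#' @param seed root seed for the run.
#' @param verbose log stage progress?
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, synthetic_config = NULL,
                            effects = NULL, counts_path = NULL,
                            metadata_path = NULL, format = "generic",
                            taxonomy = default_taxonomy(), L_sample = 10000,
                            resampling = resampling_config(),
                            f_enter = 3.84, f_remove = 2.71,
                            correlation_level = c("family", "genus"),
                            p_threshold = 0.05, outdir = tempfile("beecomm_run"),
                            seed = 1, verbose = TRUE) {
  correlation_level <- match.arg(correlation_level)
  if (!synthetic) {
    if (is.null(counts_path) || is.null(metadata_path))
      stop("counts_path and metadata_path are required when synthetic = FALSE")
    for (p in c(counts_path, metadata_path))
      if (!file.exists(p)) stop("no such file: ", p)
  } else if (is.null(synthetic_config)) {
    synthetic_config <- default_synthetic_config(seed = seed)
  }
  structure(list(synthetic = synthetic, synthetic_config = synthetic_config,
                 effects = effects, counts_path = counts_path,
                 metadata_path = metadata_path, format = format,
                 taxonomy = taxonomy, L_sample = L_sample,
                 resampling = resampling, f_enter = f_enter,
                 f_remove = f_remove, correlation_level = correlation_level,
                 p_threshold = p_threshold, outdir = outdir,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys match the arguments of [pipeline_config()]; nested
#' `resampling:` keys match [resampling_config()].
#'
#' @param path YAML file.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$resampling)) {
    r <- y$resampling
    # YAML key for the library count is n_libraries (a bare `N:` would be
    # parsed as a boolean under YAML 1.1)
    names(r)[names(r) == "n_libraries"] <- "N"
    y$resampling <- do.call(resampling_config, r)
  }
  args <- utils::modifyList(y, list(...))
  do.call(pipeline_config, args)
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[beecomm] ", ...)
}

run_stage <- function(config, name, expr) {
  pipeline_log(config, "stage: ", name)
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes `diversity.tsv`,
#' `kw_results.tsv`, `da_trace.tsv`, `da_summary.tsv`, `edges.tsv`,
#' `resampling_ci.tsv` and `report.json` into `config$outdir`.  Each output
#' header records the run seed; runs are byte-identical given the same
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of class `beecomm_run` with every stage result
#'   and the report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  table <- run_stage(config, "input", {
    if (config$synthetic) {
      sc <- config$synthetic_config
      sc$seed <- derive_seed(seed, "synthetic")
      sample_table(sc, config$effects)
    } else {
      tab <- read_count_table(config$counts_path, config$format)
      attach_metadata(tab, read_sample_metadata(config$metadata_path))
    }
  })

  rarefied <- run_stage(config, "rarefaction",
    rarefy_table(table, config$L_sample, seed = derive_seed(seed, "rarefy")))

  div <- run_stage(config, "diversity", {
    d <- diversity_table(rarefied)
    write_stage_tsv(d, file.path(config$outdir, "diversity.tsv"), seed)
    d
  })
  med <- group_medians(div)

  kw <- run_stage(config, "kruskal_wallis", {
    k <- kw_all_taxa(rarefied)
    write_stage_tsv(as.data.frame(k), file.path(config$outdir, "kw_results.tsv"), seed)
    k
  })

  da <- run_stage(config, "discriminant_analysis", {
    fit <- stepwise_da(rarefied, f_enter = config$f_enter,
                       f_remove = config$f_remove)
    write_stage_tsv(fit$trace, file.path(config$outdir, "da_trace.tsv"), seed)
    smry <- data.frame(
      predictors = paste(fit$selected, collapse = ","),
      wilks_lambda = fit$lambda, chisq = fit$chisq, df = fit$df,
      p = fit$p.value, loo_accuracy = fit$accuracy, stringsAsFactors = FALSE)
    write_stage_tsv(smry, file.path(config$outdir, "da_summary.tsv"), seed)
    fit
  })

  net <- run_stage(config, "network", {
    tab_level <- if (config$correlation_level == "family")
      aggregate_taxa(rarefied, config$taxonomy, "family") else rarefied
    cm <- suppressWarnings(correlation_matrix(tab_level))
    nw <- build_network(cm, config$p_threshold)
    export_edges(nw, file.path(config$outdir, "edges.tsv"), seed)
    nw
  })

  ci <- run_stage(config, "resampling_ci", {
    rc <- config$resampling
    rc$seed <- derive_seed(seed, "resampling")
    res <- group_resampling_ci(table, rc)
    write_resampling_ci(res, file.path(config$outdir, "resampling_ci.tsv"), seed)
    res
  })

  results <- list(table = table, rarefied = rarefied, diversity = div,
                  medians = med, kw = kw, da = da, network = net,
                  resampling = ci, config = config)
  report <- run_stage(config, "report",
    write_report(results, file.path(config$outdir, "report.json")))
  results$report <- report
  class(results) <- "beecomm_run"
  pipeline_log(config, "done: ", config$outdir)
  invisible(results)
}

#' Write the machine-readable run report
#'
#' Single JSON document with per-stage summaries, the parameters actually
#' used, the seed, and the package version; validated against the shipped
#' schema before writing.
#'
#' @param results stage results as assembled by [run_pipeline()].
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
write_report <- function(results, path) {
  need <- c("table", "rarefied", "diversity", "medians", "kw", "da",
            "network", "resampling", "config")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0L)
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  cfg <- results$config
  kw <- results$kw
  kw_ok <- kw[!is.na(kw$p), , drop = FALSE]
  da <- results$da
  ci <- results$resampling
  report <- list(
    package = "beecomm",
    version = as.character(packageVersion("beecomm")),
    seed = cfg$seed,
    parameters = list(
      L_sample = cfg$L_sample,
      resampling_L = attr(ci, "L"), resampling_N = attr(ci, "N"),
      ci_level = attr(ci, "ci_level"),
      f_enter = cfg$f_enter, f_remove = cfg$f_remove,
      correlation_level = cfg$correlation_level,
      p_threshold = cfg$p_threshold,
      synthetic = cfg$synthetic),
    input = list(
      n_taxa = n_taxa(results$table),
      n_samples = n_samples(results$table),
      min_depth = min(colSums(results$table$counts)),
      max_depth = max(colSums(results$table$counts)),
      group_sizes = as.list(table(sample_groups(results$table)))),
    diversity = list(medians = results$medians),
    kruskal_wallis = list(
      n_tested = nrow(kw_ok), n_degenerate = sum(kw$note == "degenerate"),
      n_significant = sum(kw_ok$p < 0.05),
      top_taxon = if (nrow(kw_ok)) kw_ok$taxon[1] else NA),
    discriminant_analysis = list(
      predictors = da$selected, wilks_lambda = da$lambda,
      chisq = da$chisq, df = da$df, p = da$p.value,
      loo_accuracy = da$accuracy),
    network = list(
      edge_count = nrow(results$network$edges),
      n_positive = sum(results$network$edges$sign == "positive"),
      n_negative = sum(results$network$edges$sign == "negative")),
    resampling_ci = list(
      n_taxa = nrow(ci), n_flagged = sum(ci$flagged),
      flagged_taxa = ci$taxon[ci$flagged]))
  validate_report(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(report)
}

#' Validate a run report against the shipped schema
#'
#' The schema (`inst/extdata/report_schema.json`) lists the required
#' top-level sections and the required fields of each.
#'
#' @param report report list as built by [write_report()].
#' @return `TRUE`, invisibly; errors describe what is missing.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "beecomm")
  schema <- jsonlite::read_json(schema_path)
  miss <- setdiff(unlist(schema$required), names(report))
  if (length(miss) > 0L)
    stop("report missing required sections: ", paste(miss, collapse = ", "))
  for (sec in names(schema$sections)) {
    miss <- setdiff(unlist(schema$sections[[sec]]), names(report[[sec]]))
    if (length(miss) > 0L)
      stop("report section '", sec, "' missing fields: ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
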