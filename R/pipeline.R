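#' Configuration of an end-to-end pipeline run
#'
#' @param data Either a `"synthetic_dataset"` (see [generate_dataset()])
#'   or a named list of file paths with elements `expression`, `survival`,
#'   `signatures`, and (for the ontology-aware procedures) `ontology`,
#'   `annotations`, optionally `pg`.
#' @param procedure `"grp1"`, `"grp2"`, `"grp2star"` or `"falsify"`.
#' @param signatures Optional character vector restricting the run to a
#'   subset of signature names.
#' @param repeats Random sets per pool per regime.
#' @param alpha Significance level.
#' @param correction `"bonferroni"`, `"none"`, or `"both"` to run the two
#'   regimes side by side (independent draws per regime, as when a
#'   resampling study is repeated with and without correction).
#' @param namespace Ontology namespace driving procedure-2 removal.
#' @param level_convention Passed to [compute_term_levels()].
#' @param seed Master seed; every signature/pool/regime stream derives
#'   from it, so adding a signature never perturbs another's draws.
#' @param out_dir Output directory.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(data, procedure = c("grp1", "grp2", "grp2star",
                                                "falsify"),
                            signatures = NULL, repeats = 1000L,
                            alpha = 0.001,
                            correction = c("bonferroni", "none", "both"),
                            namespace = "BP",
                            level_convention = "longest",
                            seed = 1L, out_dir = tempfile("sigsurr_run_")) {
  structure(list(data = data, procedure = match.arg(procedure),
                 signatures = signatures, repeats = as.integer(repeats),
                 alpha = alpha, correction = match.arg(correction),
                 namespace = namespace,
                 level_convention = level_convention,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(data) {
  if (inherits(data, "synthetic_dataset")) return(data)
  stopifnot(is.list(data), all(c("expression", "survival", "signatures")
                               %in% names(data)))
  dag <- if (!is.null(data$ontology)) read_obo_subset(data$ontology)
  list(expression = read_expression(data$expression),
       survival = read_survival(data$survival),
       signatures = read_gmt(data$signatures),
       ontology = dag,
       annotation = if (!is.null(data$annotations))
         read_annotations(data$annotations, dag = dag),
       pg = if (!is.null(data$pg)) readLines(data$pg, warn = FALSE))
}

#' Execute a full constrained-resampling run
#'
#' Runs the three analysis steps — pool construction, PC1 patient
#' stratification, survival testing — for the selected procedure over
#' every signature of the collection, in one or two correction regimes.
#' Per signature and regime it writes the per-level report TSV, a
#' p-value dump (one value per line per repeat), and a summary JSON;
#' plus `bounds.tsv` (surrogate-count bound per signature) and
#' `manifest.json` (the config, master seed, total draw counter and input
#' file checksums) for the whole run. A rerun from the same manifest is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"pipeline_run"`: list with `out_dir`,
#'   `manifest` and `reports` (nested list, regime -> signature ->
#'   report object).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_pipeline_inputs(config$data)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(config$out_dir, "inputs")
  if (inherits(config$data, "synthetic_dataset")) {
    write_dataset(inp, input_dir)
    input_files <- list.files(input_dir, full.names = TRUE)
  } else {
    input_files <- unlist(config$data, use.names = FALSE)
  }
  checksums <- as.list(tools::md5sum(input_files))
  names(checksums) <- basename(names(checksums))

  sigs <- inp$signatures
  if (!is.null(config$signatures)) sigs <- sigs[config$signatures]
  expr <- inp$expression
  surv <- inp$survival
  needs_ontology <- config$procedure %in% c("grp2", "grp2star", "falsify")
  levels <- NULL
  if (needs_ontology) {
    if (is.null(inp$ontology) || is.null(inp$annotation))
      stop("procedure '", config$procedure,
           "' needs an ontology and annotations")
    levels <- compute_term_levels(inp$ontology,
                                  convention = config$level_convention)
  }
  regimes <- if (config$correction == "both") c("none", "bonferroni")
             else config$correction

  n_draws <- 0L
  reports <- list()
  for (ri in seq_along(regimes)) {
    regime <- regimes[[ri]]
    reports[[regime]] <- list()
    for (si in seq_along(sigs)) {
      bm <- sigs[[si]]
      sseed <- derive_seed(config$seed, 1000L * ri + si)
      res <- switch(config$procedure,
        grp1 = grp1(expr, surv, bm, repeats = config$repeats,
                    alpha = config$alpha, correction = regime,
                    seed = sseed),
        grp2 = grp2(expr, surv, bm, inp$annotation, levels,
                    dag = inp$ontology, namespace = config$namespace,
                    repeats = config$repeats, alpha = config$alpha,
                    correction = regime, seed = sseed),
        grp2star = grp2(expr, surv, bm, inp$annotation, levels,
                        dag = inp$ontology, namespace = config$namespace,
                        remove_proliferation = TRUE, pg = inp$pg,
                        repeats = config$repeats, alpha = config$alpha,
                        correction = regime, seed = sseed),
        falsify = falsification_test(expr, surv, bm, inp$annotation,
                                     pg = inp$pg, repeats = config$repeats,
                                     alpha = config$alpha,
                                     correction = regime, seed = sseed))
      reports[[regime]][[bm$name]] <- res
      stem <- file.path(config$out_dir, paste0(bm$name, "_", regime))
      if (inherits(res, "resampling_report")) {
        n_draws <- n_draws + res$n_draws
        write_level_report(res, paste0(stem, "_levels.tsv"))
        writeLines(sprintf("%.17g", unlist(res$p_raw)),
                   paste0(stem, "_pvalues.txt"))
        smry <- list(signature = bm$name, procedure = config$procedure,
                     correction = regime,
                     accuracy_pct = res$table$accuracy_pct,
                     median_p = res$table$median_p,
                     percentile3_p = res$table$percentile3_p,
                     signature_p = res$table$signature_p[[1L]],
                     n_draws = res$n_draws)
      } else {
        n_draws <- n_draws + config$repeats
        writeLines(sprintf("%.17g", res$p_raw),
                   paste0(stem, "_pvalues.txt"))
        smry <- list(signature = bm$name, procedure = "falsify",
                     correction = regime,
                     n_surrogates_found = res$n_surrogates_found,
                     p_sgs = res$p_sgs,
                     has_testable_meaning = res$has_testable_meaning,
                     pool_size = res$pool_size,
                     removed_gene_count = res$removed_gene_count)
      }
      jsonlite::write_json(smry, paste0(stem, "_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      message("[", config$procedure, "/", regime, "] ", bm$name,
              ": done")
    }
  }

  bounds <- do.call(rbind, lapply(sigs, function(bm) {
    size <- length(intersect(bm$genes, rownames(expr)))
    n_pool <- nrow(expr) - size
    b <- surrogate_bound(n_pool, size)
    data.frame(signature = bm$name, pool_size = n_pool, set_size = size,
               exponent = b$x, exponent_1pct = b$x_percentile,
               stringsAsFactors = FALSE)
  }))
  rownames(bounds) <- NULL
  utils::write.table(bounds, file.path(config$out_dir, "bounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(procedure = config$procedure,
                   signatures = names(sigs),
                   repeats = config$repeats, alpha = config$alpha,
                   correction = config$correction,
                   regimes = regimes,
                   namespace = config$namespace,
                   level_convention = config$level_convention,
                   seed = config$seed,
                   n_draws = n_draws,
                   input_checksums = checksums)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(out_dir = config$out_dir, manifest = manifest,
                 reports = reports),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run [", m$procedure, "]: ", length(m$signatures),
      " signature(s) x ", m$repeats, " repeats x ",
      length(m$regimes), " regime(s) = ", m$n_draws,
      " random gene sets\n", sep = "")
  cat("  outputs in ", x$out_dir, "\n", sep = "")
  invisible(x)
}
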