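#' Read a gene expression matrix from tab-separated text
#'
#' The expected layout is the field-standard genes-in-rows table: the first
#' row holds sample identifiers, the first column gene identifiers and the
#' body numeric expression values (assumed already normalised/log-scale;
#' no transformation is applied).
#'
#' A transposed file (samples in rows) is rejected rather than guessed, and
#' missing or non-numeric cells are an error: silent imputation would
#' contaminate every resampling null built on top of the matrix.
#'
#' @param path Path to a TSV file; header row = sample ids, first column =
#'   gene ids, numeric body.
#' @return A numeric matrix with genes as rows and samples as columns,
#'   carrying unique `rownames` (genes) and `colnames` (samples).
#' @seealso [write_expression()], [read_survival()]
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 3L)
    stop("expression file must have a gene-id column and at least 2 samples")
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in expression file: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s) in expression file: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(values) | body == "" | is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("malformed numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]],
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(values) <- list(genes, samples)
  if (nrow(values) < 1L) stop("expression file contains no genes")
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Values are printed with 17 significant digits so that
#' `read_expression(write_expression(x))` reproduces `x` exactly.
#'
#' @param x Numeric matrix, genes in rows, with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  body <- apply(x, 2L, function(col) sprintf("%.17g", col))
  tab <- cbind(gene = rownames(x), body)
  colnames(tab) <- c("gene", colnames(x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read right-censored survival metadata
#'
#' @param path Path to a TSV with (at least) columns `sample`, `time`
#'   and `event`. `time` is a nonnegative time-to-event in study units;
#'   `event` is 1 if the event was observed and 0 if right-censored.
#' @return A data frame with columns `sample` (character), `time` (numeric)
#'   and `event` (integer in \{0, 1\}).
#' @export
read_survival <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(raw)))
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0L) stop("survival file contains no samples")
  out <- data.frame(sample = as.character(raw$sample),
                    time = as.numeric(raw$time),
                    event = as.integer(raw$event),
                    stringsAsFactors = FALSE)
  validate_survival(out)
}

validate_survival <- function(x) {
  if (anyDuplicated(x$sample))
    stop("duplicate sample identifier(s) in survival data")
  if (anyNA(x$time) || any(x$time < 0))
    stop("survival times must be nonnegative numbers")
  if (anyNA(x$event) || !all(x$event %in% c(0L, 1L)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  x
}

#' Write survival metadata as tab-separated text
#'
#' @param surv Data frame as returned by [read_survival()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  validate_survival(surv)
  out <- surv[, c("sample", "time", "event")]
  out$time <- sprintf("%.17g", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Create a gene signature
#'
#' @param name Signature name (nonempty string).
#' @param genes Character vector of gene identifiers; duplicates are
#'   collapsed, order of first occurrence kept. At least 2 distinct genes.
#' @param description Free-text description (kept, unused downstream).
#' @return An object of class `"signature"`: a list with elements `name`,
#'   `genes` and `description`.
#' @export
signature_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("signature name must be a nonempty string")
  genes <- unique(as.character(genes))
  if (length(genes) < 2L)
    stop("signature '", name, "' has fewer than 2 distinct genes")
  structure(list(name = name, genes = genes, description = description),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  shown <- utils::head(x$genes, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a signature collection from a GMT file
#'
#' Standard MSigDB dialect: one signature per line,
#' `name TAB description TAB gene TAB gene ...`.
#'
#' @param path Path to a GMT file.
#' @return An object of class `"signature_collection"`: a named list of
#'   [signature_set()] objects in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file contains no signatures")
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 tab-separated fields")
    sigs[[i]] <- signature_set(fields[[1L]], fields[-(1:2)],
                               description = fields[[2L]])
  }
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  if (anyDuplicated(names(sigs)))
    stop("duplicate signature name(s) in GMT file: ",
         paste(unique(names(sigs)[duplicated(names(sigs))]), collapse = ", "))
  structure(sigs, class = "signature_collection")
}

#' Write a signature collection to a GMT file
#'
#' @param sigs A `"signature_collection"` or list of signatures.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.signature_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), 0L)
  cat("Signature collection: ", length(x), " signatures, sizes ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

report_columns <- c("hierarchy_level", "genes_removed", "cum_genes_removed",
                    "genes_left", "terms_removed", "cum_terms_removed",
                    "accuracy_pct", "signature_accuracy_pct")

#' Write a per-hierarchy-level resampling report as TSV
#'
#' One row per hierarchy level in iteration order (highest level first),
#' with the removal bookkeeping and accuracy columns: level, genes removed
#' at the level, cumulative genes removed, genes left in the pool, ontology
#' terms removed, cumulative terms removed, accuracy (% of random sets
#' significant) and the signature-only-removal accuracy.
#'
#' @param report A `"resampling_report"` (see [run_resampling()]) or a data
#'   frame with the report columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_level_report()]
#' @export
write_level_report <- function(report, path) {
  tab <- if (is.data.frame(report)) report else report$table
  stopifnot(all(report_columns %in% colnames(tab)))
  out <- tab[, report_columns]
  for (col in c("accuracy_pct", "signature_accuracy_pct"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a per-level report written by [write_level_report()]
#'
#' @param path Path to the TSV report.
#' @return Data frame with the report columns.
#' @export
read_level_report <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(report_columns %in% colnames(tab)))
    stop("not a level report: missing columns")
  tab
}
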