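#' Asymmetric pairwise overlap of two sets
#'
#' The fraction of the first set's elements also present in the second:
#' `|si intersect sj| / |si|`. The measure is deliberately asymmetric —
#' when the sets differ in size the two directions disagree, but both
#' directions agree on the shared count `|si intersect sj|`.
#'
#' @param si,sj Character vectors (gene ids or term ids); `si` nonempty.
#' @return A fraction in \[0, 1\].
#' @export
pairwise_overlap <- function(si, sj) {
  si <- unique(as.character(si)); sj <- unique(as.character(sj))
  if (length(si) == 0L) stop("first set is empty: overlap undefined")
  length(intersect(si, sj)) / length(si)
}

#' Pairwise overlap matrix of a signature collection
#'
#' Entry (i, j) is the fraction of signature i's elements shared with
#' signature j ([pairwise_overlap()]). With `on = "terms"` the comparison
#' is between the signatures' biological meanings ([meaning_of()]) instead
#' of their gene lists. The per-signature number of partners with nonzero
#' overlap is attached.
#'
#' @param sigs A `"signature_collection"`.
#' @param on `"genes"` (default) or `"terms"`.
#' @param ann An [annotation_map()], required for `on = "terms"`.
#' @return Object of class `"overlap_matrix"`: list with `z` (square
#'   numeric matrix, unit diagonal), `shared` (integer matrix of shared
#'   counts) and `n_partners` (named integer vector of nonzero partners,
#'   excluding self).
#' @export
overlap_matrix <- function(sigs, on = c("genes", "terms"), ann = NULL) {
  on <- match.arg(on)
  sets <- lapply(sigs, function(s) {
    if (on == "genes") s$genes else meaning_of(s$genes, ann)
  })
  if (on == "terms" && is.null(ann))
    stop("on = \"terms\" needs an annotation map")
  n <- length(sets)
  nm <- names(sigs)
  z <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  shared <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      common <- length(intersect(sets[[i]], sets[[j]]))
      shared[i, j] <- common
      z[i, j] <- if (length(sets[[i]]) == 0L) NA_real_
                 else common / length(sets[[i]])
    }
  }
  n_partners <- vapply(seq_len(n), function(i)
    sum(shared[i, -i, drop = FALSE] > 0L), 0L)
  names(n_partners) <- nm
  structure(list(z = z, shared = shared, n_partners = n_partners, on = on),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Pairwise signature overlap (", x$on, "): ", nrow(x$z),
      " signatures\n", sep = "")
  cat("Nonzero partners per signature: ",
      paste(range(x$n_partners), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Per-namespace ontology term counts of a signature
#'
#' Counts the distinct terms of each namespace in the signature's
#' biological meaning, and the fraction relative to all terms of that
#' namespace present in the loaded ontology (the loaded DAG's totals are
#' the denominators and are reported alongside).
#'
#' @param bm A [signature_set()] or character vector of genes.
#' @param ann An [annotation_map()].
#' @param dag An [ontology_dag()].
#' @return Data frame with columns `namespace`, `n_terms`, `total_terms`,
#'   `fraction`.
#' @export
term_counts <- function(bm, ann, dag) {
  genes <- if (inherits(bm, "signature")) bm$genes else bm
  terms <- meaning_of(genes, ann)
  ns_all <- sort(unique(dag$namespace))
  n_terms <- vapply(ns_all, function(ns)
    sum(dag$namespace[terms] == ns), 0L)
  totals <- vapply(ns_all, function(ns) sum(dag$namespace == ns), 0L)
  data.frame(namespace = ns_all, n_terms = unname(n_terms),
             total_terms = unname(totals),
             fraction = unname(ifelse(totals > 0L, n_terms / totals,
                                      NA_real_)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank-order conservation test
#'
#' Tests whether the ordering of one per-signature quantity (e.g. the
#' signature sizes) is conserved by another (e.g. their ontology term
#' counts), using Spearman's rho with a two-sided p-value from the
#' t-distribution approximation and average ranks for ties.
#'
#' @param a,b Paired numeric vectors, at least 4 pairs, neither constant.
#' @return List with `rho` and `p.value`.
#' @export
spearman_order_test <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must be paired")
  if (length(a) < 4L) stop("need at least 4 paired values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE,
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Hierarchy-level distribution of a signature's ontology terms
#'
#' Collects the hierarchy levels of the signature's terms in the chosen
#' namespace and summarises them (median, quartiles, Bowley quartile
#' skewness). An unannotated signature yields an empty distribution with
#' `NA` summaries and `annotated = FALSE`.
#'
#' @param bm A [signature_set()] or character vector of genes.
#' @param ann An [annotation_map()].
#' @param levels Named integer vector from [compute_term_levels()].
#' @param dag Optional [ontology_dag()] used to restrict to `namespace`.
#' @param namespace Namespace to summarise (default `"BP"`).
#' @return Object of class `"level_distribution"`: list with `levels`
#'   (integer vector), `median`, `q1`, `q3`, `skew` and `annotated`.
#' @export
level_distribution <- function(bm, ann, levels, dag = NULL,
                               namespace = "BP") {
  genes <- if (inherits(bm, "signature")) bm$genes else bm
  pairs <- genes_to_leveled_terms(genes, ann, levels)
  if (!is.null(dag))
    pairs <- pairs[dag$namespace[pairs$term] == namespace, , drop = FALSE]
  lv <- sort(pairs$level)
  if (length(lv) == 0L)
    return(structure(list(levels = integer(0L), median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_, skew = NA_real_,
                          annotated = FALSE),
                     class = "level_distribution"))
  qs <- stats::quantile(lv, probs = c(0.25, 0.5, 0.75), type = 7L)
  iqr <- qs[[3L]] - qs[[1L]]
  skew <- if (iqr > 0) ((qs[[3L]] - qs[[2L]]) - (qs[[2L]] - qs[[1L]])) / iqr
          else 0
  structure(list(levels = lv, median = qs[[2L]], q1 = qs[[1L]],
                 q3 = qs[[3L]], skew = skew, annotated = TRUE),
            class = "level_distribution")
}

#' @export
print.level_distribution <- function(x, ...) {
  if (!x$annotated) {
    cat("Level distribution: no annotated terms\n")
    return(invisible(x))
  }
  cat("Level distribution over ", length(x$levels), " terms: median ",
      x$median, " [Q1 ", x$q1, ", Q3 ", x$q3, "], quartile skew ",
      signif(x$skew, 3L), "\n", sep = "")
  invisible(x)
}

#' Descriptive statistics of a signature collection
#'
#' Sizes, per-namespace term counts, both overlap matrices and
#' hierarchy-level summaries for every signature — the collection-level
#' description that precedes the resampling analysis.
#'
#' @param sigs A `"signature_collection"`.
#' @param ann An [annotation_map()].
#' @param dag An [ontology_dag()].
#' @param levels Term levels (computed from `dag` when omitted).
#' @param namespace Namespace for the level distributions.
#' @return Object of class `"signature_description"`: list with `sizes`,
#'   `term_counts` (data frame), `overlap_genes`, `overlap_terms`,
#'   `level_summary` (data frame) and `size_order_tests` (Spearman tests
#'   of size order vs term-count order per namespace).
#' @export
describe_signatures <- function(sigs, ann, dag, levels = NULL,
                                namespace = "BP") {
  if (is.null(levels)) levels <- compute_term_levels(dag)
  sizes <- vapply(sigs, function(s) length(s$genes), 0L)
  tc <- do.call(rbind, lapply(names(sigs), function(nm) {
    d <- term_counts(sigs[[nm]], ann, dag)
    d$signature <- nm
    d
  }))
  lvs <- lapply(sigs, level_distribution, ann = ann, levels = levels,
                dag = dag, namespace = namespace)
  level_summary <- data.frame(
    signature = names(sigs),
    n_terms = vapply(lvs, function(l) length(l$levels), 0L),
    median_level = vapply(lvs, `[[`, 0, "median"),
    q1 = vapply(lvs, `[[`, 0, "q1"),
    q3 = vapply(lvs, `[[`, 0, "q3"),
    skew = vapply(lvs, `[[`, 0, "skew"),
    row.names = NULL, stringsAsFactors = FALSE)
  order_tests <- lapply(split(tc, tc$namespace), function(d) {
    d <- d[match(names(sigs), d$signature), ]
    if (stats::sd(d$n_terms) == 0 || stats::sd(sizes) == 0) return(NULL)
    spearman_order_test(sizes, d$n_terms)
  })
  structure(list(sizes = sizes, term_counts = tc,
                 overlap_genes = overlap_matrix(sigs, on = "genes"),
                 overlap_terms = overlap_matrix(sigs, on = "terms",
                                                ann = ann),
                 level_summary = level_summary,
                 size_order_tests = order_tests),
            class = "signature_description")
}

#' @export
print.signature_description <- function(x, ...) {
  cat("Signature collection description\n")
  cat("  signatures: ", length(x$sizes), ", sizes ",
      min(x$sizes), "-", max(x$sizes), " (mean ",
      signif(mean(x$sizes), 4L), ")\n", sep = "")
  for (ns in names(x$size_order_tests)) {
    t <- x$size_order_tests[[ns]]
    if (!is.null(t))
      cat("  size-order vs ", ns, " term-count order: rho = ",
          signif(t$rho, 3L), ", p = ", format(t$p.value, digits = 3L),
          "\n", sep = "")
  }
  invisible(x)
}
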