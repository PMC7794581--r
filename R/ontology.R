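#' Construct an ontology DAG
#'
#' Internal-facing constructor also used by the synthetic-data generator.
#' Edges are `is_a` child-to-parent links; each namespace has exactly one
#' root (a term without parents). The graph must be acyclic, every term
#' must reach a root, and an edge may not cross namespaces.
#'
#' @param terms Character vector of term identifiers.
#' @param name Named character vector, term -> label.
#' @param namespace Named character vector, term -> namespace
#'   (conventionally `"BP"`, `"MF"`, `"CC"`).
#' @param parents Named list, term -> character vector of parent term ids
#'   (empty for roots).
#' @return An object of class `"ontology_dag"`.
#' @export
ontology_dag <- function(terms, name, namespace, parents) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term identifiers")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p))
  dangling <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(dangling) > 0L)
    stop("is_a edge points to unknown term(s): ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  namespace <- namespace[terms]
  for (t in terms) {
    for (p in parents[[t]]) {
      if (!identical(namespace[[t]], namespace[[p]]))
        stop("edge crosses namespaces: ", t, " -> ", p)
    }
  }
  dag <- structure(list(terms = terms,
                        name = name[terms],
                        namespace = namespace,
                        parents = parents,
                        roots = terms[lengths(parents) == 0L]),
                   class = "ontology_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "))
  if (length(dag$roots) == 0L) stop("ontology has no root term")
  dag
}

# Kahn-style topological order over child->parent edges, parents first.
# Returns NULL and records an offending cycle when the graph is cyclic.
topo_order <- function(dag) {
  unresolved <- lengths(dag$parents)
  children <- split(rep(names(dag$parents), lengths(dag$parents)),
                    unlist(dag$parents, use.names = FALSE))
  queue <- dag$terms[unresolved == 0L]
  order <- character(0L)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      unresolved[[ch]] <- unresolved[[ch]] - 1L
      if (unresolved[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(dag$terms)) return(NULL)
  order
}

# Walk parent links from a term stuck in a cycle until a term repeats.
find_cycle <- function(dag) {
  ord <- topo_order(dag)
  if (!is.null(ord)) return(NULL)
  in_order <- dag$terms %in% {
    # terms resolvable from roots; the rest participate in/depend on a cycle
    resolved <- character(0L)
    unresolved <- lengths(dag$parents)
    queue <- dag$terms[unresolved == 0L]
    children <- split(rep(names(dag$parents), lengths(dag$parents)),
                      unlist(dag$parents, use.names = FALSE))
    while (length(queue) > 0L) {
      t <- queue[[1L]]; queue <- queue[-1L]
      resolved <- c(resolved, t)
      for (ch in children[[t]]) {
        unresolved[[ch]] <- unresolved[[ch]] - 1L
        if (unresolved[[ch]] == 0L) queue <- c(queue, ch)
      }
    }
    resolved
  }
  start <- dag$terms[!in_order][[1L]]
  path <- start
  cur <- start
  repeat {
    nxt <- setdiff(dag$parents[[cur]], dag$terms[in_order])
    cur <- nxt[[1L]]
    if (cur %in% path) {
      i <- match(cur, path)
      return(c(path[i:length(path)], cur))
    }
    path <- c(path, cur)
  }
}

#' @export
print.ontology_dag <- function(x, ...) {
  ns <- table(x$namespace)
  cat("Ontology DAG: ", length(x$terms), " terms (",
      paste(names(ns), ns, sep = ":", collapse = ", "), "), ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Read a restricted-dialect OBO ontology file
#'
#' Parses `[Term]` stanzas honouring the tags `id`, `name`, `namespace`,
#' `is_a` and `is_obsolete`; all other tags and trailing `!` comments are
#' ignored. Obsolete terms are skipped (a message reports how many).
#' Namespace strings `biological_process`, `molecular_function` and
#' `cellular_component` are abbreviated to `BP`, `MF`, `CC`.
#'
#' @param path Path to the OBO file.
#' @return An [ontology_dag()].
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found")
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0L); nm <- character(0L); ns <- character(0L)
  parents <- list()
  n_obsolete <- 0L
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  for (i in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !grepl("^\\[", chunk)]
    tagval <- regmatches(chunk, regexec("^([a-z_]+):\\s*(.*)$", chunk))
    tags <- vapply(tagval, function(m) if (length(m)) m[[2L]] else "", "")
    vals <- vapply(tagval, function(m) if (length(m)) m[[3L]] else "", "")
    get1 <- function(tag) {
      v <- vals[tags == tag]
      if (length(v) == 0L) NA_character_ else trimws(v[[1L]])
    }
    if (identical(tolower(get1("is_obsolete")), "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- get1("id")
    if (is.na(id)) stop("[Term] stanza without id (stanza ", i, ")")
    ids <- c(ids, id)
    nm[[id]] <- if (is.na(get1("name"))) id else get1("name")
    raw_ns <- get1("namespace")
    ns[[id]] <- if (!is.na(raw_ns) && raw_ns %in% names(ns_map))
      ns_map[[raw_ns]] else if (is.na(raw_ns)) "BP" else raw_ns
    parents[[id]] <- trimws(vals[tags == "is_a"])
  }
  if (n_obsolete > 0L)
    message("read_obo_subset: skipped ", n_obsolete, " obsolete term(s)")
  ontology_dag(ids, nm, ns, parents)
}

#' Write an ontology DAG in the restricted OBO dialect
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `namespace` and
#' `is_a` tags — exactly the dialect [read_obo_subset()] parses back.
#'
#' @param dag An [ontology_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  ns_map <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    ns <- dag$namespace[[t]]
    writeLines(c("",
                 "[Term]",
                 paste0("id: ", t),
                 paste0("name: ", dag$name[[t]]),
                 paste0("namespace: ",
                        if (ns %in% names(ns_map)) ns_map[[ns]] else ns),
                 if (length(dag$parents[[t]]) > 0L)
                   paste0("is_a: ", dag$parents[[t]])), con)
  }
  invisible(path)
}

#' Compute hierarchy levels of ontology terms
#'
#' The level of a term is 1 plus the number of edges on the *longest*
#' directed path from the term up to its namespace root; roots are level 1.
#' Under this convention deeper terms carry more specific biological
#' information, and for every `is_a` edge the child's level exceeds the
#' parent's. A shortest-path convention is available as an option.
#'
#' @param dag An [ontology_dag()].
#' @param convention `"longest"` (default) or `"shortest"` path to root.
#' @return Named integer vector, term -> level.
#' @export
compute_term_levels <- function(dag, convention = c("longest", "shortest")) {
  convention <- match.arg(convention)
  agg <- if (convention == "longest") max else min
  ord <- topo_order(dag)
  if (is.null(ord)) stop("ontology graph contains a cycle")
  lev <- integer(length(dag$terms))
  names(lev) <- dag$terms
  for (t in ord) {
    ps <- dag$parents[[t]]
    lev[[t]] <- if (length(ps) == 0L) 1L else 1L + agg(lev[ps])
  }
  lev
}

#' Construct a gene/term annotation map
#'
#' @param gene_to_terms Named list, gene -> character vector of term ids.
#' @param dag Optional [ontology_dag()]; when given, every referenced term
#'   must exist in it.
#' @return An object of class `"annotation_map"` with mutually inverse
#'   `gene_to_terms` and `term_to_genes` lists.
#' @export
annotation_map <- function(gene_to_terms, dag = NULL) {
  gene_to_terms <- lapply(gene_to_terms, function(x) unique(as.character(x)))
  gene_to_terms <- gene_to_terms[lengths(gene_to_terms) > 0L]
  all_terms <- unique(unlist(gene_to_terms, use.names = FALSE))
  if (!is.null(dag)) {
    unknown <- setdiff(all_terms, dag$terms)
    if (length(unknown) > 0L)
      stop("annotation references term(s) absent from the ontology: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  pairs_gene <- rep(names(gene_to_terms), lengths(gene_to_terms))
  pairs_term <- unlist(gene_to_terms, use.names = FALSE)
  term_to_genes <- lapply(split(pairs_gene, pairs_term), unique)
  structure(list(gene_to_terms = gene_to_terms,
                 term_to_genes = term_to_genes),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map: ", length(x$gene_to_terms), " genes <-> ",
      length(x$term_to_genes), " terms\n", sep = "")
  invisible(x)
}

#' Read a two-column gene/term annotation table
#'
#' @param path TSV with two columns: gene id, term id (no header by
#'   default). Duplicate pairs are collapsed.
#' @param dag Optional [ontology_dag()] used to validate term ids.
#' @param header Does the file carry a header row?
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, dag = NULL, header = FALSE) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("annotation file must have two columns")
  annotation_map(split(raw[[2L]], raw[[1L]]), dag = dag)
}

#' Write an annotation map as a two-column TSV
#'
#' @param ann An [annotation_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  g <- rep(names(ann$gene_to_terms), lengths(ann$gene_to_terms))
  t <- unlist(ann$gene_to_terms, use.names = FALSE)
  utils::write.table(data.frame(g, t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map genes to (term, level) pairs
#'
#' The union, over the given genes, of their term annotations, each term
#' paired with its hierarchy level. Genes without annotation contribute
#' nothing. This is the mapping that seeds the level-by-level removal loop.
#'
#' @param genes Character vector of gene ids.
#' @param ann An [annotation_map()].
#' @param levels Named integer vector from [compute_term_levels()].
#' @return Data frame with columns `term` and `level`, one row per distinct
#'   term.
#' @export
genes_to_leveled_terms <- function(genes, ann, levels) {
  terms <- unlist(ann$gene_to_terms[
    intersect(genes, names(ann$gene_to_terms))], use.names = FALSE)
  terms <- if (is.null(terms)) character(0L) else unique(terms)
  missing_lv <- setdiff(terms, names(levels))
  if (length(missing_lv) > 0L)
    stop("no hierarchy level for term(s): ",
         paste(utils::head(missing_lv, 5L), collapse = ", "))
  data.frame(term = terms,
             level = if (length(terms)) unname(levels[terms]) else integer(0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map ontology terms to the union of their annotated genes
#'
#' @param terms Character vector of term ids; every term must be known to
#'   the annotation map's ontology side (an unknown term is an error, so
#'   meaning is never silently dropped). Terms with no annotated genes are
#'   allowed when `dag` confirms they exist.
#' @param ann An [annotation_map()].
#' @param dag Optional [ontology_dag()]; terms present in the DAG but
#'   unannotated contribute no genes instead of erroring.
#' @return Character vector of gene ids.
#' @export
terms_to_genes <- function(terms, ann, dag = NULL) {
  terms <- unique(as.character(terms))
  known <- names(ann$term_to_genes)
  if (!is.null(dag)) known <- union(known, dag$terms)
  unknown <- setdiff(terms, known)
  if (length(unknown) > 0L)
    stop("unknown ontology term(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  out <- unlist(ann$term_to_genes[intersect(terms, names(ann$term_to_genes))],
                use.names = FALSE)
  if (is.null(out)) character(0L) else unique(out)
}

#' Biological meaning of a gene set
#'
#' The meaning of a single gene is the set of ontology terms it is
#' annotated with; the meaning of a gene set is the union of its genes'
#' term sets. Two gene sets whose meanings are disjoint share no ontology
#' annotation at all and are "complementary" in this sense.
#'
#' @param genes Character vector of gene ids (may be empty).
#' @param ann An [annotation_map()].
#' @return Character vector of term ids (possibly empty).
#' @export
meaning_of <- function(genes, ann) {
  genes <- if (inherits(genes, "signature")) genes$genes else genes
  out <- unlist(ann$gene_to_terms[intersect(genes, names(ann$gene_to_terms))],
                use.names = FALSE)
  if (is.null(out)) character(0L) else unique(out)
}
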