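#' Falsification test for the biological meaning of a prognostic signature
#'
#' The decision procedure: map the signature's genes to *all* their
#' ontology terms, map those terms back to every annotated gene, and
#' delete that union (plus the signature's own unannotated genes, and
#' optionally a proliferation gene list) from the universe in one shot.
#' Random sets of the signature's size are then drawn from the remaining
#' pool — sets that by construction share no ontology term with the
#' signature — and scored by PC1 stratification + log-rank test with a
#' Bonferroni correction. If any such set is significant ("a surrogate"),
#' the signature's prognostic performance cannot support a biological
#' interpretation; only when no surrogate is found does the signature have
#' a testable meaning.
#'
#' Unlike the level-wise procedure 2 loop, removal here is not iterated by
#' hierarchy level; the two code paths are kept separate deliberately so
#' each stays auditable against its definition. All namespaces
#' participate: the disjointness claim is about the full meaning set.
#'
#' @inheritParams run_resampling
#' @param bm A [signature_set()].
#' @param ann An [annotation_map()].
#' @param pg Optional proliferation gene list, removed before the meaning
#'   removal.
#' @param repeats Random sets to draw (default 1000). When the verdict is
#'   "no surrogate found", remember that resolving a surrogate probability
#'   p requires more than 1/p repeats; a warning restates this.
#' @return Object of class `"falsification_verdict"`: list with
#'   `signature`, `n_surrogates_found`, `p_sgs` (their fraction),
#'   `has_testable_meaning` (`TRUE` iff no surrogate found),
#'   `removed_gene_count` (the size of the deleted meaning union `D`),
#'   `pool_size`, `pool` (the pool's genes), `p_raw`, `p_corrected`, and
#'   the run parameters.
#' @seealso [verify_disjoint()], [grp2()]
#' @export
falsification_test <- function(expr, surv, bm, ann, pg = NULL,
                               repeats = 1000L, alpha = 0.001,
                               correction = c("bonferroni", "none"),
                               seed = 1L) {
  correction <- match.arg(correction)
  G <- rownames(expr)
  pool_genes <- if (is.null(pg)) G else setdiff(G, pg)
  GT <- meaning_of(bm$genes, ann)
  D <- if (length(GT)) terms_to_genes(GT, ann) else character(0L)
  pool_genes <- setdiff(pool_genes, D)
  pool_genes <- setdiff(pool_genes, bm$genes)  # unannotated signature genes
  size <- length(intersect(bm$genes, G))
  if (size < 2L)
    stop("signature '", bm$name,
         "' has fewer than 2 genes in the expression universe")
  if (length(pool_genes) < size)
    stop("meaning removal exhausts the gene universe: pool of ",
         length(pool_genes), " genes cannot yield sets of size ", size)
  pool <- sampling_pool(pool_genes,
                        label = paste0(bm$name, "/falsification"),
                        procedure = "falsification",
                        genes_removed = length(intersect(D, G)),
                        cum_genes_removed = length(intersect(D, G)),
                        terms_removed = length(GT),
                        cum_terms_removed = length(GT))
  res <- run_resampling(expr, surv, pool, size = size, repeats = repeats,
                        alpha = alpha, correction = correction, seed = seed,
                        signature = bm)
  p_cor <- res$p_corrected[[1L]]
  n_sgs <- sum(p_cor < alpha, na.rm = TRUE)
  if (n_sgs == 0L)
    warning("no surrogate found with ", repeats, " repeats; resolving a ",
            "surrogate probability p needs more than 1/p repeats",
            call. = FALSE)
  structure(list(signature = bm$name,
                 n_surrogates_found = n_sgs,
                 p_sgs = n_sgs / repeats,
                 has_testable_meaning = n_sgs == 0L,
                 removed_gene_count = length(intersect(D, G)),
                 removed_term_count = length(GT),
                 pool_size = length(pool_genes),
                 pool = pool_genes,
                 signature_size = size,
                 p_raw = res$p_raw[[1L]],
                 p_corrected = p_cor,
                 signature_p = res$table$signature_p[[1L]],
                 params = list(repeats = repeats, alpha = alpha,
                               correction = correction, seed = seed,
                               proliferation_removed = !is.null(pg))),
            class = "falsification_verdict")
}

#' @export
print.falsification_verdict <- function(x, ...) {
  cat("Falsification test for signature '", x$signature, "'\n", sep = "")
  cat("  meaning removal: ", x$removed_term_count, " terms -> ",
      x$removed_gene_count, " genes deleted; pool of ", x$pool_size,
      " genes left\n", sep = "")
  cat("  surrogates found: ", x$n_surrogates_found, " / ",
      x$params$repeats, " random sets (p_sgs = ",
      signif(x$p_sgs, 3L), ")\n", sep = "")
  cat(if (x$has_testable_meaning)
        "  verdict: no surrogate found - the signature's biological meaning is testable\n"
      else
        "  verdict: surrogates exist - prognostic performance cannot support a biological interpretation\n")
  invisible(x)
}

#' Verify meaning disjointness of a signature and a candidate surrogate
#'
#' `TRUE` iff the two gene sets' biological meanings (term unions) share
#' no ontology term. Every set sampled from a falsification pool satisfies
#' this by construction; the verifier makes the guarantee checkable on any
#' pair.
#'
#' @param bm A [signature_set()] or character vector of genes.
#' @param sgs Character vector of genes (the candidate surrogate set).
#' @param ann An [annotation_map()].
#' @return Logical scalar.
#' @export
verify_disjoint <- function(bm, sgs, ann) {
  genes <- if (inherits(bm, "signature")) bm$genes else bm
  length(intersect(meaning_of(genes, ann), meaning_of(sgs, ann))) == 0L
}
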