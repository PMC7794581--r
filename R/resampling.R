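#' Construct a sampling pool (internal representation)
#'
#' @param genes Character vector: the genes available for random sampling.
#' @param label Human-readable descriptor.
#' @param procedure `"grp1"`, `"grp2"`, `"grp2star"` or `"falsification"`.
#' @param level Hierarchy level the pool corresponds to (`NA` when the
#'   pool is not level-specific).
#' @param genes_removed,cum_genes_removed Genes removed at this level /
#'   cumulatively over the level loop (the signature's own removal is
#'   bookkept separately and not counted here).
#' @param terms_removed,cum_terms_removed Ontology terms removed at this
#'   level / cumulatively.
#' @return Object of class `"sampling_pool"`.
#' @keywords internal
#' @export
sampling_pool <- function(genes, label, procedure, level = NA_integer_,
                          genes_removed = 0L, cum_genes_removed = 0L,
                          terms_removed = 0L, cum_terms_removed = 0L) {
  structure(list(genes = as.character(genes), label = label,
                 procedure = procedure, level = level,
                 genes_removed = genes_removed,
                 cum_genes_removed = cum_genes_removed,
                 terms_removed = terms_removed,
                 cum_terms_removed = cum_terms_removed),
            class = "sampling_pool")
}

#' @export
print.sampling_pool <- function(x, ...) {
  cat("Sampling pool [", x$procedure, "] ", x$label, ": ",
      length(x$genes), " genes",
      if (!is.na(x$level)) paste0(" (hierarchy level ", x$level, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Gene removal procedure 1: remove the signature itself
#'
#' The pool is the gene universe minus the signature's genes; random sets
#' drawn from it can share no gene with the signature, but may still share
#' its ontology annotations.
#'
#' @param G Character vector, the gene universe (typically
#'   `rownames(expr)`).
#' @param bm A [signature_set()].
#' @return A `"sampling_pool"` of `G \\ BM`.
#' @export
grp1_pool <- function(G, bm) {
  G <- unique(as.character(G))
  present <- intersect(bm$genes, G)
  if (length(present) == 0L)
    warning("signature '", bm$name, "' shares no gene with the universe")
  pool <- setdiff(G, bm$genes)
  if (length(pool) < length(present))
    stop("pool smaller than the signature: cannot sample")
  sampling_pool(pool, label = paste0(bm$name, "/grp1"), procedure = "grp1")
}

#' Gene removal procedure 2 (and 2*): level-wise removal of shared
#' biological processes
#'
#' Starting from the universe minus the signature (minus a
#' proliferation-gene list for the starred variant), the signature's genes
#' are mapped to their ontology terms and hierarchy levels. Looping over
#' the levels from the signature's deepest (most specific) level down to
#' its shallowest, all genes annotated to any signature-derived term at the
#' current level are deleted, and the surviving pool is emitted with its
#' removal bookkeeping. The loop stops at the shallowest level or as soon
#' as the pool would become smaller than the signature.
#'
#' Only terms of the chosen namespace (biological process by default)
#' drive removal; unannotated genes are never removed by the level loop.
#'
#' @param G Gene universe (character vector).
#' @param bm A [signature_set()].
#' @param ann An [annotation_map()].
#' @param levels Term levels from [compute_term_levels()] on the same DAG
#'   as `ann`.
#' @param dag The [ontology_dag()]; used to restrict terms to `namespace`.
#' @param namespace Namespace whose terms drive removal (default `"BP"`).
#' @param remove_proliferation Apply the optional proliferation-removal
#'   step (procedure 2*)?
#' @param pg Proliferation gene list (required when
#'   `remove_proliferation = TRUE`).
#' @return List of `"sampling_pool"` objects in iteration order (deepest
#'   level first), with attribute `early_stop` (logical) and
#'   `signature_size` (the sampling size `|BM|` after intersection
#'   with `G`).
#' @export
grp2_pools <- function(G, bm, ann, levels, dag = NULL, namespace = "BP",
                       remove_proliferation = FALSE, pg = NULL) {
  G <- unique(as.character(G))
  size <- length(intersect(bm$genes, G))
  proc <- if (remove_proliferation) "grp2star" else "grp2"
  cur <- setdiff(G, bm$genes)
  if (remove_proliferation) {
    if (is.null(pg)) stop("remove_proliferation = TRUE needs a `pg` gene list")
    cur <- setdiff(cur, pg)
  }
  pairs <- genes_to_leveled_terms(bm$genes, ann, levels)
  if (!is.null(dag))
    pairs <- pairs[dag$namespace[pairs$term] == namespace, , drop = FALSE]
  mk <- function(pool, level, grm, cgrm, trm, ctrm) {
    sampling_pool(pool, label = paste0(bm$name, "/", proc,
                                       if (!is.na(level)) paste0("/L", level)),
                  procedure = proc, level = level, genes_removed = grm,
                  cum_genes_removed = cgrm, terms_removed = trm,
                  cum_terms_removed = ctrm)
  }
  if (nrow(pairs) == 0L) {
    out <- list(mk(cur, NA_integer_, 0L, 0L, 0L, 0L))
    attr(out, "early_stop") <- FALSE
    attr(out, "signature_size") <- size
    return(out)
  }
  l_max <- max(pairs$level)
  l_min <- min(pairs$level)
  pools <- list()
  cum_g <- 0L; cum_t <- 0L
  early <- FALSE
  for (l in seq(l_max, l_min, by = -1L)) {
    terms_l <- pairs$term[pairs$level == l]
    D <- if (length(terms_l)) terms_to_genes(terms_l, ann, dag = dag)
         else character(0L)
    removed <- intersect(cur, D)
    cur <- setdiff(cur, D)
    cum_g <- cum_g + length(removed)
    cum_t <- cum_t + length(terms_l)
    if (length(cur) < size) {
      early <- TRUE
      break
    }
    pools[[length(pools) + 1L]] <-
      mk(cur, l, length(removed), cum_g, length(terms_l), cum_t)
  }
  attr(pools, "early_stop") <- early
  attr(pools, "signature_size") <- size
  pools
}

#' Draw random gene sets from a pool
#'
#' Each set is drawn uniformly without replacement within the set and
#' independently across repeats; distinct repeats may coincide (at
#' realistic pool sizes the collision probability is negligible).
#'
#' @param pool A `"sampling_pool"` or plain character vector of genes.
#' @param size Number of genes per set.
#' @param repeats Number of sets to draw.
#' @param seed Integer seed making the draws reproducible.
#' @return List of `repeats` character vectors of length `size`.
#' @export
sample_random_sets <- function(pool, size, repeats, seed = NULL) {
  genes <- if (inherits(pool, "sampling_pool")) pool$genes else pool
  if (length(genes) < size)
    stop("pool of ", length(genes), " genes cannot yield sets of size ", size)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(repeats), function(i) sample(genes, size))
}

#' Bonferroni correction with explicit multiplicity
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Multiplicity; defaults to `length(p)` (the number of repeats in
#'   a batch).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("multiplicity m must be >= 1")
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  pmin(1, m * p)
}

#' Summaries of a batch of resampling p-values
#'
#' @param p Nonempty numeric vector of p-values.
#' @param alpha Significance level.
#' @return List with `median`, `percentile3` (the empirical 3rd percentile,
#'   linear-interpolation quantile) and `fraction_significant`
#'   (share with `p < alpha`).
#' @export
summarize_pvalues <- function(p, alpha = 0.001) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values to summarize")
  list(median = stats::median(p),
       percentile3 = unname(stats::quantile(p, probs = 0.03, type = 7L)),
       fraction_significant = mean(p < alpha))
}

# Evaluate one gene set: PC1 median-split stratification + log-rank p.
# Degenerate draws return NA with the reason recorded by the caller.
eval_gene_set <- function(expr, time, event, genes) {
  sub <- t(expr[genes, , drop = FALSE])
  score <- stats::prcomp(sub, center = TRUE, scale. = FALSE, rank. = 1L)$x[, 1L]
  med <- stats::median(score)
  g <- score > med
  if (all(g) || !any(g)) stop("median split produced a single group")
  if (sum(event) == 0L) stop("zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  stats::pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE)
}

#' Run the survival resampling over one or more sampling pools
#'
#' For each pool, `repeats` random gene sets of the given size are drawn,
#' each is scored by PC1 median-split stratification followed by the
#' two-sample log-rank test, the batch of p-values is (optionally)
#' Bonferroni-corrected with multiplicity `repeats`, and sets with
#' (corrected) `p < alpha` are counted as true positives. Accuracy is
#' `TP / repeats` (non-significant sets are false negatives; the
#' declaration scheme admits no true negatives or false positives).
#' Degenerate draws (constant submatrix, single-group split) count as
#' false negatives rather than being redrawn, which would bias the null;
#' their number is recorded per pool.
#'
#' The original signature is evaluated once on the same data; its p-value
#' is reported alongside every pool.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param surv Survival data frame; joined to `expr` on sample ids (the
#'   join is order-independent).
#' @param pools A `"sampling_pool"` or list of pools (e.g. from
#'   [grp2_pools()]).
#' @param size Genes per random set; defaults to the signature's size
#'   within the universe when `signature` is given.
#' @param repeats Random sets per pool (default 1000).
#' @param alpha Significance level (default 0.001).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param seed Master integer seed; each pool draws from its own stream
#'   derived from it.
#' @param signature Optional [signature_set()] evaluated for the
#'   `signature_p` column.
#' @param signature_accuracy Optional \\%-accuracy from a signature-only
#'   removal run, echoed into the report's `signature_accuracy_pct` column
#'   (`NA` when not supplied; for procedure-1 pools it equals the pool's
#'   own accuracy).
#' @return Object of class `"resampling_report"`: list with `table` (one
#'   row per pool: bookkeeping, accuracy, p-value summaries), `p_raw` and
#'   `p_corrected` (lists of per-repeat p-value vectors), `n_draws` (total
#'   sets drawn), and the run parameters.
#' @export
run_resampling <- function(expr, surv, pools, size = NULL, repeats = 1000L,
                           alpha = 0.001, correction = c("bonferroni", "none"),
                           seed = 1L, signature = NULL,
                           signature_accuracy = NA_real_) {
  correction <- match.arg(correction)
  if (inherits(pools, "sampling_pool")) pools <- list(pools)
  samples <- intersect(colnames(expr), surv$sample)
  if (length(samples) < 4L)
    stop("fewer than 4 samples shared between expression and survival data")
  samples <- sort(samples)   # canonical order: join is permutation-invariant
  expr <- expr[, samples, drop = FALSE]
  idx <- match(samples, surv$sample)
  time <- surv$time[idx]
  event <- surv$event[idx]

  if (is.null(size)) {
    if (is.null(signature))
      stop("give `size` or a `signature` to take the size from")
    size <- length(intersect(signature$genes, rownames(expr)))
  }

  sig_p_raw <- NA_real_
  if (!is.null(signature)) {
    sig_genes <- intersect(signature$genes, rownames(expr))
    sig_p_raw <- tryCatch(eval_gene_set(expr, time, event, sig_genes),
                          error = function(e) NA_real_)
  }
  sig_p <- if (correction == "bonferroni" && !is.na(sig_p_raw))
    min(1, repeats * sig_p_raw) else sig_p_raw

  rows <- vector("list", length(pools))
  p_raw_all <- vector("list", length(pools))
  p_cor_all <- vector("list", length(pools))
  for (k in seq_along(pools)) {
    pool <- pools[[k]]
    draws <- sample_random_sets(pool, size, repeats,
                                seed = derive_seed(seed, k))
    p_raw <- rep(NA_real_, repeats)
    n_failed <- 0L
    for (r in seq_len(repeats)) {
      p_raw[[r]] <- tryCatch(eval_gene_set(expr, time, event, draws[[r]]),
                             error = function(e) NA_real_)
      if (is.na(p_raw[[r]])) n_failed <- n_failed + 1L
    }
    if (n_failed > 0L)
      message("pool '", pool$label, "': ", n_failed,
              " degenerate draw(s) counted as false negatives")
    p_eff <- if (correction == "bonferroni") bonferroni(p_raw, m = repeats)
             else p_raw
    tp <- sum(p_eff < alpha, na.rm = TRUE)
    smry <- if (all(is.na(p_eff))) list(median = NA_real_,
                                        percentile3 = NA_real_,
                                        fraction_significant = NA_real_)
            else summarize_pvalues(p_eff, alpha)
    rows[[k]] <- data.frame(
      pool_label = pool$label,
      hierarchy_level = pool$level,
      genes_removed = pool$genes_removed,
      cum_genes_removed = pool$cum_genes_removed,
      genes_left = length(pool$genes),
      terms_removed = pool$terms_removed,
      cum_terms_removed = pool$cum_terms_removed,
      n_significant = tp,
      n_failed = n_failed,
      accuracy_pct = 100 * tp / repeats,
      signature_accuracy_pct = signature_accuracy,
      median_p = smry$median,
      percentile3_p = smry$percentile3,
      signature_p = sig_p,
      stringsAsFactors = FALSE)
    p_raw_all[[k]] <- p_raw
    p_cor_all[[k]] <- p_eff
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  procedure <- pools[[1L]]$procedure
  if (procedure == "grp1")
    tab$signature_accuracy_pct <- tab$accuracy_pct
  structure(list(table = tab, p_raw = p_raw_all, p_corrected = p_cor_all,
                 n_draws = length(pools) * repeats,
                 params = list(size = size, repeats = repeats, alpha = alpha,
                               correction = correction, seed = seed,
                               procedure = procedure,
                               n_samples = length(samples)),
                 signature_p_raw = sig_p_raw),
            class = "resampling_report")
}

# Deterministic per-pool RNG stream seeds, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

#' @export
print.resampling_report <- function(x, ...) {
  p <- x$params
  cat("Constrained-resampling report [", p$procedure, "]: ",
      nrow(x$table), " pool(s), ", p$repeats, " repeats each, size ",
      p$size, ", alpha ", p$alpha, " (", p$correction, ")\n", sep = "")
  show <- x$table[, c("hierarchy_level", "genes_left", "genes_removed",
                      "terms_removed", "accuracy_pct", "median_p")]
  print(show, digits = 4L, row.names = FALSE)
  invisible(x)
}

#' @export
summary.resampling_report <- function(object, ...) {
  tab <- object$table
  cat("Pools:               ", nrow(tab), "\n")
  cat("Random sets drawn:   ", object$n_draws, "\n")
  cat("Accuracy range (%):  ", paste(signif(range(tab$accuracy_pct), 4L),
                                     collapse = " - "), "\n")
  i <- which.min(tab$accuracy_pct)
  cat("Minimal accuracy:    ", signif(tab$accuracy_pct[i], 4L), "% at level ",
      tab$hierarchy_level[i], "\n", sep = "")
  if (!all(is.na(tab$signature_p)))
    cat("Signature p-value:   ", format(tab$signature_p[1L], digits = 4L),
        "\n")
  invisible(object)
}

#' @export
plot.resampling_report <- function(x, ...) {
  lp <- lapply(x$p_corrected, function(p) -log10(pmax(p[!is.na(p)], 1e-300)))
  labs <- ifelse(is.na(x$table$hierarchy_level), "all",
                 x$table$hierarchy_level)
  graphics::boxplot(lp, names = labs, xlab = "hierarchy level",
                    ylab = expression(-log[10](p)),
                    main = "Random gene set p-values per pool", ...)
  graphics::abline(h = -log10(x$params$alpha), col = "blue", lty = 2L)
  invisible(x)
}

#' Upper bound on the number of candidate surrogate gene sets
#'
#' The number of distinct gene sets of size `k` drawn from a pool of `n`
#' genes is `choose(n, k)`, which is bounded above by `(n e / k)^k`.
#' Writing the bound as a power of ten gives the exponent
#' `x = k * log10(n e / k)`, reported after rounding (half away from zero)
#' to an integer. The one-percent exponent `x - 2` bounds one percent of
#' the candidate sets, the order of magnitude of surrogate sets when a
#' percent-range fraction of random sets is significant.
#'
#' @param n Pool size (`n >= k`).
#' @param k Gene-set size (`k >= 1`).
#' @return Object of class `"surrogate_bound"`: list with `n`, `k`, `x`
#'   (integer exponent), `x_exact` (unrounded), and `x_percentile`
#'   (`x - 2`).
#' @export
surrogate_bound <- function(n, k) {
  if (k < 1) stop("k must be >= 1")
  if (n < k) stop("n must be >= k")
  ratio <- n * exp(1) / k
  if (ratio <= 1) stop("bound invalid: n*e/k must exceed 1")
  x_exact <- k * log10(ratio)
  x <- as.integer(sign(x_exact) * floor(abs(x_exact) + 0.5))
  structure(list(n = n, k = k, x = x, x_exact = x_exact,
                 x_percentile = x - 2L),
            class = "surrogate_bound")
}

#' @export
print.surrogate_bound <- function(x, ...) {
  cat("choose(", x$n, ", ", x$k, ") <= (n e / k)^k = 10^", x$x,
      "  (1% of the sets: 10^", x$x_percentile, ")\n", sep = "")
  invisible(x)
}
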