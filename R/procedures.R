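#' Run gene removal procedure 1 for one signature
#'
#' Convenience wrapper: builds the signature-removal pool over the
#' expression matrix's gene universe and runs the survival resampling on
#' it. Random sets drawn from the pool contain no signature gene; a
#' significant set is a *surrogate* for the signature under the gene-based
#' (Mendelian) view of biological meaning.
#'
#' @inheritParams run_resampling
#' @param bm A [signature_set()].
#' @return A `"resampling_report"` with a single pool row.
#' @seealso [grp2()], [falsification_test()]
#' @export
grp1 <- function(expr, surv, bm, repeats = 1000L, alpha = 0.001,
                 correction = c("bonferroni", "none"), seed = 1L) {
  correction <- match.arg(correction)
  pool <- grp1_pool(rownames(expr), bm)
  lost <- setdiff(bm$genes, rownames(expr))
  if (length(lost) > 0L)
    message("signature '", bm$name, "': ", length(lost),
            " gene(s) absent from the expression universe; sampling size ",
            "uses the intersected signature")
  run_resampling(expr, surv, pool, repeats = repeats, alpha = alpha,
                 correction = correction, seed = seed, signature = bm)
}

#' Run gene removal procedure 2 (or 2*) for one signature
#'
#' Builds the level-wise pools of [grp2_pools()] and runs the survival
#' resampling on every level's pool. The `signature_accuracy_pct` column
#' ("Sig. Acc.") reports the accuracy obtained when only the signature is
#' removed (procedure 1), computed on the same data with the same
#' parameters.
#'
#' @inheritParams run_resampling
#' @inheritParams grp2_pools
#' @param bm A [signature_set()].
#' @return A `"resampling_report"` with one row per hierarchy level, in
#'   iteration order (deepest level first), plus attribute `early_stop`.
#' @export
grp2 <- function(expr, surv, bm, ann, levels, dag = NULL, namespace = "BP",
                 remove_proliferation = FALSE, pg = NULL, repeats = 1000L,
                 alpha = 0.001, correction = c("bonferroni", "none"),
                 seed = 1L) {
  correction <- match.arg(correction)
  pools <- grp2_pools(rownames(expr), bm, ann, levels, dag = dag,
                      namespace = namespace,
                      remove_proliferation = remove_proliferation, pg = pg)
  if (length(pools) == 0L)
    stop("no samplable pool: the first level removal already exhausted the universe")
  sig_run <- grp1(expr, surv, bm, repeats = repeats, alpha = alpha,
                  correction = correction, seed = derive_seed(seed, 7919L))
  sig_acc <- sig_run$table$accuracy_pct[[1L]]
  rep2 <- run_resampling(expr, surv, pools, repeats = repeats, alpha = alpha,
                         correction = correction, seed = seed, signature = bm,
                         signature_accuracy = sig_acc)
  attr(rep2, "early_stop") <- attr(pools, "early_stop")
  rep2
}
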