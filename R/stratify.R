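#' Stratify samples by the first principal component of a gene set
#'
#' Restricts the expression matrix to the gene set, treats samples as
#' observations and genes as features, computes a covariance PCA (features
#' centred, not scaled, via [stats::prcomp()]) and splits the samples at
#' the median of their PC1 scores: label `-1` for scores at or below the
#' median, `+1` above. Because a principal component's algebraic sign is
#' arbitrary, the split is meaningful only up to a global label swap, and
#' every downstream quantity in the package (the two-sample log-rank test)
#' is invariant under that swap.
#'
#' @param expr Numeric genes-by-samples matrix with dimnames
#'   (see [read_expression()]).
#' @param gene_set Character vector of gene ids; at least 2 must be present
#'   in `expr`.
#' @param scale. Scale features to unit variance before the PCA
#'   (correlation PCA)? Default `FALSE`, the standard behaviour of
#'   `prcomp`.
#' @return Named integer vector over samples with values in \{-1, +1\};
#'   both labels are guaranteed present.
#' @export
pc1_stratify <- function(expr, gene_set, scale. = FALSE) {
  gene_set <- if (inherits(gene_set, "signature")) gene_set$genes else gene_set
  gs <- intersect(gene_set, rownames(expr))
  if (length(gs) < 2L)
    stop("degenerate gene set: fewer than 2 genes found in the expression matrix")
  if (ncol(expr) < 2L)
    stop("need at least 2 samples for a median-split stratification")
  sub <- t(expr[gs, , drop = FALSE])     # samples x genes
  if (all(abs(sweep(sub, 2L, colMeans(sub))) < 1e-12))
    stop("constant expression submatrix: PC1 undefined")
  score <- stats::prcomp(sub, center = TRUE, scale. = scale.,
                         rank. = 1L)$x[, 1L]
  med <- stats::median(score)
  lab <- ifelse(score > med, 1L, -1L)
  names(lab) <- rownames(sub)
  if (length(unique(lab)) < 2L)
    stop("median split produced a single group (all PC1 scores tied)")
  lab
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv Survival data frame (columns `sample`, `time`, `event`).
#' @param groups Optional named group-label vector (as returned by
#'   [pc1_stratify()]); with `label`, restricts the estimate to one group.
#' @param label Group label to keep when `groups` is given.
#' @return Object of class `"km_estimate"`: a list with `time` (increasing
#'   event/censoring times), `surv` (nonincreasing survival probabilities),
#'   `n_risk`, `n_event`, and `n` (group size). With no events the curve is
#'   identically 1.
#' @export
km_estimate <- function(surv, groups = NULL, label = NULL) {
  validate_survival(surv)
  if (!is.null(groups)) {
    if (is.null(label)) stop("give `label` to select a group")
    keep <- names(groups)[groups == label]
    surv <- surv[surv$sample %in% keep, , drop = FALSE]
  }
  if (nrow(surv) == 0L) stop("empty group: no samples to estimate from")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = nrow(surv)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: n = ", x$n, ", events = ", sum(x$n_event),
      ", final S(t) = ", signif(min(x$surv), 4L), "\n", sep = "")
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "time", ylab = "S(t)", ylim = c(0, 1),
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Two-sample Mantel-Haenszel (log-rank) test
#'
#' Compares the survival curves of the two groups of a stratification with
#' the standard log-rank chi-square on 1 degree of freedom
#' (via [survival::survdiff()]); ties are handled by the hypergeometric
#' variance. The test is symmetric under swapping the group labels.
#'
#' @param surv Survival data frame (columns `sample`, `time`, `event`).
#' @param groups Named vector of two group labels covering the analysis
#'   samples (extra survival rows are dropped on the join).
#' @return Object of class `"logrank_test"`: list with `statistic`
#'   (chi-square), `df` (1), and `p.value` (upper chi-square tail, never
#'   truncated to zero below float precision).
#' @export
logrank_test <- function(surv, groups) {
  validate_survival(surv)
  idx <- match(names(groups), surv$sample)
  if (anyNA(idx))
    stop("group assignment refers to sample(s) missing from survival data")
  time <- surv$time[idx]
  event <- surv$event[idx]
  g <- as.vector(groups)
  if (length(unique(g)) != 2L)
    stop("log-rank test needs exactly two nonempty groups")
  if (sum(event) == 0L)
    stop("test undefined: zero events in the data")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  chisq <- unname(sd$chisq)
  structure(list(statistic = chisq, df = 1L,
                 p.value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Mantel-Haenszel (log-rank) test: chi-square = ",
      signif(x$statistic, 5L), " on 1 df, p = ",
      format(x$p.value, digits = 4L), "\n", sep = "")
  invisible(x)
}
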