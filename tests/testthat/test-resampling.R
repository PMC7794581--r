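test_that("procedure-1 pools are exact set differences", {
  G <- paste0("g", 1:10)
  bm <- signature_set("bm", c("g1", "g2"))
  pool <- grp1_pool(G, bm)
  expect_length(pool$genes, 8L)
  expect_length(intersect(pool$genes, bm$genes), 0L)
  # disjoint signature: pool = G, with a warning
  out <- signature_set("out", c("x1", "x2"))
  expect_warning(p2 <- grp1_pool(G, out), "no gene")
  expect_setequal(p2$genes, G)
})

test_that("procedure-2 pools follow the level loop on a hand-traced toy", {
  # G = g1..g8, BM = {g1}, g1 -> T at level 2, T -> {g1,g2,g3}
  dag <- ontology_dag(c("R", "T"), c(R = "r", T = "t"),
                      c(R = "BP", T = "BP"),
                      list(R = character(0), T = "R"))
  ann <- annotation_map(list(g1 = "T", g2 = "T", g3 = "T"), dag = dag)
  lv <- compute_term_levels(dag)
  bm <- raw_signature("toy", "g1")
  pools <- grp2_pools(paste0("g", 1:8), bm, ann, lv, dag = dag)
  expect_length(pools, 1L)
  expect_setequal(pools[[1L]]$genes, paste0("g", 4:8))
  expect_identical(pools[[1L]]$genes_removed, 2L)   # g2, g3; g1 already gone
  expect_identical(pools[[1L]]$terms_removed, 1L)
  expect_identical(pools[[1L]]$level, 2L)
})

test_that("a fully unannotated signature yields a single level-free pool", {
  u <- tiny_universe()
  bm <- signature_set("unann", c("g7", "g8"))
  pools <- grp2_pools(u$G, bm, u$ann, u$levels, dag = u$dag)
  expect_length(pools, 1L)
  expect_true(is.na(pools[[1L]]$level))
  expect_setequal(pools[[1L]]$genes, paste0("g", 1:6))
})

test_that("level pools are nested with exact cumulative bookkeeping", {
  ds <- generate_dataset(sim_config(n_genes = 200, n_samples = 20,
                                    ontology_depth = 5, terms_per_level = 12,
                                    n_signatures = 2, signature_size = 10,
                                    seed = 21))
  lv <- compute_term_levels(ds$ontology)
  bm <- ds$signatures[[1L]]
  pools <- grp2_pools(rownames(ds$expression), bm, ds$annotation, lv,
                      dag = ds$ontology)
  expect_gt(length(pools), 1L)
  levels_seen <- vapply(pools, `[[`, 0L, "level")
  expect_true(all(diff(levels_seen) == -1L))      # descending from L_max
  for (k in seq_along(pools)[-1L])
    expect_true(all(pools[[k]]$genes %in% pools[[k - 1L]]$genes))
  grm <- vapply(pools, `[[`, 0L, "genes_removed")
  expect_identical(vapply(pools, `[[`, 0L, "cum_genes_removed"),
                   cumsum(grm))
  trm <- vapply(pools, `[[`, 0L, "terms_removed")
  expect_identical(vapply(pools, `[[`, 0L, "cum_terms_removed"),
                   cumsum(trm))
  # the final pool's meaning is disjoint from the signature's
  expect_true(verify_disjoint(bm, pools[[length(pools)]]$genes,
                              ds$annotation))
})

test_that("random set draws are uniform, reproducible and size-checked", {
  pool <- sampling_pool(paste0("g", 1:20), "p", "grp1")
  expect_error(sample_random_sets(pool, 21, 2, seed = 1), "cannot yield")
  # size = |pool|: every repeat returns the whole pool
  full <- sample_random_sets(pool, 20, 3, seed = 1)
  for (s in full) expect_setequal(s, pool$genes)
  # reproducibility
  expect_identical(sample_random_sets(pool, 5, 10, seed = 42),
                   sample_random_sets(pool, 5, 10, seed = 42))
  expect_false(identical(sample_random_sets(pool, 5, 10, seed = 42),
                         sample_random_sets(pool, 5, 10, seed = 43)))
  # per-gene inclusion frequency ~ hypergeometric size/|pool|
  draws <- sample_random_sets(pool, 5, 10000, seed = 7)
  freq <- table(factor(unlist(draws), levels = pool$genes)) / 10000
  p <- 5 / 20
  tol <- 4 * sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < tol))
})

test_that("Bonferroni correction is exact arithmetic with a cap", {
  expect_equal(bonferroni(0.0005, m = 1000), 0.5)
  expect_equal(bonferroni(0.01, m = 1000), 1)
  expect_equal(bonferroni(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  expect_error(bonferroni(0.1, m = 0), "m")
  expect_error(bonferroni(0, m = 10), "0, 1")
})

test_that("p-value summaries report median, 3rd percentile and hit rate", {
  s <- summarize_pvalues(rep(0.5, 10), alpha = 0.05)
  expect_equal(s$median, 0.5)
  expect_equal(s$percentile3, 0.5)
  expect_equal(s$fraction_significant, 0)
  p <- (1:1000 - 0.5) / 1000          # 1000 evenly spread values in (0, 1]
  expect_equal(summarize_pvalues(p, alpha = 0.001)$fraction_significant,
               0.001)
  # a significant median forces a majority of significant sets
  p2 <- c(rep(1e-5, 6), rep(0.5, 4))
  s2 <- summarize_pvalues(p2, alpha = 0.001)
  expect_lt(s2$median, 0.001)
  expect_gte(s2$fraction_significant, 0.5)
})

test_that("the surrogate-count bound holds exactly for small n", {
  for (n in 1:30)
    for (k in 1:n)
      expect_lte(choose(n, k), (n * exp(1) / k)^k)
  b <- surrogate_bound(50, 5)
  expect_identical(b$x, 7L)                     # 5*log10(50e/5) = 7.17
  expect_identical(b$x_percentile, 5L)
  expect_error(surrogate_bound(5, 10), ">= k")
})

test_that("resampling accuracy is exact at the alpha = 1 boundary and deterministic", {
  expr <- make_expr(30, 16, seed = 5)
  surv <- make_surv(16, seed = 6)
  bm <- signature_set("bm", rownames(expr)[1:4])
  r <- grp1(expr, surv, bm, repeats = 20, alpha = 1, correction = "none",
            seed = 3)
  expect_equal(r$table$accuracy_pct, 100)       # every p < 1
  r2 <- grp1(expr, surv, bm, repeats = 20, alpha = 1, correction = "none",
             seed = 3)
  expect_identical(r$table, r2$table)
  expect_identical(r$p_raw, r2$p_raw)
})

test_that("correction can only lower the accuracy for identical draws", {
  expr <- make_expr(40, 20, seed = 8)
  surv <- make_surv(20, seed = 9)
  bm <- signature_set("bm", rownames(expr)[1:5])
  a <- grp1(expr, surv, bm, repeats = 30, alpha = 0.3, correction = "none",
            seed = 11)
  b <- grp1(expr, surv, bm, repeats = 30, alpha = 0.3,
            correction = "bonferroni", seed = 11)
  expect_identical(a$p_raw, b$p_raw)            # same draws, same raw p
  expect_lte(b$table$accuracy_pct, a$table$accuracy_pct)
  expect_true(all(b$p_corrected[[1L]] >= a$p_raw[[1L]]))
})

test_that("the report's survival join is independent of row order", {
  expr <- make_expr(30, 16, seed = 5)
  surv <- make_surv(16, seed = 6)
  bm <- signature_set("bm", rownames(expr)[1:4])
  r1 <- grp1(expr, surv, bm, repeats = 15, seed = 2)
  perm <- sample(nrow(surv))
  r2 <- grp1(expr[, sample(ncol(expr))], surv[perm, ], bm, repeats = 15,
             seed = 2)
  expect_identical(r1$table, r2$table)
})
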