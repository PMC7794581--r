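test_that("identical configs reproduce the dataset bit-identically", {
  cfg <- sim_config(n_genes = 100, n_samples = 20, ontology_depth = 4,
                    terms_per_level = 8, n_signatures = 3,
                    signature_size = 6, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  expect_identical(lapply(a$signatures, `[[`, "genes"),
                   lapply(b$signatures, `[[`, "genes"))
  expect_identical(a$pg, b$pg)
})

test_that("gene roles, proliferation list and signatures respect the config", {
  cfg <- sim_config(n_genes = 500, n_samples = 30,
                    prognostic_fraction = 0.2, n_signatures = 4,
                    signature_size = 20, signature_enrichment = 0.5,
                    seed = 17)
  ds <- generate_dataset(cfg)
  roles <- ds$truth$roles
  expect_equal(sum(roles == "prognostic"), 100L)
  # pg is exactly the genes annotated to proliferation-like terms,
  # i.e. the prognostic genes
  expect_setequal(ds$pg, names(roles)[roles == "prognostic"])
  for (s in ds$signatures) {
    expect_length(s$genes, 20L)
    expect_equal(sum(roles[s$genes] == "prognostic"), 10L)
  }
  # weak genes never share the proliferation-like terms
  weak <- names(roles)[roles == "weak"]
  expect_length(intersect(
    unlist(ds$annotation$gene_to_terms[weak], use.names = FALSE),
    ds$truth$prolif_terms), 0L)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(n_genes = 100, signature_size = 40,
                          signature_enrichment = 1,
                          prognostic_fraction = 0.1),
               "infeasible")
  expect_error(sim_config(prognostic_fraction = 1.2), "fractions")
})

test_that("event fraction follows the competing-exponentials law", {
  # at gamma = 0, P(event) = b / (b + c); censoring -> 0 gives all events
  cfg <- sim_config(n_genes = 10, n_samples = 4000, hazard_effect = 0,
                    baseline_hazard = 0.1, censoring_rate = 0.05,
                    ontology_depth = 3, terms_per_level = 4,
                    n_signatures = 1, signature_size = 3,
                    signature_enrichment = 0, seed = 23)
  ds <- generate_dataset(cfg)
  p <- 0.1 / 0.15
  tol <- 4 * sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(ds$survival$event) - p), tol)
  cfg2 <- sim_config(n_genes = 10, n_samples = 500, hazard_effect = 0,
                     censoring_rate = 0, ontology_depth = 3,
                     terms_per_level = 4, n_signatures = 1,
                     signature_size = 3, signature_enrichment = 0,
                     seed = 23)
  expect_equal(mean(generate_dataset(cfg2)$survival$event), 1)
})

test_that("observed times match the closed-form exponential mixture", {
  # gamma = 0: min(T, C) ~ Exp(b + c); Kolmogorov-Smirnov at n = 10000
  cfg <- sim_config(n_genes = 10, n_samples = 10000, hazard_effect = 0,
                    baseline_hazard = 0.1, censoring_rate = 0.05,
                    ontology_depth = 3, terms_per_level = 4,
                    n_signatures = 1, signature_size = 3,
                    signature_enrichment = 0, seed = 29)
  ds <- generate_dataset(cfg)
  ks <- suppressWarnings(stats::ks.test(ds$survival$time, "pexp",
                                        rate = 0.15))
  expect_gt(ks$p.value, 0.001)
})

test_that("zero-loading cohorts carry no outcome signal", {
  # beta = 0 with gamma > 0: expression independent of survival, so the
  # hit rate tracks alpha; sets are spread over independent cohorts
  # because p-values within one cohort are correlated
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_genes = 200, n_samples = 80, loading = 0,
                      weak_loading = 0, hazard_effect = 1,
                      ontology_depth = 4, terms_per_level = 10,
                      n_signatures = 2, signature_size = 10, seed = 31 + s)
    ds <- generate_dataset(cfg)
    r <- suppressMessages(grp1(ds$expression, ds$survival,
                               ds$signatures[[1L]], repeats = 20,
                               alpha = 0.05, correction = "none",
                               seed = 131 + s))
    hits <- hits + r$table$n_significant
  }
  tol <- 4 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(hits / 200 - 0.05), tol)
})

test_that("null generation forces a zero hazard effect", {
  cfg <- sim_config(n_genes = 50, n_samples = 20, ontology_depth = 3,
                    terms_per_level = 4, n_signatures = 1,
                    signature_size = 5, seed = 37)
  ds <- generate_null_dataset(cfg)
  expect_equal(ds$truth$config$hazard_effect, 0)
})

test_that("a dataset writes to disk and reads back equal", {
  ds <- generate_dataset(sim_config(n_genes = 60, n_samples = 12,
                                    ontology_depth = 3, terms_per_level = 5,
                                    n_signatures = 2, signature_size = 5,
                                    seed = 61))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_identical(read_expression(file.path(dir, "expression.tsv")),
                   ds$expression)
  expect_identical(read_survival(file.path(dir, "survival.tsv"))$time,
                   ds$survival$time)
  sigs <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_identical(lapply(sigs, `[[`, "genes"),
                   lapply(ds$signatures, `[[`, "genes"))
  dag <- read_obo_subset(file.path(dir, "ontology.obo"))
  expect_setequal(dag$terms, ds$ontology$terms)
  ann <- read_annotations(file.path(dir, "annotations.tsv"), dag = dag)
  expect_identical(lapply(ann$gene_to_terms, sort),
                   lapply(ds$annotation$gene_to_terms[
                     names(ann$gene_to_terms)], sort))
})
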