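test_that("the OBO subset reader builds a validated DAG", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: R", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: A", "name: a",
               "namespace: biological_process", "is_a: R ! root", "",
               "[Term]", "id: B", "name: b",
               "namespace: biological_process", "is_a: A"), f)
  dag <- read_obo_subset(f)
  expect_identical(sort(dag$terms), c("A", "B", "R"))
  expect_identical(dag$roots, "R")
  expect_identical(dag$namespace[["A"]], "BP")

  # obsolete stanzas are skipped with a count
  writeLines(c("[Term]", "id: R", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: OLD", "is_obsolete: true"), f)
  expect_message(dag2 <- read_obo_subset(f), "1 obsolete")
  expect_identical(dag2$terms, "R")

  # a self-loop is reported as a cycle, a dangling parent as unknown
  writeLines(c("[Term]", "id: A", "namespace: biological_process",
               "is_a: A"), f)
  expect_error(read_obo_subset(f), "cycle")
  writeLines(c("[Term]", "id: A", "namespace: biological_process",
               "is_a: MISSING"), f)
  expect_error(read_obo_subset(f), "unknown term")
})

test_that("edges may not cross namespaces", {
  expect_error(
    ontology_dag(c("R", "M"), c(R = "r", M = "m"),
                 c(R = "BP", M = "MF"),
                 list(R = character(0), M = "R")),
    "namespace")
})

test_that("hierarchy levels follow the longest path to the root", {
  dag <- chain_dag()
  expect_identical(compute_term_levels(dag),
                   c(R = 1L, a = 2L, b = 3L))
  # diamond: R->x->z and R->y, y->x; paths to z of length 2 and 3
  dia <- ontology_dag(c("R", "x", "y", "z"),
                      c(R = "r", x = "x", y = "y", z = "z"),
                      stats::setNames(rep("BP", 4), c("R", "x", "y", "z")),
                      list(R = character(0), x = c("R", "y"), y = "R",
                           z = "x"))
  lv <- compute_term_levels(dia)
  expect_identical(lv[["z"]], 4L)
  expect_identical(lv[["x"]], 3L)
  expect_identical(compute_term_levels(dia, "shortest")[["z"]], 3L)
})

test_that("levels equal exhaustive path enumeration on random DAGs", {
  for (seed in 1:6) {
    n <- sample(5:50, 1L)
    dag <- random_dag(n, seed = seed)
    lv <- compute_term_levels(dag)
    oracle <- vapply(dag$terms, function(t) oracle_term_level(dag, t), 0)
    expect_equal(unname(lv), unname(oracle))
    # child strictly deeper than parent along every edge
    for (t in dag$terms)
      for (p in dag$parents[[t]])
        expect_gt(lv[[t]], lv[[p]])
  }
})

test_that("annotation maps are mutual inverses and validated", {
  u <- tiny_universe()
  ann <- u$ann
  for (g in names(ann$gene_to_terms))
    for (t in ann$gene_to_terms[[g]])
      expect_true(g %in% ann$term_to_genes[[t]])
  for (t in names(ann$term_to_genes))
    for (g in ann$term_to_genes[[t]])
      expect_true(t %in% ann$gene_to_terms[[g]])
  expect_error(annotation_map(list(g1 = "NOPE"), dag = u$dag), "absent")
  # two-column TSV reader collapses duplicates
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tT2", "g1\tT2", "g2\tT3"), f)
  ann2 <- read_annotations(f, dag = u$dag)
  expect_identical(ann2$gene_to_terms$g1, "T2")
})

test_that("gene-to-leveled-term mapping is a union and additive", {
  u <- tiny_universe()
  pairs <- genes_to_leveled_terms(c("g1", "g2"), u$ann, u$levels)
  expect_setequal(pairs$term, c("T2", "T3"))
  expect_identical(pairs$level[match(c("T2", "T3"), pairs$term)],
                   c(3L, 3L))
  # additivity: equals union of singleton calls
  single <- rbind(genes_to_leveled_terms("g1", u$ann, u$levels),
                  genes_to_leveled_terms("g2", u$ann, u$levels))
  expect_setequal(pairs$term, unique(single$term))
  # unannotated genes contribute nothing
  expect_identical(nrow(genes_to_leveled_terms(c("g7", "g8"), u$ann,
                                               u$levels)), 0L)
})

test_that("terms_to_genes unions annotations and rejects unknown terms", {
  u <- tiny_universe()
  expect_setequal(terms_to_genes(c("T2", "T3"), u$ann), c("g1", "g2", "g3"))
  expect_identical(terms_to_genes(character(0), u$ann), character(0))
  expect_error(terms_to_genes("GHOST", u$ann), "unknown")
  # a DAG term with no annotations contributes no genes but is legal
  expect_identical(terms_to_genes("R", u$ann, dag = u$dag), character(0))
  # containment: an annotated gene is recovered through its own terms
  for (g in names(u$ann$gene_to_terms))
    expect_true(g %in% terms_to_genes(u$ann$gene_to_terms[[g]], u$ann))
})

test_that("biological meaning is the term union and is monotone", {
  u <- tiny_universe()
  expect_identical(meaning_of(character(0), u$ann), character(0))
  expect_setequal(meaning_of(c("g1", "g4"), u$ann), c("T2", "T1"))
  a <- meaning_of("g2", u$ann)
  b <- meaning_of(c("g2", "g3", "g4"), u$ann)
  expect_true(all(a %in% b))
})

test_that("the OBO writer round-trips through the reader", {
  u <- tiny_universe()
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(u$dag, f)
  back <- read_obo_subset(f)
  expect_setequal(back$terms, u$dag$terms)
  expect_identical(compute_term_levels(back)[u$dag$terms],
                   compute_term_levels(u$dag)[u$dag$terms])
})
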