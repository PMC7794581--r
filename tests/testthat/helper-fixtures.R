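# Small in-code fixtures shared across test files.

make_expr <- function(m = 6, n = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(paste0("g", seq_len(m)), paste0("s", seq_len(n))))
}

make_surv <- function(n = 8, seed = 1, p_event = 0.7) {
  set.seed(seed)
  data.frame(sample = paste0("s", seq_len(n)),
             time = rexp(n, 0.2),
             event = rbinom(n, 1, p_event),
             stringsAsFactors = FALSE)
}

# Chain ontology R -> a -> b with configurable extra terms.
chain_dag <- function() {
  ontology_dag(c("R", "a", "b"),
               c(R = "root", a = "mid", b = "leaf"),
               c(R = "BP", a = "BP", b = "BP"),
               list(R = character(0), a = "R", b = "a"))
}

# A tiny annotated universe: 8 genes, 4 BP terms in a chain of depth 3.
tiny_universe <- function() {
  dag <- ontology_dag(
    c("R", "T1", "T2", "T3"),
    c(R = "root", T1 = "t1", T2 = "t2", T3 = "t3"),
    c(R = "BP", T1 = "BP", T2 = "BP", T3 = "BP"),
    list(R = character(0), T1 = "R", T2 = "T1", T3 = "T1"))
  ann <- annotation_map(list(g1 = "T2", g2 = c("T2", "T3"), g3 = "T3",
                             g4 = "T1"), dag = dag)
  list(dag = dag, ann = ann, levels = compute_term_levels(dag),
       G = paste0("g", 1:8))
}

# Signature object bypassing the >= 2 genes constructor check, for toy
# traces with a single-gene set.
raw_signature <- function(name, genes) {
  structure(list(name = name, genes = genes, description = ""),
            class = "signature")
}
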