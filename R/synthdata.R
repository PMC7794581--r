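#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the resampling
#' analysis assumes in a real breast-cancer cohort, at desk scale: a
#' single latent prognostic factor (think proliferation) loading on a
#' sizeable fraction of genes, right-censored survival whose hazard
#' depends on that factor, a layered ontology DAG, annotations that
#' cluster the outcome-linked genes into dedicated "proliferation-like"
#' terms, and signatures enriched for those genes.
#'
#' Defaults mirror the shape of the cohorts the method targets while
#' staying desk-sized: 300 samples (a ~295-sample cohort), 2000 genes (a
#' scaled-down 13k-gene array), signatures of 100 genes (the order of
#' magnitude of the average published signature) in a 48-signature
#' collection, and a prognostic-gene share of 10% defining the
#' proliferation stand-in list.
#'
#' @param n_genes,n_samples Universe and cohort sizes.
#' @param prognostic_fraction Fraction of genes loading on the latent
#'   factor (these genes define the proliferation stand-in `pg`).
#' @param loading Loading strength of prognostic genes on the factor
#'   (expression units per factor SD).
#' @param hazard_effect Log-hazard increase per factor SD; 0 gives a null
#'   cohort with no expression-survival link.
#' @param baseline_hazard,censoring_rate Exponential event and independent
#'   exponential censoring rates (per study time unit); a zero
#'   `censoring_rate` disables censoring.
#' @param noise_sd Gene-level Gaussian noise SD.
#' @param weak_fraction Fraction of the *non*-prognostic genes carrying a
#'   residual weak loading — annotated away from the proliferation-like
#'   terms, these genes keep the falsification pool weakly prognostic.
#' @param weak_loading Loading strength of those weak genes.
#' @param ontology_depth Number of DAG layers (root = level 1).
#' @param terms_per_level Terms per layer below the root.
#' @param annotations_per_gene Terms annotated to each non-prognostic
#'   gene.
#' @param unannotated_fraction Fraction of non-prognostic genes left
#'   without any annotation.
#' @param n_signatures,signature_size Collection size and genes per
#'   signature.
#' @param signature_enrichment Probability mass of a signature devoted to
#'   prognostic genes.
#' @param seed Integer seed; every draw flows from it.
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 300L,
                       prognostic_fraction = 0.1, loading = 1,
                       hazard_effect = 1, baseline_hazard = 0.1,
                       censoring_rate = 0.05, noise_sd = 1,
                       weak_fraction = 0.3, weak_loading = 0.2,
                       ontology_depth = 8L, terms_per_level = 60L,
                       annotations_per_gene = 3L,
                       unannotated_fraction = 0.05,
                       n_signatures = 48L, signature_size = 100L,
                       signature_enrichment = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              prognostic_fraction = prognostic_fraction,
              loading = loading, hazard_effect = hazard_effect,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate, noise_sd = noise_sd,
              weak_fraction = weak_fraction, weak_loading = weak_loading,
              ontology_depth = as.integer(ontology_depth),
              terms_per_level = as.integer(terms_per_level),
              annotations_per_gene = as.integer(annotations_per_gene),
              unannotated_fraction = unannotated_fraction,
              n_signatures = as.integer(n_signatures),
              signature_size = as.integer(signature_size),
              signature_enrichment = signature_enrichment,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 10L, n_samples >= 4L, ontology_depth >= 2L,
              terms_per_level >= 2L, annotations_per_gene >= 1L,
              n_signatures >= 1L, signature_size >= 2L,
              baseline_hazard > 0, censoring_rate >= 0, noise_sd > 0)
    for (f in c(prognostic_fraction, weak_fraction, unannotated_fraction,
                signature_enrichment))
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  })
  n_prog <- round(cfg$prognostic_fraction * cfg$n_genes)
  n_enr <- round(cfg$signature_enrichment * cfg$signature_size)
  if (n_enr > n_prog)
    stop("infeasible config: signatures need ", n_enr,
         " prognostic genes but only ", n_prog, " exist")
  if (cfg$signature_size - n_enr > cfg$n_genes - n_prog)
    stop("infeasible config: not enough non-prognostic genes for a signature")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic cohort, ontology and signature collection
#'
#' See [sim_config()] for the generative model. All randomness flows from
#' the config's seed, so an identical config reproduces the dataset
#' bit-identically.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `"synthetic_dataset"`: list with `expression`
#'   (genes x samples matrix), `survival` (data frame), `ontology`
#'   ([ontology_dag()]), `annotation` ([annotation_map()]), `signatures`
#'   (`"signature_collection"`), `pg` (the proliferation stand-in gene
#'   list: every gene annotated to a proliferation-like term), and `truth`
#'   (latent factor, gene roles, proliferation terms, the config).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  samples <- sprintf("s%04d", seq_len(cfg$n_samples))

  ## gene roles
  n_prog <- round(cfg$prognostic_fraction * cfg$n_genes)
  perm <- sample(genes)
  prog <- perm[seq_len(n_prog)]
  rest <- perm[-seq_len(n_prog)]
  n_weak <- round(cfg$weak_fraction * length(rest))
  weak <- rest[seq_len(n_weak)]
  null_genes <- rest[-seq_len(n_weak)]
  roles <- stats::setNames(rep("null", cfg$n_genes), genes)
  roles[prog] <- "prognostic"
  roles[weak] <- "weak"

  ## expression: latent factor + noise
  u <- stats::rnorm(cfg$n_samples)
  expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples,
                              sd = cfg$noise_sd),
                 cfg$n_genes, cfg$n_samples,
                 dimnames = list(genes, samples))
  if (n_prog > 0L)
    expr[prog, ] <- expr[prog, ] +
      cfg$loading * matrix(u, n_prog, cfg$n_samples, byrow = TRUE)
  if (n_weak > 0L)
    expr[weak, ] <- expr[weak, ] +
      cfg$weak_loading * matrix(u, n_weak, cfg$n_samples, byrow = TRUE)

  ## survival: exponential event times, independent exponential censoring
  rate <- cfg$baseline_hazard * exp(cfg$hazard_effect * u)
  t_event <- stats::rexp(cfg$n_samples, rate)
  t_cens <- if (cfg$censoring_rate > 0)
    stats::rexp(cfg$n_samples, cfg$censoring_rate) else rep(Inf, cfg$n_samples)
  surv <- data.frame(sample = samples,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)

  ## layered ontology DAG (BP), levels equal layer depth by construction
  term_id <- local({
    counter <- 0L
    function(n) {
      ids <- sprintf("GO:S%07d", counter + seq_len(n))
      counter <<- counter + n
      ids
    }
  })
  root <- term_id(1L)
  layers <- list(root)
  parents <- stats::setNames(list(character(0L)), root)
  for (d in 2:cfg$ontology_depth) {
    ids <- term_id(cfg$terms_per_level)
    for (t in ids)
      parents[[t]] <- sample(layers[[d - 1L]], 1L)
    layers[[d]] <- ids
  }
  terms <- unlist(layers, use.names = FALSE)
  dag <- ontology_dag(terms,
                      name = stats::setNames(paste("synthetic process",
                                                   seq_along(terms)), terms),
                      namespace = stats::setNames(rep("BP", length(terms)),
                                                  terms),
                      parents = parents)

  ## annotations: prognostic genes cluster into proliferation-like terms
  ## on the deepest layer; everything else annotates elsewhere
  deepest <- layers[[cfg$ontology_depth]]
  n_prolif <- min(length(deepest), max(2L, cfg$terms_per_level %/% 8L))
  prolif_terms <- deepest[seq_len(n_prolif)]
  other_terms <- setdiff(terms, c(root, prolif_terms))
  g2t <- vector("list", cfg$n_genes)
  names(g2t) <- genes
  for (g in prog)
    g2t[[g]] <- sample(prolif_terms, min(2L, n_prolif))
  annotate <- setdiff(genes, prog)
  n_unann <- round(cfg$unannotated_fraction * length(annotate))
  if (n_unann > 0L)
    annotate <- setdiff(annotate, sample(annotate, n_unann))
  for (g in annotate)
    g2t[[g]] <- sample(other_terms,
                       min(cfg$annotations_per_gene, length(other_terms)))
  ann <- annotation_map(g2t[lengths(g2t) > 0L], dag = dag)

  ## signatures enriched for prognostic genes
  n_enr <- round(cfg$signature_enrichment * cfg$signature_size)
  sigs <- lapply(seq_len(cfg$n_signatures), function(i) {
    picked <- c(if (n_enr > 0L) sample(prog, n_enr),
                sample(rest, cfg$signature_size - n_enr))
    signature_set(sprintf("sig%02d", i), picked,
                  description = "synthetic signature")
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  class(sigs) <- "signature_collection"

  structure(list(expression = expr, survival = surv, ontology = dag,
                 annotation = ann, signatures = sigs,
                 pg = terms_to_genes(prolif_terms, ann),
                 truth = list(u = stats::setNames(u, samples),
                              roles = roles, prolif_terms = prolif_terms,
                              config = cfg)),
            class = "synthetic_dataset")
}

#' Generate a null cohort (no expression-survival association)
#'
#' Identical to [generate_dataset()] with the hazard effect forced to
#' zero: survival is independent of the latent factor and hence of every
#' gene, making the cohort a calibration fixture for the resampling null.
#'
#' @param cfg A [sim_config()].
#' @return A `"synthetic_dataset"`.
#' @export
generate_null_dataset <- function(cfg = sim_config()) {
  cfg$hazard_effect <- 0
  class(cfg) <- "sim_config"
  generate_dataset(cfg)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic cohort: ", cfg$n_genes, " genes x ", cfg$n_samples,
      " samples, ", sum(x$survival$event), " events\n", sep = "")
  cat("  roles: ", sum(x$truth$roles == "prognostic"), " prognostic, ",
      sum(x$truth$roles == "weak"), " weak, ",
      sum(x$truth$roles == "null"), " null\n", sep = "")
  cat("  ontology: ", length(x$ontology$terms), " BP terms, depth ",
      cfg$ontology_depth, "; pg list: ", length(x$pg), " genes\n", sep = "")
  cat("  signatures: ", length(x$signatures), " of size ",
      cfg$signature_size, " (enrichment ", cfg$signature_enrichment,
      ")\n", sep = "")
  invisible(x)
}

#' Write every component of a synthetic dataset to a directory
#'
#' Files use the package's external formats: `expression.tsv`,
#' `survival.tsv`, `signatures.gmt`, `ontology.obo`, `annotations.tsv`,
#' `pg.txt` (one gene per line) and `truth.json`.
#'
#' @param ds A `"synthetic_dataset"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(ds$expression, file.path(dir, "expression.tsv"))
  write_survival(ds$survival, file.path(dir, "survival.tsv"))
  write_gmt(ds$signatures, file.path(dir, "signatures.gmt"))
  write_obo(ds$ontology, file.path(dir, "ontology.obo"))
  write_annotations(ds$annotation, file.path(dir, "annotations.tsv"))
  writeLines(ds$pg, file.path(dir, "pg.txt"))
  jsonlite::write_json(list(roles = as.list(ds$truth$roles),
                            u = as.list(ds$truth$u),
                            prolif_terms = ds$truth$prolif_terms,
                            config = unclass(ds$truth$config)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
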