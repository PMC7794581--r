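# Independent oracles: deliberately brute-force, sharing no code with the
# package's computation paths.

# Longest-path term level by explicit enumeration of every directed path
# from the term to a root (level = 1 + max path edge count).
oracle_term_level <- function(dag, term) {
  enumerate <- function(t) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) return(list(t))
    out <- list()
    for (p in ps)
      for (path in enumerate(p))
        out <- c(out, list(c(t, path)))
    out
  }
  max(lengths(enumerate(term)))
}

# Two-sample log-rank by the explicit O/E/V table over distinct event times.
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[[1L]]
  event_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tj in event_times) {
    at_risk <- time >= tj
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tj & event == 1)
    d1 <- sum(time == tj & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(statistic = chisq,
       p.value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Product-limit estimator computed step by step.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Exact permutation p-value of Spearman's rho (two-sided), all n! shuffles.
oracle_spearman_perm <- function(a, b) {
  rho <- function(x, y) cor(rank(x), rank(y))
  obs <- rho(a, b)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out <- c(out, list(c(v[i], rest)))
    out
  }
  all_rho <- vapply(perms(b), function(p) rho(a, p), 0)
  list(rho = obs, p.value = mean(abs(all_rho) >= abs(obs) - 1e-12))
}

# Random small survival fixture (with tied times and censoring patterns).
random_surv_fixture <- function(n, seed) {
  set.seed(seed)
  data.frame(sample = paste0("s", seq_len(n)),
             time = sample(1:5, n, replace = TRUE) + 0.5 *
               rbinom(n, 1, 0.5),
             event = rbinom(n, 1, 0.7),
             stringsAsFactors = FALSE)
}

# Random DAG on <= n terms: term i may take parents among earlier terms,
# term 1 is the root, so the graph is acyclic by construction.
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("T", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- ids
  parents[[1L]] <- character(0L)
  for (i in 2:n)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)],
                                min(i - 1L, sample(1:2, 1L)))
  ontology_dag(ids, stats::setNames(ids, ids),
               stats::setNames(rep("BP", n), ids), parents)
}
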