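# Shared fixtures and independent brute-force oracles.  Oracles never
# call the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_run <- function(run_id, spc, cohort = "Wt", subject = "S1",
                     kind = "technical") {
  run_list(run_id = run_id, subject_id = subject, cohort = cohort,
           replicate_kind = kind,
           entries = data.frame(accession = names(spc),
                                spc = unname(spc),
                                stringsAsFactors = FALSE))
}

# deterministic toy matrix: 3 cohorts x 2 runs each
toy_matrix <- function() {
  counts <- matrix(
    c(10L, 12L, 5L, 6L, 1L, 0L,
      11L, 13L, 5L, 5L, 0L, 1L,
      2L,  2L, 20L, 22L, 3L, 2L,
      3L,  1L, 21L, 19L, 2L, 3L),
    nrow = 4L, byrow = TRUE,
    dimnames = list(paste0("P", 1:4),
                    c("wt1", "wt2", "he1", "he2", "ho1", "ho2")))
  spc_matrix(counts[, c(1, 2, 3, 4, 5, 6)], data.frame(
    run_id = c("wt1", "wt2", "he1", "he2", "ho1", "ho2"),
    subject_id = c("W", "W", "H", "H", "O", "O"),
    cohort = c("Wt", "Wt", "He", "He", "Ho", "Ho"),
    replicate_kind = "technical", stringsAsFactors = FALSE))
}

small_sim <- function(seed = 1L, n = 300L, ...) {
  simulate_dataset(sim_config(n_proteins = n, seed = seed, ...))
}

# --- oracles ---------------------------------------------------------

# DEP flag by literal re-derivation of both indexes from first principles
oracle_dep_flag <- function(x, y, dave_thr = 0.4, dci_thr = 15) {
  da <- if (x + y == 0) 0 else (x - y) / (x + y) / 0.5
  dc <- (x + y) * (x - y) / 2
  if (da >= dave_thr && dc >= dci_thr) "up_in_x"
  else if (da <= -dave_thr && dc <= -dci_thr) "up_in_y"
  else "unchanged"
}

# one-way ANOVA through R's linear-model machinery
oracle_f_ratio <- function(values_by_group) {
  y <- unlist(values_by_group)
  g <- factor(rep(seq_along(values_by_group), lengths(values_by_group)))
  av <- stats::anova(stats::lm(y ~ g))
  c(f = av[["F value"]][1L], p = av[["Pr(>F)"]][1L])
}

# hypergeometric upper tail by exhaustive enumeration of query draws
oracle_hyper_tail <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1L))) / choose(N, n)
}

# induced subgraph by brute-force filtering of the edge list
oracle_subgraph_edges <- function(edges, query) {
  keep <- edges[, 1L] %in% query & edges[, 2L] %in% query
  e <- edges[keep, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  sort(apply(e, 1L, function(r) paste(sort(r), collapse = "|")))
}

edge_key <- function(g) {
  e <- igraph::as_edgelist(g)
  if (!nrow(e)) return(character(0))
  sort(apply(e, 1L, function(r) paste(sort(r), collapse = "|")))
}
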