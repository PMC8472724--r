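## Protein-protein interaction layer: ingest an interactome edge list as
## a simple undirected graph, project protein sets onto it, attach
## cohort-state attributes for visualization, and test functional-term
## over-representation with the hypergeometric distribution and
## Benjamini-Hochberg correction.

#' Load an interactome edge list as a simple undirected graph
#'
#' Accepts a 2-column TSV (`a<TAB>b`) or SIF (`a<TAB>relation<TAB>b`)
#' file.  Node names are upper-cased gene symbols; self-interactions and
#' duplicate edges are removed (counts reported via a message) since
#' they distort topological statistics.
#'
#' @param path edge-list file; lines starting with `#` are skipped.
#' @return an undirected simple `igraph` graph.
#' @export
load_network <- function(path) {
  if (!file.exists(path))
    stop("parse error: file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad))
    stop("parse error: line ", lineno[bad[1L]],
         ": expected 2 (edge list) or 3 (SIF) tab-separated fields",
         call. = FALSE)
  ends <- t(vapply(parts, function(p)
    toupper(trimws(p[c(1L, length(p))])), character(2L)))
  if (any(!nzchar(ends)))
    stop("parse error: empty node name", call. = FALSE)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- igraph::ecount(g) - n_loops - igraph::ecount(gs)
  if (n_loops || n_dup)
    message("removed ", n_loops, " self-interaction(s) and ", n_dup,
            " duplicate edge(s)")
  gs
}

#' Induced subnetwork of a query protein set
#'
#' @param net an undirected `igraph` graph.
#' @param query character vector of gene symbols (matched upper-case).
#' @param drop_isolated drop query nodes with no internal edge
#'   (default `FALSE`).
#' @return list: `graph` (the induced subgraph), `n_nodes`, `n_edges`,
#'   `n_query_unmatched` (query genes absent from the network).
#' @export
induced_subnetwork <- function(net, query, drop_isolated = FALSE) {
  query <- unique(toupper(query))
  present <- intersect(query, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, present)
  if (drop_isolated)
    sub <- igraph::delete_vertices(sub, igraph::V(sub)[
      igraph::degree(sub) == 0])
  list(graph = sub, n_nodes = igraph::vcount(sub),
       n_edges = igraph::ecount(sub),
       n_query_unmatched = length(query) - length(present))
}

#' Attach cohort-state attributes to subnetwork nodes
#'
#' For every node: the (normalized) aSpC in each cohort profile and a
#' state from the pairwise comparisons covering that protein
#' (`up_in_<cohort>` from the first comparison that flags it, else
#' `unchanged`); nodes absent from all profiles are marked `missing`.
#'
#' @param subnet result of [induced_subnetwork] (or an `igraph`).
#' @param profiles list of `cohort_profile`s.
#' @param reports optional list of `comparison_report`s for the state
#'   flags.
#' @return data.frame with one row per node: `node`, one `aspc_<cohort>`
#'   column per profile, `state`.
#' @export
color_by_state <- function(subnet, profiles, reports = list()) {
  g <- if (inherits(subnet, "igraph")) subnet else subnet$graph
  stopifnot(length(profiles) >= 1L)
  nodes <- igraph::V(g)$name
  out <- data.frame(node = nodes, stringsAsFactors = FALSE)
  seen <- rep(FALSE, length(nodes))
  for (p in profiles) {
    v <- unname(p$aspc[nodes])
    seen <- seen | !is.na(v)
    out[[paste0("aspc_", p$cohort)]] <- v
  }
  state <- rep("unchanged", length(nodes))
  for (rep_ in reports) {
    r <- rep_$records
    ix <- match(nodes, r$protein)
    fl <- r$flag[ix]
    up_x <- !is.na(fl) & fl == "up_in_x" & state == "unchanged"
    up_y <- !is.na(fl) & fl == "up_in_y" & state == "unchanged"
    state[up_x] <- paste0("up_in_", rep_$pair[1L])
    state[up_y] <- paste0("up_in_", rep_$pair[2L])
  }
  state[!seen] <- "missing"
  out$state <- state
  out
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For a term with `K` annotated genes in a universe of size `N` and a
#' query of size `n` containing `k` of them, the p-value is the
#' upper-tail probability `P(X >= k)` of the hypergeometric
#' distribution.  Terms with BH-adjusted q-value at or below `alpha` are
#' flagged significant.  Universe genes without any term simply stay in
#' `N`.
#'
#' @param query character vector, a subset of `universe`.
#' @param universe character vector of all candidate genes (e.g. every
#'   identified protein).
#' @param terms data.frame mapping `gene` to `term` (one row per pair).
#' @param alpha significance level on q-values (default 0.001).
#' @return data.frame sorted by p-value: `term`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `significant`.
#' @export
hypergeom_enrich <- function(query, universe, terms, alpha = 0.001) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("validation error: query must be a subset of the universe",
         call. = FALSE)
  tm <- terms[terms$gene %in% universe, , drop = FALSE]
  tm <- unique(tm[, c("gene", "term")])
  if (!nrow(tm))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  n <- length(query)
  N <- length(universe)
  k_tab <- table(factor(tm$term[tm$gene %in% query],
                        levels = unique(tm$term)))
  big_k <- table(factor(tm$term, levels = unique(tm$term)))
  k <- as.integer(k_tab)
  K <- as.integer(big_k)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(big_k), k = k, K = K, n = n, N = N,
                    p_value = p, q_value = q, significant = q <= alpha,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$term), , drop = FALSE]
}
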