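## Discriminant-protein selection and run-level structure discovery.
##
## The selection screen is a per-protein one-way F statistic across the
## cohorts (model mean square over error mean square); proteins passing
## F > 3.4 and p < 0.05 are the discriminant set.  Group assignment then
## uses the Mahalanobis distance to each cohort centroid under a single
## pooled covariance, and run relationships are summarized by
## agglomerative hierarchical clustering (Euclidean distance, Ward
## linkage) with an AGNES-style agglomerative coefficient.

#' One-way F ratio and p-value for a single protein
#'
#' @param values_by_group list of numeric vectors, one per cohort (>= 2
#'   groups, every group non-empty, total n > number of groups).
#' @return named numeric `c(f_ratio, p_value)`.  Zero error mean square
#'   with unequal group means yields `f_ratio = Inf`, `p_value = 0`; an
#'   entirely constant protein yields `f_ratio = 0`, `p_value = 1`.
#' @export
protein_f_ratio <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  n_i <- lengths(values_by_group)
  if (any(n_i == 0L))
    stop("validation error: empty group", call. = FALSE)
  g <- length(values_by_group)
  n <- sum(n_i)
  if (n <= g)
    stop("validation error: need total n > number of groups", call. = FALSE)
  m_i <- vapply(values_by_group, mean, numeric(1L))
  gm <- sum(n_i * m_i) / n
  ms_between <- sum(n_i * (m_i - gm)^2) / (g - 1)
  ss_within <- sum(vapply(values_by_group,
                          function(v) sum((v - mean(v))^2), numeric(1L)))
  ms_within <- ss_within / (n - g)
  if (ms_within == 0) {
    if (ms_between > 0) return(c(f_ratio = Inf, p_value = 0))
    return(c(f_ratio = 0, p_value = 1))
  }
  f <- ms_between / ms_within
  c(f_ratio = f,
    p_value = stats::pf(f, g - 1, n - g, lower.tail = FALSE))
}

f_ratio_matrix <- function(counts, groups) {
  ## vectorized one-way ANOVA over all rows; groups: list of column indices
  g <- length(groups)
  n_i <- lengths(groups)
  n <- sum(n_i)
  m_i <- vapply(groups, function(ix) rowMeans(counts[, ix, drop = FALSE]),
                numeric(nrow(counts)))
  if (nrow(counts) == 1L) m_i <- matrix(m_i, nrow = 1L)
  gm <- as.vector(m_i %*% n_i) / n
  ss_between <- rowSums(sweep(m_i, 2L, n_i, `*`) * m_i) -
    n * gm^2
  ss_within <- numeric(nrow(counts))
  for (k in seq_len(g)) {
    d <- counts[, groups[[k]], drop = FALSE] - m_i[, k]
    ss_within <- ss_within + rowSums(d * d)
  }
  ss_between <- pmax(ss_between, 0)   # guard tiny negative rounding
  ms_b <- ss_between / (g - 1)
  ms_w <- ss_within / (n - g)
  f <- ifelse(ms_w > 0, ms_b / ms_w, ifelse(ms_b > 0, Inf, 0))
  p <- ifelse(is.finite(f),
              stats::pf(f, g - 1, n - g, lower.tail = FALSE),
              0)
  p[ms_w == 0 & ms_b == 0] <- 1
  list(f_ratio = f, p_value = p)
}

#' Select discriminant proteins by the F-ratio / p-value screen
#'
#' Counts are depth-normalized first ([normalize_runs], `"total"`),
#' and accessions deriving from the same gene are collapsed when an
#' annotation is supplied.  Selection requires `f_ratio > f_thr` and
#' `p_value < p_thr` (both strict).
#'
#' @param mat an [spc_matrix].
#' @param f_thr F-ratio threshold (default 3.4).
#' @param p_thr p-value threshold (default 0.05; set 0.01 for the
#'   stricter preset).
#' @param collapse_by_gene collapse shared-gene rows before testing
#'   (default `TRUE`; requires `ann`).
#' @param ann annotation data.frame for the gene collapse (optional).
#' @param normalize depth-normalize before testing (default `TRUE`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `lda_records`: `protein`, `f_ratio`,
#'   `p_value`, `selected`.
#' @export
select_lda_sps <- function(mat, f_thr = 3.4, p_thr = 0.05,
                           collapse_by_gene = TRUE, ann = NULL,
                           normalize = TRUE, p_adjust = c("none", "BH")) {
  stopifnot(inherits(mat, "spc_matrix"))
  p_adjust <- match.arg(p_adjust)
  cohorts <- unique(mat$runs$cohort)
  for (co in cohorts)
    if (sum(mat$runs$cohort == co) < 2L)
      stop("validation error: cohort '", co, "' has < 2 runs", call. = FALSE)
  if (collapse_by_gene && !is.null(ann))
    mat <- map_accessions(mat, ann, collapse_by_gene = TRUE)
  counts <- if (normalize) normalize_runs(mat)$counts else mat$counts
  groups <- lapply(cohorts, function(co) which(mat$runs$cohort == co))
  res <- f_ratio_matrix(counts, groups)
  p <- if (p_adjust == "BH") stats::p.adjust(res$p_value, "BH")
       else res$p_value
  out <- data.frame(protein = rownames(counts), f_ratio = res$f_ratio,
                    p_value = p,
                    selected = res$f_ratio > f_thr & p < p_thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("lda_records", "data.frame")
  out
}

pooled_covariance <- function(x, groups, mode) {
  ## x: runs in rows, features in columns; groups: list of row indices
  n <- nrow(x)
  g <- length(groups)
  centered <- x
  for (ix in groups)
    centered[ix, ] <- sweep(x[ix, , drop = FALSE], 2L,
                            colMeans(x[ix, , drop = FALSE]))
  if (mode == "diagonal_pooled") {
    v <- colSums(centered^2) / (n - g)
    v <- pmax(v, 1e-8 * max(mean(v), .Machine$double.eps))
    return(diag(v, ncol(x)))
  }
  s <- crossprod(centered) / (n - g)
  # ridge toward the average variance keeps the estimate usable when
  # features outnumber runs
  s + diag(0.1 * max(mean(diag(s)), .Machine$double.eps), ncol(x))
}

#' Assign runs to cohorts by Mahalanobis distance
#'
#' Linear discriminant assignment under a common covariance: every run
#' is placed in the cohort whose multivariate mean is closest in
#' Mahalanobis distance.  With far more proteins than runs a full pooled
#' covariance is singular, so the default uses its diagonal (pooled
#' per-protein variances); `"shrunk_pooled"` ridges the full matrix and
#' falls back to the diagonal (with a warning) if it still cannot be
#' inverted.
#'
#' @param mat an [spc_matrix] or normalized matrix ([normalize_runs]).
#' @param proteins identifiers to restrict to (e.g. the selected set
#'   from [select_lda_sps]); `NULL` uses all rows.
#' @param covariance_mode `"diagonal_pooled"` (default) or
#'   `"shrunk_pooled"`.
#' @return data.frame: `run_id`, `cohort` (true), `predicted`,
#'   `correct`, plus one `dist_<cohort>` column per cohort.
#' @export
mahalanobis_assign <- function(mat, proteins = NULL,
                               covariance_mode = c("diagonal_pooled",
                                                   "shrunk_pooled")) {
  covariance_mode <- match.arg(covariance_mode)
  counts <- mat$counts
  if (!is.null(proteins)) {
    if (!length(proteins))
      stop("validation error: need >= 1 selected protein", call. = FALSE)
    counts <- counts[intersect(rownames(counts), proteins), , drop = FALSE]
    if (!nrow(counts))
      stop("validation error: no selected protein present in the matrix",
           call. = FALSE)
  }
  cohorts <- unique(mat$runs$cohort)
  groups <- lapply(cohorts, function(co) which(mat$runs$cohort == co))
  names(groups) <- cohorts
  if (any(lengths(groups) < 2L))
    stop("validation error: every cohort needs >= 2 runs", call. = FALSE)
  x <- t(counts)                      # runs in rows
  s <- pooled_covariance(x, groups, covariance_mode)
  s_inv <- tryCatch(solve(s), error = function(e) {
    warning("singular pooled covariance; falling back to diagonal_pooled")
    solve(pooled_covariance(x, groups, "diagonal_pooled"))
  })
  centers <- t(vapply(groups, function(ix)
    colMeans(x[ix, , drop = FALSE]), numeric(ncol(x))))
  d2 <- vapply(seq_along(cohorts), function(k) {
    d <- sweep(x, 2L, centers[k, ])
    rowSums((d %*% s_inv) * d)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d2 <- matrix(d2, nrow = 1L)
  dist <- sqrt(pmax(d2, 0))
  colnames(dist) <- paste0("dist_", cohorts)
  predicted <- cohorts[apply(dist, 1L, which.min)]
  data.frame(run_id = mat$runs$run_id, cohort = mat$runs$cohort,
             predicted = predicted, correct = predicted == mat$runs$cohort,
             dist, stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering of runs with agglomerative coefficient
#'
#' Runs are sorted lexicographically by run id (deterministic
#' tie-breaks), distances are Euclidean on the supplied values, linkage
#' is Ward (default) or average.  The agglomerative coefficient is the
#' AGNES measure: the mean over leaves of `1 - d_first/d_final`, where
#' `d_first` is the height at which the leaf first merges and `d_final`
#' the height of the last merge; an all-identical input gives 0.
#'
#' @param mat an [spc_matrix] or normalized matrix.
#' @param proteins optional row restriction (e.g. LDA-selected).
#' @param linkage `"ward"` (Ward's minimum-variance on squared
#'   Euclidean distances, `hclust` `"ward.D2"`) or `"average"` (the
#'   classical AGNES default).
#' @return list of class `clustering_result`: `hclust` (the merge
#'   tree), `agglomerative_coefficient`, `labels`.
#' @export
hierarchical_cluster <- function(mat, proteins = NULL,
                                 linkage = c("ward", "average")) {
  linkage <- match.arg(linkage)
  counts <- mat$counts
  if (!is.null(proteins))
    counts <- counts[intersect(rownames(counts), proteins), , drop = FALSE]
  if (ncol(counts) < 2L)
    stop("validation error: need >= 2 runs to cluster", call. = FALSE)
  ord <- order(colnames(counts))
  x <- t(counts[, ord, drop = FALSE])
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = switch(linkage, ward = "ward.D2",
                                      average = "average"))
  structure(list(hclust = hc,
                 agglomerative_coefficient = agnes_coefficient(hc),
                 labels = hc$labels),
            class = "clustering_result")
}

#' AGNES agglomerative coefficient of a merge tree
#' @param hc an `hclust` object.
#' @return coefficient in \[0, 1\]; 0 for a zero-height tree.
#' @export
agnes_coefficient <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  d_final <- max(hc$height)
  if (d_final <= 0) return(0)
  n <- length(hc$order)
  first <- numeric(n)
  for (i in seq_along(hc$height)) {
    leaves <- hc$merge[i, ]
    for (l in leaves[leaves < 0]) first[-l] <- hc$height[i]
  }
  mean(1 - first / d_final)
}

#' Cut a clustering result into k groups
#' @param res a `clustering_result`.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships per run.
#' @export
cluster_cut <- function(res, k) {
  stats::cutree(res$hclust, k = k)
}

#' Export a clustering result dendrogram as a Newick string
#' @param res a `clustering_result`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
cluster_newick <- function(res, path = NULL) {
  phy <- ape::as.phylo(res$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d runs, linkage=%s, AC=%.3f\n",
              length(x$labels), x$hclust$method,
              x$agglomerative_coefficient))
  invisible(x)
}
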