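## Cohort-level profiling: average spectral counts, depth normalization,
## three-way Venn partitioning, virtual 2D MW/pI maps and
## subcellular-location summaries.

#' Average spectral counts of one cohort
#'
#' For every protein, the mean SpC over all runs of the cohort, zeros
#' included (a protein absent from a run contributes 0 to its average).
#'
#' @param mat an [spc_matrix]; numeric (e.g. normalized) values are
#'   accepted via the `counts` element of a compatible list.
#' @param cohort cohort label.
#' @return list of class `cohort_profile`: `cohort`, `aspc` (named
#'   numeric), `n_runs`, `identified` (accessions with aspc > 0).
#' @export
cohort_aspc <- function(mat, cohort) {
  ids <- cohort_runs(mat, cohort)
  sub <- mat$counts[, ids, drop = FALSE]
  aspc <- rowMeans(sub)
  structure(list(cohort = cohort, aspc = aspc, n_runs = length(ids),
                 identified = names(aspc)[aspc > 0]),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> %s: %d runs, %d identified proteins\n",
              x$cohort, x$n_runs, length(x$identified)))
  invisible(x)
}

#' Normalize run depth
#'
#' `"total"` rescales every column so its total equals the mean of the
#' original column totals — global count mass is conserved exactly and
#' equal-depth matrices are a fixed point.  `"nsaf"` computes the
#' normalized spectral abundance factor, SpC/MW divided by the column
#' sum of SpC/MW (requires `mw_kda`); each column then sums to 1.
#'
#' @param mat an [spc_matrix].
#' @param method `"total"` (default) or `"nsaf"`.
#' @param mw_kda named molecular weights covering the matrix proteins
#'   (NSAF only; length normalization uses MW as a proxy for sequence
#'   length).
#' @return list shaped like an `spc_matrix` but with a numeric `counts`
#'   matrix (class `norm_matrix`).
#' @export
normalize_runs <- function(mat, method = c("total", "nsaf"),
                           mw_kda = NULL) {
  stopifnot(inherits(mat, "spc_matrix") || is.list(mat))
  method <- match.arg(method)
  counts <- mat$counts
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("validation error: empty run (zero total count)", call. = FALSE)
  if (method == "total") {
    scaled <- sweep(counts, 2L, mean(totals) / totals, `*`)
  } else {
    if (is.null(mw_kda))
      stop("validation error: NSAF needs mw_kda", call. = FALSE)
    w <- mw_kda[rownames(counts)]
    if (anyNA(w) || any(w <= 0))
      stop("validation error: NSAF needs positive MW for every protein",
           call. = FALSE)
    saf <- counts / w
    scaled <- sweep(saf, 2L, colSums(saf), `/`)
  }
  structure(list(counts = scaled, runs = mat$runs), class = "norm_matrix")
}

#' Cohort membership sets for Venn partitioning
#'
#' `"any_run"`: proteins identified (SpC >= 1) in at least one run of
#' the cohort.  `"average_list"`: proteins whose cohort aSpC rounds to
#' at least one spectrum (aspc >= 0.5), a stricter per-group list.
#'
#' @param mat an [spc_matrix].
#' @param cohort cohort label.
#' @param membership `"any_run"` (default) or `"average_list"`.
#' @return character vector of protein identifiers.
#' @export
cohort_members <- function(mat, cohort,
                           membership = c("any_run", "average_list")) {
  membership <- match.arg(membership)
  ids <- cohort_runs(mat, cohort)
  sub <- mat$counts[, ids, drop = FALSE]
  if (membership == "any_run")
    rownames(sub)[rowSums(sub >= 1) > 0]
  else
    rownames(sub)[rowMeans(sub) >= 0.5]
}

#' Three-way Venn partition of identified proteins
#'
#' @param sets named list of exactly three character vectors (protein
#'   sets per cohort), or three `cohort_profile`s (their `identified`
#'   sets are used).
#' @return list of class `venn_partition`: `regions` (7 named protein
#'   sets, e.g. `"Wt"`, `"Wt&He"`, `"Wt&He&Ho"`) and `sizes`.
#' @export
venn_partition <- function(sets) {
  if (all(vapply(sets, inherits, logical(1L), "cohort_profile"))) {
    names(sets) <- vapply(sets, `[[`, character(1L), "cohort")
    sets <- lapply(sets, `[[`, "identified")
  }
  stopifnot(length(sets) == 3L, !is.null(names(sets)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- list(c(1L), c(2L), c(3L), c(1L, 2L), c(1L, 3L), c(2L, 3L),
                 c(1L, 2L, 3L))
  regions <- lapply(combos, function(ix) {
    inside <- rowSums(member[, ix, drop = FALSE]) == length(ix) &
      rowSums(member[, -ix, drop = FALSE]) == 0
    universe[inside]
  })
  names(regions) <- vapply(combos, function(ix) paste(nm[ix], collapse = "&"),
                           character(1L))
  structure(list(regions = regions,
                 sizes = vapply(regions, length, integer(1L))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (r in names(x$sizes))
    cat(sprintf("  %-12s %d\n", r, x$sizes[[r]]))
  invisible(x)
}

#' Virtual 2D map: MW/pI scatter and extreme-tail counts
#'
#' The electronic analogue of a 2D gel: every protein plotted by
#' theoretical molecular weight and isoelectric point.  Records lacking
#' either value are excluded (and counted in `n_missing`).
#'
#' @param records data.frame with columns `mw_kda` and `pi` (e.g. an
#'   annotation table).
#' @param mw_bounds kDa interval outside which a protein is an MW tail
#'   (default `c(10, 200)`).
#' @param pi_bounds pI interval outside which a protein is a pI tail
#'   (default `c(4, 10)`).
#' @return list: `tails` (named counts `mw_low`, `mw_high`, `pi_low`,
#'   `pi_high`), `table` (the MW/pI scatter), `n_missing`.
#' @export
virtual_2d_map <- function(records, mw_bounds = c(10, 200),
                           pi_bounds = c(4, 10)) {
  stopifnot(all(c("mw_kda", "pi") %in% names(records)))
  ok <- !is.na(records$mw_kda) & !is.na(records$pi)
  if (any(!ok))
    message(sum(!ok), " record(s) without MW/pI excluded from the map")
  r <- records[ok, , drop = FALSE]
  tails <- c(mw_low = sum(r$mw_kda < mw_bounds[1L]),
             mw_high = sum(r$mw_kda > mw_bounds[2L]),
             pi_low = sum(r$pi < pi_bounds[1L]),
             pi_high = sum(r$pi > pi_bounds[2L]))
  list(tails = tails, table = r[, c("accession", "mw_kda", "pi")[
    c("accession", "mw_kda", "pi") %in% names(r)], drop = FALSE],
    n_missing = sum(!ok))
}

#' Subcellular-location composition of a protein set
#'
#' Fractions are computed over the proteins with a known location;
#' `"unknown"` and unannotated proteins are excluded from the
#' denominator.
#'
#' @param proteins character vector of identifiers (matched against the
#'   annotation's accession, or gene when `by = "gene"`).
#' @param ann annotation data.frame with a `location` column.
#' @param by match on `"accession"` (default) or `"gene"`.
#' @return named numeric vector of fractions summing to 1 (empty when no
#'   protein has a known location).
#' @export
location_summary <- function(proteins, ann, by = c("accession", "gene")) {
  by <- match.arg(by)
  loc <- ann$location[match(proteins, ann[[by]])]
  loc <- loc[!is.na(loc) & loc != "unknown"]
  if (!length(loc)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(loc)
  out <- as.numeric(tab) / sum(tab)
  stats::setNames(out, names(tab))
}
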