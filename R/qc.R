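## Identification-quality layer: per-charge Xcorr filtering, target-decoy
## FDR, and the technical/biological replicate repeatability regression.

#' Standard per-charge Xcorr thresholds
#'
#' 1.5 / 2.0 / 2.5 / 3.0 for singly- to quadruply-charged precursor ions,
#' the usual SEQUEST acceptance levels; charges above 4 reuse the
#' charge-4 value.
#' @return named numeric vector for charges 1-4.
#' @export
xcorr_thresholds_default <- function() {
  c(`1` = 1.5, `2` = 2.0, `3` = 2.5, `4` = 3.0)
}

#' Filter PSMs on Xcorr, probability and consensus score
#'
#' Keeps a PSM only when all three clauses hold: Xcorr strictly greater
#' than the threshold for its charge state (charges > 4 use the charge-4
#' threshold), peptide probability at most `max_prob` (smaller is
#' better), and consensus score strictly greater than `min_consensus`.
#' Idempotent; raising any threshold can only remove PSMs.
#'
#' @param psms PSM data.frame (schema of [read_psm_table]).
#' @param xcorr_by_charge named numeric vector of thresholds for charges
#'   1..4 (names `"1"`..`"4"`).
#' @param max_prob probability upper bound (default 1e-3).
#' @param min_consensus consensus-score lower bound (default 10).
#' @return the retained subset of `psms`.
#' @export
filter_psms <- function(psms, xcorr_by_charge = xcorr_thresholds_default(),
                        max_prob = 1e-3, min_consensus = 10) {
  validate_psms(psms)
  if (!all(as.character(1:4) %in% names(xcorr_by_charge)))
    stop("validation error: thresholds required for charges 1-4",
         call. = FALSE)
  thr <- xcorr_by_charge[as.character(pmin(psms$charge, 4L))]
  keep <- psms$xcorr > thr &
    psms$probability <= max_prob &
    psms$consensus_score > min_consensus
  psms[keep, , drop = FALSE]
}

#' Target-decoy false discovery rate
#'
#' The reverse-database estimate: number of decoy PSMs divided by the
#' number of target PSMs.
#'
#' @param psms PSM data.frame with logical `is_decoy`.
#' @return FDR as a fraction (0 when no decoys survive).
#' @export
compute_fdr <- function(psms) {
  n_decoy <- sum(psms$is_decoy)
  n_target <- sum(!psms$is_decoy)
  if (n_target == 0L)
    stop("undefined-FDR error: no target PSMs", call. = FALSE)
  n_decoy / n_target
}

#' Replicate repeatability regression
#'
#' Ordinary least-squares of run B's spectral counts on run A's, over the
#' shared proteins (default) or the union with zeros filled.  A slope
#' near 1 with R-squared >= 0.95 is the quality band expected of
#' technical replicates.
#'
#' @param run_a,run_b [run_list] objects.
#' @param shared_only use only proteins identified in both runs
#'   (default `TRUE`); `FALSE` takes the union, filling absences with 0.
#' @return list of class `repeatability_result` with `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
repeatability <- function(run_a, run_b, shared_only = TRUE) {
  stopifnot(inherits(run_a, "run_list"), inherits(run_b, "run_list"))
  a <- stats::setNames(run_a$entries$spc, run_a$entries$accession)
  b <- stats::setNames(run_b$entries$spc, run_b$entries$accession)
  prots <- if (shared_only) intersect(names(a), names(b))
           else union(names(a), names(b))
  if (length(prots) < 2L)
    stop("validation error: need >= 2 proteins in the comparison set",
         call. = FALSE)
  x <- ifelse(prots %in% names(a), a[prots], 0)
  y <- ifelse(prots %in% names(b), b[prots], 0)
  if (stats::var(x) == 0)
    stop("degenerate-regression error: constant predictor", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1.0 else stats::cor(x, y)^2
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(prots)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> slope=%.3f intercept=%.2f R2=%.4f n=%d\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
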