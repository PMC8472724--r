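## Dual-index label-free differential analysis on average spectral
## counts.  DAve = 2(X - Y)/(X + Y) measures the direction and relative
## size of a change (range [-2, 2]); DCI = (X + Y)(X - Y)/2 weights the
## same difference by total evidence, so low-count proteins cannot pass
## on ratio alone.  A protein is called differential only when both
## indexes clear their thresholds (defaults 0.4 and 15, inclusive).

#' Differential average index
#'
#' `dave(x, y) = (x - y) / (x + y) / 0.5 = 2(x - y)/(x + y)`, with the
#' convention `dave(0, 0) = 0` (absent in both conditions = unchanged).
#' Antisymmetric and scale-invariant; |DAve| = 0.4 corresponds to a
#' 1.5-fold change.
#'
#' @param x,y average spectral counts (non-negative, vectorized).
#' @return numeric in \[-2, 2\].
#' @export
dave <- function(x, y) {
  if (any(x < 0 | y < 0))
    stop("validation error: negative spectral count", call. = FALSE)
  s <- x + y
  ifelse(s == 0, 0, 2 * (x - y) / s)
}

#' Differential confidence index
#'
#' `dci(x, y) = (x + y)(x - y)/2`.  Antisymmetric; multiplying both
#' inputs by c scales DCI by c^2, so confidence grows with total counts.
#'
#' @param x,y average spectral counts (non-negative, vectorized).
#' @return numeric.
#' @export
dci <- function(x, y) {
  if (any(x < 0 | y < 0))
    stop("validation error: negative spectral count", call. = FALSE)
  (x + y) * (x - y) / 2
}

#' Pairwise cohort comparison with dual-threshold DEP calling
#'
#' Computes DAve and DCI per protein on the two profiles' aSpC values
#' (union of the protein universes, zeros filled) and flags `up_in_x`
#' when `dave >= dave_thr & dci >= dci_thr`, `up_in_y` on the mirrored
#' conditions; both tests are inclusive.
#'
#' @param px,py `cohort_profile` objects (condition X and Y).
#' @param dave_thr,dci_thr thresholds (defaults 0.4 and 15).
#' @return list of class `comparison_report`: `pair`, `records`
#'   (data.frame protein/x/y/dave/dci/flag), `dep_up_x`, `dep_up_y`,
#'   `thresholds`.
#' @export
compare_pair <- function(px, py, dave_thr = 0.4, dci_thr = 15) {
  stopifnot(inherits(px, "cohort_profile"), inherits(py, "cohort_profile"))
  prots <- union(names(px$aspc), names(py$aspc))
  x <- ifelse(prots %in% names(px$aspc), px$aspc[prots], 0)
  y <- ifelse(prots %in% names(py$aspc), py$aspc[prots], 0)
  da <- dave(x, y)
  dc <- dci(x, y)
  flag <- rep("unchanged", length(prots))
  flag[da >= dave_thr & dc >= dci_thr] <- "up_in_x"
  flag[da <= -dave_thr & dc <= -dci_thr] <- "up_in_y"
  records <- data.frame(protein = prots, x = unname(x), y = unname(y),
                        dave = unname(da), dci = unname(dc), flag = flag,
                        stringsAsFactors = FALSE)
  structure(list(pair = c(px$cohort, py$cohort), records = records,
                 dep_up_x = sum(flag == "up_in_x"),
                 dep_up_y = sum(flag == "up_in_y"),
                 thresholds = c(dave = dave_thr, dci = dci_thr)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %s vs %s: %d up in %s, %d up in %s (|DAve|>=%g, |DCI|>=%g)\n",
    x$pair[1L], x$pair[2L], x$dep_up_x, x$pair[1L], x$dep_up_y, x$pair[2L],
    x$thresholds["dave"], x$thresholds["dci"]))
  invisible(x)
}

#' Proteins flagged in a comparison report
#' @param report a `comparison_report`.
#' @param direction `"any"`, `"up_in_x"` or `"up_in_y"`.
#' @return character vector of protein identifiers.
#' @export
dep_proteins <- function(report, direction = c("any", "up_in_x", "up_in_y")) {
  direction <- match.arg(direction)
  r <- report$records
  if (direction == "any") r$protein[r$flag != "unchanged"]
  else r$protein[r$flag == direction]
}

#' Union of differentially expressed proteins across comparisons
#'
#' @param reports list of `comparison_report`s (>= 1).
#' @return character vector of distinct proteins flagged (either
#'   direction) in any report.
#' @export
dep_union <- function(reports) {
  stopifnot(length(reports) >= 1L)
  sort(unique(unlist(lapply(reports, dep_proteins))))
}

#' Write a comparison report to TSV
#' @param report a `comparison_report`.
#' @param path output path; thresholds are echoed in `#`-comment header
#'   lines for provenance.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pair: %s vs %s", report$pair[1L], report$pair[2L]),
    sprintf("# dave_threshold: %g", report$thresholds["dave"]),
    sprintf("# dci_threshold: %g", report$thresholds["dci"])), con)
  utils::write.table(report$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
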