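#' @keywords internal
"_PACKAGE"

#' Cohort labels recognized throughout the package
#'
#' Wild-type (`Wt`), heterozygous carrier (`He`) and homozygous affected
#' (`Ho`), the three-group family design the pipeline targets.  Functions
#' that take a `cohort` argument validate against this set unless the
#' containing object carries its own label set.
#' @export
COHORTS <- c("Wt", "He", "Ho")

#' Recognized subcellular location labels, in resolution priority order
#' @export
LOCATIONS <- c("cellular", "organelle", "macromolecular complex",
               "membrane", "unknown")

#' Construct a per-run protein identification list
#'
#' A `run_list` is the atomic unit of a spectral-count experiment: the set
#' of proteins identified in one LC-MS/MS run together with their spectral
#' counts (SpC, the number of MS/MS spectra assigned to each protein).
#' Absence from the list encodes SpC = 0; listed entries must have
#' SpC >= 1.
#'
#' @param run_id unique run identifier.
#' @param subject_id subject the sample came from.
#' @param cohort cohort label (by default one of `Wt`, `He`, `Ho`).
#' @param replicate_kind `"technical"` or `"biological"`.
#' @param entries data.frame with at least columns `accession` (character,
#'   unique) and `spc` (positive integer); optional columns `gene`,
#'   `description`, `mw_kda`, `pi`, `location` are retained.
#' @return an object of class `run_list`.
#' @export
run_list <- function(run_id, subject_id, cohort, entries,
                     replicate_kind = c("technical", "biological")) {
  replicate_kind <- match.arg(replicate_kind)
  stopifnot(is.character(run_id), length(run_id) == 1L, nzchar(run_id))
  if (!is.data.frame(entries) ||
      !all(c("accession", "spc") %in% names(entries))) {
    stop("run_list format error: 'entries' needs columns accession and spc",
         call. = FALSE)
  }
  entries$accession <- as.character(entries$accession)
  entries$spc <- as.integer(round(entries$spc))
  if (anyNA(entries$accession) || any(!nzchar(entries$accession)))
    stop("run_list validation error: empty accession", call. = FALSE)
  dup <- entries$accession[duplicated(entries$accession)]
  if (length(dup))
    stop("run_list validation error: duplicate accession '", dup[1L], "'",
         call. = FALSE)
  if (any(entries$spc <= 0L))
    stop("run_list validation error: SpC must be >= 1 (absence encodes 0)",
         call. = FALSE)
  if ("pi" %in% names(entries)) {
    bad <- !is.na(entries$pi) & (entries$pi < 0 | entries$pi > 14)
    if (any(bad))
      stop("run_list validation error: pI outside [0, 14]", call. = FALSE)
  }
  if ("mw_kda" %in% names(entries)) {
    if (any(!is.na(entries$mw_kda) & entries$mw_kda < 0))
      stop("run_list validation error: negative MW", call. = FALSE)
  }
  canon <- c("accession", "spc", "gene", "description", "mw_kda", "pi",
             "location")
  ord <- c(intersect(canon, names(entries)),
           setdiff(names(entries), canon))
  entries <- entries[, ord, drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(run_id = run_id, subject_id = as.character(subject_id),
         cohort = as.character(cohort), replicate_kind = replicate_kind,
         entries = entries),
    class = "run_list")
}

#' @export
print.run_list <- function(x, ...) {
  cat(sprintf("<run_list> %s  subject=%s cohort=%s (%s), %d proteins, %d spectra\n",
              x$run_id, x$subject_id, x$cohort, x$replicate_kind,
              nrow(x$entries), sum(x$entries$spc)))
  invisible(x)
}

#' Construct a spectral-count matrix
#'
#' The pipeline's spine: an integer proteins-by-runs count matrix with
#' per-run metadata (subject, cohort, replicate kind).
#'
#' @param counts integer matrix, proteins in rows (rownames = accessions or
#'   gene symbols), runs in columns (colnames = run ids).
#' @param runs data.frame with one row per column of `counts` and columns
#'   `run_id`, `subject_id`, `cohort`, `replicate_kind`.
#' @return object of class `spc_matrix`.
#' @export
spc_matrix <- function(counts, runs) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("spc_matrix validation error: counts must have dimnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("spc_matrix validation error: duplicate protein row", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("spc_matrix validation error: duplicate run column", call. = FALSE)
  if (any(counts < 0L))
    stop("spc_matrix validation error: negative count", call. = FALSE)
  stopifnot(is.data.frame(runs), nrow(runs) == ncol(counts),
            all(c("run_id", "subject_id", "cohort", "replicate_kind")
                %in% names(runs)))
  if (!identical(unname(as.character(runs$run_id)),
                 unname(colnames(counts))))
    stop("spc_matrix validation error: runs$run_id must match column order",
         call. = FALSE)
  rownames(runs) <- NULL
  structure(list(counts = counts, runs = runs), class = "spc_matrix")
}

#' @export
print.spc_matrix <- function(x, ...) {
  tab <- table(x$runs$cohort)
  cat(sprintf("<spc_matrix> %d proteins x %d runs (%s); %d spectra total\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.spc_matrix <- function(x) dim(x$counts)

#' Run ids belonging to one cohort
#' @param mat an `spc_matrix`.
#' @param cohort cohort label present in `mat$runs$cohort`.
#' @return character vector of run ids.
#' @export
cohort_runs <- function(mat, cohort) {
  stopifnot(inherits(mat, "spc_matrix"))
  if (!cohort %in% mat$runs$cohort)
    stop("validation error: unknown cohort '", cohort, "'", call. = FALSE)
  mat$runs$run_id[mat$runs$cohort == cohort]
}

#' Resolve multiple subcellular locations to a single label
#'
#' Proteins annotated with several compartments are resolved
#' deterministically by a fixed priority: cellular > organelle >
#' macromolecular complex > membrane; anything unrecognized maps to
#' `"unknown"`.
#'
#' @param x character vector; multiple labels per element separated by
#'   `;`, `,` or `|`.
#' @return character vector of single labels from [LOCATIONS].
#' @export
resolve_location <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return("unknown")
    parts <- trimws(tolower(strsplit(s, "[;,|]")[[1L]]))
    hit <- match(setdiff(LOCATIONS, "unknown"), parts)
    i <- which(!is.na(hit))
    if (length(i)) LOCATIONS[min(i)] else "unknown"
  }, character(1L), USE.NAMES = FALSE)
}
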