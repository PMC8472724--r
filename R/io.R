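## TSV readers/writers for protein lists, PSM tables and annotation, plus
## matrix assembly.  All files are UTF-8, tab-separated, with a mandatory
## header; column names are remappable through `dialect` so exports from
## arbitrary search-engine frontends can be ingested without editing.

default_dialect <- function() {
  list(accession = "accession", gene = "gene", description = "description",
       spc = "spc", mw_kda = "mw_kda", pi = "pi", location = "location")
}

read_tsv_checked <- function(path) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read one per-run protein list from a TSV file
#'
#' The file must carry a header naming at least the accession and
#' spectral-count columns (names remappable via `dialect`).  Rows with
#' SpC <= 0 are dropped with a message: a protein that contributed no
#' spectra is by definition absent from the run.
#'
#' @param path TSV file path.
#' @param run_id,subject_id,cohort,replicate_kind run metadata; `run_id`
#'   defaults to the file name without extension.
#' @param dialect named list mapping canonical column names
#'   (`accession`, `spc`, `gene`, `description`, `mw_kda`, `pi`,
#'   `location`) to the names used in the file.
#' @return a [run_list].
#' @export
read_run_list <- function(path, run_id = NULL, subject_id = "S1",
                          cohort = "Wt", replicate_kind = "technical",
                          dialect = default_dialect()) {
  df <- read_tsv_checked(path)
  dia <- utils::modifyList(default_dialect(), dialect)
  need <- c("accession", "spc")
  miss <- need[!unlist(dia[need]) %in% names(df)]
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(unlist(dia[miss]), collapse = ", "), call. = FALSE)
  keep <- intersect(unlist(dia), names(df))
  df <- df[, keep, drop = FALSE]
  names(df) <- names(dia)[match(keep, unlist(dia))]
  nonpos <- df$spc <= 0 | is.na(df$spc)
  if (any(nonpos)) {
    message(sum(nonpos), " row(s) with SpC <= 0 dropped from ", basename(path))
    df <- df[!nonpos, , drop = FALSE]
  }
  if ("location" %in% names(df)) df$location <- resolve_location(df$location)
  if (is.null(run_id))
    run_id <- sub("\\.[^.]+$", "", basename(path))
  run_list(run_id = run_id, subject_id = subject_id, cohort = cohort,
           replicate_kind = replicate_kind, entries = df)
}

#' Write a run list to TSV (inverse of [read_run_list])
#' @param x a [run_list].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_list <- function(x, path) {
  stopifnot(inherits(x, "run_list"))
  utils::write.table(x$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a PSM (peptide-spectrum match) table from TSV
#'
#' Expected columns: `peptide`, `charge`, `xcorr`, `probability`,
#' `consensus_score`, `is_decoy`, `accession`.  `is_decoy` accepts
#' logicals or 0/1.
#'
#' @param path TSV file path.
#' @return data.frame of PSM records.
#' @export
read_psm_table <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("peptide", "charge", "xcorr", "probability",
            "consensus_score", "is_decoy", "accession")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing PSM column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$charge <- as.integer(df$charge)
  df$is_decoy <- as.logical(df$is_decoy)
  validate_psms(df)
  df
}

validate_psms <- function(psms) {
  stopifnot(is.data.frame(psms))
  if (any(psms$charge < 1L))
    stop("validation error: PSM charge must be >= 1", call. = FALSE)
  if (any(psms$probability <= 0 | psms$probability > 1))
    stop("validation error: PSM probability must lie in (0, 1]",
         call. = FALSE)
  if (any(psms$xcorr < 0))
    stop("validation error: negative Xcorr", call. = FALSE)
  invisible(psms)
}

#' Write a PSM table to TSV
#' @param psms data.frame as returned by [read_psm_table] or
#'   [simulate_psm_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein annotation table
#'
#' One row per accession with columns `accession`, `gene` and optionally
#' `mw_kda`, `pi`, `location`.  Locations are resolved to a single label
#' by [resolve_location].
#'
#' @param path TSV file path.
#' @return data.frame keyed by accession.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path)
  if (!"accession" %in% names(df))
    stop("format error: annotation needs an 'accession' column",
         call. = FALSE)
  if (anyDuplicated(df$accession))
    stop("validation error: duplicate accession in annotation",
         call. = FALSE)
  if ("location" %in% names(df)) df$location <- resolve_location(df$location)
  df
}

#' Read a two-column gene-to-term mapping
#' @param path TSV with columns `gene` and `term`.
#' @return data.frame with columns `gene`, `term` (one row per pair).
#' @export
read_terms <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("gene", "term") %in% names(df)))
    stop("format error: term mapping needs columns gene, term",
         call. = FALSE)
  unique(df[, c("gene", "term")])
}

#' Assemble run lists into a spectral-count matrix
#'
#' Rows are the union of all accessions (in order of first appearance);
#' a protein absent from a run receives count 0.  Column order follows
#' the input order of `lists`.
#'
#' @param lists list of [run_list] objects (>= 2, unique run ids).
#' @return an [spc_matrix].
#' @export
assemble_matrix <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  lapply(lists, function(x) stopifnot(inherits(x, "run_list")))
  ids <- unname(vapply(lists, `[[`, character(1L), "run_id"))
  if (anyDuplicated(ids))
    stop("validation error: duplicate run_id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  prots <- unique(unlist(lapply(lists, function(x) x$entries$accession)))
  counts <- matrix(0L, nrow = length(prots), ncol = length(lists),
                   dimnames = list(prots, ids))
  for (j in seq_along(lists)) {
    e <- lists[[j]]$entries
    counts[e$accession, j] <- e$spc
  }
  runs <- data.frame(
    run_id = ids,
    subject_id = vapply(lists, `[[`, character(1L), "subject_id"),
    cohort = vapply(lists, `[[`, character(1L), "cohort"),
    replicate_kind = vapply(lists, `[[`, character(1L), "replicate_kind"),
    stringsAsFactors = FALSE)
  spc_matrix(counts, runs)
}

#' Map accessions to genes, optionally collapsing shared-gene rows
#'
#' Accessions without annotation coverage pass through unchanged (and are
#' reported via a message).  When `collapse_by_gene` is `TRUE`, rows whose
#' accessions map to the same gene symbol are summed into one row keyed by
#' the gene; total count mass per run is conserved exactly.
#'
#' @param mat an [spc_matrix] keyed by accession.
#' @param ann annotation data.frame ([read_annotation]).
#' @param collapse_by_gene collapse rows sharing a gene (default `TRUE`).
#' @return an [spc_matrix] keyed by gene (collapsed) or accession.
#' @export
map_accessions <- function(mat, ann, collapse_by_gene = TRUE) {
  stopifnot(inherits(mat, "spc_matrix"))
  acc <- rownames(mat$counts)
  gene <- ann$gene[match(acc, ann$accession)]
  unmapped <- is.na(gene) | !nzchar(gene)
  if (any(unmapped))
    message(sum(unmapped), " accession(s) without gene annotation kept as-is")
  key <- ifelse(unmapped, acc, gene)
  if (!collapse_by_gene) {
    out <- mat
    rownames(out$counts) <- make.unique(key)
    return(out)
  }
  counts <- rowsum(mat$counts, group = key, reorder = FALSE)
  storage.mode(counts) <- "integer"
  spc_matrix(counts, mat$runs)
}

#' Export a spectral-count matrix as TSV plus a metadata sidecar
#'
#' The matrix goes to `<path>` with a leading `protein` column; run
#' metadata goes to `<path>.meta` in DCF (`key: value`) blocks so the
#' pair round-trips through [read_matrix_tsv].
#'
#' @param mat an [spc_matrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "spc_matrix"))
  df <- data.frame(protein = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write.dcf(mat$runs, paste0(path, ".meta"))
  invisible(path)
}

#' Read a spectral-count matrix written by [write_matrix_tsv]
#' @param path TSV path (expects `<path>.meta` alongside).
#' @return an [spc_matrix].
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path)
  meta <- as.data.frame(read.dcf(paste0(path, ".meta")),
                        stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$protein
  spc_matrix(counts, meta)
}
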