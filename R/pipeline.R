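## End-to-end orchestration: a declarative configuration, a staged
## pipeline (QC -> profile -> diff -> lda -> cluster -> network/enrich)
## and a failure-tolerant replication harness for the original study's
## supplementary protein lists.

#' Build and validate a pipeline configuration
#'
#' @param data_dir directory with `runs.tsv` (run metadata: run_id,
#'   subject_id, cohort, replicate_kind), one `<run_id>.tsv` protein
#'   list per run, and optionally `annotation.tsv`; `NULL` simulates a
#'   dataset instead.
#' @param network_path,terms_path optional interactome edge list and
#'   gene-term mapping for the network stage.
#' @param psm_path optional PSM table for the identification-filter QC.
#' @param dave_thr,dci_thr,f_thr,p_thr,alpha stage thresholds.
#' @param membership Venn membership mode (see [cohort_members]).
#' @param normalization `"total"` or `"nsaf"`.
#' @param covariance_mode Mahalanobis covariance mode.
#' @param linkage clustering linkage (`"ward"`/`"average"`).
#' @param seed integer seed used for any simulation.
#' @param sim a [sim_config] to override the simulated dataset (its seed
#'   is replaced by `seed`).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL, network_path = NULL,
                            terms_path = NULL, psm_path = NULL,
                            dave_thr = 0.4, dci_thr = 15,
                            f_thr = 3.4, p_thr = 0.05, alpha = 0.001,
                            membership = "any_run",
                            normalization = "total",
                            covariance_mode = "diagonal_pooled",
                            linkage = "ward", seed = 1L, sim = NULL) {
  thr <- c(dave_thr = dave_thr, dci_thr = dci_thr, f_thr = f_thr,
           p_thr = p_thr, alpha = alpha)
  if (any(thr <= 0))
    stop("config error: thresholds must be positive (",
         paste(names(thr)[thr <= 0], collapse = ", "), ")", call. = FALSE)
  membership <- match.arg(membership, c("any_run", "average_list"))
  normalization <- match.arg(normalization, c("total", "nsaf"))
  covariance_mode <- match.arg(covariance_mode,
                               c("diagonal_pooled", "shrunk_pooled"))
  linkage <- match.arg(linkage, c("ward", "average"))
  for (p in c(data_dir = data_dir, network_path = network_path,
              terms_path = terms_path, psm_path = psm_path))
    if (!is.null(p) && !file.exists(p))
      stop("config error: path does not exist: ", p, call. = FALSE)
  structure(list(data_dir = data_dir, network_path = network_path,
                 terms_path = terms_path, psm_path = psm_path,
                 dave_thr = dave_thr, dci_thr = dci_thr, f_thr = f_thr,
                 p_thr = p_thr, alpha = alpha, membership = membership,
                 normalization = normalization,
                 covariance_mode = covariance_mode, linkage = linkage,
                 seed = as.integer(seed), sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a DCF (`key: value`) file
#'
#' Recognized keys mirror the arguments of [pipeline_config]; numeric
#' values are converted.  Unknown keys raise a config error naming the
#' field.
#'
#' @param path DCF file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config error: config file not found: ", path, call. = FALSE)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  numeric_keys <- c("dave_thr", "dci_thr", "f_thr", "p_thr", "alpha",
                    "seed")
  known <- c("data_dir", "network_path", "terms_path", "psm_path",
             numeric_keys, "membership", "normalization",
             "covariance_mode", "linkage")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("config error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (k in intersect(numeric_keys, names(kv)))
    kv[[k]] <- as.numeric(kv[[k]])
  do.call(pipeline_config, kv)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "sim")]), f)
  unname(tools::md5sum(f))
}

load_dataset_dir <- function(dir) {
  meta_path <- file.path(dir, "runs.tsv")
  if (!file.exists(meta_path))
    stop("config error: missing runs.tsv in ", dir, call. = FALSE)
  meta <- read_tsv_checked(meta_path)
  runs <- lapply(seq_len(nrow(meta)), function(i)
    read_run_list(file.path(dir, paste0(meta$run_id[i], ".tsv")),
                  run_id = meta$run_id[i], subject_id = meta$subject_id[i],
                  cohort = meta$cohort[i],
                  replicate_kind = meta$replicate_kind[i]))
  ann_path <- file.path(dir, "annotation.tsv")
  list(runs = runs,
       annotation = if (file.exists(ann_path)) read_annotation(ann_path)
                    else NULL)
}

#' Run the full profiling pipeline
#'
#' Stages, in order: load or simulate the runs; assemble the
#' spectral-count matrix; replicate-repeatability QC (all technical
#' replicate pairs within each subject) and, when a PSM table is
#' configured, identification filtering plus target-decoy FDR; cohort
#' profiling with Venn partitioning; all pairwise DAve/DCI comparisons
#' and the DEP union; discriminant-protein selection, Mahalanobis
#' assignment and hierarchical clustering; and, when an interactome is
#' configured, subnetwork extraction with state coloring and term
#' enrichment.  Reruns with identical config and inputs are
#' reproducible bit for bit.
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir optional directory for TSV exports; every file carries
#'   the config hash and seed in `#` header lines.
#' @return result bundle (list) with the per-stage objects, plus
#'   `config`, `config_hash` and `log` (character vector of applied
#'   thresholds and stage notes).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  note("seed: %d", cfg$seed)
  dat <- stage("load", {
    if (is.null(cfg$data_dir)) {
      sc <- if (is.null(cfg$sim)) sim_config(seed = cfg$seed) else {
        s <- cfg$sim; s$seed <- cfg$seed; s
      }
      note("simulating dataset: %d proteins, seed %d", sc$n_proteins,
           sc$seed)
      simulate_dataset(sc)
    } else {
      note("loading dataset from %s", cfg$data_dir)
      load_dataset_dir(cfg$data_dir)
    }
  })
  mat <- stage("assemble", assemble_matrix(dat$runs))
  cohorts <- unique(mat$runs$cohort)

  qc <- stage("qc", {
    pairs <- list()
    for (s in unique(mat$runs$subject_id)) {
      ids <- mat$runs$run_id[mat$runs$subject_id == s &
                               mat$runs$replicate_kind == "technical"]
      if (length(ids) >= 2L)
        for (i in seq_len(length(ids) - 1L)) {
          rr <- repeatability(dat$runs[[which(vapply(dat$runs, `[[`,
                  character(1L), "run_id") == ids[i])]],
                dat$runs[[which(vapply(dat$runs, `[[`, character(1L),
                  "run_id") == ids[i + 1L])]])
          note("repeatability %s~%s: slope=%.3f R2=%.4f", ids[i],
               ids[i + 1L], rr$slope, rr$r_squared)
          pairs[[paste(ids[i], ids[i + 1L], sep = "~")]] <- rr
        }
    }
    fdr <- NULL
    if (!is.null(cfg$psm_path)) {
      psms <- read_psm_table(cfg$psm_path)
      kept <- filter_psms(psms)
      fdr <- compute_fdr(kept)
      note("PSM filter: %d -> %d, FDR=%.4f", nrow(psms), nrow(kept), fdr)
    }
    list(repeatability = pairs, fdr = fdr)
  })

  profiles <- stage("profile", {
    note("membership mode: %s; normalization: %s", cfg$membership,
         cfg$normalization)
    stats::setNames(lapply(cohorts, function(co) cohort_aspc(mat, co)),
                    cohorts)
  })
  venn <- stage("profile", {
    sets <- stats::setNames(lapply(cohorts, function(co)
      cohort_members(mat, co, cfg$membership)), cohorts)
    venn_partition(sets)
  })

  reports <- stage("diff", {
    note("thresholds: dave=%g dci=%g (inclusive)", cfg$dave_thr,
         cfg$dci_thr)
    combs <- utils::combn(cohorts, 2L, simplify = FALSE)
    stats::setNames(
      lapply(combs, function(pr)
        compare_pair(profiles[[pr[1L]]], profiles[[pr[2L]]],
                     cfg$dave_thr, cfg$dci_thr)),
      vapply(combs, paste, character(1L), collapse = "_vs_"))
  })
  deps <- stage("diff", dep_union(reports))
  note("DEP union: %d proteins", length(deps))

  lda <- stage("lda", {
    note("LDA thresholds: F>%g, p<%g", cfg$f_thr, cfg$p_thr)
    select_lda_sps(mat, f_thr = cfg$f_thr, p_thr = cfg$p_thr,
                   ann = dat$annotation)
  })
  sel <- lda$protein[lda$selected]
  note("LDA-selected proteins: %d", length(sel))
  gene_mat <- if (!is.null(dat$annotation))
    map_accessions(mat, dat$annotation) else mat
  norm <- stage("lda", normalize_runs(gene_mat, cfg$normalization,
    mw_kda = if (cfg$normalization == "nsaf" && !is.null(dat$annotation))
      stats::setNames(dat$annotation$mw_kda, dat$annotation$gene)))
  assign <- stage("lda", if (length(sel))
    mahalanobis_assign(norm, sel, cfg$covariance_mode) else NULL)
  clust <- stage("cluster", if (length(sel) >= 1L)
    hierarchical_cluster(norm, sel, cfg$linkage) else NULL)

  network <- stage("network", {
    if (is.null(cfg$network_path)) NULL else {
      net <- load_network(cfg$network_path)
      gene_deps <- if (!is.null(dat$annotation))
        unique(dat$annotation$gene[match(deps, dat$annotation$accession)])
      else deps
      sub <- induced_subnetwork(net, gene_deps[!is.na(gene_deps)])
      note("subnetwork: %d nodes, %d edges", sub$n_nodes, sub$n_edges)
      gene_profiles <- lapply(cohorts, function(co) cohort_aspc(gene_mat, co))
      attrs <- color_by_state(sub, gene_profiles, reports)
      list(subnetwork = sub, attributes = attrs)
    }
  })
  enrich <- stage("enrich", {
    if (is.null(cfg$terms_path)) NULL else {
      terms <- read_terms(cfg$terms_path)
      universe <- if (!is.null(dat$annotation))
        unique(dat$annotation$gene[match(rownames(mat$counts),
                                         dat$annotation$accession)])
      else rownames(mat$counts)
      gene_deps <- if (!is.null(dat$annotation))
        unique(dat$annotation$gene[match(deps, dat$annotation$accession)])
      else deps
      hypergeom_enrich(intersect(gene_deps, universe),
                       universe[!is.na(universe)], terms, cfg$alpha)
    }
  })

  bundle <- list(matrix = mat, annotation = dat$annotation,
                 truth = dat$truth, qc = qc, profiles = profiles,
                 venn = venn, reports = reports, dep_union = deps,
                 lda = lda, assignment = assign, clustering = clust,
                 network = network, enrichment = enrich,
                 config = cfg, config_hash = config_hash(cfg), log = log)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# config_hash: %s", bundle$config_hash),
           sprintf("# seed: %d", bundle$config$seed))
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w", encoding = "UTF-8")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  write_matrix_tsv(bundle$matrix, file.path(out_dir, "matrix.tsv"))
  emit(data.frame(region = names(bundle$venn$sizes),
                  size = unname(bundle$venn$sizes)), "venn.tsv")
  for (nm in names(bundle$reports))
    write_comparison_report(bundle$reports[[nm]],
                            file.path(out_dir, paste0("diff_", nm, ".tsv")))
  emit(data.frame(protein = bundle$dep_union), "dep_union.tsv")
  emit(as.data.frame(bundle$lda), "lda.tsv")
  if (!is.null(bundle$assignment)) emit(bundle$assignment, "assignment.tsv")
  if (!is.null(bundle$clustering))
    cluster_newick(bundle$clustering, file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(bundle$network))
    emit(bundle$network$attributes, "node_attributes.tsv")
  if (!is.null(bundle$enrichment)) emit(bundle$enrichment, "enrichment.tsv")
  writeLines(c(hdr, bundle$log), file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Published reference values of the original family study
#'
#' Headline numbers the replication harness compares against: Venn
#' region sizes, per-pair and union DEP counts, the discriminant-protein
#' count and its DEP overlap, the distinct-protein total, and the
#' replicate-QC band.
#' @return data.frame with columns `target`, `published`.
#' @export
replication_reference <- function() {
  data.frame(
    target = c("total_proteins", "venn_shared", "venn_wt_specific",
               "venn_he_specific", "venn_ho_specific", "dep_wt_ho",
               "dep_he_ho", "dep_up_he_vs_wt", "dep_union", "lda_sp",
               "lda_dep_overlap", "r_squared_min", "slope"),
    published = c(3458, 1478, 448, 335, 452, 147, 28, 108, 192, 475,
                  128, 0.95, 1.08),
    stringsAsFactors = FALSE)
}

#' Replicate the study's headline numbers from supplementary lists
#'
#' Expects `appendix_dir` in the dataset-directory dialect of
#' [run_pipeline] (`runs.tsv` + per-run lists).  Recomputes every
#' replication target it can and reports observed vs published side by
#' side; missing or malformed inputs mark targets `unavailable` instead
#' of failing.
#'
#' @param appendix_dir directory with the supplementary protein lists.
#' @param membership Venn membership mode.
#' @return data.frame: `target`, `published`, `observed`, `status`.
#' @export
replicate_paper <- function(appendix_dir, membership = "any_run") {
  ref <- replication_reference()
  ref$observed <- NA_real_
  ref$status <- "unavailable"
  bundle <- tryCatch({
    cfg <- pipeline_config(data_dir = appendix_dir,
                           membership = membership)
    run_pipeline(cfg)
  }, error = function(e) {
    message("replication inputs unusable: ", conditionMessage(e))
    NULL
  })
  if (is.null(bundle)) return(ref)
  put <- function(target, value) {
    i <- ref$target == target
    ref$observed[i] <<- value
    ref$status[i] <<- "available"
  }
  put("total_proteins", nrow(bundle$matrix$counts))
  vs <- bundle$venn$sizes
  if (all(c("Wt", "He", "Ho") %in% unique(bundle$matrix$runs$cohort))) {
    put("venn_shared", vs[["Wt&He&Ho"]])
    put("venn_wt_specific", vs[["Wt"]])
    put("venn_he_specific", vs[["He"]])
    put("venn_ho_specific", vs[["Ho"]])
    rp <- bundle$reports
    pick <- function(a, b) {
      nm <- paste0(a, "_vs_", b)
      if (nm %in% names(rp)) rp[[nm]]
      else rp[[paste0(b, "_vs_", a)]]
    }
    wt_ho <- pick("Wt", "Ho")
    if (!is.null(wt_ho))
      put("dep_wt_ho", length(dep_proteins(wt_ho)))
    he_ho <- pick("He", "Ho")
    if (!is.null(he_ho))
      put("dep_he_ho", length(dep_proteins(he_ho)))
    he_wt <- pick("He", "Wt")
    if (!is.null(he_wt)) {
      dir_up_he <- if (he_wt$pair[1L] == "He") "up_in_x" else "up_in_y"
      put("dep_up_he_vs_wt", length(dep_proteins(he_wt, dir_up_he)))
    }
  }
  put("dep_union", length(bundle$dep_union))
  put("lda_sp", sum(bundle$lda$selected))
  sel_genes <- bundle$lda$protein[bundle$lda$selected]
  dep_genes <- if (!is.null(bundle$annotation))
    unique(bundle$annotation$gene[match(bundle$dep_union,
                                        bundle$annotation$accession)])
  else bundle$dep_union
  put("lda_dep_overlap", length(intersect(sel_genes,
                                          dep_genes[!is.na(dep_genes)])))
  if (length(bundle$qc$repeatability)) {
    r2 <- vapply(bundle$qc$repeatability, `[[`, numeric(1L), "r_squared")
    sl <- vapply(bundle$qc$repeatability, `[[`, numeric(1L), "slope")
    put("r_squared_min", min(r2))
    put("slope", mean(sl))
  }
  ref
}
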