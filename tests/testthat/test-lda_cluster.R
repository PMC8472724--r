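test_that("protein_f_ratio matches hand ANOVA and handles degeneracy", {
  out <- protein_f_ratio(list(c(0, 2), c(1, 3), c(2, 4)))
  expect_equal(out[["f_ratio"]], 1.0)
  const <- protein_f_ratio(list(c(3, 3), c(3, 3)))
  expect_equal(const[["f_ratio"]], 0)
  expect_equal(const[["p_value"]], 1)
  sep <- protein_f_ratio(list(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(sep[["f_ratio"]], Inf)
  expect_equal(sep[["p_value"]], 0)
  expect_error(protein_f_ratio(list(c(1, 2), numeric(0))), "empty group")
  expect_error(protein_f_ratio(list(1, 2)), "total n")
})

test_that("protein_f_ratio is shift- and relabel-invariant", {
  set.seed(8)
  for (i in 1:20) {
    gs <- lapply(1:3, function(k) rnorm(sample(2:6, 1L), mean = k))
    a <- protein_f_ratio(gs)
    b <- protein_f_ratio(lapply(gs, `+`, 17.3))
    expect_equal(a, b, tolerance = 1e-9)
    expect_equal(protein_f_ratio(rev(gs))[["f_ratio"]], a[["f_ratio"]],
                 tolerance = 1e-12)
  }
})

test_that("F ratios agree with the lm/anova oracle on random matrices", {
  set.seed(19)
  for (i in 1:30) {
    np <- sample(2:20, 1L)
    counts <- matrix(rpois(np * 9L, 12), nrow = np,
                     dimnames = list(sprintf("P%02d", seq_len(np)),
                                     sprintf("r%d", 1:9)))
    mat <- spc_matrix(counts, data.frame(
      run_id = sprintf("r%d", 1:9), subject_id = "S",
      cohort = rep(c("Wt", "He", "Ho"), each = 3L),
      replicate_kind = "technical"))
    recs <- select_lda_sps(mat, collapse_by_gene = FALSE,
                           normalize = FALSE)
    for (p in sample(rownames(counts), min(3L, np))) {
      gs <- split(counts[p, ], mat$runs$cohort)
      ora <- oracle_f_ratio(gs)
      got <- recs[recs$protein == p, ]
      if (is.finite(got$f_ratio)) {
        expect_equal(got$f_ratio, ora[["f"]], tolerance = 1e-10)
        expect_equal(got$p_value, ora[["p"]], tolerance = 1e-10)
      }
    }
  }
})

test_that("select_lda_sps finds a planted group shift and respects gates", {
  counts <- matrix(5L, nrow = 3L, ncol = 9L,
                   dimnames = list(c("HIT", "N1", "N2"),
                                   sprintf("r%d", 1:9)))
  set.seed(4)
  counts[2:3, ] <- matrix(rpois(18, 5), nrow = 2L)
  counts["HIT", 7:9] <- c(50L, 52L, 48L)
  mat <- spc_matrix(counts, data.frame(
    run_id = sprintf("r%d", 1:9), subject_id = "S",
    cohort = rep(c("Wt", "He", "Ho"), each = 3L),
    replicate_kind = "technical"))
  recs <- select_lda_sps(mat, collapse_by_gene = FALSE, normalize = FALSE)
  expect_true(recs$selected[recs$protein == "HIT"])
  none <- select_lda_sps(mat, f_thr = Inf, collapse_by_gene = FALSE,
                         normalize = FALSE)
  expect_false(any(none$selected))
  expect_error(select_lda_sps(toy_matrix()[["counts"]]), "spc_matrix")
})

test_that("pure-noise selection rate stays near nominal", {
  rates <- vapply(1:10, function(seed) {
    set.seed(seed)
    counts <- matrix(rpois(500L * 19L, 10), nrow = 500L,
                     dimnames = list(sprintf("P%03d", 1:500),
                                     sprintf("r%02d", 1:19)))
    mat <- spc_matrix(counts, data.frame(
      run_id = sprintf("r%02d", 1:19), subject_id = "S",
      cohort = rep(c("Wt", "He", "Ho"), c(7L, 6L, 6L)),
      replicate_kind = "technical"))
    mean(select_lda_sps(mat, collapse_by_gene = FALSE,
                        normalize = FALSE)$selected)
  }, numeric(1L))
  expect_lt(mean(rates), 0.07)
})

test_that("mahalanobis distances match hand evaluation", {
  # 2 features, identity-like pooled covariance via constructed data
  counts <- matrix(c(0, 2, 10, 12, 0, 2, 10, 12), nrow = 2L, byrow = TRUE,
                   dimnames = list(c("F1", "F2"), sprintf("r%d", 1:4)))
  mat <- list(counts = counts, runs = data.frame(
    run_id = sprintf("r%d", 1:4), subject_id = "S",
    cohort = rep(c("A", "B"), each = 2L),
    replicate_kind = "technical", stringsAsFactors = FALSE))
  res <- mahalanobis_assign(mat)
  # pooled within variance per feature = ((0-1)^2+(2-1)^2)*2 / (4-2) = 2
  # run r1 = (0,0): distance to A mean (1,1) = sqrt(2*1/2) = 1
  expect_equal(res$dist_A[1L], 1.0, tolerance = 1e-12)
  expect_equal(res$predicted, c("A", "A", "B", "B"))
  expect_true(all(res$correct))
})

test_that("shrunk covariance falls back gracefully and assigns runs", {
  sim <- small_sim(seed = 6L, n = 120L)
  mat <- assemble_matrix(sim$runs)
  lda <- select_lda_sps(mat, ann = sim$annotation)
  sel <- lda$protein[lda$selected]
  nm <- normalize_runs(suppressMessages(map_accessions(mat,
                                                       sim$annotation)))
  res <- mahalanobis_assign(nm, sel, "shrunk_pooled")
  expect_equal(nrow(res), 19L)
  expect_true(all(c("dist_Wt", "dist_He", "dist_Ho") %in% names(res)))
  expect_error(mahalanobis_assign(nm, "NOT_A_PROTEIN"), "no selected")
})

test_that("hierarchical_cluster separates constructed groups", {
  counts <- matrix(c(100, 98, 5, 6, 100, 102, 4, 5), nrow = 2L,
                   byrow = TRUE,
                   dimnames = list(c("F1", "F2"), c("a1", "a2", "b1", "b2")))
  mat <- list(counts = counts, runs = data.frame(
    run_id = c("a1", "a2", "b1", "b2"), subject_id = "S",
    cohort = c("A", "A", "B", "B"), replicate_kind = "technical",
    stringsAsFactors = FALSE))
  res <- hierarchical_cluster(mat)
  k2 <- cluster_cut(res, 2L)
  expect_equal(unname(k2[c("a1", "a2")]), rep(k2[["a1"]], 2L))
  expect_equal(unname(k2[c("b1", "b2")]), rep(k2[["b1"]], 2L))
  expect_false(k2[["a1"]] == k2[["b1"]])
  nwk <- cluster_newick(res)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(c("a1", "a2", "b1", "b2"), grepl, logical(1L),
                         x = nwk, fixed = TRUE)))
})

test_that("agnes coefficient behaves at its boundaries and grows with duplication", {
  same <- matrix(3, nrow = 2L, ncol = 3L,
                 dimnames = list(c("F1", "F2"), c("r1", "r2", "r3")))
  mat <- list(counts = same, runs = data.frame(
    run_id = c("r1", "r2", "r3"), subject_id = "S", cohort = "A",
    replicate_kind = "technical", stringsAsFactors = FALSE))
  expect_equal(hierarchical_cluster(mat)$agglomerative_coefficient, 0)

  sim <- small_sim(seed = 13L, n = 100L)
  m <- assemble_matrix(sim$runs)
  base <- hierarchical_cluster(m)
  dup_counts <- cbind(m$counts, m$counts)
  colnames(dup_counts) <- c(colnames(m$counts),
                            paste0(colnames(m$counts), "_dup"))
  dup <- list(counts = dup_counts,
              runs = rbind(m$runs, transform(m$runs,
                run_id = paste0(run_id, "_dup"))))
  duped <- hierarchical_cluster(dup)
  expect_gt(duped$agglomerative_coefficient,
            base$agglomerative_coefficient)
  expect_true(base$agglomerative_coefficient >= 0 &&
                base$agglomerative_coefficient <= 1)
})
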