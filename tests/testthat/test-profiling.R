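test_that("cohort_aspc averages with zeros included", {
  counts <- matrix(c(10L, 12L, 14L, 10L, 0L, 2L), nrow = 2L, byrow = TRUE,
                   dimnames = list(c("P1", "P2"), c("a", "b", "c")))
  mat <- spc_matrix(counts, data.frame(
    run_id = c("a", "b", "c"), subject_id = "S", cohort = "Wt",
    replicate_kind = "technical"))
  pr <- cohort_aspc(mat, "Wt")
  expect_equal(unname(pr$aspc), c(12.0, 4.0))
  expect_equal(pr$n_runs, 3L)
  expect_error(cohort_aspc(mat, "Xx"), "unknown cohort")
})

test_that("cohort_aspc on a single run equals that run; linear in scale", {
  mat <- toy_matrix()
  one <- spc_matrix(mat$counts[, "wt1", drop = FALSE], mat$runs[1, ])
  expect_equal(cohort_aspc(one, "Wt")$aspc, mat$counts[, "wt1"] + 0)
  scaled <- spc_matrix(mat$counts * 3L, mat$runs)
  expect_equal(cohort_aspc(scaled, "He")$aspc,
               3 * cohort_aspc(mat, "He")$aspc)
})

test_that("normalize_runs equalizes totals and conserves global mass", {
  counts <- matrix(c(10L, 90L, 75L, 225L), nrow = 2L,
                   dimnames = list(c("P1", "P2"), c("r1", "r2")))
  mat <- spc_matrix(counts, data.frame(
    run_id = c("r1", "r2"), subject_id = "S", cohort = "Wt",
    replicate_kind = "technical"))
  nm <- normalize_runs(mat)
  expect_equal(unname(colSums(nm$counts)), c(200, 200))
  expect_equal(sum(nm$counts), sum(counts))
  # equal depth is a fixed point
  eq <- spc_matrix(matrix(c(5L, 5L, 3L, 7L), 2L,
                          dimnames = list(c("P1", "P2"), c("r1", "r2"))),
                   mat$runs)
  expect_equal(normalize_runs(eq)$counts, eq$counts + 0)
  empty <- matrix(c(1L, 0L), 1L, dimnames = list("P1", c("r1", "r2")))
  expect_error(normalize_runs(spc_matrix(empty, mat$runs)), "empty run")
})

test_that("NSAF normalization sums to one per run", {
  mat <- toy_matrix()
  mw <- stats::setNames(c(50, 20, 100, 10), paste0("P", 1:4))
  nm <- normalize_runs(mat, "nsaf", mw_kda = mw)
  expect_equal(unname(colSums(nm$counts)), rep(1, 6), tolerance = 1e-12)
  expect_error(normalize_runs(mat, "nsaf"), "mw_kda")
})

test_that("venn_partition enumerates the 7 regions exactly", {
  v <- venn_partition(list(Wt = c("A", "B", "C", "D"),
                           He = c("B", "C", "D", "E"),
                           Ho = c("C", "D", "F")))
  expect_equal(sort(v$regions[["Wt&He&Ho"]]), c("C", "D"))
  expect_equal(v$sizes[["Wt"]], 1L)
  expect_equal(v$sizes[["He"]], 1L)
  expect_equal(v$sizes[["Ho"]], 1L)
  expect_equal(v$regions[["Wt"]], "A")

  same <- venn_partition(list(a = letters[1:5], b = letters[1:5],
                              c = letters[1:5]))
  expect_equal(same$sizes[["a&b&c"]], 5L)
  expect_equal(sum(same$sizes), 5L)

  disj <- venn_partition(list(a = "x", b = "y", c = c("z", "w")))
  expect_equal(unname(disj$sizes[c("a", "b", "c", "a&b&c")]),
               c(1L, 1L, 2L, 0L))
})

test_that("venn region sizes always sum to the union size (fuzz)", {
  set.seed(77)
  for (i in 1:50) {
    pool <- sprintf("P%02d", 1:30)
    sets <- list(Wt = sample(pool, sample(0:20, 1L)),
                 He = sample(pool, sample(1:20, 1L)),
                 Ho = sample(pool, sample(1:20, 1L)))
    v <- venn_partition(sets)
    expect_equal(sum(v$sizes), length(unique(unlist(sets))))
    expect_equal(anyDuplicated(unlist(v$regions)), 0L)
  }
})

test_that("virtual_2d_map counts the configured tails", {
  rec <- data.frame(accession = paste0("P", 1:4),
                    mw_kda = c(50, 250, 5, 60), pi = c(7, 7, 7, 11))
  vm <- virtual_2d_map(rec)
  expect_equal(unname(vm$tails),
               c(1L, 1L, 0L, 1L))  # mw_low, mw_high, pi_low, pi_high
  all_mid <- data.frame(accession = "P1", mw_kda = 50, pi = 7)
  expect_equal(sum(virtual_2d_map(all_mid)$tails), 0L)
  with_na <- rbind(rec, data.frame(accession = "P5", mw_kda = NA, pi = 5))
  expect_equal(suppressMessages(virtual_2d_map(with_na))$n_missing, 1L)
})

test_that("location_summary fractions are over known locations only", {
  ann <- data.frame(accession = paste0("P", 1:4),
                    gene = paste0("G", 1:4),
                    location = c("cellular", "cellular", "membrane",
                                 "unknown"), stringsAsFactors = FALSE)
  ls <- location_summary(paste0("P", 1:4), ann)
  expect_equal(ls[["cellular"]], 2 / 3)
  expect_equal(ls[["membrane"]], 1 / 3)
  expect_equal(sum(ls), 1.0)
  expect_length(location_summary(character(0), ann), 0L)
  expect_length(location_summary("P4", ann), 0L)
})

test_that("cohort membership modes differ as documented", {
  # P1 appears once in 3 runs (aSpC 1/3 < 0.5): any_run yes, average no
  counts <- matrix(c(1L, 0L, 0L, 9L, 9L, 9L), nrow = 2L, byrow = TRUE,
                   dimnames = list(c("P1", "P2"), c("r1", "r2", "r3")))
  mat <- spc_matrix(counts, data.frame(
    run_id = c("r1", "r2", "r3"), subject_id = "S", cohort = "He",
    replicate_kind = "technical"))
  expect_setequal(cohort_members(mat, "He", "any_run"), c("P1", "P2"))
  expect_setequal(cohort_members(mat, "He", "average_list"), "P2")
})
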