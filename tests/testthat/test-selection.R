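test_that("dual-threshold filter applies min_reads per condition, inclusively", {
  counts <- make_counts(c(12, 8,
                          12, 12,
                          10, 10,
                          0, 0), samples = c("a", "b"))
  expr <- summarize_expression(counts, c(a = 1000, b = 1000))
  # g1 has one condition below threshold: excluded
  expect_false("g1" %in% filter_candidates(expr, counts, 50, 10))
  # constant transcript (CV 0) with all counts at the threshold: included
  expect_true("g3" %in% filter_candidates(expr, counts, 0.5, 10))
  # all-zero transcript can never pass
  expect_false("g4" %in% filter_candidates(expr, counts, 100, 0))
  # total mode sums across conditions
  expect_true("g1" %in%
                filter_candidates(expr, counts, 50, 20,
                                  min_reads_mode = "total"))
  expect_error(filter_candidates(expr, counts, 0, 10), "cv_max")
})

test_that("threshold comparisons are inclusive at the boundary on full precision", {
  counts <- make_counts(c(100, 150), samples = c("a", "b"))
  expr <- summarize_expression(counts, c(a = 1000, b = 1000))
  cv <- expr$cv_percent[["g1"]]   # exactly 20
  expect_equal(cv, 20)
  expect_true("g1" %in% filter_candidates(expr, counts, 20, 100))
  expect_false("g1" %in% filter_candidates(expr, counts, 20 - 1e-9, 100))
})

test_that("filtering matches the brute-force oracle on random tables", {
  for (seed in 1:10) {
    sim <- simulate_counts(n_invariant = 5, n_variable = 25, n_samples = 4,
                           seed = seed)
    expr <- summarize_expression(sim$counts, sim$lib_sizes)
    for (cv_max in c(5, 10, 30)) {
      got <- filter_candidates(expr, sim$counts, cv_max, 10)
      want <- oracle_filter(sim$counts, as.list(sim$lib_sizes), cv_max, 10)
      expect_equal(got, want)
    }
  }
})

test_that("ortholog collapsing keeps the highest mean RPMM per group", {
  counts <- make_counts(c(40, 40, 25, 25, 7, 7, 3, 3),
                        transcripts = c("t1", "t2", "t3", "t4"),
                        samples = c("a", "b"))
  expr <- summarize_expression(counts, c(a = 100, b = 100))
  ann <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    ortholog_id = c("Q1", "Q1", "Q2"),
                    description = NA_character_, stringsAsFactors = FALSE)
  # t1 (mean RPMM 4e5) beats t2 (2.5e5); t3 annotated alone; t4 unannotated
  expect_equal(collapse_orthologs(c("t1", "t2", "t3", "t4"), expr, ann),
               c("t1", "t3", "t4"))
  # empty annotation: identity
  expect_equal(collapse_orthologs(c("t1", "t2"), expr, NULL), c("t1", "t2"))
  # ties break to the lexicographically smallest id
  ann2 <- data.frame(transcript_id = c("t1", "t2"),
                     ortholog_id = c("Q", "Q"),
                     description = NA_character_, stringsAsFactors = FALSE)
  counts2 <- make_counts(c(10, 10, 10, 10), transcripts = c("t2", "t1"),
                         samples = c("a", "b"))
  expr2 <- summarize_expression(counts2, c(a = 100, b = 100))
  expect_equal(collapse_orthologs(c("t2", "t1"), expr2, ann2), "t1")
})

test_that("collapsing matches the per-group argmax oracle and is idempotent", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 30
    ids <- sprintf("t%02d", 1:n)
    counts <- matrix(rpois(n * 3, 200), nrow = n,
                     dimnames = list(ids, c("a", "b", "c"))) + 0
    expr <- summarize_expression(counts, c(a = 1e4, b = 1e4, c = 1e4))
    annotated <- sample(ids, 22)
    ann <- data.frame(transcript_id = annotated,
                      ortholog_id = sample(sprintf("Q%d", 1:8),
                                           length(annotated), replace = TRUE),
                      description = NA_character_, stringsAsFactors = FALSE)
    got <- collapse_orthologs(ids, expr, ann)
    expect_equal(got, oracle_collapse(ids, expr$mean_rpmm, ann))
    expect_equal(collapse_orthologs(got, expr, ann), got)
    # one survivor per represented group; unannotated stay
    n_groups <- length(unique(ann$ortholog_id)) + (n - length(annotated))
    expect_length(got, n_groups)
  }
})

test_that("Venn regions enumerate all membership signatures", {
  # identical sets: only the full intersection is populated
  r <- venn_regions(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(r, c(A = 0L, B = 0L, "A&B" = 2L))
  # nested chain
  r <- venn_regions(list(A = c("1", "2", "3"), B = c("1", "2"), C = "1"))
  expect_equal(r[["A"]], 1L)
  expect_equal(r[["A&B"]], 1L)
  expect_equal(r[["A&B&C"]], 1L)
  expect_equal(sum(r), 3L)
  expect_length(r, 7L)
  # six sets need the explicit escape hatch
  six <- setNames(rep(list("x"), 6), LETTERS[1:6])
  expect_error(venn_regions(six), "5 sets")
  expect_equal(sum(venn_regions(six, allow_many = TRUE)), 1L)
})

test_that("Venn counts match the per-element oracle on random sets", {
  set.seed(5)
  for (rep in 1:10) {
    universe <- sprintf("e%02d", 1:50)
    sets <- lapply(setNames(nm = c("S1", "S2", "S3")),
                   function(nm) sample(universe, sample(5:40, 1)))
    got <- venn_regions(sets)
    want <- oracle_venn(sets)
    for (sig in names(want)) expect_equal(got[[sig]], want[[sig]])
    expect_equal(sum(got), length(unique(unlist(sets))))
  }
})

test_that("the sweep covers the grid and candidate sets are nested", {
  sim <- simulate_counts(n_invariant = 10, n_variable = 90, seed = 17)
  expr <- summarize_expression(sim$counts, sim$lib_sizes)
  sweep <- run_sweep(expr, sim$counts, NULL,
                     cv_list = c(10, 20), min_reads_list = c(10, 50, 100))
  expect_s3_class(sweep, "rg_sweep")
  expect_length(sweep$grid, 6L)
  expect_named(sweep$venn, c("10", "20"))
  for (cv in c(10, 20)) {
    cells <- Filter(function(g) g$cv_max == cv, sweep$grid)
    sets <- lapply(cells, `[[`, "candidates")
    # raising min_reads only removes candidates
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
  # lowering cv_max never adds candidates at fixed min_reads
  for (mr in c(10, 50, 100)) {
    at <- Filter(function(g) g$min_reads == mr, sweep$grid)
    expect_true(all(at[[1]]$candidates %in% at[[2]]$candidates))
  }
  # a single pair degenerates to one cell and a one-set "Venn"
  one <- run_sweep(expr, sim$counts, NULL, cv_list = 10, min_reads_list = 10)
  expect_length(one$grid, 1L)
  expect_length(one$venn[["10"]], 1L)
})

test_that("sweep Venn membership uses ortholog ids when annotated", {
  counts <- make_counts(c(100, 100, 98, 102, 5, 5),
                        transcripts = c("t1", "t2", "t3"),
                        samples = c("a", "b"))
  expr <- summarize_expression(counts, c(a = 1000, b = 1000))
  ann <- data.frame(transcript_id = c("t1", "t2"),
                    ortholog_id = c("Q1", "Q1"),
                    description = NA_character_, stringsAsFactors = FALSE)
  sweep <- run_sweep(expr, counts, ann, cv_list = 10,
                     min_reads_list = c(0, 100))
  # t1/t2 collapse to the ortholog Q1 (tie broken to t1); t3 is its own group
  cell0 <- sweep$grid[[1]]
  expect_equal(cell0$candidates, c("t1", "t3"))
  expect_equal(cell0$venn_ids, c("Q1", "t3"))
  # at min_reads 100, t2 (98 reads in one sample) and t3 drop out
  cell100 <- sweep$grid[[2]]
  expect_equal(cell100$venn_ids, "Q1")
  venn <- sweep$venn[["10"]]
  expect_equal(venn[["0&100"]], 1L)  # Q1 shared
  expect_equal(venn[["0"]], 1L)      # t3 only at the lax threshold
  expect_equal(venn[["100"]], 0L)
})

test_that("planted invariant genes are recovered by the strictest cell", {
  sim <- simulate_counts(n_invariant = 3, n_variable = 97, n_samples = 6,
                         dispersion = 0, seed = 23)
  expr <- summarize_expression(sim$counts, sim$lib_sizes)
  sweep <- run_sweep(expr, sim$counts, NULL, cv_list = c(2, 20),
                     min_reads_list = c(10, 100))
  strict <- Filter(function(g) g$cv_max == 2 && g$min_reads == 100,
                   sweep$grid)[[1]]
  expect_setequal(strict$candidates,
                  names(sim$truth)[sim$truth == "invariant"])
})
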