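aln_df <- function(...) {
  rows <- list(...)
  data.frame(qname = vapply(rows, `[[`, "", 1),
             flag = as.integer(vapply(rows, function(r) r[[2]], numeric(1))),
             rname = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("properly-paired counting follows the 0x2/0x4 flag rule", {
  expect_length(count_paired_end(aln_df()), 0)

  # both mates proper on the same transcript: each record adds 1
  both <- aln_df(list("r1", 0x1 + 0x2 + 0x40, "T1"),
                 list("r1", 0x1 + 0x2 + 0x80, "T1"))
  expect_equal(count_paired_end(both), c(T1 = 2L))

  # discordant pair without 0x2: excluded entirely
  disc <- aln_df(list("r1", 0x1 + 0x40, "T1"),
                 list("r1", 0x1 + 0x80, "T2"))
  expect_length(count_paired_end(disc), 0)

  # multi-mapped proper pair counts on every transcript it hits
  mm <- aln_df(list("r1", 0x1 + 0x2 + 0x40, "T1"),
               list("r1", 0x1 + 0x2 + 0x80, "T1"),
               list("r1", 0x1 + 0x2 + 0x40 + 0x100, "T2"),
               list("r1", 0x1 + 0x2 + 0x80 + 0x100, "T2"))
  expect_equal(count_paired_end(mm), c(T1 = 2L, T2 = 2L))
  expect_equal(count_paired_end(mm, primary_only = TRUE), c(T1 = 2L))
  expect_equal(count_paired_end(mm, unit = "fragment"), c(T1 = 1L, T2 = 1L))

  # proper flag with no reference is malformed input
  bad <- aln_df(list("r1", 0x1 + 0x2 + 0x40, "*"))
  expect_error(count_paired_end(bad), "malformed")
})

test_that("single-end counting tallies every mapped record", {
  two <- aln_df(list("r1", 0, "T1"), list("r1", 0x100, "T2"))
  expect_equal(count_single_end(two), c(T1 = 1L, T2 = 1L))
  unm <- aln_df(list("r1", 0x4, "*"))
  expect_length(count_single_end(unm), 0)
})

test_that("library size counts distinct mapped read units", {
  # one read, three alignment records: one unit
  multi <- aln_df(list("r1", 0, "T1"), list("r1", 0x100, "T2"),
                  list("r1", 0x100, "T3"))
  expect_equal(library_size(multi), 1L)
  # paired read with both mates mapped: two units
  pair <- aln_df(list("r1", 0x1 + 0x2 + 0x40, "T1"),
                 list("r1", 0x1 + 0x2 + 0x80, "T1"))
  expect_equal(library_size(pair), 2L)
  expect_error(library_size(aln_df(list("r1", 0x4, "*"))), "positive")
})

test_that("counting agrees with the per-record oracle on random streams", {
  for (seed in 1:10) {
    aln <- random_alignments(200, n_refs = 4, seed = seed)
    expect_equal(count_paired_end(aln)[order(names(count_paired_end(aln)))],
                 oracle_count_paired(aln))
    expect_equal(count_single_end(aln)[order(names(count_single_end(aln)))],
                 oracle_count_single(aln))
    expect_equal(library_size(aln), oracle_library_size(aln))
    # multi-mapping inflates counts, never deflates
    expect_gte(sum(count_single_end(aln)), library_size(aln))
    # record order never matters
    shuf <- aln[sample.int(nrow(aln)), ]
    expect_equal(count_paired_end(shuf), count_paired_end(aln))
  }
})

test_that("the SAM reader keeps QNAME/FLAG/RNAME and skips headers", {
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:T1\tLN:1000",
               "r1\t99\tT1\t1\t255\t50M\t=\t100\t149\tACGT\tFFFF",
               "r1\t147\tT1\t100\t255\t50M\t=\t1\t-149\tACGT\tFFFF"), tf)
  aln <- read_sam(tf)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$qname, c("r1", "r1"))
  expect_equal(aln$flag, c(99L, 147L))
  expect_equal(count_paired_end(aln), c(T1 = 2L))

  writeLines("r1\t99", tf)
  expect_error(read_sam(tf), "malformed")
})

test_that("SAM files assemble into a count table with library sizes", {
  dir <- withr::local_tempdir()
  for (s in 1:3) {
    fx <- simulate_sam(n_pairs = 60, n_refs = 4, seed = s)
    writeLines(fx$sam, file.path(dir, sprintf("cond%d.sam", s)))
  }
  res <- count_sam_files(file.path(dir, sprintf("cond%d.sam", 1:3)))
  expect_equal(colnames(res$counts), sprintf("cond%d", 1:3))
  expect_true(all(res$lib_sizes > 0))
  fx1 <- simulate_sam(n_pairs = 60, n_refs = 4, seed = 1)
  expect_equal(unname(res$counts[names(fx1$expected_paired), "cond1"]),
               unname(as.numeric(fx1$expected_paired)))
})
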