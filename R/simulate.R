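#' Simulate a count table with planted invariant genes
#'
#' Generates a transcripts-by-samples count matrix in which a known subset
#' of genes has constant relative abundance across samples — the ground
#' truth for reference-gene recovery — while the rest vary. An invariant
#' gene `g` with relative abundance `p_g` receives counts with mean
#' `p_g * L_s` in a sample of library size `L_s`, so its expected RPMM,
#' `10^6 * p_g`, is the same in every sample no matter how heterogeneous
#' the sequencing depths are. A variable gene additionally gets an
#' independent per-sample fold factor drawn uniformly from
#' `fold_change_range`, which makes its RPMM fluctuate across samples.
#'
#' Counts are drawn from a negative binomial parameterized by mean and
#' dispersion (`Var = mu + dispersion * mu^2`), the standard RNA-seq count
#' model; as `dispersion` approaches 0 the noise tends to Poisson, and at
#' exactly 0 counts are the deterministic `round(mean)`, so planted genes
#' become (up to integer rounding) exactly proportional to library size.
#'
#' Defaults draw 500 genes (20 planted invariant, 480 variable) over 6
#' samples with library sizes spread up to threefold around 10^5 reads,
#' base relative abundances log-uniform in [0.005, 0.05] and folds in
#' [1, 4] — conditions under which the default selection thresholds
#' (CV <= 10%, >= 10 reads per condition) are expected to recover the
#' planted set.
#'
#' @param n_invariant Number of planted invariant genes.
#' @param n_variable Number of variable genes.
#' @param n_samples Number of samples (conditions), at least 2.
#' @param library_sizes Optional vector of positive library sizes (length
#'   `n_samples`); when `NULL`, drawn uniformly from `library_size_range`.
#' @param library_size_range Range the library sizes are drawn from.
#' @param base_abundance_range Range of per-gene relative abundances
#'   (log-uniform draw).
#' @param fold_change_range Range of the per-sample fold factors applied to
#'   variable genes (uniform draw).
#' @param dispersion Negative-binomial dispersion; 0 for deterministic
#'   counts.
#' @param seed Integer seed; all randomness flows through it.
#' @return List of class `rg_simulation` with `counts` (matrix),
#'   `lib_sizes` (named vector — the nominal depths used as RPMM
#'   denominators), and `truth` (named character vector,
#'   `"invariant"`/`"variable"` per transcript).
#' @export
simulate_counts <- function(n_invariant = 20L, n_variable = 480L,
                            n_samples = 6L, library_sizes = NULL,
                            library_size_range = c(1e5, 3e5),
                            base_abundance_range = c(0.005, 0.05),
                            fold_change_range = c(1, 4),
                            dispersion = 0.001, seed = NULL) {
  if (n_invariant < 0L || n_variable < 0L || n_invariant + n_variable < 1L) {
    stop("need at least one gene", call. = FALSE)
  }
  if (n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  if (any(base_abundance_range <= 0) || diff(base_abundance_range) < 0) {
    stop("base_abundance_range must be positive and ordered", call. = FALSE)
  }
  if (any(fold_change_range <= 0) || diff(fold_change_range) < 0) {
    stop("fold_change_range must be positive and ordered", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  if (is.null(library_sizes)) {
    library_sizes <- round(stats::runif(n_samples, library_size_range[1L],
                                        library_size_range[2L]))
  }
  if (length(library_sizes) != n_samples || any(library_sizes <= 0)) {
    stop("library_sizes must be ", n_samples, " positive values",
         call. = FALSE)
  }
  sample_ids <- names(library_sizes)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(n_samples))
  lib_sizes <- stats::setNames(as.numeric(library_sizes), sample_ids)

  n_genes <- n_invariant + n_variable
  ids <- sprintf("tx%05d", seq_len(n_genes))
  truth <- stats::setNames(
    rep(c("invariant", "variable"), c(n_invariant, n_variable)), ids)

  draw_abundance <- function(n) {
    exp(stats::runif(n, log(base_abundance_range[1L]),
                     log(base_abundance_range[2L])))
  }
  p <- draw_abundance(n_genes)
  mu <- outer(p, lib_sizes)
  if (n_variable > 0L) {
    folds <- matrix(stats::runif(n_variable * n_samples,
                                 fold_change_range[1L],
                                 fold_change_range[2L]),
                    nrow = n_variable)
    mu[n_invariant + seq_len(n_variable), ] <-
      mu[n_invariant + seq_len(n_variable), , drop = FALSE] * folds
  }
  counts <- if (dispersion == 0) {
    round(mu)
  } else {
    matrix(as.numeric(stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / dispersion)),
           nrow = n_genes)
  }
  dimnames(counts) <- list(ids, sample_ids)
  structure(list(counts = counts, lib_sizes = lib_sizes, truth = truth),
            class = "rg_simulation")
}

#' @export
print.rg_simulation <- function(x, ...) {
  cat(sprintf("Simulated count table: %d transcripts (%d invariant) x %d samples\n",
              nrow(x$counts), sum(x$truth == "invariant"), ncol(x$counts)))
  cat("Library sizes:",
      paste(sprintf("%s=%.0f", names(x$lib_sizes), x$lib_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write simulation artifacts
#'
#' Writes `counts.tsv`, `library_sizes.tsv` and `truth.tsv` (transcript ID
#' and its invariant/variable label) in the dialects the I/O module reads.
#'
#' @param sim An `rg_simulation` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rg_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  write_count_table(sim$counts, counts_path)
  lib_path <- file.path(dir, "library_sizes.tsv")
  writeLines(c("sample_id\tmapped_reads",
               sprintf("%s\t%.0f", names(sim$lib_sizes), sim$lib_sizes)),
             lib_path)
  truth_path <- file.path(dir, "truth.tsv")
  writeLines(c("transcript_id\tstatus",
               sprintf("%s\t%s", names(sim$truth), sim$truth)),
             truth_path)
  invisible(c(counts_path, lib_path, truth_path))
}

#' Simulate a SAM alignment stream with known expected counts
#'
#' Emits well-formed SAM text for `n_pairs` read pairs over `n_refs`
#' reference transcripts, together with the expected per-transcript counts
#' and library size under the counting contracts, computed record by record
#' on the generator side. A fraction of pairs is properly paired (flag 0x2
#' on both mates); the rest are either discordant (both mates mapped to
#' different transcripts, no 0x2) or have both mates unmapped. A fraction
#' of the mapped pairs additionally aligns to 1–2 extra transcripts,
#' reported as secondary records (flag 0x100), emulating report-all
#' multi-mapping.
#'
#' @param n_pairs Number of read pairs.
#' @param n_refs Number of reference transcripts (`T1`, `T2`, ...).
#' @param proper_fraction Probability that a pair is properly paired.
#' @param multimap_fraction Probability that a mapped pair multi-maps.
#' @param seed Integer seed.
#' @return List with `sam` (character vector of SAM lines, header
#'   included), `records` (the parsed-form data frame), and the
#'   generator-side expectations `expected_paired`, `expected_single`
#'   (named integer vectors) and `expected_library_size`.
#' @export
simulate_sam <- function(n_pairs = 200L, n_refs = 5L, proper_fraction = 0.9,
                         multimap_fraction = 0.2, seed = NULL) {
  if (n_pairs < 0L || n_refs < 1L) {
    stop("need n_pairs >= 0 and n_refs >= 1", call. = FALSE)
  }
  if (proper_fraction < 0 || proper_fraction > 1 ||
      multimap_fraction < 0 || multimap_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  refs <- sprintf("T%d", seq_len(n_refs))

  qname <- character(0); flag <- integer(0); rname <- character(0)
  add <- function(q, f, r) {
    qname <<- c(qname, q); flag <<- c(flag, f); rname <<- c(rname, r)
  }
  for (i in seq_len(n_pairs)) {
    q <- sprintf("read%05d", i)
    proper <- stats::runif(1) < proper_fraction
    if (proper) {
      targets <- sample(refs, 1L)
      if (n_refs > 1L && stats::runif(1) < multimap_fraction) {
        extra <- sample(setdiff(refs, targets),
                        min(sample(1:2, 1L), n_refs - 1L))
        targets <- c(targets, extra)
      }
      for (k in seq_along(targets)) {
        sec <- if (k == 1L) 0L else 0x100L
        add(q, bitwOr(0x1L + 0x2L + 0x40L, sec), targets[k])
        add(q, bitwOr(0x1L + 0x2L + 0x80L, sec), targets[k])
      }
    } else if (n_refs > 1L && stats::runif(1) < 0.5) {
      # discordant: mates mapped to different transcripts, no 0x2
      pick <- sample(refs, 2L)
      add(q, 0x1L + 0x40L, pick[1L])
      add(q, 0x1L + 0x80L, pick[2L])
    } else {
      add(q, 0x1L + 0x4L + 0x8L + 0x40L, "*")
      add(q, 0x1L + 0x4L + 0x8L + 0x80L, "*")
    }
  }
  records <- data.frame(qname = qname, flag = flag, rname = rname,
                        stringsAsFactors = FALSE)

  # generator-side brute-force expectations, one record at a time
  expected_paired <- stats::setNames(integer(length(refs)), refs)
  expected_single <- stats::setNames(integer(length(refs)), refs)
  units <- character(0)
  for (i in seq_len(nrow(records))) {
    f <- records$flag[i]; r <- records$rname[i]
    mapped <- bitwAnd(f, 0x4L) == 0L && r != "*"
    if (mapped) {
      expected_single[r] <- expected_single[r] + 1L
      if (bitwAnd(f, 0x2L) > 0L) {
        expected_paired[r] <- expected_paired[r] + 1L
      }
      mate <- if (bitwAnd(f, 0x40L) > 0L) "/1"
              else if (bitwAnd(f, 0x80L) > 0L) "/2" else ""
      units <- union(units, paste0(records$qname[i], mate))
    }
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:1000", refs))
  body <- if (nrow(records)) {
    mapped <- records$rname != "*"
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            records$qname, records$flag, records$rname,
            ifelse(mapped, 1L, 0L), ifelse(mapped, 255L, 0L),
            ifelse(mapped, "50M", "*"))
  } else {
    character(0)
  }
  list(sam = c(header, body),
       records = records,
       expected_paired = expected_paired[expected_paired > 0L],
       expected_single = expected_single[expected_single > 0L],
       expected_library_size = length(units))
}
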