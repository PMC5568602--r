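#' RPMM normalization
#'
#' Converts raw counts to reads per mapped million: each count is divided by
#' the library size (transcriptome-mapped reads) of its sample and scaled by
#' 10^6. Because a transcript is only ever compared with itself across
#' samples, no length normalization is applied; every count in a
#' transcript's row would be divided by the same constant, leaving the
#' cross-sample comparison unchanged.
#'
#' @param counts Count matrix (see [read_count_table()]).
#' @param lib_sizes Named numeric vector of positive library sizes covering
#'   every sample of `counts`. When `NULL`, column sums of the count table
#'   are used. Column sums over-state the true denominator when reads were
#'   mapped multi-hit (each read may appear under several transcripts), so
#'   pass explicit sizes when they are known.
#' @return Numeric matrix of RPMM values, same dimnames as `counts`, full
#'   floating-point precision.
#' @export
#' @examples
#' m <- matrix(c(50, 100, 25, 50), 2, dimnames = list(c("g1", "g2"),
#'                                                    c("a", "b")))
#' rpmm_normalize(m, c(a = 125000, b = 250000))
rpmm_normalize <- function(counts, lib_sizes = NULL) {
  validate_count_table(counts)
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  sweep(counts, 2L, lib_sizes[colnames(counts)], `/`) * 1e6
}

resolve_lib_sizes <- function(counts, lib_sizes) {
  if (is.null(lib_sizes)) {
    return(colSums(counts))
  }
  if (is.null(names(lib_sizes))) {
    if (length(lib_sizes) != ncol(counts)) {
      stop("unnamed lib_sizes must have one entry per sample", call. = FALSE)
    }
    names(lib_sizes) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(lib_sizes))
  if (length(missing)) {
    stop("no library size for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(lib_sizes) || any(lib_sizes <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  lib_sizes
}

#' Coefficient of variation, percent
#'
#' The stability statistic: the ratio of the standard deviation to the mean,
#' expressed as a percentage. The standard deviation is the population form
#' (divisor `n`, not `n - 1`); the small set of conditions is treated as the
#' complete universe of interest, not a sample from a larger one. When the
#' mean is zero (an all-zero expression row) the CV is undefined and `NA` is
#' returned.
#'
#' @param values Numeric vector of non-negative values, length at least 2.
#' @return CV as a percentage, or `NA_real_` when the mean is zero.
#' @export
#' @examples
#' cv_percent(c(205, 209, 206, 208, 177, 154)) # ~10.72
#' cv_percent(c(5, 5, 5))                      # 0
cv_percent <- function(values) {
  if (length(values) < 2L) {
    stop("CV needs at least 2 values", call. = FALSE)
  }
  if (anyNA(values)) stop("CV input contains missing values", call. = FALSE)
  if (any(values < 0)) stop("CV input must be non-negative", call. = FALSE)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sqrt(mean((values - m)^2)) / m
}

#' Per-transcript expression summary: RPMM, mean RPMM and CV
#'
#' Normalizes a count table to RPMM and computes, for every transcript, the
#' arithmetic mean of its RPMM values and the population coefficient of
#' variation across samples. This summary is the input to candidate
#' filtering and ranking.
#'
#' @inheritParams rpmm_normalize
#' @return An object of class `rg_expression`: a list with elements `rpmm`
#'   (matrix), `mean_rpmm` and `cv_percent` (named vectors, `cv_percent` is
#'   `NA` for all-zero transcripts), `lib_sizes`, and `lib_sizes_source`
#'   (`"given"` or `"column_sums"`).
#' @seealso [cv_percent()], [filter_candidates()], [run_sweep()]
#' @export
summarize_expression <- function(counts, lib_sizes = NULL) {
  validate_count_table(counts)
  source <- if (is.null(lib_sizes)) "column_sums" else "given"
  lib_sizes <- resolve_lib_sizes(counts, lib_sizes)
  rpmm <- rpmm_normalize(counts, lib_sizes)
  m <- rowMeans(rpmm)
  v <- rowMeans((rpmm - m)^2)
  cv <- ifelse(m == 0, NA_real_, 100 * sqrt(v) / m)
  names(cv) <- rownames(rpmm)
  structure(list(rpmm = rpmm,
                 mean_rpmm = m,
                 cv_percent = cv,
                 lib_sizes = lib_sizes[colnames(counts)],
                 lib_sizes_source = source),
            class = "rg_expression")
}

#' @export
print.rg_expression <- function(x, ...) {
  cat(sprintf("Expression summary: %d transcripts x %d samples\n",
              nrow(x$rpmm), ncol(x$rpmm)))
  cat(sprintf("Library sizes (%s): %s\n", x$lib_sizes_source,
              paste(sprintf("%s=%.0f", names(x$lib_sizes), x$lib_sizes),
                    collapse = ", ")))
  defined <- !is.na(x$cv_percent)
  if (any(defined)) {
    cat(sprintf("CV%% range over %d expressed transcripts: %.2f - %.2f\n",
                sum(defined), min(x$cv_percent[defined]),
                max(x$cv_percent[defined])))
  }
  invisible(x)
}

#' Suggested minimum-read threshold
#'
#' A useful starting point for the minimum counted-reads filter: 0.00003
#' times the lowest library size of the experiment. The value is returned
#' unrounded; `ceiling()` it to obtain an integer threshold.
#'
#' @param lib_sizes Numeric vector of positive library sizes.
#' @return `0.00003 * min(lib_sizes)`.
#' @export
#' @examples
#' suggest_min_reads(c(8859088, 12678437)) # 265.77264
suggest_min_reads <- function(lib_sizes) {
  if (!length(lib_sizes)) stop("no library sizes given", call. = FALSE)
  if (anyNA(lib_sizes) || any(lib_sizes <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  0.00003 * min(lib_sizes)
}
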