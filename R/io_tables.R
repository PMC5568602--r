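#' Read a transcripts-by-conditions count table
#'
#' Loads a delimited text file whose first row names the samples
#' (experimental conditions), whose first column holds transcript
#' identifiers, and whose cells are raw read counts. The header row may or
#' may not carry a label for the identifier column; both layouts are
#' accepted.
#'
#' Counts must be non-negative integers. Values written with a decimal point
#' that are still integral (such as `"3.0"`, an exporter quirk) are accepted
#' with a warning; genuinely fractional, negative, missing or non-numeric
#' cells are rejected with the offending row and column named.
#'
#' @param path Path to the count table.
#' @param sep Field delimiter; tab by default, `","` for CSV exports.
#' @return A numeric matrix of counts with transcript IDs as row names and
#'   sample IDs as column names, in file order.
#' @seealso [write_count_table()], [summarize_expression()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\ts1\ts2", "g1\t3\t5", "g2\t0\t7"), tf)
#' read_count_table(tf)
read_count_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("count table file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2L) {
    stop("count table must contain a header row and at least one transcript",
         call. = FALSE)
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]

  widths <- lengths(body)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, widths[bad], widths[1L]), call. = FALSE)
  }
  width <- widths[1L]
  if (width < 3L) {
    stop("count table needs at least 2 sample columns", call. = FALSE)
  }

  sample_ids <- if (length(header) == width) {
    header[-1L]
  } else if (length(header) == width - 1L) {
    header
  } else {
    stop(sprintf("header has %d fields but data rows have %d",
                 length(header), width), call. = FALSE)
  }

  transcript_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), byrow = TRUE)

  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(!nzchar(cells) | is.na(vals))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("non-numeric or missing count for transcript '%s', sample '%s'",
                 transcript_ids[i], sample_ids[j]), call. = FALSE)
  }
  vals <- matrix(vals, nrow = nrow(cells))
  neg <- which(vals < 0)
  if (length(neg)) {
    i <- ((neg[1L] - 1L) %% nrow(vals)) + 1L
    j <- ((neg[1L] - 1L) %/% nrow(vals)) + 1L
    stop(sprintf("negative count for transcript '%s', sample '%s'",
                 transcript_ids[i], sample_ids[j]), call. = FALSE)
  }
  nonint <- abs(vals - round(vals)) > 1e-8
  if (any(nonint)) {
    k <- which(nonint)[1L]
    i <- ((k - 1L) %% nrow(vals)) + 1L
    j <- ((k - 1L) %/% nrow(vals)) + 1L
    stop(sprintf("non-integer count %s for transcript '%s', sample '%s'",
                 cells[k], transcript_ids[i], sample_ids[j]), call. = FALSE)
  }
  decimal_form <- grepl("[.eE]", cells)
  if (any(decimal_form)) {
    warning(sprintf("%d count(s) written in decimal form were coerced to integers",
                    sum(decimal_form)), call. = FALSE)
  }

  counts <- matrix(round(vals), nrow = nrow(vals),
                   dimnames = list(transcript_ids, sample_ids))
  validate_count_table(counts)
}

#' Validate a count matrix
#'
#' Checks the count-table contract: a numeric matrix of non-negative
#' integral values with unique transcript row names, unique sample column
#' names, at least one transcript and at least two samples (a coefficient of
#' variation over one sample is meaningless).
#'
#' @param counts Numeric matrix, transcripts in rows and samples in columns.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (nrow(counts) < 1L) stop("count table has no transcripts", call. = FALSE)
  if (ncol(counts) < 2L) {
    stop("count table needs at least 2 samples", call. = FALSE)
  }
  ids <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(ids) || is.null(samples)) {
    stop("counts must carry transcript row names and sample column names",
         call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate transcript ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- samples[duplicated(samples)]
  if (length(dup)) {
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  counts
}

#' Write a count table
#'
#' Inverse of [read_count_table()]: writes a tab-delimited file with a
#' `transcript_id` header column so that reading it back yields an
#' identical matrix.
#'
#' @param counts Count matrix as returned by [read_count_table()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  validate_count_table(counts)
  header <- paste(c("transcript_id", colnames(counts)), collapse = sep)
  body <- paste(rownames(counts),
                apply(counts, 1L, function(r) {
                  paste(sprintf("%.0f", r), collapse = sep)
                }),
                sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a transcript-to-ortholog annotation table
#'
#' The annotation table maps transcript identifiers to a reference ID of an
#' orthologous gene, so that redundant transcripts of the same gene can be
#' collapsed. It is tab-delimited with two mandatory columns (transcript ID,
#' ortholog ID) and an optional third column holding a free-text
#' description. A header row starting with `transcript_id` is skipped if
#' present. Transcripts absent from the table are simply treated as their
#' own group downstream; they need not be listed.
#'
#' @param path Path to the annotation table.
#' @param sep Field delimiter.
#' @return A data frame with columns `transcript_id`, `ortholog_id` and
#'   `description` (`NA` when the file has no third column).
#' @seealso [collapse_orthologs()]
#' @export
read_annotation_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("annotation table file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (length(fields) && identical(fields[[1L]][1L], "transcript_id")) {
    fields <- fields[-1L]
  }
  if (!length(fields)) {
    return(data.frame(transcript_id = character(), ortholog_id = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  # strsplit drops trailing empty fields: a row "t2<TAB>" still has a second
  # (empty) column, which must be rejected as an empty ortholog, not as a
  # missing column
  n_seps <- lengths(gregexpr(sep, lines, fixed = TRUE)) *
    (regexpr(sep, lines, fixed = TRUE) > 0L)
  n_seps <- utils::tail(n_seps, length(fields))
  if (any(n_seps < 1L)) {
    bad <- which(n_seps < 1L)[1L]
    stop(sprintf("annotation row %d has fewer than 2 columns", bad),
         call. = FALSE)
  }
  fields <- lapply(fields, function(f) c(f, "", "")[1:3])
  transcript_id <- vapply(fields, `[[`, character(1L), 1L)
  ortholog_id <- vapply(fields, `[[`, character(1L), 2L)
  description <- vapply(fields, function(f) {
    if (length(f) >= 3L && nzchar(f[3L])) f[3L] else NA_character_
  }, character(1L))

  dup <- transcript_id[duplicated(transcript_id)]
  if (length(dup)) {
    stop("duplicate transcript ID(s) in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(ortholog_id)
  if (any(empty)) {
    stop("empty ortholog ID for transcript(s): ",
         paste(transcript_id[empty], collapse = ", "), call. = FALSE)
  }
  data.frame(transcript_id = transcript_id, ortholog_id = ortholog_id,
             description = description, stringsAsFactors = FALSE)
}

#' Read a per-sample library-size table
#'
#' Two tab-delimited columns: sample ID and the number of
#' transcriptome-mapped reads of that sample (the RPMM denominator). A
#' header row starting with `sample_id` is skipped if present.
#'
#' @param path Path to the library-size table.
#' @param sep Field delimiter.
#' @return Named numeric vector of positive library sizes.
#' @export
read_library_sizes <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("library-size file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (length(fields) && identical(fields[[1L]][1L], "sample_id")) {
    fields <- fields[-1L]
  }
  if (!length(fields)) stop("library-size file is empty", call. = FALSE)
  if (any(lengths(fields) < 2L)) {
    stop("library-size rows need 2 columns: sample_id<TAB>mapped_reads",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  sizes <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  if (anyNA(sizes) || any(sizes <= 0)) {
    stop("library sizes must be positive numbers", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ID(s) in library-size file", call. = FALSE)
  }
  stats::setNames(sizes, ids)
}
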