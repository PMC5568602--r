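#' Read SAM alignment records (minimal)
#'
#' A deliberately minimal SAM text reader: header lines (`@...`) are
#' skipped and only the three fields the counting stage needs are kept —
#' QNAME (read name), FLAG (SAM bit-field) and RNAME (reference transcript,
#' `*` when unmapped). CIGAR strings, positions and qualities are ignored;
#' counting here is per-reference, not per-coordinate.
#'
#' @param path Path to a SAM text file.
#' @return A data frame of alignment records with columns `qname`
#'   (character), `flag` (integer) and `rname` (character).
#' @seealso [count_paired_end()], [count_single_end()], [library_size()]
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("malformed SAM record at line %d: fewer than 3 fields",
                 which(short)[1L]), call. = FALSE)
  }
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  if (anyNA(flag) || any(flag < 0L)) {
    stop("malformed SAM FLAG field (must be a non-negative integer)",
         call. = FALSE)
  }
  data.frame(qname = vapply(fields, `[[`, character(1L), 1L),
             flag = flag,
             rname = vapply(fields, `[[`, character(1L), 3L),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln) {
  need <- c("qname", "flag", "rname")
  if (!is.data.frame(aln) || !all(need %in% names(aln))) {
    stop("alignments must be a data frame with columns qname, flag, rname",
         call. = FALSE)
  }
  if (nrow(aln) && (anyNA(aln$flag) || any(aln$flag < 0L))) {
    stop("SAM flags must be non-negative integers", call. = FALSE)
  }
  aln
}

flag_set <- function(flag, bit) bitwAnd(flag, bit) > 0L

#' Count properly-paired reads per transcript
#'
#' The paired-end counting contract: an alignment record contributes 1 to
#' its reference transcript if and only if it is flagged properly paired
#' (bit 0x2, both ends concordant on the same transcript) and mapped (bit
#' 0x4 clear) — the record-level semantics of `samtools view -f2`. When the
#' aligner reported all alignments of a multi-mapping read, each alignment
#' record counts, so multi-mapped reads inflate counts on every transcript
#' they hit.
#'
#' @param aln Alignment records from [read_sam()] (or any data frame with
#'   `qname`, `flag`, `rname`).
#' @param unit `"record"` (default; each mate's record adds 1) or
#'   `"fragment"` (a read pair adds 1 per transcript it is properly paired
#'   on).
#' @param primary_only Drop secondary (0x100) and supplementary (0x800)
#'   records before counting. Off by default: when mapping was run in
#'   report-all mode, secondary records carry the extra transcripts of
#'   multi-mapped reads and are intended to count.
#' @return Named integer vector, counts per reference transcript;
#'   transcripts with no passing record are absent.
#' @export
count_paired_end <- function(aln, unit = c("record", "fragment"),
                             primary_only = FALSE) {
  unit <- match.arg(unit)
  validate_alignments(aln)
  if (!nrow(aln)) return(stats::setNames(integer(0), character(0)))
  proper <- flag_set(aln$flag, 0x2L)
  if (any(proper & aln$rname == "*")) {
    stop("malformed input: properly-paired record with no reference",
         call. = FALSE)
  }
  keep <- proper & !flag_set(aln$flag, 0x4L)
  if (primary_only) {
    keep <- keep & !flag_set(aln$flag, bitwOr(0x100L, 0x800L))
  }
  aln <- aln[keep, , drop = FALSE]
  if (!nrow(aln)) return(stats::setNames(integer(0), character(0)))
  if (unit == "fragment") {
    aln <- aln[!duplicated(paste0(aln$qname, "\r", aln$rname)), , drop = FALSE]
  }
  tally_rnames(aln$rname)
}

#' Count mapped reads per transcript (single-end)
#'
#' The single-end counting contract (long-read/454 path): every mapped
#' record (bit 0x4 clear) contributes 1 to its reference; no pairing filter
#' is applied and multi-mapped reads contribute once per alignment record.
#'
#' @inheritParams count_paired_end
#' @return Named integer vector of counts per reference transcript.
#' @export
count_single_end <- function(aln, primary_only = FALSE) {
  validate_alignments(aln)
  if (!nrow(aln)) return(stats::setNames(integer(0), character(0)))
  keep <- !flag_set(aln$flag, 0x4L) & aln$rname != "*"
  if (primary_only) {
    keep <- keep & !flag_set(aln$flag, bitwOr(0x100L, 0x800L))
  }
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tally_rnames(aln$rname[keep])
}

tally_rnames <- function(rnames) {
  tab <- table(rnames)
  stats::setNames(as.integer(tab), names(tab))
}

#' Library size: distinct mapped read units
#'
#' The RPMM denominator is the number of transcriptome-mapped reads of the
#' sample, each read counted once no matter how many transcripts it aligned
#' to. A read unit is a (read name, mate) pair — for paired-end data each
#' mapped mate counts as one read; for single-end data the read itself is
#' the unit.
#'
#' @inheritParams count_paired_end
#' @return Positive integer count of distinct mapped read units.
#' @export
library_size <- function(aln) {
  validate_alignments(aln)
  mapped <- !flag_set(aln$flag, 0x4L) & aln$rname != "*"
  if (!any(mapped)) {
    stop("no mapped reads: library size must be positive", call. = FALSE)
  }
  aln <- aln[mapped, , drop = FALSE]
  mate <- ifelse(flag_set(aln$flag, 0x40L), "/1",
                 ifelse(flag_set(aln$flag, 0x80L), "/2", ""))
  length(unique(paste0(aln$qname, mate)))
}

#' Assemble a count table from SAM files
#'
#' Runs the counting contract over one SAM file per sample and binds the
#' per-sample counts into a transcripts-by-samples matrix (zero where a
#' transcript received no reads in a sample), together with the per-sample
#' library sizes.
#'
#' @param paths Character vector of SAM file paths, one per sample.
#' @param sample_ids Sample names; default the file stems.
#' @param paired Use the properly-paired contract ([count_paired_end()]);
#'   otherwise [count_single_end()].
#' @param unit,primary_only Passed to [count_paired_end()].
#' @return List with `counts` (matrix, transcripts sorted by ID) and
#'   `lib_sizes` (named vector from [library_size()]).
#' @export
count_sam_files <- function(paths, sample_ids = NULL, paired = TRUE,
                            unit = "record", primary_only = FALSE) {
  if (!length(paths)) stop("no SAM files given", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths) || anyDuplicated(sample_ids)) {
    stop("sample IDs must be unique and match the number of SAM files",
         call. = FALSE)
  }
  per_sample <- lapply(paths, function(p) {
    aln <- read_sam(p)
    cnt <- if (paired) {
      count_paired_end(aln, unit = unit, primary_only = primary_only)
    } else {
      count_single_end(aln, primary_only = primary_only)
    }
    list(counts = cnt, lib = library_size(aln))
  })
  refs <- sort(unique(unlist(lapply(per_sample, function(s) names(s$counts)))))
  counts <- matrix(0, nrow = length(refs), ncol = length(sample_ids),
                   dimnames = list(refs, sample_ids))
  for (k in seq_along(per_sample)) {
    cnt <- per_sample[[k]]$counts
    counts[names(cnt), k] <- as.numeric(cnt)
  }
  lib_sizes <- stats::setNames(
    vapply(per_sample, function(s) as.numeric(s$lib), numeric(1L)),
    sample_ids)
  list(counts = counts, lib_sizes = lib_sizes)
}
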