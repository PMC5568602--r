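#' Filter candidate reference genes by the dual thresholds
#'
#' A transcript is a candidate when (1) its CV is defined and at most
#' `cv_max` — expression as invariant as possible — and (2) its raw read
#' count reaches `min_reads`, by default in every single sample, so that
#' expression is high enough everywhere for reliable PCR amplification.
#' Both comparisons are inclusive and are made on full-precision values,
#' never on rounded ones.
#'
#' @param expr Expression summary from [summarize_expression()].
#' @param counts The count matrix the summary was built from.
#' @param cv_max Maximum CV, percent, in (0, 100].
#' @param min_reads Minimum raw count threshold (non-negative).
#' @param min_reads_mode `"per-condition"` (default: every sample must reach
#'   `min_reads`) or `"total"` (the transcript's summed count must).
#' @return Character vector of passing transcript IDs, in table order.
#' @export
filter_candidates <- function(expr, counts, cv_max, min_reads,
                              min_reads_mode = c("per-condition", "total")) {
  min_reads_mode <- match.arg(min_reads_mode)
  stopifnot(inherits(expr, "rg_expression"))
  validate_count_table(counts)
  if (!identical(rownames(counts), rownames(expr$rpmm)) ||
      !identical(colnames(counts), colnames(expr$rpmm))) {
    stop("counts and expression summary cover different transcripts/samples",
         call. = FALSE)
  }
  if (length(cv_max) != 1L || is.na(cv_max) || cv_max <= 0) {
    stop("cv_max must be a single positive percentage", call. = FALSE)
  }
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 0) {
    stop("min_reads must be a single non-negative number", call. = FALSE)
  }
  cv_ok <- !is.na(expr$cv_percent) & expr$cv_percent <= cv_max
  reads_ok <- if (min_reads_mode == "per-condition") {
    rowSums(counts >= min_reads) == ncol(counts)
  } else {
    rowSums(counts) >= min_reads
  }
  rownames(counts)[cv_ok & reads_ok]
}

#' Collapse candidates to one transcript per ortholog group
#'
#' When the reference transcriptome over-fragments genes, several candidate
#' transcripts may annotate to the same orthologous gene. Among candidates
#' sharing an ortholog ID, only the one with the highest mean RPMM is
#' retained; candidates missing from the annotation map are kept unchanged
#' (each is its own group). Ties on mean RPMM are broken by the
#' lexicographically smallest transcript ID, so the result is deterministic.
#'
#' @param candidates Character vector of candidate transcript IDs.
#' @param expr Expression summary from [summarize_expression()].
#' @param annot Annotation data frame from [read_annotation_table()], or
#'   `NULL` for no collapsing.
#' @return Character vector of surviving transcript IDs (a subset of
#'   `candidates`, original order preserved).
#' @export
collapse_orthologs <- function(candidates, expr, annot = NULL) {
  stopifnot(inherits(expr, "rg_expression"))
  if (is.null(annot) || !nrow(annot) || !length(candidates)) {
    return(candidates)
  }
  group <- annot$ortholog_id[match(candidates, annot$transcript_id)]
  self <- is.na(group)
  group[self] <- paste0("\r__self__", candidates[self])
  mean_rpmm <- expr$mean_rpmm[candidates]
  keep <- unlist(lapply(split(seq_along(candidates), group), function(idx) {
    ids <- candidates[idx]
    best <- idx[mean_rpmm[idx] == max(mean_rpmm[idx])]
    best[order(candidates[best])][1L]
  }), use.names = FALSE)
  candidates[sort(keep)]
}

#' Ranked candidate report
#'
#' Builds the per-candidate report: transcript ID, RPMM in every sample,
#' CV, mean RPMM, and (when annotated) the ortholog best hit and its
#' description. Rows are ranked by ascending CV; ties fall back to
#' descending mean RPMM, then transcript ID, giving a total, reproducible
#' order.
#'
#' @inheritParams collapse_orthologs
#' @return Data frame with columns `transcript_id`, one RPMM column per
#'   sample, `cv_percent`, `mean_rpmm`, `best_hit`, `description`. Values
#'   are full precision; rounding happens only in
#'   [write_candidate_report()].
#' @export
candidate_report <- function(candidates, expr, annot = NULL) {
  stopifnot(inherits(expr, "rg_expression"))
  rpmm <- expr$rpmm[candidates, , drop = FALSE]
  cv <- expr$cv_percent[candidates]
  m <- expr$mean_rpmm[candidates]
  if (!is.null(annot) && nrow(annot)) {
    idx <- match(candidates, annot$transcript_id)
    best_hit <- annot$ortholog_id[idx]
    description <- annot$description[idx]
  } else {
    best_hit <- rep(NA_character_, length(candidates))
    description <- rep(NA_character_, length(candidates))
  }
  ord <- order(cv, -m, candidates)
  out <- data.frame(transcript_id = candidates, stringsAsFactors = FALSE)
  for (s in colnames(rpmm)) out[[s]] <- rpmm[, s]
  out$cv_percent <- cv
  out$mean_rpmm <- m
  out$best_hit <- best_hit
  out$description <- description
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

#' Write a ranked candidate report
#'
#' Tab-delimited, header always present (an empty candidate list yields a
#' header-only file). For display, per-sample RPMM and CV are printed to 2
#' decimals and mean RPMM to 1 decimal; the in-memory values keep full
#' precision.
#'
#' @param report Data frame from [candidate_report()], already ranked.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  fixed <- c("transcript_id", "cv_percent", "mean_rpmm", "best_hit",
             "description")
  samples <- setdiff(names(report), fixed)
  cols <- c("transcript_id", samples, "cv_percent", "mean_rpmm", "best_hit",
            "description")
  lines <- paste(cols, collapse = "\t")
  if (nrow(report)) {
    fmt <- function(x, digits) {
      ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
    }
    body <- report$transcript_id
    for (s in samples) body <- paste(body, fmt(report[[s]], 2L), sep = "\t")
    body <- paste(body,
                  fmt(report$cv_percent, 2L),
                  fmt(report$mean_rpmm, 1L),
                  ifelse(is.na(report$best_hit), "", report$best_hit),
                  ifelse(is.na(report$description), "", report$description),
                  sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Venn region counts over labeled sets
#'
#' Partitions the union of 1–5 labeled sets into its membership regions and
#' counts the elements in each. Regions are named by the sorted labels of
#' the sets an element belongs to, joined with `"&"` (e.g. `"10&50"` for
#' elements in the 10-read and 50-read sets but no other); all `2^k - 1`
#' non-empty signatures are reported, including zero counts.
#'
#' @param sets Named list of character vectors (duplicates within a set are
#'   ignored). More than 5 sets exceeds what a Venn diagram can show and is
#'   rejected unless `allow_many = TRUE`.
#' @param allow_many Permit more than 5 sets (counts only, no diagram
#'   semantics).
#' @return Named integer vector of region counts; the counts sum to the
#'   size of the union.
#' @export
#' @examples
#' venn_regions(list(A = c("1", "2", "3"), B = c("1", "2"), C = "1"))
venn_regions <- function(sets, allow_many = FALSE) {
  if (!is.list(sets) || !length(sets) || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("set labels must be unique", call. = FALSE)
  }
  if (length(sets) > 5L && !allow_many) {
    stop("more than 5 sets cannot be drawn as a Venn diagram; ",
         "use allow_many = TRUE for counts only", call. = FALSE)
  }
  labels <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  # every non-empty membership signature, in subset-size order
  k <- length(labels)
  signatures <- unlist(lapply(seq_len(k), function(size) {
    combos <- utils::combn(labels, size, simplify = FALSE)
    vapply(combos, function(cc) paste(sort(cc), collapse = "&"),
           character(1L))
  }))
  counts <- stats::setNames(integer(length(signatures)), signatures)
  if (length(universe)) {
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    membership <- matrix(membership, nrow = length(universe),
                         dimnames = list(NULL, labels))
    sig <- apply(membership, 1L, function(row) {
      paste(sort(labels[row]), collapse = "&")
    })
    tab <- table(sig)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Sweep the dual-threshold parameter grid
#'
#' Evaluates every (cv_max, min_reads) pair of the cross product, collapses
#' each candidate set to ortholog level when an annotation is supplied,
#' ranks each report by CV, and — per CV cutoff — computes Venn region
#' counts across the minimum-read sets so the effect of the read threshold
#' can be inspected at a glance. Venn membership compares ortholog IDs when
#' an annotation map is given (with unannotated transcripts standing for
#' themselves), transcript IDs otherwise.
#'
#' For a fixed CV cutoff the candidate sets are nested: raising `min_reads`
#' can only remove candidates, never add them.
#'
#' @inheritParams filter_candidates
#' @param annot Optional annotation data frame ([read_annotation_table()]).
#' @param cv_list Numeric vector of CV cutoffs (percent).
#' @param min_reads_list Numeric vector of minimum-read thresholds.
#' @param collapse_on `"auto"` (ortholog level when `annot` is given),
#'   `"ortholog"` or `"transcript"` — the identifier space used for Venn
#'   membership.
#' @return An object of class `rg_sweep`: `grid` is a list of cells, each
#'   holding `cv_max`, `min_reads`, the collapsed `candidates`, their
#'   `venn_ids`, and the ranked `report`; `venn` maps each CV cutoff (as a
#'   character key) to its region counts; `params` records the call.
#' @export
run_sweep <- function(expr, counts, annot = NULL, cv_list, min_reads_list,
                      min_reads_mode = c("per-condition", "total"),
                      collapse_on = c("auto", "ortholog", "transcript")) {
  min_reads_mode <- match.arg(min_reads_mode)
  collapse_on <- match.arg(collapse_on)
  if (!length(cv_list) || !length(min_reads_list)) {
    stop("cv_list and min_reads_list must be non-empty", call. = FALSE)
  }
  use_ortho <- switch(collapse_on,
                      auto = !is.null(annot) && nrow(annot) > 0,
                      ortholog = TRUE,
                      transcript = FALSE)
  grid <- list()
  venn <- list()
  for (cv_max in cv_list) {
    sets <- list()
    for (min_reads in min_reads_list) {
      ids <- filter_candidates(expr, counts, cv_max, min_reads,
                               min_reads_mode)
      ids <- collapse_orthologs(ids, expr, annot)
      venn_ids <- if (use_ortho && !is.null(annot) && nrow(annot)) {
        ortho <- annot$ortholog_id[match(ids, annot$transcript_id)]
        ifelse(is.na(ortho), ids, ortho)
      } else {
        ids
      }
      grid[[length(grid) + 1L]] <- list(
        cv_max = cv_max,
        min_reads = min_reads,
        candidates = ids,
        venn_ids = venn_ids,
        report = candidate_report(ids, expr, annot))
      sets[[format_param(min_reads)]] <- venn_ids
    }
    venn[[format_param(cv_max)]] <- venn_regions(sets,
                                                 allow_many = length(sets) > 5L)
  }
  structure(list(grid = grid, venn = venn,
                 params = list(cv_list = cv_list,
                               min_reads_list = min_reads_list,
                               min_reads_mode = min_reads_mode,
                               collapse_on = if (use_ortho) "ortholog"
                                             else "transcript")),
            class = "rg_sweep")
}

format_param <- function(x) {
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

#' @export
print.rg_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep: %d CV cutoff(s) x %d min-read threshold(s)\n",
              length(x$params$cv_list), length(x$params$min_reads_list)))
  for (cell in x$grid) {
    cat(sprintf("  cv_max=%s min_reads=%s: %d candidate(s)\n",
                format_param(cell$cv_max), format_param(cell$min_reads),
                length(cell$candidates)))
  }
  invisible(x)
}

#' Write all sweep artifacts to a directory
#'
#' One ranked TSV report per grid cell, named
#' `rg_cv<cv>_min<reads>.tsv`, plus a `venn_summary.json` mapping each CV
#' cutoff to its Venn region counts.
#'
#' @param sweep An `rg_sweep` object from [run_sweep()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "rg_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (cell in sweep$grid) {
    f <- file.path(dir, sprintf("rg_cv%s_min%s.tsv",
                                format_param(cell$cv_max),
                                format_param(cell$min_reads)))
    write_candidate_report(cell$report, f)
    written <- c(written, f)
  }
  venn_path <- file.path(dir, "venn_summary.json")
  venn <- lapply(sweep$venn, as.list)
  jsonlite::write_json(venn, venn_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, venn_path))
}
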