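# Independent brute-force oracles: deliberately naive, element-at-a-time
# recomputations of every contract, kept free of the package's vectorized
# code paths.

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  if (m == 0) return(NA_real_)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  100 * sqrt(ss / length(x)) / m
}

oracle_rpmm <- function(counts, lib_sizes) {
  out <- counts * 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      out[i, j] <- counts[i, j] * 1e6 / lib_sizes[[colnames(counts)[j]]]
    }
  }
  out
}

oracle_count_paired <- function(records) {
  counts <- list()
  for (i in seq_len(nrow(records))) {
    f <- records$flag[i]
    if (bitwAnd(f, 0x2) > 0 && bitwAnd(f, 0x4) == 0) {
      r <- records$rname[i]
      counts[[r]] <- (counts[[r]] %||% 0L) + 1L
    }
  }
  sort_by_name(unlist(counts))
}

oracle_count_single <- function(records) {
  counts <- list()
  for (i in seq_len(nrow(records))) {
    if (bitwAnd(records$flag[i], 0x4) == 0 && records$rname[i] != "*") {
      r <- records$rname[i]
      counts[[r]] <- (counts[[r]] %||% 0L) + 1L
    }
  }
  sort_by_name(unlist(counts))
}

sort_by_name <- function(x) {
  if (is.null(x)) x <- stats::setNames(integer(0), character(0))
  x[order(names(x))]
}

oracle_library_size <- function(records) {
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    f <- records$flag[i]
    if (bitwAnd(f, 0x4) == 0 && records$rname[i] != "*") {
      mate <- if (bitwAnd(f, 0x40) > 0) "/1"
              else if (bitwAnd(f, 0x80) > 0) "/2" else ""
      unit <- paste0(records$qname[i], mate)
      if (!(unit %in% seen)) seen <- c(seen, unit)
    }
  }
  length(seen)
}

oracle_filter <- function(counts, lib_sizes, cv_max, min_reads) {
  hits <- character(0)
  for (id in rownames(counts)) {
    rp <- numeric(0)
    for (s in colnames(counts)) {
      rp <- c(rp, counts[id, s] * 1e6 / lib_sizes[[s]])
    }
    cv <- oracle_cv(rp)
    if (is.na(cv) || cv > cv_max) next
    if (all(counts[id, ] >= min_reads)) hits <- c(hits, id)
  }
  hits
}

oracle_collapse <- function(candidates, mean_rpmm, annot) {
  groups <- list()
  for (id in candidates) {
    g <- annot$ortholog_id[annot$transcript_id == id]
    key <- if (length(g)) g else paste0("self:", id)
    groups[[key]] <- c(groups[[key]], id)
  }
  kept <- character(0)
  for (ids in groups) {
    best <- ids[mean_rpmm[ids] == max(mean_rpmm[ids])]
    kept <- c(kept, sort(best)[1])
  }
  candidates[candidates %in% kept]
}

oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- list()
  for (el in universe) {
    members <- sort(names(sets)[vapply(sets, function(s) el %in% s, TRUE)])
    sig <- paste(members, collapse = "&")
    counts[[sig]] <- (counts[[sig]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random alignment records independent of simulate_sam()
random_alignments <- function(n, n_refs = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refs <- paste0("T", seq_len(n_refs))
  qname <- sprintf("q%04d", sample.int(ceiling(n / 2), n, replace = TRUE))
  flag <- integer(n)
  rname <- character(n)
  for (i in seq_len(n)) {
    f <- 0x1
    if (runif(1) < 0.45) f <- f + 0x2
    unmapped <- runif(1) < 0.15
    if (unmapped) f <- f + 0x4 - (if (bitwAnd(f, 0x2) > 0) 0x2 else 0)
    f <- f + sample(c(0x40, 0x80), 1)
    if (!unmapped && runif(1) < 0.2) f <- f + 0x100
    flag[i] <- f
    rname[i] <- if (unmapped) "*" else sample(refs, 1)
  }
  data.frame(qname = qname, flag = flag, rname = rname,
             stringsAsFactors = FALSE)
}

make_counts <- function(values, transcripts = NULL, samples = NULL) {
  nc <- if (is.null(samples)) 2L else length(samples)
  m <- matrix(values, ncol = nc, byrow = TRUE)
  rownames(m) <- transcripts %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}
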