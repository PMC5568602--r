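#' Published per-sample RPMM anchor tables
#'
#' Two small curated tables of per-sample RPMM values for published
#' candidate reference genes, shipped with the package as plain TSV:
#' `"olive"` — 17 candidates across six olive reproductive-tissue
#' conditions (mature pollen, two pollen stages, three pistil stages) — and
#' `"arabidopsis"` — rubisco-dominated candidates for two Arabidopsis
#' accessions (Col-0 vs Kil-0) in three sequencing replicates. Each row
#' carries the published CV (percent, 2 decimals) and mean RPMM (1
#' decimal), so recomputing both from the per-sample values checks the
#' statistic conventions end to end; in particular only the population
#' (divisor-n) standard deviation reproduces the published CV column.
#'
#' @param which `"olive"` or `"arabidopsis"`.
#' @return A data frame; per-sample RPMM columns are `PM`, `PG1`, `PG5`,
#'   `S2`, `S3`, `S4` for olive and `Col_0`, `Kil_0` (plus a `replicate`
#'   index) for arabidopsis, alongside `cv_published` and
#'   `mean_rpmm_published`.
#' @export
#' @examples
#' oli <- published_rpmm("olive")
#' cv_percent(as.numeric(oli[1, c("PM", "PG1", "PG5", "S2", "S3", "S4")]))
published_rpmm <- function(which = c("olive", "arabidopsis")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   switch(which,
                          olive = "olive_reproductive_rpmm.tsv",
                          arabidopsis = "arabidopsis_flower_rpmm.tsv"),
                   package = "rgselect", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Sample columns of a published anchor table
#'
#' @param which `"olive"` or `"arabidopsis"`.
#' @return Character vector of the per-sample RPMM column names.
#' @export
published_rpmm_samples <- function(which = c("olive", "arabidopsis")) {
  switch(match.arg(which),
         olive = c("PM", "PG1", "PG5", "S2", "S3", "S4"),
         arabidopsis = c("Col_0", "Kil_0"))
}
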