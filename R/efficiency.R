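#' Published per-locus editing efficiencies
#'
#' Reported precise-deletion efficiencies (% of NGS samples) per rice locus
#' and strategy from the transgenic-plant study whose cohort statistics
#' this package reimplements; used to recompute strategy fold-changes.
#'
#' @param path Optional path to an alternative TSV with columns `locus`,
#'   `strategy`, `pct_precise`.
#' @return data.frame.
#' @export
load_reported_efficiencies <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reported_efficiencies.tsv",
                        package = "pegdel")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Fold change between two strategies at one locus
#'
#' @param tab data.frame from [load_reported_efficiencies()] (or a cohort
#'   table with the same columns).
#' @param locus Locus name.
#' @param num,den Strategy names for numerator and denominator.
#' @return Numeric fold change.
#' @examples
#' strategy_fold_change(load_reported_efficiencies(), "OsALS")  # 1.5
#' @export
strategy_fold_change <- function(tab, locus, num = "PDel", den = "PE3") {
  get1 <- function(strategy) {
    v <- tab$pct_precise[tab$locus == locus & tab$strategy == strategy]
    if (length(v) != 1L)
      stop(sprintf("no unique %s entry for locus %s", strategy, locus))
    v
  }
  get1(num) / get1(den)
}
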