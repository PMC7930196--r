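#' Packaged published summary tables
#'
#' Small plain-text fixtures of published summary tables for the
#' modern-vs-ancient mitogenome comparison: per-period difference counts
#' by macrohaplogroup, a compilation of literature rate estimates, and
#' rho-based coalescence ages under the two clock calibrations. These
#' are inputs for reproduction checks; the package recomputes derived
#' columns from them.
#'
#' @name fixtures
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mitotempo",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Per-period modern-ancient difference summary (published)
#'
#' Ten dated periods: mean age +/- sd (years BP), per-macrohaplogroup
#' mean difference, sd and pair count (`m_*`, `n_*`, `r_*` for
#' macrohaplogroups M, N, R), pooled totals, and the published expected
#' column.
#'
#' @return data.frame, one row per period (youngest first).
#' @export
period_difference_table <- function() {
  read_extdata("period_differences.tsv")
}

#' Literature compilation of mtDNA evolutionary rates (published)
#'
#' Rates and 95% intervals in units of 1e-8 substitutions per site per
#' year.
#'
#' @return data.frame with columns `rate, ci_low, ci_high, source`.
#' @export
literature_rate_table <- function() {
  read_extdata("literature_rates.tsv")
}

#' Rho-based coalescence ages under the two clocks (published)
#'
#' Coalescence ages in thousand years (95% intervals) for major
#' haplogroup founding events, under the modern purifying-selection
#' corrected clock ("soares", one mutation / 3624 yr) and the mean
#' ancient tip-dated clock ("amtdna", one mutation / 2454 yr).
#'
#' @return data.frame, one row per event.
#' @export
coalescence_age_table <- function() {
  read_extdata("coalescence_ages.tsv")
}
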