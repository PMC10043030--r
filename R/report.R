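#' Percentage from a count ratio
#'
#' @param numerator,denominator counts.
#' @param digits decimal places (default 1).
#' @return `100 * numerator / denominator`, rounded.
#' @export
ratio_percent <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round(100 * numerator / denominator, digits)
}

#' Reported tallies of the field campaign the defaults emulate
#'
#' The raw counts behind the headline data-coverage ratios of the field
#' study whose design the synthetic generator mirrors: scats containing
#' seeds of the focal tree out of all collected scats, visits where fruit
#' handling could be observed out of all visits with potential handling,
#' and first-year seedlings whose diameter was measured. These are inputs
#' (printed tallies), not outputs of this package.
#'
#' @return Data frame: `quantity`, `numerator`, `denominator`.
#' @export
study_tallies <- function() {
  data.frame(
    quantity = c("scats_with_focal_seeds", "handling_observed",
                 "seedlings_measured"),
    numerator = c(375, 766, 65),
    denominator = c(3632, 821, 253),
    stringsAsFactors = FALSE
  )
}

#' Data-coverage ratios from tallies
#'
#' @param tallies data frame with `numerator` and `denominator` columns
#'   (default [study_tallies()]).
#' @param digits decimal places for the percentage.
#' @return The tallies with a `percent` column appended.
#' @export
summary_ratios <- function(tallies = study_tallies(), digits = 1) {
  tallies$percent <- ratio_percent(tallies$numerator, tallies$denominator,
                                   digits)
  tallies
}
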