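#' Geographic unit universes
#'
#' Returns the set of unit labels (two-letter postal codes plus "DC") used at
#' the different analysis stages. Aggregate analyses are variously run on all
#' 50 states plus DC, on the 48 contiguous states plus DC, or on the 48
#' contiguous states alone, depending on which secondary data cover a unit.
#'
#' @param subset one of `"all51"` (50 states + DC), `"contiguous49"`
#'   (contiguous states + DC), `"contiguous48"` (contiguous states only).
#' @return character vector of unit labels.
#' @examples
#' length(us_units("contiguous48"))
#' @export
us_units <- function(subset = c("all51", "contiguous49", "contiguous48")) {
  subset <- match.arg(subset)
  all51 <- c(
    "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "DC", "FL", "GA", "HI",
    "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN",
    "MS", "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH",
    "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA",
    "WV", "WI", "WY"
  )
  switch(subset,
    all51 = all51,
    contiguous49 = setdiff(all51, c("AK", "HI")),
    contiguous48 = setdiff(all51, c("AK", "HI", "DC"))
  )
}

#' Big Five trait labels
#'
#' Default trait names used throughout the package.
#'
#' @return character vector of five trait labels.
#' @export
big_five <- function() {
  c("Conscientiousness", "Agreeableness", "Neuroticism", "Openness",
    "Extraversion")
}
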