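# Shipped reference data.

#' Reference cross-system contingency counts
#'
#' Pooled 2x2 contingency counts of matching and non-matching cold/warm
#' classifications between a dimictic reference reservoir (50.73 degrees N)
#' and thirteen other European aquatic systems (five dimictic lakes, five
#' Baltic Sea stations, three North Sea stations), from multi-decade
#' monitoring series. Two blocks: \code{constant_lake} uses the constant lake
#' threshold profile (3, 4, 14, 20 degC) for every system;
#' \code{site_specific} uses marine station-specific thresholds.
#'
#' @param thresholds \code{"constant_lake"}, \code{"site_specific"} or
#'   \code{"all"}.
#' @return a data frame with columns \code{thresholds}, \code{site},
#'   \code{system_class}, \code{ncc}, \code{nww}, \code{ncw}, \code{nwc}.
#' @examples
#' counts <- reference_contingency_counts()
#' tab <- contingency_2x2(counts$ncc[1], counts$nww[1],
#'                        counts$ncw[1], counts$nwc[1])
#' phi_coefficient(tab)
#' @export
reference_contingency_counts <- function(thresholds = c("all", "constant_lake",
                                                        "site_specific")) {
  thresholds <- match.arg(thresholds)
  path <- system.file("extdata", "coherence_reference_counts.csv",
                      package = "limnocw", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (thresholds != "all") df <- df[df$thresholds == thresholds, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Latitudes of the six reference lakes
#'
#' Decimal latitudes (degrees N) of the six dimictic lakes spanning the
#' 47-59 degree latitudinal gradient over which the radiation date-transfer
#' was validated: Greifensee, Saidenbach (the reference), Bautzen,
#' Scharmuetzelsee, Stechlinsee and Erken.
#'
#' @return a named numeric vector of latitudes.
#' @export
reference_lake_latitudes <- function() {
  c(Greifensee = 47 + 20 / 60,
    Saidenbach = 50 + 44 / 60,
    Bautzen = 51 + 12 / 60,
    Scharmuetzelsee = 52 + 15 / 60,
    Stechlinsee = 53 + 9 / 60,
    Erken = 59 + 31 / 60)
}
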