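#' @include AllClasses.R
NULL

#' @describeIn totalHeight sum of the three stacked section heights; the
#'   reference insert gives 3 + 10 + 4 = 17 mm, matching the depth of a
#'   24-well plate so the lid still closes.
#' @examples
#' totalHeight(insertGeometry())  # 17
#' @export
setMethod("totalHeight", "InsertGeometry", function(geom) {
  geom@topHeightMm + geom@midHeightMm + geom@bottomHeightMm
})

#' Theoretical area of the stamped cell-free zone
#'
#' Area of the circular zone the insert foot stamps into the monolayer,
#' \eqn{\pi d^2 / 4}. For the reference 5 mm foot this is 19.63 mm^2
#' (19.6 at one decimal), the value measured cell-free areas are validated
#' against.
#'
#' @param diameterMm zone diameter in millimetres (>= 0).
#' @return area in square millimetres.
#' @examples
#' theoreticalZoneArea(5)  # 19.63495
#' @export
theoreticalZoneArea <- function(diameterMm) {
  if (!is.numeric(diameterMm) || any(!is.finite(diameterMm)) ||
      any(diameterMm < 0)) {
    stop("zone diameter must be a non-negative finite number")
  }
  pi * diameterMm^2 / 4
}
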