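#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cf <- function(...) stop(sprintf(...), call. = FALSE)

#' Signed percent change, rounded to the nearest integer
#'
#' Computes `round(100 * (scenario - baseline) / baseline)`. Reductions come
#' out negative; reports conventionally quote their magnitude as a
#' "reduction".
#'
#' @param baseline baseline value, must be > 0
#' @param scenario scenario value
#' @return integer percent change (negative for reductions)
#' @examples
#' percent_change(172, 50)   # -71
#' percent_change(1.17, 0.83) # -29
#' @export
percent_change <- function(baseline, scenario) {
  if (any(baseline <= 0)) stop_cf("percent_change: baseline must be > 0")
  as.integer(round(100 * (scenario - baseline) / baseline))
}

## euclidean distance in km between (x, y) points given in km coordinates
point_dist_km <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
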