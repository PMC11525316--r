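#' Wrap an angle into the signed interval (-180, 180]
#'
#' The project-wide convention for circular errors: results are congruent to
#' the input modulo 360 and lie in \code{(-180, 180]} (so both +180 and -180
#' map to 180).
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Wrapped angles in degrees.
#' @examples
#' wrap_angle(350 - 10)  # -20
#' @export
wrap_angle <- function(angle) {
  if (any(!is.finite(angle))) stop("angles must be finite", call. = FALSE)
  w <- angle %% 360            # [0, 360)
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Absolute circular error between target and response
#'
#' \code{|wrap_angle(response - target)|}, in \code{[0, 180]} degrees.
#'
#' @param target,response Angles in degrees.
#' @return Absolute angular error in degrees.
#' @export
abs_error <- function(target, response) {
  abs(wrap_angle(response - target))
}

# unsigned circular distance between two degrees on the 360 circle
circ_dist <- function(a, b) abs(wrap_angle(a - b))
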