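#' Immobilized pH gradient of the first-dimension strip
#'
#' Linear pH gradient along the isoelectric-focusing strip; gel x coordinates
#' (fractions of strip length) map affinely onto pI. The study's strips are
#' linear pH 4--7, the default here.
#'
#' @param ph_min,ph_max pH at the acidic (x = 0) and basic (x = 1) strip ends.
#' @return object of class \code{ph_gradient}.
#' @export
ph_gradient <- function(ph_min = 4, ph_max = 7) {
  if (!(is.numeric(ph_min) && is.numeric(ph_max) && ph_min < ph_max))
    stop("need ph_min < ph_max")
  structure(list(ph_min = as.numeric(ph_min), ph_max = as.numeric(ph_max)),
            class = "ph_gradient")
}

#' Experimental pI from gel x coordinate
#'
#' @param x horizontal gel coordinate(s) in [0, 1].
#' @param gradient a [ph_gradient()].
#' @return pI in pH units; affine and monotone increasing in \code{x}.
#' @export
pi_from_x <- function(x, gradient = ph_gradient()) {
  stopifnot(inherits(gradient, "ph_gradient"))
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("x outside [0, 1]")
  gradient$ph_min + x * (gradient$ph_max - gradient$ph_min)
}

#' Molecular-mass marker ladder
#'
#' Calibration ladder for the second (SDS-PAGE) dimension: pairs of vertical
#' position \code{y} (fraction of gel height, increasing downwards) and
#' marker mass \code{mr_kda}. Migration is modelled as linear in log10(Mr),
#' the standard SDS-PAGE mobility model, so masses must be strictly
#' decreasing with \code{y}.
#'
#' @param y numeric vector of marker positions in [0, 1], strictly increasing.
#' @param mr_kda marker masses in kDa, strictly decreasing, all positive.
#' @return object of class \code{marker_ladder}.
#' @export
marker_ladder <- function(y = c(0, 1), mr_kda = c(200, 15)) {
  y <- as.numeric(y); mr_kda <- as.numeric(mr_kda)
  if (length(y) < 2 || length(y) != length(mr_kda))
    stop("ladder needs >= 2 (y, mr) pairs of equal length")
  if (any(mr_kda <= 0)) stop("marker masses must be positive")
  if (any(diff(y) <= 0)) stop("ladder y values must be strictly increasing")
  if (any(diff(mr_kda) >= 0)) stop("ladder masses must be strictly decreasing")
  if (any(y < 0 | y > 1)) stop("ladder y values must lie in [0, 1]")
  structure(list(y = y, mr_kda = mr_kda), class = "marker_ladder")
}

#' Experimental Mr from gel y coordinate
#'
#' Piecewise-linear interpolation of log10(Mr) against migration distance,
#' exact at the ladder knots. Positions outside the ladder span are refused
#' rather than extrapolated, so no Mr is ever fabricated beyond the markers.
#'
#' @param y vertical gel coordinate(s) within the ladder span.
#' @param ladder a [marker_ladder()].
#' @return Mr in kDa; monotone decreasing in \code{y}.
#' @export
mr_from_y <- function(y, ladder = marker_ladder()) {
  stopifnot(inherits(ladder, "marker_ladder"))
  ok <- is.na(y) | (y >= ladder$y[1] & y <= ladder$y[length(ladder$y)])
  if (!all(ok))
    stop("y = ", y[!ok][1], " outside the marker span [", ladder$y[1], ", ",
         ladder$y[length(ladder$y)], "]; refusing to extrapolate")
  10^stats::approx(ladder$y, log10(ladder$mr_kda), xout = y,
                   method = "linear", ties = "ordered")$y
}

#' Read a marker ladder from CSV
#'
#' @param path CSV with columns \code{y,mr_kda}.
#' @return a [marker_ladder()].
#' @export
read_marker_ladder <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("y", "mr_kda") %in% names(d)))
    stop("ladder file needs columns y,mr_kda")
  marker_ladder(d$y, d$mr_kda)
}
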