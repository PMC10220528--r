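#' Round half away from zero
#'
#' Table-style rounding: 0.5 always rounds up in magnitude, unlike base R's
#' banker's rounding. Used when mirroring printed table values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sample standard deviation (n - 1 denominator)
#'
#' @param values numeric vector, length >= 2.
#' @return the sample SD.
#' @export
sample_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("sample_sd needs at least 2 values")
  if (any(!is.finite(values))) stop("sample_sd: non-finite values")
  m <- sum(values) / length(values)
  sqrt(sum((values - m)^2) / (length(values) - 1))
}

#' Coefficient of variation
#'
#' CV = sample SD / mean; dimensionless fluctuation measure used to compare
#' series with different means.
#'
#' @param values numeric vector, length >= 2 with nonzero mean.
#' @return the CV.
#' @export
cv <- function(values) {
  values <- as.numeric(values)
  m <- mean(values)
  if (!is.finite(m) || m == 0) stop("cv: mean is zero or non-finite")
  sample_sd(values) / m
}

# minimum-image displacement for an orthorhombic box; dx is a matrix (n x 3)
# or vector of length 3, box a length-3 vector.
min_image <- function(dx, box) {
  if (is.matrix(dx)) {
    dx - sweep(round(sweep(dx, 2, box, "/")), 2, box, "*")
  } else {
    dx - box * round(dx / box)
  }
}

# wrap coordinates into [0, box)
wrap_coords <- function(coords, box) {
  coords - sweep(floor(sweep(coords, 2, box, "/")), 2, box, "*")
}

# Make a connected path of atoms whole across periodic images: each atom is
# shifted to the image nearest its predecessor in `order`. Exact for chains
# whose consecutive bonds are shorter than half the box.
unwrap_path <- function(coords, box, order = seq_len(nrow(coords))) {
  out <- coords
  for (i in seq_along(order)[-1]) {
    a <- order[i - 1L]; b <- order[i]
    d <- min_image(out[b, ] - out[a, ], box)
    out[b, ] <- out[a, ] + d
  }
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (length(x) != 1 || !is.finite(x)) stop(sprintf("%s must be a finite scalar", name))
  if (positive && x <= 0) stop(sprintf("%s must be > 0", name))
  invisible(x)
}
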