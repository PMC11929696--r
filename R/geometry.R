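#' Area of a closed planar polyline
#'
#' Absolute shoelace area; orientation independent. The first and last
#' vertex are treated as joined (a duplicated closing vertex is tolerated).
#'
#' @param polyline A two-column matrix or data frame of vertex coordinates
#'   in mm (x, y), at least 3 distinct vertices.
#' @return Area in mm^2. A degenerate (collinear) polygon returns 0 with a
#'   warning.
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square
polygon_area <- function(polyline) {
  p <- as.matrix(polyline)
  if (!is.numeric(p) || ncol(p) != 2)
    stop("polyline must be a two-column numeric matrix of vertices")
  # drop a duplicated closing vertex
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop("polyline needs at least 3 distinct vertices")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- abs(sum(x * yn - xn * y)) / 2
  if (a == 0) warning("degenerate (collinear) polygon: area 0")
  a
}

#' Cortical-to-total cross-sectional area ratio (Ct.Ar/Tt.Ar)
#'
#' The cortical bone of the odontoid cross-section is the shell between the
#' outer and inner cortical contours, so its area is the outer area minus
#' the inner area and the ratio is
#' `100 * (area(outer) - area(inner)) / area(outer)` percent.
#'
#' @param outer,inner Closed polylines (two-column coordinate matrices in
#'   mm) tracing the outer and inner cortical contour. The inner contour
#'   must enclose a strictly smaller area than the outer.
#' @return Ct.Ar/Tt.Ar in percent, in (0, 100].
#' @export
#' @examples
#' sq <- function(h) cbind(c(-h, h, h, -h), c(-h, -h, h, h))
#' ct_tt_ratio(sq(5), sq(4))  # 36
ct_tt_ratio <- function(outer, inner) {
  a_out <- polygon_area(outer)
  a_in <- polygon_area(inner)
  if (a_out <= 0) stop("outer contour has zero area")
  if (a_in >= a_out)
    stop(sprintf("inner area (%.3f) must be smaller than outer area (%.3f)",
                 a_in, a_out))
  100 * (a_out - a_in) / a_out
}

#' Read a contour polyline from a two-column CSV
#'
#' @param path CSV with two numeric columns (x, y vertex coordinates, mm);
#'   a header row is detected automatically.
#' @return A two-column numeric matrix.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1]])))
  m <- as.matrix(utils::read.csv(path, header = has_header))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("unparsable vertex coordinates in ", path)
  unname(m[, 1:2, drop = FALSE])
}
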