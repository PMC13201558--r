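#' Wall contour container
#'
#' Holds sampled wall points with unit tangents and outward unit normals on
#' the imaging plane. Coordinates are mm; tangents point along increasing
#' arc length, normals point out of the lumen.
#'
#' @param points A data frame with columns `wall_id` ("upper"/"lower"),
#'   `z`, `x` (mm), `tz`, `tx` (unit tangent), `nz`, `nx` (outward unit
#'   normal) and optionally `quad_a`, `quad_b`, `quad_c` (local quadratic
#'   coefficients) and `flag` (fit fallback marker).
#' @return An object of class `wall_contour` (a data frame with arc length
#'   column `s` added per wall).
#' @export
wall_contour <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("wall_id", "z", "x", "tz", "tx", "nz", "nx") %in% names(points)))
  tn <- sqrt(points$tz^2 + points$tx^2)
  nn <- sqrt(points$nz^2 + points$nx^2)
  if (any(abs(tn - 1) > 1e-9) || any(abs(nn - 1) > 1e-9))
    stop("tangents and normals must be unit vectors")
  if (any(abs(points$tz * points$nz + points$tx * points$nx) > 1e-9))
    stop("normals must be orthogonal to tangents")
  # arc length per wall, in z-order
  points <- points[order(points$wall_id, points$z), , drop = FALSE]
  points$s <- NA_real_
  for (w in unique(points$wall_id)) {
    sel <- which(points$wall_id == w)
    dzs <- diff(points$z[sel]); dxs <- diff(points$x[sel])
    points$s[sel] <- c(0, cumsum(sqrt(dzs^2 + dxs^2)))
  }
  rownames(points) <- NULL
  class(points) <- c("wall_contour", "data.frame")
  points
}

# analytic slope dx_wall/dz of the cosine-tapered walls
.wall_slope <- function(geom, z, which = c("upper", "lower")) {
  which <- match.arg(which)
  if (geom$stenosis_severity <= 0) return(numeric(length(z)))
  u <- (z - geom$stenosis_center) / (geom$stenosis_length / 2)
  dbell <- numeric(length(z))
  inside <- abs(u) < 1
  dbell[inside] <- -0.5 * pi * sin(pi * u[inside]) / (geom$stenosis_length / 2)
  dent_slope <- geom$stenosis_severity * geom$diameter * dbell
  if (geom$eccentric) {
    if (which == "upper") -dent_slope else numeric(length(z))
  } else {
    if (which == "upper") -dent_slope / 2 else dent_slope / 2
  }
}

#' Exact wall contour of a parametric geometry
#'
#' Builds a `wall_contour` directly from the analytic wall curves (with exact
#' tangents and outward normals); the noise-free counterpart of
#' [fit_wall_contour()] for validation work.
#'
#' @param geom A `vessel_geometry`.
#' @param z Axial sample positions, mm.
#' @param walls Which walls to include.
#' @return A `wall_contour`.
#' @export
contour_from_geometry <- function(geom, z, walls = c("both", "upper", "lower")) {
  walls <- match.arg(walls)
  w <- geometry_walls(geom, z)
  build <- function(side) {
    xw <- if (side == "upper") w$upper else w$lower
    sl <- .wall_slope(geom, z, side)
    tn <- sqrt(1 + sl^2)
    tz <- 1 / tn; tx <- sl / tn
    if (side == "upper") { nz_ <- -tx; nx_ <- tz } else { nz_ <- tx; nx_ <- -tz }
    data.frame(wall_id = side, z = z, x = xw, tz = tz, tx = tx,
               nz = nz_, nx = nx_)
  }
  df <- switch(walls,
               both = rbind(build("upper"), build("lower")),
               upper = build("upper"),
               lower = build("lower"))
  wall_contour(df)
}
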