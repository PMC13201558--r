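#' Parametric 2D vessel geometry
#'
#' Defines a vessel segment on the imaging plane through the tube axis.
#' The centerline lies at x = 0; the upper and lower walls are smooth curves
#' `x_upper(z)` and `x_lower(z)` over the axial coordinate `z` in \[0, length\].
#'
#' A stenosis is a cosine-tapered indentation of the stated fractional diameter
#' reduction over `stenosis_length`, centered at `stenosis_center`. Eccentric
#' stenoses put the full indentation on the upper wall; concentric ones split
#' it evenly. The cosine bell keeps the walls C1-smooth so wall normals are
#' well defined everywhere.
#'
#' Malapposed stent struts are modeled as free-standing obstacles in the lumen
#' (the wall curves are unchanged): `malapposition_offset` is the strut-to-wall
#' gap on the upper side, `strut_pitch` the axial strut spacing, and
#' `strut_extent` the axial extent of the stented region (centered at
#' `stenosis_center`). Their hemodynamic effect enters through a near-wall
#' wake-shielding factor in [analytic_flow_field()].
#'
#' @param kind "straight" or "stenotic".
#' @param diameter Reference lumen diameter, mm.
#' @param length Axial extent of the segment, mm.
#' @param stenosis_severity Fractional diameter reduction in \[0, 1).
#' @param stenosis_length Axial extent of the stenosis taper, mm.
#' @param stenosis_center Axial position of the throat, mm (default mid-segment).
#' @param eccentric If `TRUE` (default) the indentation is one-sided.
#' @param malapposition_offset Strut-to-wall gap of malapposed struts, mm
#'   (0 = no struts). Must be below `diameter / 2`.
#' @param strut_pitch Axial spacing of struts, mm.
#' @param strut_extent Axial extent of the stented region, mm.
#' @return An object of class `vessel_geometry`.
#' @examples
#' make_geometry("straight", diameter = 3.2)
#' make_geometry("stenotic", stenosis_severity = 0.55, stenosis_length = 4)
#' @export
make_geometry <- function(kind = c("straight", "stenotic"),
                          diameter = 3.2,
                          length = 20,
                          stenosis_severity = if (kind == "stenotic") 0.55 else 0,
                          stenosis_length = 4,
                          stenosis_center = length / 2,
                          eccentric = TRUE,
                          malapposition_offset = 0,
                          strut_pitch = 1.0,
                          strut_extent = 4) {
  kind <- match.arg(kind)
  if (!is.numeric(diameter) || diameter <= 0) stop("`diameter` must be positive (mm)")
  if (!is.numeric(length) || length <= 0) stop("`length` must be positive (mm)")
  if (stenosis_severity < 0 || stenosis_severity >= 1)
    stop("`stenosis_severity` must lie in [0, 1)")
  if (stenosis_length <= 0) stop("`stenosis_length` must be positive (mm)")
  if (kind == "stenotic") {
    if (stenosis_center - stenosis_length / 2 < 0 ||
        stenosis_center + stenosis_length / 2 > length)
      stop("stenosis extent must lie within [0, length]")
  } else {
    stenosis_severity <- 0
  }
  if (malapposition_offset < 0 || malapposition_offset >= diameter / 2)
    stop("`malapposition_offset` must lie in [0, diameter/2)")
  if (strut_pitch <= 0) stop("`strut_pitch` must be positive (mm)")

  structure(list(kind = kind,
                 diameter = diameter,
                 length = length,
                 stenosis_severity = stenosis_severity,
                 stenosis_length = stenosis_length,
                 stenosis_center = stenosis_center,
                 eccentric = isTRUE(eccentric),
                 malapposition_offset = malapposition_offset,
                 strut_pitch = strut_pitch,
                 strut_extent = strut_extent),
            class = "vessel_geometry")
}

# cosine bell in [0,1]: 1 at center, 0 outside +/- half_len
.cosine_bell <- function(z, center, full_len) {
  u <- (z - center) / (full_len / 2)
  out <- numeric(length(z))
  inside <- abs(u) < 1
  out[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  out
}

#' Wall curves of a vessel geometry
#'
#' Evaluates the upper and lower wall positions at given axial locations.
#'
#' @param geom A `vessel_geometry`.
#' @param z Axial positions, mm.
#' @return A list with numeric vectors `upper` and `lower` (x positions, mm).
#' @export
geometry_walls <- function(geom, z) {
  stopifnot(inherits(geom, "vessel_geometry"))
  half <- geom$diameter / 2
  upper <- rep(half, length(z))
  lower <- rep(-half, length(z))
  if (geom$stenosis_severity > 0) {
    dent <- geom$stenosis_severity * geom$diameter *
      .cosine_bell(z, geom$stenosis_center, geom$stenosis_length)
    if (geom$eccentric) {
      upper <- upper - dent
    } else {
      upper <- upper - dent / 2
      lower <- lower + dent / 2
    }
  }
  list(upper = upper, lower = lower)
}

#' Local lumen radius r(z) = (x_upper - x_lower) / 2
#' @param geom A `vessel_geometry`.
#' @param z Axial positions, mm.
#' @return Numeric vector of radii, mm.
#' @export
geometry_radius <- function(geom, z) {
  w <- geometry_walls(geom, z)
  (w$upper - w$lower) / 2
}

# Wake-shielding amplitude A(z) in [0,1] behind malapposed struts: periodic at
# the strut pitch (strong right behind each strut, weaker between), tapered by
# a cosine ramp at the ends of the stented region. Zero when no struts.
.strut_shielding_amplitude <- function(geom, z) {
  if (geom$malapposition_offset <= 0) return(numeric(length(z)))
  z0 <- geom$stenosis_center - geom$strut_extent / 2
  z1 <- geom$stenosis_center + geom$strut_extent / 2
  amp <- numeric(length(z))
  inside <- z >= z0 & z <= z1
  zz <- z[inside]
  # oscillation between 0.1 and 0.9 at the strut pitch: the deficit is near
  # stagnation immediately behind a strut and the boundary layer nearly
  # re-attaches midway between struts
  osc <- 0.1 + 0.8 * (1 + cos(2 * pi * (zz - z0) / geom$strut_pitch)) / 2
  # ramp over half a pitch at either end of the stented region
  ramp_len <- geom$strut_pitch / 2
  ramp <- pmin(1, pmin(zz - z0, z1 - zz) / ramp_len)
  amp[inside] <- osc * ramp
  amp
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> %s, diameter %.2f mm, length %.1f mm\n",
              x$kind, x$diameter, x$length))
  if (x$stenosis_severity > 0)
    cat(sprintf("  stenosis: %.0f%% diameter, %.1f mm long at z = %.1f mm (%s)\n",
                100 * x$stenosis_severity, x$stenosis_length, x$stenosis_center,
                if (x$eccentric) "eccentric" else "concentric"))
  if (x$malapposition_offset > 0)
    cat(sprintf("  malapposed struts: %.2f mm gap, pitch %.2f mm over %.1f mm\n",
                x$malapposition_offset, x$strut_pitch, x$strut_extent))
  invisible(x)
}
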