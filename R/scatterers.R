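#' Seed microbubble-like scatterers in a vessel lumen
#'
#' Draws scatterer positions uniformly over the planar lumen of the imaging
#' plane. The expected count converts the volumetric microbubble
#' concentration to a planar count through an elevational slice thickness:
#' `count = concentration * lumen_area * slice_thickness` (area in mm^2,
#' thickness in mm, concentration per mL = per 1000 mm^3).
#'
#' Scatterer reflectivities are drawn as circular complex Gaussians, giving
#' fully developed speckle in the rendered images.
#'
#' @param geom A `vessel_geometry`.
#' @param concentration Scatterers per mL (default 2.5e6).
#' @param slice_thickness Elevational slice thickness, mm.
#' @param seed RNG seed (integer) for reproducible clouds.
#' @return An object of class `scatterer_cloud` with fields `z`, `x` (mm),
#'   `amp` (complex), `n`, `seed`.
#' @examples
#' g <- make_geometry("straight", diameter = 3.2, length = 20)
#' cl <- seed_scatterers(g, concentration = 1e5, seed = 1)
#' @export
seed_scatterers <- function(geom, concentration = 2.5e6, slice_thickness = 0.3,
                            seed = 1L) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (concentration < 0) stop("`concentration` must be nonnegative")
  if (slice_thickness <= 0) stop("`slice_thickness` must be positive (mm)")
  zq <- seq(0, geom$length, length.out = 512)
  w <- geometry_walls(geom, zq)
  widths <- w$upper - w$lower
  if (all(widths <= 0)) stop("empty lumen: geometry has no open cross-section")
  area <- mean(widths) * geom$length                      # mm^2
  n <- as.integer(round(concentration * area * slice_thickness / 1000))
  rng <- .seeded_rng(seed)
  if (n == 0L) {
    return(structure(list(z = numeric(0), x = numeric(0),
                          amp = complex(0), n = 0L, seed = seed),
                     class = "scatterer_cloud"))
  }
  # rejection sampling: uniform over the bounding box, keep points in lumen
  half <- geom$diameter / 2
  zs <- xs <- numeric(0)
  while (length(zs) < n) {
    m <- max(2L * (n - length(zs)), 1024L)
    cz <- stats::runif(m, 0, geom$length)
    cx <- stats::runif(m, -half, half)
    ww <- geometry_walls(geom, cz)
    keep <- cx > ww$lower & cx < ww$upper
    zs <- c(zs, cz[keep]); xs <- c(xs, cx[keep])
  }
  zs <- zs[seq_len(n)]; xs <- xs[seq_len(n)]
  amp <- complex(real = stats::rnorm(n, sd = 1 / sqrt(2)),
                 imaginary = stats::rnorm(n, sd = 1 / sqrt(2)))
  rng$restore()
  structure(list(z = zs, x = xs, amp = amp, n = n, seed = seed),
            class = "scatterer_cloud")
}

# run code under a local RNG state seeded with `seed`; call $restore() after
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' @export
print.scatterer_cloud <- function(x, ...) {
  cat(sprintf("<scatterer_cloud> %d scatterers (seed %s)\n", x$n, format(x$seed)))
  invisible(x)
}
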