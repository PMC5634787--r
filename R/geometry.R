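#' Parametric endolymphatic-sac lumen geometry
#'
#' The lumen is modelled as a conical frustum of axial length `L` with end
#' radii `r1` and `r2`, closed at each end by a spherical cap of height `h1`
#' and `h2` whose base circles coincide with the frustum ends.  All lengths
#' are in micrometres.  A cap height of zero means a flat (open) end.
#'
#' @param r1,r2 End radii of the frustum (µm), both `> 0`.
#' @param L Axial length of the frustum (µm), `> 0`.
#' @param h1,h2 Heights of the spherical caps at the `r1` and `r2` ends
#'   (µm), `>= 0`.
#' @param center Numeric length-3, axial position of the solid's midpoint in
#'   stack coordinates `(z, y, x)` (µm).
#' @param axis Numeric length-3 direction of the frustum axis in `(z, y, x)`
#'   order; normalised internally.  Defaults to the stack z-axis.
#' @return An object of class `sac_geometry`.
#' @seealso [sac_analytic_volume()], [sac_analytic_area()], [render_stack()]
#' @export
sac_geometry <- function(r1, r2, L, h1 = 0, h2 = 0,
                         center = c(0, 0, 0), axis = c(1, 0, 0)) {
  stopifnot(length(center) == 3, length(axis) == 3)
  if (!all(is.finite(c(r1, r2, L, h1, h2))))
    stop("geometry parameters must be finite")
  if (r1 <= 0 || r2 <= 0 || L <= 0)
    stop("r1, r2 and L must be positive")
  if (h1 < 0 || h2 < 0)
    stop("cap heights must be non-negative")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a non-zero vector")
  structure(
    list(r1 = r1, r2 = r2, L = L, h1 = h1, h2 = h2,
         center = as.numeric(center), axis = as.numeric(axis) / nrm),
    class = "sac_geometry")
}

#' @export
print.sac_geometry <- function(x, ...) {
  cat("Sac lumen geometry (two spherical caps + conical frustum)\n")
  cat(sprintf("  end radii     : %.1f, %.1f um\n", x$r1, x$r2))
  cat(sprintf("  frustum length: %.1f um\n", x$L))
  cat(sprintf("  cap heights   : %.1f, %.1f um\n", x$h1, x$h2))
  cat(sprintf("  volume        : %.4f nl, surface %.4f mm^2\n",
              sac_analytic_volume(x) * 1e-6, sac_analytic_area(x) * 1e-6))
  invisible(x)
}

# volume of a spherical cap with base radius a and height h (um^3)
cap_volume <- function(a, h) {
  if (h == 0) return(0)
  pi * h * (3 * a^2 + h^2) / 6
}

frustum_volume <- function(r1, r2, L) {
  pi * L * (r1^2 + r1 * r2 + r2^2) / 3
}

#' Analytic volume of a sac geometry
#'
#' Sum of the two spherical-cap volumes and the frustum volume.
#'
#' @param geom A [sac_geometry()].
#' @return Volume in µm³.
#' @export
sac_analytic_volume <- function(geom) {
  stopifnot(inherits(geom, "sac_geometry"))
  cap_volume(geom$r1, geom$h1) + frustum_volume(geom$r1, geom$r2, geom$L) +
    cap_volume(geom$r2, geom$h2)
}

#' Lateral surface area of a spherical cap
#'
#' For a cap with base radius `a` and height `h` the curved surface is
#' `2*pi*R*h` with sphere radius `R = (a^2 + h^2) / (2h)`, which simplifies to
#' `pi * (a^2 + h^2)`.  The limit `h = 0` gives the flat disk `pi * a^2`.
#'
#' @param a Base radius (µm), `>= 0`.
#' @param h Cap height (µm), `>= 0`.
#' @return Area in µm².
#' @export
cap_area <- function(a, h) {
  if (a < 0 || h < 0) stop("a and h must be non-negative")
  if (a == 0 && h == 0) stop("cap with a = h = 0 is degenerate")
  pi * (a^2 + h^2)
}

#' Lateral surface area of a conical frustum
#'
#' `pi * (r1 + r2) * sqrt((r1 - r2)^2 + L^2)`; the end disks are not
#' included (they belong to the caps).  `L = 0` degenerates to the annulus
#' `pi * |r1^2 - r2^2|`.
#'
#' @param r1,r2 End radii (µm), `>= 0`.
#' @param L Axial length (µm), `>= 0`.
#' @return Area in µm².
#' @export
frustum_area <- function(r1, r2, L) {
  if (r1 < 0 || r2 < 0 || L < 0) stop("r1, r2 and L must be non-negative")
  if (r1 == 0 && r2 == 0 && L == 0) stop("fully degenerate frustum")
  pi * (r1 + r2) * sqrt((r1 - r2)^2 + L^2)
}

#' Analytic surface area of a sac geometry
#'
#' @param geom A [sac_geometry()].
#' @return Area in µm² (caps + frustum lateral surface).
#' @export
sac_analytic_area <- function(geom) {
  stopifnot(inherits(geom, "sac_geometry"))
  cap_area(geom$r1, geom$h1) + frustum_area(geom$r1, geom$r2, geom$L) +
    cap_area(geom$r2, geom$h2)
}

# isotropic rescaling about the centroid; scales all linear dimensions by s
scale_geometry <- function(geom, s) {
  stopifnot(inherits(geom, "sac_geometry"), s > 0)
  sac_geometry(geom$r1 * s, geom$r2 * s, geom$L * s,
               geom$h1 * s, geom$h2 * s,
               center = geom$center, axis = geom$axis)
}
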