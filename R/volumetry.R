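#' Smooth a stack with a 3D mean filter
#'
#' Separable box (mean) filter of odd width `width` applied along z, y and x
#' with edge replication, equivalent to a `width`³ mean kernel.  Values stay
#' within the input intensity range.
#'
#' @param stack An [image_stack()].
#' @param width Odd integer filter width, default 5.
#' @return A smoothed [image_stack()].
#' @export
smooth_stack <- function(stack, width = 5) {
  stopifnot(inherits(stack, "image_stack"))
  if (width < 1 || width %% 2 == 0) stop("width must be an odd integer >= 1")
  if (width == 1) return(stack)
  v <- stack$values
  for (ax in 1:3) v <- box_filter_axis(v, ax, width)
  image_stack(v, stack$voxel_size, stack$time)
}

# 1D running mean of odd width w along axis ax, replicated edges
box_filter_axis <- function(a, ax, w) {
  k <- (w - 1L) / 2L
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, d[1], prod(d[-1]))
  mp <- rbind(m[rep(1L, k), , drop = FALSE], m,
              m[rep(nrow(m), k), , drop = FALSE])
  f <- stats::filter(mp, rep(1 / w, w), sides = 2)
  out <- array(as.numeric(f[(k + 1L):(k + d[1]), , drop = FALSE]), d)
  aperm(out, order(perm))
}

#' Otsu threshold of an intensity sample
#'
#' Global threshold maximizing the between-class variance of the full
#' intensity histogram (256 bins spanning the data range).
#'
#' @param values Numeric vector or array of finite intensities.
#' @param levels Number of histogram bins.
#' @return Threshold on the intensity scale.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  v <- as.numeric(values)
  if (!all(is.finite(v))) stop("intensities must be finite")
  rg <- range(v)
  if (rg[1] == rg[2]) stop("constant image: no threshold exists")
  br <- seq(rg[1], rg[2], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), levels),
                nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  bc <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  i <- which.max(bc)
  br[i + 1L]   # upper edge of the optimal background class
}

#' Segment the lumen from an intensity stack
#'
#' Voxels at or above the threshold are kept and the largest 26-connected
#' component is returned; smaller suprathreshold specks are discarded.
#'
#' @param stack An [image_stack()].
#' @param threshold `"otsu"` for an automatic global threshold, or a numeric
#'   intensity value.
#' @return A [voxel_mask()].
#' @export
segment_lumen <- function(stack, threshold = "otsu") {
  stopifnot(inherits(stack, "image_stack"))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(stack$values)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1)
      stop("threshold must be \"otsu\" or a single number")
    threshold
  }
  bin <- stack$values >= thr
  if (!any(bin)) stop("no lumen found: no voxel reaches the threshold")
  keep <- largest_component_26(bin)
  voxel_mask(keep, stack$voxel_size)
}

# largest 26-connected component of a 3D logical array
largest_component_26 <- function(bin) {
  d <- dim(bin)
  fg <- which(bin)
  nfg <- length(fg)
  if (nfg == 1L) return(bin)
  id <- integer(prod(d))
  id[fg] <- seq_len(nfg)
  co <- arrayInd(fg, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]        # half neighbourhood (13 offsets)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[i, ], nfg, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nid <- id[lin]
    hit <- nid > 0L
    edges[[i]] <- rbind(which(ok)[hit], nid[hit])
  }
  em <- do.call(cbind, edges)
  memb <- if (length(em) == 0) {
    seq_len(nfg)
  } else {
    g <- igraph::make_graph(as.vector(em), n = nfg, directed = FALSE)
    igraph::components(g)$membership
  }
  big <- which.max(tabulate(memb))
  out <- array(FALSE, d)
  out[fg[memb == big]] <- TRUE
  out
}

#' Luminal volume of a voxel mask
#'
#' Exact voxel count converted to µm³ and nanoliters: one voxel contributes
#' `voxel_size`³ µm³; 1 nl = 10⁶ µm³ (a 3 µm voxel is 27 µm³ = 2.7e-5 nl).
#'
#' @param mask A [voxel_mask()].
#' @return A list of class `volume_estimate` with `voxel_count`,
#'   `volume_um3`, `volume_nl`.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  n <- sum(mask$values)
  um3 <- n * mask$voxel_size^3
  structure(list(voxel_count = n, volume_um3 = um3, volume_nl = um3 * 1e-6),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("volume_estimate: %d voxels = %.0f um^3 = %.4g nl\n",
              x$voxel_count, x$volume_um3, x$volume_nl))
  invisible(x)
}

#' Linear dimensions of a segmented lumen
#'
#' Recovers the parameters of the caps-plus-frustum surface model from a
#' binary mask: the principal axis comes from the second moments of the
#' foreground voxel coordinates; the frustum is taken to span the central
#' `1 - 2 * cap_fraction` of the axial extent; `a1`, `a2` are the
#' equivalent-circle radii (`sqrt(A/pi)`) of the cross sections at the
#' `cap_fraction` and `1 - cap_fraction` axial positions, and `h1`, `h2` the
#' axial extents beyond those planes.
#'
#' @param mask A non-empty, connected [voxel_mask()].
#' @param cap_fraction Fraction of the axial extent assigned to each cap;
#'   default 0.1.  Shapes with strongly bulging midsections (spheres) are
#'   better served by larger fractions.
#' @return A list of class `sac_measurements` with `a1`, `a2`, `h1`, `h2`,
#'   `L` (µm) and the axial `extent`.
#' @export
measure_linear_dimensions <- function(mask, cap_fraction = 0.1) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (cap_fraction <= 0 || cap_fraction >= 0.5)
    stop("cap_fraction must be in (0, 0.5)")
  fg <- which(mask$values)
  if (length(fg) == 0) stop("empty mask")
  vs <- mask$voxel_size
  co <- arrayInd(fg, dim(mask$values))
  spans <- apply(co, 2, function(x) diff(range(x))) + 1L
  if (all(spans < 3)) stop("degenerate shape: mask thinner than 3 voxels along every axis")
  xyz <- (co - 1) * vs
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  s <- as.numeric(cc %*% axis)
  smin <- min(s) - vs / 2
  smax <- max(s) + vs / 2
  extent <- smax - smin
  p1 <- smin + cap_fraction * extent
  p2 <- smin + (1 - cap_fraction) * extent
  # sample one layer to the frustum side of each split plane: the cap curves
  # in steeply at the junction, while the frustum taper is gentle and its
  # effect cancels between the two ends
  a1 <- equiv_radius_at(s, p1 + vs, vs)
  a2 <- equiv_radius_at(s, p2 - vs, vs)
  structure(list(a1 = a1, a2 = a2,
                 h1 = cap_fraction * extent, h2 = cap_fraction * extent,
                 L = (1 - 2 * cap_fraction) * extent,
                 extent = extent, axis = axis, cap_fraction = cap_fraction),
            class = "sac_measurements")
}

# equivalent-circle radius of the cross section at axial position p:
# voxels are binned into one-voxel-thick layers along the axis, each layer's
# count gives its cross-section area (n * vs^2), and the area is linearly
# interpolated at p between adjacent layer centers
equiv_radius_at <- function(s, p, vs) {
  k <- round((s - min(s)) / vs)
  cnt <- tabulate(k + 1L, max(k) + 1L)
  centers <- min(s) + (seq_along(cnt) - 1L) * vs
  a_p <- if (length(cnt) == 1L) cnt else
    stats::approx(centers, cnt, xout = p, rule = 2)$y
  sqrt(a_p * vs^2 / pi)
}

#' @export
print.sac_measurements <- function(x, ...) {
  cat(sprintf("sac_measurements: a1 = %.1f, a2 = %.1f, h1 = %.1f, h2 = %.1f, L = %.1f um\n",
              x$a1, x$a2, x$h1, x$h2, x$L))
  invisible(x)
}

#' Luminal surface area from linear dimensions
#'
#' Caps-plus-frustum model: `cap_area(a1, h1) + frustum_area(a1, a2, L) +
#' cap_area(a2, h2)`, reported in mm² (1 mm² = 10⁶ µm²).
#'
#' @param m A [measure_linear_dimensions()] result (or any list with fields
#'   `a1`, `a2`, `h1`, `h2`, `L` in µm).
#' @return A list of class `surface_estimate` with `area_mm2` and the
#'   `components` (cap1, frustum, cap2, mm²).
#' @export
sac_surface_area <- function(m) {
  comp <- c(cap1 = cap_area(m$a1, m$h1),
            frustum = frustum_area(m$a1, m$a2, m$L),
            cap2 = cap_area(m$a2, m$h2)) * 1e-6
  structure(list(area_mm2 = sum(comp), components = comp),
            class = "surface_estimate")
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat(sprintf("surface_estimate: %.5f mm^2 (cap1 %.5f + frustum %.5f + cap2 %.5f)\n",
              x$area_mm2, x$components[1], x$components[2], x$components[3]))
  invisible(x)
}

#' Quantify one stack: smooth, segment, count voxels
#'
#' @param stack An [image_stack()].
#' @param smooth_width Mean-filter width (odd), default 5.
#' @param threshold `"otsu"` or a numeric intensity.
#' @return List with `volume` ([mask_volume()] result) and `mask`.
#' @export
quantify_stack <- function(stack, smooth_width = 5, threshold = "otsu") {
  sm <- smooth_stack(stack, smooth_width)
  mask <- segment_lumen(sm, threshold)
  list(volume = mask_volume(mask), mask = mask)
}
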