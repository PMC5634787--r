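#' Intensity noise model for synthetic stacks
#'
#' Additive Gaussian intensity model: voxels outside the lumen draw from
#' `N(background_mean, background_sd)`, voxels inside from
#' `N(lumen_mean, lumen_sd)`; draws are clipped at zero.  The high lumen
#' intensity emulates a dye-filled lumen imaged against unstained tissue.
#'
#' @param background_mean,background_sd Background intensity mean / sd (a.u.).
#' @param lumen_mean,lumen_sd Lumen intensity mean / sd (a.u.).
#' @param seed Integer RNG seed; identical seeds give identical stacks.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_mean = 150, background_sd = 30,
                        lumen_mean = 2000, lumen_sd = 150, seed = 1L) {
  if (background_sd < 0 || lumen_sd < 0) stop("noise SDs must be non-negative")
  if (lumen_mean <= background_mean)
    stop("lumen_mean must exceed background_mean")
  structure(list(background_mean = background_mean,
                 background_sd = background_sd,
                 lumen_mean = lumen_mean, lumen_sd = lumen_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Draw a random sac geometry that fits a stack
#'
#' Radii are drawn uniformly from `size_range`, the frustum length as 2.0–2.6
#' times the first radius, and the cap heights near `L/8` so that each cap
#' occupies roughly 10% of the total axial extent (a shallow, rounded-end
#' sac).  The solid is centred in the stack with its axis along z and must
#' fit with a two-voxel margin.
#'
#' @param rng_seed Integer seed.
#' @param size_range Length-2 numeric, range of the first end radius in µm.
#' @param stack_dim Stack dimensions `(z, y, x)` in voxels.
#' @param voxel_size Voxel edge (µm).
#' @return A [sac_geometry()].
#' @export
make_sac_geometry <- function(rng_seed = 1L, size_range = c(30, 42),
                              stack_dim = c(64, 64, 64), voxel_size = 3) {
  stopifnot(length(size_range) == 2, size_range[1] > 0,
            size_range[2] >= size_range[1])
  rng <- local_rng(rng_seed)
  r1 <- rng(stats::runif(1, size_range[1], size_range[2]))
  r2 <- r1 * rng(stats::runif(1, 0.75, 1.0))
  L  <- r1 * rng(stats::runif(1, 2.0, 2.6))
  h1 <- 0.125 * L * rng(stats::runif(1, 0.9, 1.1))
  h2 <- 0.125 * L * rng(stats::runif(1, 0.9, 1.1))
  extent_um <- (stack_dim - 1) * voxel_size
  center <- extent_um / 2
  geom <- sac_geometry(r1, r2, L, h1, h2, center = center, axis = c(1, 0, 0))
  check_geometry_fits(geom, stack_dim, voxel_size)
  geom
}

# run expr with a private RNG stream restored afterwards
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(expr) {
    outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(outer)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", outer, globalenv())
    })
    expr
  }
}

check_geometry_fits <- function(geom, stack_dim, voxel_size) {
  margin <- 2 * voxel_size
  half_axial <- (geom$L / 2 + max(geom$h1, geom$h2))
  rad <- max(geom$r1, geom$r2)
  a <- abs(geom$axis)
  half <- half_axial * a + rad * sqrt(pmax(1 - a^2, 0))
  lo <- geom$center - half
  hi <- geom$center + half
  extent <- (stack_dim - 1) * voxel_size
  if (any(lo < margin - 1e-9) || any(hi > extent - margin + 1e-9))
    stop("geometry does not fit inside the stack with a 2-voxel margin")
  invisible(TRUE)
}

# logical 3D array: voxel centers inside the caps+frustum solid
inside_solid <- function(geom, stack_dim, voxel_size) {
  z <- voxel_centers(stack_dim[1], voxel_size) - geom$center[1]
  y <- voxel_centers(stack_dim[2], voxel_size) - geom$center[2]
  x <- voxel_centers(stack_dim[3], voxel_size) - geom$center[3]
  Z <- array(rep(z, times = stack_dim[2] * stack_dim[3]), stack_dim)
  Y <- array(rep(rep(y, each = stack_dim[1]), times = stack_dim[3]), stack_dim)
  X <- array(rep(x, each = stack_dim[1] * stack_dim[2]), stack_dim)
  a <- geom$axis
  s <- Z * a[1] + Y * a[2] + X * a[3]            # axial coordinate
  rho2 <- Z^2 + Y^2 + X^2 - s^2                  # squared radial distance
  rho2[rho2 < 0] <- 0
  halfL <- geom$L / 2
  inside <- array(FALSE, stack_dim)
  fr <- abs(s) <= halfL
  rad <- geom$r1 + (s + halfL) / geom$L * (geom$r2 - geom$r1)
  inside[fr] <- rho2[fr] <= rad[fr]^2
  if (geom$h1 > 0) {
    R1 <- (geom$r1^2 + geom$h1^2) / (2 * geom$h1)
    sc <- -halfL + (R1 - geom$h1)                # sphere center (axial)
    cp <- s < -halfL & s >= -halfL - geom$h1
    inside[cp] <- rho2[cp] + (s[cp] - sc)^2 <= R1^2
  }
  if (geom$h2 > 0) {
    R2 <- (geom$r2^2 + geom$h2^2) / (2 * geom$h2)
    sc <- halfL - (R2 - geom$h2)
    cp <- s > halfL & s <= halfL + geom$h2
    inside[cp] <- rho2[cp] + (s[cp] - sc)^2 <= R2^2
  }
  inside
}

#' Render a synthetic dye-filled lumen stack
#'
#' Voxels whose centers lie inside the solid receive lumen intensity draws,
#' all others background draws; intensities are clipped at zero.  The exact
#' inside-voxel mask is returned alongside the stack so that segmentation can
#' be tested against ground truth.
#'
#' @param geometry A [sac_geometry()].
#' @param noise A [noise_model()]; its `seed` makes rendering reproducible.
#' @param voxel_size Voxel edge (µm), default 3.
#' @param stack_dim Stack dimensions `(z, y, x)` in voxels, default 64³.
#' @param time Acquisition time (hours) stored on the stack.
#' @return A list with elements `stack` ([image_stack()]) and
#'   `inside` ([voxel_mask()], the true inside-voxel set).
#' @export
render_stack <- function(geometry, noise, voxel_size = 3,
                         stack_dim = c(64, 64, 64), time = 0) {
  stopifnot(inherits(geometry, "sac_geometry"), inherits(noise, "noise_model"))
  if (voxel_size <= 0) stop("voxel_size must be positive")
  check_geometry_fits(geometry, stack_dim, voxel_size)
  inside <- inside_solid(geometry, stack_dim, voxel_size)
  rng <- local_rng(noise$seed)
  n <- prod(stack_dim)
  vals <- rng({
    v <- stats::rnorm(n, noise$background_mean, noise$background_sd)
    nin <- sum(inside)
    v[inside] <- stats::rnorm(nin, noise$lumen_mean, noise$lumen_sd)
    v
  })
  vals[vals < 0] <- 0
  list(stack = image_stack(array(vals, stack_dim), voxel_size, time),
       inside = voxel_mask(inside, voxel_size))
}

#' Simulate a shrinking-lumen image time course
#'
#' The true luminal volume decays linearly, `V(t) = max(V0 - rate_norm * S0 *
#' t, V_floor)`, where `S0` is the analytic surface area of the starting
#' geometry; the geometry is rescaled isotropically about its centroid at
#' each timepoint to match the true volume, then rendered.  `V_floor`
#' defaults to 5% of `V0`.
#'
#' @param geometry Starting [sac_geometry()].
#' @param noise A [noise_model()]; timepoint `i` is rendered with seed
#'   `noise$seed + i - 1`.
#' @param rate_norm True normalized absorption rate (nl·hr⁻¹·mm⁻²), `>= 0`.
#' @param times Hours, strictly increasing, starting at 0.
#' @param voxel_size,stack_dim Rendering grid, as in [render_stack()].
#' @param floor_frac Volume floor as a fraction of `V0`.
#' @return A list with `stacks` (list of [image_stack()]) and `truth`
#'   (list with `volumes_nl`, `surface_mm2`, `rate_norm`, `times`).
#' @export
simulate_timecourse <- function(geometry, noise, rate_norm,
                                times = seq(0, 0.8, by = 0.2),
                                voxel_size = 3, stack_dim = c(64, 64, 64),
                                floor_frac = 0.05) {
  stopifnot(inherits(geometry, "sac_geometry"), rate_norm >= 0)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  V0 <- sac_analytic_volume(geometry) * 1e-6        # nl
  S0 <- sac_analytic_area(geometry) * 1e-6          # mm^2
  floor_nl <- floor_frac * V0
  vols <- pmax(V0 - rate_norm * S0 * times, floor_nl)
  if (rate_norm > 0 && vols[2] <= floor_nl)
    warning("volume reaches the floor before the second timepoint; trajectory plateaus")
  stacks <- vector("list", length(times))
  for (i in seq_along(times)) {
    s <- (vols[i] / V0)^(1 / 3)
    g <- scale_geometry(geometry, s)
    nz <- noise_model(noise$background_mean, noise$background_sd,
                      noise$lumen_mean, noise$lumen_sd,
                      seed = noise$seed + i - 1L)
    stacks[[i]] <- render_stack(g, nz, voxel_size, stack_dim,
                                time = times[i])$stack
  }
  list(stacks = stacks,
       truth = list(volumes_nl = vols, surface_mm2 = S0,
                    rate_norm = rate_norm, times = times))
}

#' Fluid-absorption study conditions
#'
#' The five experimental conditions of the organ-culture absorption study:
#' heterozygote controls, homozygous mutants, heterozygotes under ouabain,
#' and heterozygotes with and without gadolinium, with their group mean and
#' SD of the normalized absorption rate (nl·hr⁻¹·mm⁻²) and group sizes.
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `n`.
#' @export
absorption_scenarios <- function() {
  data.frame(
    name = c("het", "homo", "ouabain", "gado_control", "gadolinium"),
    mean = c(12.3, 6.0, 5.3, 12.6, 8.1),
    sd   = c(2.6, 1.6, 1.8, 2.7, 1.5),
    n    = c(26L, 12L, 7L, 6L, 11L),
    stringsAsFactors = FALSE)
}

#' Draw per-sac true rates for a study condition
#'
#' Draws `n` normal deviates and then recenters/rescales the sample so that
#' its sample mean and SD equal the condition's printed values exactly: the
#' published numbers are observed sample statistics, so the synthetic cohort
#' reproduces them as such.  Set `exact_moments = FALSE` for plain draws.
#'
#' @param mean,sd Group mean and SD of the normalized rate.
#' @param n Group size.
#' @param seed Integer seed.
#' @param exact_moments Standardize the sample to the target moments.
#' @return Numeric vector of `n` true normalized rates.
#' @export
simulate_rate_group <- function(mean, sd, n, seed = 1L, exact_moments = TRUE) {
  stopifnot(n >= 2, sd >= 0)
  rng <- local_rng(seed)
  x <- rng(stats::rnorm(n))
  if (exact_moments) x <- (x - base::mean(x)) / stats::sd(x)
  out <- mean + sd * x
  if (any(out <= 0))
    warning("some drawn rates are non-positive; consider a smaller SD")
  out
}
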