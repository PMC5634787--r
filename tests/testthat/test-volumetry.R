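test_that("mean filter is an identity at width 1 and on constant stacks", {
  v <- array(runif(10 * 10 * 10, 0, 100), c(10, 10, 10))
  st <- image_stack(v, 3)
  expect_equal(smooth_stack(st, 1)$values, v)
  cst <- image_stack(array(7, c(10, 10, 10)), 3)
  expect_equal(smooth_stack(cst, 5)$values, cst$values)
  expect_error(smooth_stack(st, 4), "odd")
})

test_that("box filter spreads an impulse over the 5^3 kernel", {
  v <- array(0, c(15, 15, 15))
  v[8, 8, 8] <- 125
  sm <- smooth_stack(image_stack(v, 3), 5)
  expect_equal(sm$values[8, 8, 8], 1)          # 125 / 5^3
  expect_equal(sm$values[6, 6, 6], 1)          # corner of the kernel support
  expect_equal(sm$values[5, 8, 8], 0)          # outside the support
  expect_equal(sum(sm$values), 125)            # mass conserved in the interior
})

test_that("smoothing preserves the input intensity range", {
  v <- array(runif(12^3, 50, 900), c(12, 12, 12))
  sm <- smooth_stack(image_stack(v, 3), 5)
  expect_gte(min(sm$values), min(v) - 1e-9)
  expect_lte(max(sm$values), max(v) + 1e-9)
})

test_that("segmentation recovers a two-level stack exactly at any threshold between levels", {
  m <- digitized_sphere(21, 3)
  st <- two_level_stack(m, lumen = 1000, background = 100)
  for (thr in c(200, 550, 900)) {
    seg <- segment_lumen(st, thr)
    expect_equal(seg$values, m$values)
  }
  # otsu lands between the levels too
  seg <- segment_lumen(st, "otsu")
  expect_equal(seg$values, m$values)
  expect_error(segment_lumen(st, 2000), "no lumen")
})

test_that("only the largest 26-connected component is retained", {
  v <- array(0, c(20, 20, 20))
  v[3:12, 3:12, 3:12] <- 1000          # 1000-voxel blob
  v[16:17, 16:17, 16:18] <- 1000       # small disjoint blob
  seg <- segment_lumen(image_stack(v, 3), 500)
  expect_equal(sum(seg$values), 1000)
  expect_true(all(which(seg$values) %in% which(v == 1000 &
    slice.index(v, 1) <= 12)))
  # diagonal touch counts as connected under 26-connectivity
  v2 <- array(0, c(10, 10, 10))
  v2[4, 4, 4] <- 1000; v2[5, 5, 5] <- 1000
  seg2 <- segment_lumen(image_stack(v2, 3), 500)
  expect_equal(sum(seg2$values), 2)
})

test_that("voxel counts convert exactly to volumes", {
  v <- array(FALSE, c(8, 8, 8)); v[4, 4, 4] <- TRUE
  est <- mask_volume(voxel_mask(v, 3))
  expect_identical(est$voxel_count, 1L)
  expect_equal(est$volume_um3, 27)
  expect_equal(est$volume_nl, 2.7e-5)
  v[] <- FALSE
  expect_equal(mask_volume(voxel_mask(v, 3))$volume_nl, 0)
})

test_that("digitized-sphere voxel volume is within 2% of the closed form", {
  for (r in c(18, 30, 45)) {
    est <- mask_volume(digitized_sphere(r, 3))
    expect_equal(est$volume_um3, 4 / 3 * pi * r^3, tolerance = 0.02)
  }
  est <- mask_volume(digitized_sphere(30, 3))
  expect_equal(est$volume_nl, 0.1131, tolerance = 0.02)
})

test_that("volume and area scale with voxel size as c^3 and c^2", {
  m1 <- digitized_sphere(24, 3)
  m2 <- digitized_sphere(48, 6, dim = dim(m1$values),   # same voxel grid,
                         offset = 2 * c(0.7, 1.1, 1.3)) # scaled placement
  expect_identical(m2$values, m1$values)
  expect_equal(mask_volume(m2)$volume_um3, 8 * mask_volume(m1)$volume_um3)
  a1 <- sac_surface_area(measure_linear_dimensions(m1))$area_mm2
  a2 <- sac_surface_area(measure_linear_dimensions(m2))$area_mm2
  expect_equal(a2, 4 * a1, tolerance = 1e-6)
})

test_that("linear dimensions of a digitized cylinder follow the split convention", {
  m <- digitized_cylinder(24, 120, 3)
  d <- measure_linear_dimensions(m)
  expect_equal(d$a1, 24, tolerance = 3 / 24)     # within one voxel
  expect_equal(d$a2, 24, tolerance = 3 / 24)
  expect_equal(d$L, 96, tolerance = 0.05)
  expect_equal(d$h1, 12, tolerance = 0.15)
  expect_equal(d$h2, d$h1)
  expect_error(measure_linear_dimensions(voxel_mask(array(FALSE, c(8, 8, 8)), 3)),
               "empty")
})

test_that("surface estimates match closed forms within 10% for reference solids", {
  # generator-family solid (shallow caps) at the default split
  g <- sac_geometry(36, 30, 84, 10.5, 10.5,
                    center = c(94.5, 94.5, 94.5), axis = c(1, 0, 0))
  r <- render_stack(g, noise_model(seed = 5))
  est <- sac_surface_area(measure_linear_dimensions(r$inside))
  expect_equal(est$area_mm2, sac_analytic_area(g) * 1e-6, tolerance = 0.10)
  # sphere: bulging midsection, measured with a wider cap fraction
  sp <- digitized_sphere(30, 3)
  ests <- sac_surface_area(measure_linear_dimensions(sp, cap_fraction = 0.25))
  expect_equal(ests$area_mm2, 4 * pi * 30^2 * 1e-6, tolerance = 0.10)
  sph <- measure_linear_dimensions(sp, cap_fraction = 0.25)
  expect_equal(sph$a1, sph$a2, tolerance = 0.05)
  expect_equal(sph$h1, sph$h2)
  # cylinder including its end disks, shallow cap fraction
  cy <- digitized_cylinder(24, 120, 3)
  estc <- sac_surface_area(measure_linear_dimensions(cy, cap_fraction = 0.05))
  true_cyl <- (2 * pi * 24 * 120 + 2 * pi * 24^2) * 1e-6
  expect_equal(estc$area_mm2, true_cyl, tolerance = 0.10)
})

test_that("hemisphere-capped cylinder measurements reproduce the closed-form area", {
  # a1 = a2 = h1 = h2 = 25, L = 100: 2 * 2 pi 25^2 + 2 pi 25 * 100 um^2
  m <- list(a1 = 25, a2 = 25, h1 = 25, h2 = 25, L = 100)
  est <- sac_surface_area(m)
  expect_equal(est$area_mm2, 0.023562, tolerance = 1e-4)
  expect_equal(unname(est$components["cap1"]), 2 * pi * 25^2 * 1e-6)
  # caps zero: cylinder lateral only plus two disks
  m0 <- list(a1 = 10, a2 = 10, h1 = 0, h2 = 0, L = 50)
  expect_equal(sac_surface_area(m0)$area_mm2,
               (2 * pi * 10 * 50 + 2 * pi * 10^2) * 1e-6)
})

test_that("otsu threshold separates a bimodal histogram", {
  set.seed(42)
  bg <- rnorm(5000, 100, 20); lum <- rnorm(2000, 1000, 50)
  thr <- otsu_threshold(c(bg, lum))
  # the between-class variance plateaus across the empty gap; any threshold
  # there classifies both populations essentially perfectly
  expect_lt(mean(bg >= thr), 0.001)
  expect_lt(mean(lum < thr), 0.001)
  expect_error(otsu_threshold(rep(5, 10)), "constant")
})
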