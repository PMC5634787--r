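# digitized reference solids built directly on the voxel grid (voxel centers
# at (index - 1) * vs), independent of the package's rendering path

# the solid centre is shifted off the voxel lattice (generic placement): a
# centre aligned exactly with the half-voxel lattice is a degenerate case in
# which boundary-voxel centres line up with the surface and bias the count
digitize_solid <- function(dim, vs, predicate, offset = c(0.7, 1.1, 1.3)) {
  ctr <- (dim - 1) * vs / 2 + offset
  z <- (seq_len(dim[1]) - 1) * vs - ctr[1]
  y <- (seq_len(dim[2]) - 1) * vs - ctr[2]
  x <- (seq_len(dim[3]) - 1) * vs - ctr[3]
  Z <- array(rep(z, times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(y, each = dim[1]), times = dim[3]), dim)
  X <- array(rep(x, each = dim[1] * dim[2]), dim)
  voxel_mask(predicate(Z, Y, X), vs)
}

digitized_sphere <- function(r, vs = 3, dim = rep(ceiling(2 * r / vs) + 8, 3),
                             offset = c(0.7, 1.1, 1.3)) {
  digitize_solid(dim, vs, function(Z, Y, X) Z^2 + Y^2 + X^2 <= r^2, offset)
}

digitized_cylinder <- function(r, len, vs = 3,
                               dim = c(ceiling(len / vs) + 8,
                                       rep(ceiling(2 * r / vs) + 8, 2))) {
  digitize_solid(dim, vs, function(Z, Y, X)
    abs(Z) <= len / 2 & Y^2 + X^2 <= r^2)
}

# two-level stack: lumen intensity where mask, background elsewhere
two_level_stack <- function(mask, lumen = 1000, background = 100) {
  v <- array(background, dim(mask$values))
  v[mask$values] <- lumen
  image_stack(v, mask$voxel_size)
}
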