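# Synthetic 3D phantoms with known or controllable fractal dimension.
# These are the ground-truth fixtures for the box-counting estimator: solid
# cubes (FD 3), one-voxel planes (FD 2) and lines (FD 1), the Menger sponge
# (FD log 20 / log 3), and spheres with band-limited radial perturbation
# whose boundary complexity grows with the perturbation amplitude.

#' Generate a synthetic binary shape
#'
#' @param base one of `"solid_cube"`, `"plane"`, `"line"`, `"sphere"`,
#'   `"menger_sponge"`.
#' @param grid_size voxels per axis. For the Menger sponge this must equal
#'   `3^level`.
#' @param level recursion level for the Menger sponge (the standard
#'   20-of-27 subcell occupancy rule, applied `level` times).
#' @param perturbation_amplitude relative radial displacement in `[0, 0.5]`
#'   for sphere surfaces; 0 gives the exact discretized ball.
#' @param noise_octaves number of octaves of value noise used for the
#'   radial perturbation field.
#' @param seed RNG seed; output is deterministic given the spec.
#' @return A [binary_mask()].
#' @export
make_shape <- function(base = c("solid_cube", "plane", "line", "sphere",
                                "menger_sponge"),
                       grid_size = 32L, level = 2L,
                       perturbation_amplitude = 0, noise_octaves = 3L,
                       seed = 1L) {
  base <- match.arg(base)
  grid_size <- as.integer(grid_size)
  if (grid_size < 1L) stop("grid_size must be >= 1")
  if (perturbation_amplitude < 0 || perturbation_amplitude > 0.5) {
    stop("perturbation_amplitude must be in [0, 0.5]")
  }
  arr <- switch(base,
    solid_cube = array(TRUE, rep(grid_size, 3)),
    plane = {
      a <- array(FALSE, rep(grid_size, 3))
      a[, , max(1L, grid_size %/% 2L)] <- TRUE
      a
    },
    line = {
      a <- array(FALSE, rep(grid_size, 3))
      mid <- max(1L, grid_size %/% 2L)
      a[, mid, mid] <- TRUE
      a
    },
    menger_sponge = menger_occupancy(grid_size, level),
    sphere = perturbed_sphere(grid_size, perturbation_amplitude,
                              noise_octaves, seed)
  )
  binary_mask(arr)
}

# Occupancy of the level-`level` Menger sponge on a 3^level grid: a voxel
# is kept iff at every base-3 digit position at most one of its three
# coordinate digits equals 1.
menger_occupancy <- function(grid_size, level) {
  level <- as.integer(level)
  if (level < 1L) stop("menger level must be >= 1")
  if (grid_size != 3L^level) {
    stop("menger_sponge needs grid_size == 3^level (got ", grid_size,
         " for level ", level, ")")
  }
  digits_base3 <- function(v) {
    out <- matrix(0L, length(v), level)
    for (j in seq_len(level)) {
      out[, j] <- v %% 3L
      v <- v %/% 3L
    }
    out
  }
  coord <- 0:(grid_size - 1L)
  dx <- digits_base3(coord)
  keep <- array(TRUE, rep(grid_size, 3))
  for (j in seq_len(level)) {
    ones_x <- (dx[, j] == 1L)
    n_ones <- outer(outer(ones_x, ones_x, "+"), ones_x, "+")
    keep <- keep & (n_ones <= 1L)
  }
  keep
}

# Sphere with radius displaced inward by band-limited value noise of the
# direction vector: r(u) = r0 * (1 - amplitude * (f(u) + 1) / 2) with
# f in [-1, 1], so the outer envelope (and hence the bounding box) is
# amplitude-independent and only the surface roughness changes.
perturbed_sphere <- function(grid_size, amplitude, octaves, seed) {
  centre <- (grid_size + 1) / 2
  r0 <- grid_size / 2 - 2
  if (r0 < 2) stop("grid too small for a sphere at this amplitude")
  ax <- seq_len(grid_size) - centre
  X <- array(ax, rep(grid_size, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  R <- sqrt(X^2 + Y^2 + Z^2)
  if (amplitude == 0) return(R <= r0)
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(seed)
  f <- array(0, rep(grid_size, 3))
  U <- list(X / pmax(R, 1e-9), Y / pmax(R, 1e-9), Z / pmax(R, 1e-9))
  for (o in seq_len(max(1L, as.integer(octaves)))) {
    ng <- 3L + 4L * 2L^o  # lattice resolution doubles per octave
    lattice <- array(stats::rnorm(ng^3), rep(ng, 3))
    f <- f + trilinear_unit(lattice, U[[1]], U[[2]], U[[3]])
  }
  f <- f / max(abs(f))
  R <= r0 * (1 - amplitude * (f + 1) / 2)
}

# Trilinear interpolation of a cubic lattice over the unit cube [-1,1]^3.
trilinear_unit <- function(lat, ux, uy, uz) {
  ng <- dim(lat)[1]
  to_idx <- function(u) pmin(pmax((u + 1) / 2 * (ng - 1) + 1, 1), ng)
  gx <- to_idx(ux); gy <- to_idx(uy); gz <- to_idx(uz)
  x0 <- pmin(floor(gx), ng - 1); y0 <- pmin(floor(gy), ng - 1)
  z0 <- pmin(floor(gz), ng - 1)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  at <- function(i, j, k) lat[cbind(as.vector(i), as.vector(j), as.vector(k))]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
    fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
    fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
  array(v, dim(ux))
}

#' Embed a binary mask into a larger label volume
#'
#' Places `mask` as region `label` at voxel `origin` of an otherwise
#' background volume, e.g. to test translation invariance of [region_fd()].
#'
#' @param mask a [binary_mask()].
#' @param dim dimensions of the enclosing volume.
#' @param origin 1-based voxel position of the mask's first corner.
#' @param label region label to assign.
#' @param spacing voxel spacing of the volume.
#' @return A [label_volume()].
#' @export
embed_mask <- function(mask, dim, origin = c(1L, 1L, 1L), label = 1L,
                       spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "binary_mask"))
  md <- base::dim(mask$data)
  if (any(origin + md - 1L > dim)) stop("mask does not fit at this origin")
  vol <- array(0L, dim)
  sl <- lapply(seq_len(3), function(a) origin[a]:(origin[a] + md[a] - 1L))
  vol[sl[[1]], sl[[2]], sl[[3]]] <-
    ifelse(mask$data, as.integer(label), 0L)
  label_volume(vol, spacing = spacing)
}
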