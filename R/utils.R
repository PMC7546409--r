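# shared geometry and interpolation helpers

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v, what = "vector") {
  n <- norm3(v)
  if (!is.finite(n) || n < 1e-12)
    stop("degenerate ", what, ": zero length")
  v / n
}

# voxel centers along one axis: origin + (i - 1/2) * h, i = 1..n
axis_centers <- function(n, h, origin = 0) origin + (seq_len(n) - 0.5) * h

# full matrix of voxel-center coordinates is avoided; most code works with
# per-axis center vectors and outer sums.

# grid index of the voxel containing each point (rows of p), NA outside
point_to_index <- function(p, dim, h, origin = c(0, 0, 0)) {
  idx <- sweep(p, 2, origin)
  idx <- floor(idx / h) + 1
  bad <- idx[, 1] < 1 | idx[, 1] > dim[1] |
         idx[, 2] < 1 | idx[, 2] > dim[2] |
         idx[, 3] < 1 | idx[, 3] > dim[3]
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

linear_index <- function(idx, dim) {
  idx[, 1] + dim[1] * (idx[, 2] - 1L) + dim[1] * dim[2] * (idx[, 3] - 1L)
}

# vectorised trilinear interpolation on a cell-centred grid; points must lie
# within the convex hull of the voxel centers (half a voxel inside the box)
trilinear <- function(arr, h, origin, p) {
  dm <- dim(arr)
  q <- sweep(p, 2, origin + 0.5 * h) / h   # continuous 0-based cell coords
  i0 <- pmin(pmax(floor(q[, 1]), 0), dm[1] - 2)
  j0 <- pmin(pmax(floor(q[, 2]), 0), dm[2] - 2)
  k0 <- pmin(pmax(floor(q[, 3]), 0), dm[3] - 2)
  fx <- q[, 1] - i0
  fy <- q[, 2] - j0
  fz <- q[, 3] - k0
  base <- (i0 + 1) + dm[1] * j0 + dm[1] * dm[2] * k0
  sx <- 1L
  sy <- dm[1]
  sz <- dm[1] * dm[2]
  v000 <- arr[base]
  v100 <- arr[base + sx]
  v010 <- arr[base + sy]
  v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz]
  v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz]
  v111 <- arr[base + sx + sy + sz]
  (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
              fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
          fy * ((1 - fx) * v011 + fx * v111))
}

# is p (rows) strictly inside the interpolable region of a grid block
in_grid_interior <- function(p, dim, h, origin, margin = 0.5) {
  lo <- origin + margin * h
  hi <- origin + (dim - margin) * h
  p[, 1] >= lo[1] & p[, 1] <= hi[1] &
    p[, 2] >= lo[2] & p[, 2] <= hi[2] &
    p[, 3] >= lo[3] & p[, 3] <= hi[3]
}

# deterministic tiny jitter used to break lattice degeneracies before the
# convex-hull construction (linear congruential, independent of R's RNG)
det_jitter <- function(n, scale) {
  out <- numeric(n)
  x <- 123456789
  for (i in seq_len(n)) {
    x <- (69069 * x + 1) %% 4294967296  # stays below 2^53, exact in doubles
    out[i] <- (x / 4294967296 - 0.5) * 2 * scale
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
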