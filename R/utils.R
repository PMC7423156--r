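# Internal helpers shared across modules.

# Linear voxel index for an n x 3 matrix of 1-based voxel coordinates.
.linIdx <- function(vox, dim) {
  vox <- matrix(as.integer(vox), ncol = 3L)
  vox[, 1L] + (vox[, 2L] - 1L) * dim[1L] + (vox[, 3L] - 1L) * dim[1L] * dim[2L]
}

# Inverse of .linIdx: n x 3 matrix of voxel coordinates.
.voxCoord <- function(idx, dim) {
  idx0 <- as.integer(idx) - 1L
  x <- idx0 %% dim[1L]
  y <- (idx0 %/% dim[1L]) %% dim[2L]
  z <- idx0 %/% (dim[1L] * dim[2L])
  cbind(x + 1L, y + 1L, z + 1L)
}

# Containing voxel of continuous positions given in voxel units
# (voxel i spans [i-1, i); its center is i - 0.5).
.posToVox <- function(pos) {
  matrix(as.integer(floor(pos)) + 1L, ncol = 3L)
}

.inGrid <- function(vox, dim) {
  vox[, 1L] >= 1L & vox[, 1L] <= dim[1L] &
    vox[, 2L] >= 1L & vox[, 2L] <= dim[2L] &
    vox[, 3L] >= 1L & vox[, 3L] <= dim[3L]
}

# Canonical sign for undirected (axial) orientations: flip each row so its
# first component of magnitude > 1e-12 is positive.
.canonicalSign <- function(v) {
  v <- matrix(v, ncol = 3L)
  s <- sign(v[, 1L])
  tiny <- abs(v[, 1L]) <= 1e-12
  s[tiny] <- sign(v[tiny, 2L])
  tiny2 <- tiny & abs(v[, 2L]) <= 1e-12
  s[tiny2] <- sign(v[tiny2, 3L])
  s[s == 0] <- 1
  v * s
}

.rowNorm <- function(v) sqrt(rowSums(v * v))

.unitRows <- function(v) {
  n <- .rowNorm(v)
  n[n == 0] <- 1
  v / n
}

# A pair of unit vectors orthogonal to each row of d (d assumed unit rows).
.perpBasis <- function(d) {
  d <- matrix(d, ncol = 3L)
  n <- nrow(d)
  a <- matrix(rep(c(1, 0, 0), each = n), ncol = 3L)
  swap <- abs(d[, 1L]) > 0.9
  a[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3L)
  e1 <- .unitRows(cbind(
    d[, 2L] * a[, 3L] - d[, 3L] * a[, 2L],
    d[, 3L] * a[, 1L] - d[, 1L] * a[, 3L],
    d[, 1L] * a[, 2L] - d[, 2L] * a[, 1L]
  ))
  e2 <- cbind(
    d[, 2L] * e1[, 3L] - d[, 3L] * e1[, 2L],
    d[, 3L] * e1[, 1L] - d[, 1L] * e1[, 3L],
    d[, 1L] * e1[, 2L] - d[, 2L] * e1[, 1L]
  )
  list(e1 = e1, e2 = e2)
}

# Guard uniforms away from exactly 0/1 before inverse-CDF transforms.
.clampU <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)

.isMask <- function(x) is.array(x) && (is.logical(x) || all(x %in% c(0, 1)))

.sameGrid <- function(a, b) identical(dim(a), dim(b))

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
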