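# Low-level array utilities shared across the imaging modules: connected
# components, separable Gaussian (derivative) filtering, morphology, trilinear
# sampling, closed-form eigenvalues of symmetric 3x3 fields.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_cac <- function(message, class) {
  stop(structure(
    class = c(class, "cacscore_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Neighbourhood offsets (voxel steps) for a given 3D connectivity.
neighbor_steps <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) {
    g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  } else if (connectivity == 18L) {
    g <- g[rowSums(abs(g)) <= 2L, , drop = FALSE]
  } else if (connectivity != 26L) {
    stop_cac("connectivity must be 6, 18 or 26", "cac_parameter_error")
  }
  g
}

#' Label connected components of a 3D logical array
#'
#' Frontier breadth-first search over a border-padded copy of the array, so
#' neighbour indexing needs no boundary checks. A 2D slice passed as an
#' `nx x ny x 1` array with `connectivity = 26` gives classic in-plane
#' 8-connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same dim; 0 = background, components numbered
#'   from 1 in discovery order.
#' @keywords internal
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) == 2L) {
    mask <- array(mask, c(d, 1L))
    d <- dim(mask)
  }
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  steps <- neighbor_steps(connectivity)
  offs <- steps[, 1L] + steps[, 2L] * dp[1L] + steps[, 3L] * dp[1L] * dp[2L]
  lab <- integer(prod(dp))
  fg <- which(padded)
  todo <- rep(TRUE, length(lab))
  cur <- 0L
  for (seed in fg) {
    if (!todo[seed] || lab[seed] > 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[frontier] <- cur
    todo[frontier] <- FALSE
    while (length(frontier)) {
      nb <- rep(frontier, each = length(offs)) + offs
      nb <- nb[padded[nb] & lab[nb] == 0L]
      if (!length(nb)) break
      nb <- unique(nb)
      lab[nb] <- cur
      todo[nb] <- FALSE
      frontier <- nb
    }
  }
  lab <- array(lab, dp)
  lab[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# Per-slice 2D 8-connected labelling; returns a list of integer matrices.
label_slices_2d <- function(mask3d) {
  d <- dim(mask3d)
  lapply(seq_len(d[3]), function(k) {
    lab <- label_components(array(mask3d[, , k], c(d[1], d[2], 1L)), 26L)
    matrix(lab, d[1], d[2])
  })
}

# Binary dilation by `iter` steps of the given connectivity.
dilate_mask <- function(mask, iter = 1L, connectivity = 26L) {
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  steps <- neighbor_steps(connectivity)
  offs <- steps[, 1L] + steps[, 2L] * dp[1L] + steps[, 3L] * dp[1L] * dp[2L]
  for (it in seq_len(iter)) {
    fg <- which(padded)
    nb <- unique(rep(fg, each = length(offs)) + offs)
    padded[nb] <- TRUE
    # re-clear the pad border so growth cannot wrap
    padded[c(1L, dp[1]), , ] <- FALSE
    padded[, c(1L, dp[2]), ] <- FALSE
    padded[, , c(1L, dp[3])] <- FALSE
  }
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# Sampled Gaussian kernel and its first/second derivatives (voxel units).
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(2L, ceiling(3.5 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    return(k - mean(k))
  }
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    return(k - mean(k))
  }
  stop_cac("kernel order must be 0, 1 or 2", "cac_parameter_error")
}

# Correlate a 3D array with a 1D kernel along one axis, replicate-padded
# edges, implemented as a dense band-matrix multiply (sizes here are small).
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  # row i of B picks up kernel taps at replicate-clamped positions
  idx <- outer(seq_len(n), seq(-r, r), `+`)
  idx <- clamp(idx, 1L, n)
  B <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    B[cbind(seq_len(n), idx[, j])] <- B[cbind(seq_len(n), idx[, j])] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- B %*% matrix(a, n, prod(da[-1L]))
  out <- array(m, da)
  aperm(out, order(perm))
}

# Separable Gaussian smoothing with per-axis sigma in voxel units.
gauss_smooth <- function(arr, sigma_vox) {
  out <- arr
  for (ax in 1:3) {
    if (sigma_vox[ax] > 1e-6) {
      out <- conv_axis(out, gauss_kernel(sigma_vox[ax], 0L), ax)
    }
  }
  out
}

# Second-derivative (Hessian entry) of a Gaussian-smoothed array, in
# physical units (per mm^2). `orders` is the derivative order per axis.
gauss_deriv <- function(arr, sigma_vox, spacing, orders) {
  out <- arr
  scale <- 1
  for (ax in 1:3) {
    out <- conv_axis(out, gauss_kernel(sigma_vox[ax], orders[ax]), ax)
    if (orders[ax] > 0L) scale <- scale / spacing[ax]^orders[ax]
  }
  out * scale
}

#' Eigenvalues of a field of symmetric 3x3 matrices
#'
#' Closed-form (trigonometric) solution, fully vectorised. Returns the three
#' eigenvalue vectors sorted by increasing absolute value, the ordering the
#' Frangi vesselness measure uses.
#' @keywords internal
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-12
  pe <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / pe; b22 <- (a22 - q) / pe; b33 <- (a33 - q) / pe
  b12 <- a12 / pe; b13 <- a13 / pe; b23 <- a23 / pe
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- clamp(detB / 2, -1, 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # sort each triple by |.| ascending with a 3-element sorting network
  sw <- function(a, b) {
    s <- abs(a) > abs(b)
    list(a = ifelse(s, b, a), b = ifelse(s, a, b))
  }
  s1 <- sw(e1, e2); e1 <- s1$a; e2 <- s1$b
  s2 <- sw(e2, e3); e2 <- s2$a; e3 <- s2$b
  s3 <- sw(e1, e2); e1 <- s3$a; e2 <- s3$b
  list(l1 = e1, l2 = e2, l3 = e3)
}

#' Trilinear interpolation of a voxel grid at physical points
#'
#' @param vol a [voxel_volume()].
#' @param pts n x 3 matrix of physical coordinates in mm.
#' @param outside value returned for points outside the grid.
#' @keywords internal
trilinear_sample <- function(vol, pts, outside = NA_real_) {
  d <- dim(vol$data)
  # continuous voxel coordinate: 1-based index of the containing sample
  cx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  cy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  cz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  x0 <- clamp(floor(cx), 1, d[1] - 1L); y0 <- clamp(floor(cy), 1, d[2] - 1L)
  z0 <- clamp(floor(cz), 1, d[3] - 1L)
  fx <- clamp(cx - x0, 0, 1); fy <- clamp(cy - y0, 0, 1); fz <- clamp(cz - z0, 0, 1)
  at <- function(i, j, k) vol$data[cbind(i, j, k)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
  bad <- cx < 1 | cx > d[1] | cy < 1 | cy > d[2] | cz < 1 | cz > d[3]
  v[bad] <- outside
  v
}

# Physical mm coordinates of voxel indices (n x 3 integer matrix).
index_to_mm <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

# Nearest voxel index of physical points; NA rows for points off the grid.
mm_to_index <- function(vol, pts) {
  d <- dim(vol$data)
  idx <- round(sweep(sweep(pts, 2, vol$origin, `-`), 2, vol$spacing, `/`)) + 1
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  idx
}
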