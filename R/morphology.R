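# 3-D binary morphology, connected components and separable Gaussian
# filtering on plain arrays. The structuring element for erosion/dilation is
# the 6-connected radius-1 cross applied `radius` times (a city-block ball);
# connected components use 26-connectivity. Nothing here knows about grids.

# shift a 3-D array along one axis by `by` voxels, padding with `fill`
shift3 <- function(x, axis, by, fill) {
  d <- dim(x)
  if (by == 0L) return(x)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- src + by
  if (axis == 1L) out[dst, , ] <- x[src, , ]
  else if (axis == 2L) out[, dst, ] <- x[, src, ]
  else out[, , dst] <- x[, , src]
  out
}

dilate_once <- function(x, axes = 1:3) {
  out <- x
  for (ax in axes) {
    if (dim(x)[ax] < 2L) next
    out <- out | shift3(x, ax, 1L, FALSE) | shift3(x, ax, -1L, FALSE)
  }
  out
}

erode_once <- function(x, axes = 1:3) {
  out <- x
  for (ax in axes) {
    out <- out & shift3(x, ax, 1L, FALSE) & shift3(x, ax, -1L, FALSE)
  }
  out
}

#' Binary dilation, erosion, closing
#'
#' Morphology with a 6-connected radius-1 cross applied `radius` times
#' (equivalently, a city-block ball of the given radius). Voxels outside the
#' array are treated as background, so erosion eats the array border —
#' matching the isotropic 1-voxel erosion used to trim the phantom mask.
#'
#' @param x Logical 3-D array.
#' @param radius Number of elementary dilations/erosions (>= 0).
#' @param axes Axes the element extends along (default all three; pass
#'   `1:2` for slice-wise 2-D morphology).
#' @return Logical 3-D array.
#' @export
mask_dilate <- function(x, radius = 1L, axes = 1:3) {
  for (i in seq_len(radius)) x <- dilate_once(x, axes)
  x
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(x, radius = 1L, axes = 1:3) {
  for (i in seq_len(radius)) x <- erode_once(x, axes)
  x
}

#' @rdname mask_dilate
#' @export
mask_close <- function(x, radius = 1L, axes = 1:3) {
  if (radius < 1L) return(x)
  # closing on the unbounded domain: pad by the radius so that dilation is
  # not clipped at the array boundary (otherwise the subsequent erosion
  # would eat objects touching the edge)
  d <- dim(x)
  pad <- integer(3)
  pad[axes] <- radius
  big <- array(FALSE, dim = d + 2L * pad)
  ix <- lapply(1:3, function(a) seq_len(d[a]) + pad[a])
  big[ix[[1]], ix[[2]], ix[[3]]] <- x
  big <- mask_erode(mask_dilate(big, radius, axes), radius, axes)
  big[ix[[1]], ix[[2]], ix[[3]]]
}

neighbour_offsets_26 <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  # keep one of each +/- pair (undirected edges)
  off[off$dz > 0 | (off$dz == 0 & (off$dy > 0 | (off$dy == 0 & off$dx > 0))), ]
}

#' Largest connected component of a binary array
#'
#' 26-connected components via an [igraph] voxel graph; returns the mask of
#' the largest component (ties broken by first label).
#'
#' @param x Logical 3-D array with at least one `TRUE` voxel.
#' @return Logical 3-D array of the same shape.
#' @export
largest_component <- function(x) {
  d <- dim(x)
  fg <- which(x)
  if (length(fg) == 0L) stop("empty mask: no connected component")
  rank <- integer(length(x))
  rank[fg] <- seq_along(fg)
  offs <- neighbour_offsets_26()
  ei <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    sx <- if (dx >= 0) 1:(d[1] - dx) else (1 - dx):d[1]
    sy <- if (dy >= 0) 1:(d[2] - dy) else (1 - dy):d[2]
    sz <- if (dz >= 0) 1:(d[3] - dz) else (1 - dz):d[3]
    a <- x[sx, sy, sz] & x[sx + dx, sy + dy, sz + dz]
    if (!any(a)) next
    # linear indices of the first endpoint within the full array
    base <- which(a)
    # convert block-local to full-array linear index
    nb1 <- length(sx); nb2 <- length(sy)
    i3 <- (base - 1L) %/% (nb1 * nb2)
    rem <- (base - 1L) %% (nb1 * nb2)
    i2 <- rem %/% nb1
    i1 <- rem %% nb1
    li1 <- (sx[1] + i1) + (sy[1] + i2 - 1L) * d[1] + (sz[1] + i3 - 1L) * d[1] * d[2]
    li2 <- li1 + dx + dy * d[1] + dz * d[1] * d[2]
    ei[[r]] <- rbind(rank[li1], rank[li2])
  }
  edges <- do.call(cbind, ei)
  if (is.null(edges) || ncol(edges) == 0L) {
    # no adjacencies: every foreground voxel is its own component
    out <- array(FALSE, dim = d)
    out[fg[1]] <- TRUE
    return(out)
  }
  g <- igraph::make_graph(edges = as.vector(edges), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, dim = d)
  out[fg[keep]] <- TRUE
  out
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing
#'
#' Per-axis separable Gaussian convolution with edge renormalisation (the
#' kernel is re-scaled by the in-bounds weight so flat regions stay flat at
#' the array border). `sigma` is given per axis in voxel units; a zero
#' entry skips that axis, so in-plane 2-D filtering is `c(0, s, s)` etc.
#'
#' @param x Numeric 3-D array.
#' @param sigma Numeric length-3 vector of standard deviations in voxels.
#' @return Numeric 3-D array.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(length(sigma) == 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel(sigma[ax])
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim = dim(x))
    wgt <- array(0, dim = dim(x))
    ones <- array(1, dim = dim(x))
    for (j in seq_along(k)) {
      by <- j - r - 1L
      if (abs(by) >= dim(x)[ax] && by != 0L) next
      acc <- acc + k[j] * shift3(x, ax, by, 0)
      wgt <- wgt + k[j] * shift3(ones, ax, by, 0)
    }
    x <- acc / wgt
  }
  x
}
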