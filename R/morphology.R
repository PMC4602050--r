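#' Structuring element specification
#'
#' Flat structuring elements for binary morphology on interval domains:
#' the unit element is a diamond/octahedron for 4- (2D) or 6-connectivity
#' (3D) and a square/cube for 8- or 26-connectivity; radius `r` means the
#' r-fold Minkowski sum of the unit element, i.e. the city-block or
#' chessboard ball of radius `r`.
#'
#' @param radius non-negative integer radius in voxels.
#' @param connectivity 4 or 8 for 2D domains, 6 or 26 for 3D.
#' @return A `structuring_spec`.
#' @export
structuring_spec <- function(radius = 1L, connectivity = 8L) {
  radius <- as.integer(radius)
  connectivity <- as.integer(connectivity)
  if (radius < 0L) stop("radius must be non-negative")
  if (!connectivity %in% c(4L, 8L, 6L, 26L))
    stop("connectivity must be 4/8 (2D) or 6/26 (3D)")
  structure(list(radius = radius, connectivity = connectivity),
            class = "structuring_spec")
}

check_connectivity <- function(dim, connectivity) {
  ok2 <- c(4L, 8L); ok3 <- c(6L, 26L)
  if (dim == 2L && !connectivity %in% ok2)
    stop("2D domains require connectivity 4 or 8")
  if (dim == 3L && !connectivity %in% ok3)
    stop("3D domains require connectivity 6 or 26")
}

as_struct <- function(s, connectivity) {
  if (inherits(s, "structuring_spec")) s
  else structuring_spec(s, connectivity)
}

# Expand every interval by r along x (no merging assumptions; canonicalized).
expand_x <- function(ivs, r) {
  if (nrow(ivs) == 0L || r == 0L) return(ivs)
  ivs[, 3] <- ivs[, 3] - r
  ivs[, 4] <- ivs[, 4] + r
  ivs
}

# Offsets (dy, dz) of the ball of radius r with per-offset x half-width:
# chessboard -> full square/cube, city-block -> diamond/octahedron.
ball_offsets <- function(r, dim, chessboard) {
  if (dim == 2L) {
    dy <- seq.int(-r, r)
    dz <- rep(0L, length(dy))
  } else {
    g <- expand.grid(dy = seq.int(-r, r), dz = seq.int(-r, r))
    dy <- g$dy; dz <- g$dz
  }
  wx <- if (chessboard) rep(r, length(dy)) else r - abs(dy) - abs(dz)
  keep <- wx >= 0L
  data.frame(dy = dy[keep], dz = dz[keep], wx = wx[keep])
}

#' Morphological dilation of an interval domain
#'
#' Dilation by the city-block (connectivity 4/6) or chessboard
#' (connectivity 8/26) ball of the given radius, computed as a union of
#' row-shifted, x-expanded copies — entirely on the interval coding. When
#' the domain carries a frame the result is clipped to the frame grid, so
#' behaviour near the model boundary is reproducible.
#'
#' @param A an `interval_domain`.
#' @param s a [structuring_spec()], or an integer radius.
#' @param connectivity used when `s` is a bare radius; defaults to 8 (2D)
#'   or 26 (3D).
#' @return The dilated `interval_domain`.
#' @export
dom_dilate <- function(A, s = 1L, connectivity = if (A$dim == 2L) 8L else 26L) {
  s <- as_struct(s, connectivity)
  check_connectivity(A$dim, s$connectivity)
  r <- s$radius
  if (r == 0L || nrow(A$ivs) == 0L) return(A)
  off <- ball_offsets(r, A$dim, s$connectivity %in% c(8L, 26L))
  parts <- lapply(seq_len(nrow(off)), function(i) {
    ivs <- A$ivs
    ivs[, 1] <- ivs[, 1] + off$dz[i]
    ivs[, 2] <- ivs[, 2] + off$dy[i]
    expand_x(ivs, off$wx[i])
  })
  out <- new_domain(cpp_iv_canon(do.call(rbind, parts)), A$dim, A$frame)
  if (!is.null(A$frame)) out <- dom_intersect(out, dom_full(A$frame))
  out
}

#' Morphological erosion of an interval domain
#'
#' Erosion by the same family of structuring elements as [dom_dilate()],
#' computed by duality: the complement (within the bounding box grown by
#' the radius) is dilated and subtracted. Voxels of `A` closer than the
#' radius to the domain boundary are removed; outside the frame (or the
#' grown bounding box for frameless domains) counts as background.
#'
#' @inheritParams dom_dilate
#' @return The eroded `interval_domain`, a subset of `A`.
#' @export
dom_erode <- function(A, s = 1L, connectivity = if (A$dim == 2L) 8L else 26L) {
  s <- as_struct(s, connectivity)
  check_connectivity(A$dim, s$connectivity)
  r <- s$radius
  if (r == 0L || nrow(A$ivs) == 0L) return(A)
  bb <- dom_bbox(A)
  pad <- r + 1L
  x0 <- bb["min", "x"] - pad; x1 <- bb["max", "x"] + pad + 1L
  y0 <- bb["min", "y"] - pad; y1 <- bb["max", "y"] + pad + 1L
  if (A$dim == 3L) {
    z0 <- bb["min", "z"] - pad; z1 <- bb["max", "z"] + pad + 1L
  } else { z0 <- 0L; z1 <- 1L }
  rect <- dom_box(x0, x1, y0, y1, z0, z1, dim = A$dim)
  comp <- new_domain(cpp_iv_setop(rect$ivs, A$ivs, 2L), A$dim)
  grown <- dom_dilate(comp, s)
  out <- new_domain(cpp_iv_setop(A$ivs, grown$ivs, 2L), A$dim, A$frame)
  out
}

#' Grid distance transform relative to a domain
#'
#' Integer shortest-path distance from every voxel of the frame to the
#' nearest voxel of `A`, under the city-block (4/6-neighbour steps) or
#' chessboard (8/26-neighbour steps) metric. Computed by successive unit
#' dilations of `A`: the d-th dilation ring receives distance d.
#'
#' @param A a nonempty `interval_domain`.
#' @param shape frame dimensions in array order; defaults to `A`'s frame.
#' @param metric `"city-block"` or `"chessboard"`.
#' @return A `distance_field`: list with `values` (integer array of
#'   dimension `shape`, 0 exactly on `A`) and `metric`.
#' @export
distance_transform <- function(A, shape = NULL,
                               metric = c("city-block", "chessboard")) {
  metric <- match.arg(metric)
  if (nrow(A$ivs) == 0L) stop("distance transform of an empty domain")
  if (is.null(shape)) {
    if (is.null(A$frame)) stop("shape is required for a frameless domain")
    shape <- A$frame$shape
  }
  shape <- as.integer(shape)
  conn <- if (metric == "city-block") {
    if (A$dim == 2L) 4L else 6L
  } else {
    if (A$dim == 2L) 8L else 26L
  }
  fr <- frame_spec(if (is.null(A$frame)) "dt" else A$frame$id, shape)
  full <- dom_full(fr)
  vals <- array(NA_integer_, shape)
  cur <- new_domain(cpp_iv_setop(A$ivs, full$ivs, 1L), A$dim, fr)
  vals[linear_indices(cur$ivs, shape)] <- 0L
  d <- 0L
  while (dom_size(cur) < prod(shape)) {
    d <- d + 1L
    nxt <- dom_dilate(cur, structuring_spec(1L, conn))
    ring <- dom_diff(nxt, cur)
    if (nrow(ring$ivs) == 0L) stop("distance transform failed to cover frame")
    vals[linear_indices(ring$ivs, shape)] <- d
    cur <- nxt
  }
  structure(list(values = vals, metric = metric), class = "distance_field")
}

#' Connected-component labelling of an interval domain
#'
#' Splits a domain into its connected components by a single pass over the
#' interval table: each interval is merged (union-find) with overlapping
#' intervals on the adjacent lines already seen, where "overlapping" is
#' widened by one voxel for the diagonal connectivities.
#'
#' @param A an `interval_domain`.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D).
#' @return A list of `interval_domain` components, pairwise disjoint, whose
#'   union is `A`, sorted by size descending with ties broken by bounding
#'   box (lexicographic, smallest first).
#' @export
dom_label <- function(A, connectivity = if (A$dim == 2L) 8L else 26L) {
  connectivity <- as.integer(connectivity)
  check_connectivity(A$dim, connectivity)
  ivs <- A$ivs
  n <- nrow(ivs)
  if (n == 0L) return(list())
  diag_xy <- connectivity %in% c(8L, 26L)
  # adjacent lines to inspect: (dz, dy) strictly before the current line
  nb <- list(c(0L, -1L))
  if (A$dim == 3L) {
    nb <- c(nb, list(c(-1L, 0L)))
    if (connectivity == 26L)
      nb <- c(nb, list(c(-1L, -1L), c(-1L, 1L)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- paste(ivs[, 1], ivs[, 2])
  line_idx <- split(seq_len(n), key)
  slack <- if (diag_xy) 1L else 0L
  for (i in seq_len(n)) {
    for (d in nb) {
      k <- paste(ivs[i, 1] + d[1], ivs[i, 2] + d[2])
      js <- line_idx[[k]]
      if (is.null(js)) next
      for (j in js) {
        if (ivs[j, 3] < ivs[i, 4] + slack && ivs[i, 3] < ivs[j, 4] + slack)
          unite(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- lapply(split(seq_len(n), roots), function(idx)
    new_domain(ivs[idx, , drop = FALSE], A$dim, A$frame))
  sizes <- vapply(comps, dom_size, numeric(1))
  bbs <- vapply(comps, function(cmp) {
    bb <- dom_bbox(cmp)
    as.numeric(rbind(bb))  # min row then max row, column order y,x[,z]
  }, numeric(if (A$dim == 2L) 4L else 6L))
  ord <- do.call(order, c(list(-sizes), lapply(seq_len(nrow(bbs)),
                                               function(r) bbs[r, ])))
  unname(comps[ord])
}

#' Threshold segmentation of a scalar image
#'
#' Domain of all cells whose value lies in the closed band
#' `[low, high]` — the scalar-channel primitive behind colour-threshold
#' signal extraction.
#'
#' @param image numeric 2D matrix or 3D array.
#' @param low,high band limits, `low <= high`.
#' @param frame optional [frame_spec()] for the result.
#' @return An `interval_domain`.
#' @export
threshold_segment <- function(image, low, high, frame = NULL) {
  if (low > high) stop("low must not exceed high")
  interval_domain(image >= low & image <= high, frame = frame)
}
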