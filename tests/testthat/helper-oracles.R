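# Dense-array brute-force oracles, written independently of the interval
# implementation: everything here works voxel-by-voxel on logical arrays.

random_mask <- function(shape, p = 0.4) {
  array(stats::runif(prod(shape)) < p, shape)
}

# Random domain + its mask, as a pair.
random_case <- function(shape, p = 0.4, frame = NULL) {
  m <- random_mask(shape, p)
  list(mask = m, dom = interval_domain(m, frame = frame))
}

# Neighbourhood offsets of the unit structuring element.
unit_offsets <- function(dim, connectivity) {
  if (dim == 2L) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = 0)
    keep <- if (connectivity == 4L) abs(g$dx) + abs(g$dy) <= 1 else TRUE
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    keep <- if (connectivity == 6L) abs(g$dx) + abs(g$dy) + abs(g$dz) <= 1 else TRUE
  }
  g[keep, , drop = FALSE]
}

# Shift a mask by (dx, dy, dz), zero-filling; mask in [y, x(, z)] order.
shift_mask <- function(m, dx, dy, dz = 0) {
  d <- dim(m)
  out <- array(FALSE, d)
  ny <- d[1]; nx <- d[2]; nz <- if (length(d) == 3) d[3] else 1
  ys <- seq_len(ny); xs <- seq_len(nx); zs <- seq_len(nz)
  sy <- ys - dy; sx <- xs - dx; sz <- zs - dz
  oky <- sy >= 1 & sy <= ny; okx <- sx >= 1 & sx <= nx; okz <- sz >= 1 & sz <= nz
  m3 <- array(m, c(ny, nx, nz))
  o3 <- array(FALSE, c(ny, nx, nz))
  o3[ys[oky], xs[okx], zs[okz]] <- m3[sy[oky], sx[okx], sz[okz]]
  array(o3, d)
}

dense_dilate <- function(m, r, connectivity) {
  off <- unit_offsets(if (length(dim(m)) == 2) 2L else 3L, connectivity)
  for (i in seq_len(r)) {
    acc <- array(FALSE, dim(m))
    for (k in seq_len(nrow(off)))
      acc <- acc | shift_mask(m, off$dx[k], off$dy[k], off$dz[k])
    m <- acc
  }
  m
}

# Erosion treating outside-of-array as background; oracle pads the array so
# boundary effects match the implementation's "outside = background" rule.
dense_erode <- function(m, r, connectivity) {
  d <- dim(m)
  if (length(d) == 2) {
    pad <- array(FALSE, d + 2 * r)
    pad[r + seq_len(d[1]), r + seq_len(d[2])] <- m
  } else {
    pad <- array(FALSE, d + 2 * r)
    pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- m
  }
  off <- unit_offsets(length(d), connectivity)
  for (i in seq_len(r)) {
    acc <- array(TRUE, dim(pad))
    for (k in seq_len(nrow(off)))
      acc <- acc & shift_mask(pad, off$dx[k], off$dy[k], off$dz[k])
    pad <- acc
  }
  if (length(d) == 2) pad[r + seq_len(d[1]), r + seq_len(d[2])]
  else pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

# Multi-source breadth-first-search grid distance.
dense_bfs_distance <- function(m, connectivity) {
  dist <- array(NA_integer_, dim(m))
  dist[m] <- 0L
  frontier <- m
  d <- 0L
  while (anyNA(dist)) {
    d <- d + 1L
    grown <- dense_dilate(frontier, 1L, connectivity)
    ring <- grown & is.na(dist)
    if (!any(ring)) break
    dist[ring] <- d
    frontier <- grown
  }
  dist
}

# Connected components by repeated seed flood-fill (dilate-and-intersect).
dense_components <- function(m, connectivity) {
  comps <- list()
  left <- m
  while (any(left)) {
    seed <- array(FALSE, dim(m))
    seed[which(left)[1]] <- TRUE
    repeat {
      grown <- dense_dilate(seed, 1L, connectivity) & m
      if (identical(grown, seed)) break
      seed <- grown
    }
    comps[[length(comps) + 1L]] <- seed
    left <- left & !seed
  }
  comps
}

dense_jaccard <- function(a, b) sum(a & b) / sum(a | b)

# The local similarity formula evaluated entirely on dense masks.
dense_lossst <- function(q, e, r, connectivity) {
  near <- e & dense_dilate(q, r, connectivity)
  sum(q & e) / sum(q | near)
}

expect_canonical <- function(dom) {
  expect_true(intervox:::cpp_iv_is_canonical(dom$ivs))
}

expect_dom_mask <- function(dom, mask) {
  expect_canonical(dom)
  expect_identical(to_mask(dom, dim(mask)), mask)
}

# Fresh scratch directory for file-format tests.
withr_like_tempdir <- function() {
  d <- tempfile("iofix")
  dir.create(d)
  d
}

# Write an .ivd JSON string to a temp file and return its path.
textConnection_ivd <- function(json) {
  f <- tempfile(fileext = ".ivd")
  writeLines(json, f)
  f
}

# Sorted member-id partition from generator labels, in cut_tree order.
truth_partition <- function(patterns, labels) {
  ids <- vapply(patterns, `[[`, character(1), "entry_id")
  gs <- unname(lapply(split(ids, labels), sort))
  gs[order(vapply(gs, `[`, character(1), 1))]
}
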