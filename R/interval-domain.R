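#' @useDynLib intervox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reference frame descriptor
#'
#' A frame ties a domain to the voxel grid of a specific reference model
#' (e.g. a Theiler-stage embryo model). Spatial comparisons are only
#' meaningful between domains mapped into the same frame, so all binary
#' operations refuse to combine domains whose frames differ.
#'
#' @param id character identifier of the reference model (e.g. `"TS17"`).
#' @param shape integer vector giving the dense grid dimensions in R array
#'   order: `c(ny, nx)` for 2D, `c(ny, nx, nz)` for 3D (rows, columns,
#'   planes) — i.e. what `dim()` of the dense mask returns.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(id, shape) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape <= 0L))
    stop("frame shape must be 2 or 3 positive extents")
  structure(list(id = as.character(id)[1], shape = shape),
            class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("<frame '%s' [%s]>\n", x$id, paste(x$shape, collapse = " x ")))
  invisible(x)
}

frames_compatible <- function(a, b) {
  (is.null(a) && is.null(b)) ||
    (!is.null(a) && !is.null(b) && identical(unclass(a), unclass(b)))
}

check_same_frame <- function(A, B, what = "operation") {
  if (A$dim != B$dim)
    stop(sprintf("%s requires domains of equal dimensionality", what))
  if (!frames_compatible(A$frame, B$frame))
    stop(sprintf("%s requires domains in the same reference frame", what))
}

new_domain <- function(ivs, dim, frame = NULL, canonicalize = FALSE) {
  storage.mode(ivs) <- "integer"
  if (canonicalize) ivs <- cpp_iv_canon(ivs)
  if (is.null(colnames(ivs))) colnames(ivs) <- c("z", "y", "start", "end")
  structure(list(dim = as.integer(dim), ivs = ivs, frame = frame),
            class = "interval_domain")
}

#' Convert a dense logical mask to an interval-coded domain
#'
#' Encodes the TRUE cells of a 2D or 3D logical array as per-row lists of
#' maximal half-open column intervals (run-length coding of the binary
#' region). The result is canonical: intervals are sorted, maximal, and two
#' domains covering the same voxel set always have identical structure.
#'
#' Coordinates are 0-based: the mask cell `mask[y + 1, x + 1, z + 1]`
#' corresponds to voxel `(x, y, z)`, and an interval `[start, end)` on row
#' `y` covers columns `start, ..., end - 1`.
#'
#' @param mask logical matrix (2D) or 3-way logical array (3D).
#' @param frame optional [frame_spec()]; when given, `dim(mask)` must equal
#'   the frame shape.
#' @return An `interval_domain`.
#' @seealso [to_mask()], [dom_union()], [dom_size()]
#' @export
interval_domain <- function(mask, frame = NULL) {
  if (!is.logical(mask))
    stop("mask must be a logical array")
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("mask must be a 2D matrix or 3D array")
  if (!is.null(frame)) {
    if (!inherits(frame, "frame_spec")) stop("frame must be a frame_spec")
    if (!identical(as.integer(d), frame$shape))
      stop("mask dimensions do not match the frame shape")
  }
  if (anyNA(mask)) stop("mask must not contain NA")
  new_domain(mask_runs(mask), length(d), frame)
}

# Run extraction: pair run starts with run ends along x within each (z, y)
# line; sorting by (z, y, x) aligns the k-th start with the k-th end.
mask_runs <- function(mask) {
  d <- dim(mask)
  ny <- d[1]; nx <- d[2]; nz <- if (length(d) == 3L) d[3] else 1L
  m <- array(mask, c(ny, nx, nz))
  if (!any(m)) return(matrix(integer(0), 0, 4))
  prev <- array(FALSE, dim(m))
  nxt <- array(FALSE, dim(m))
  if (nx > 1L) {
    prev[, 2:nx, ] <- m[, 1:(nx - 1L), , drop = FALSE]
    nxt[, 1:(nx - 1L), ] <- m[, 2:nx, , drop = FALSE]
  }
  st <- which(m & !prev, arr.ind = TRUE)
  en <- which(m & !nxt, arr.ind = TRUE)
  so <- order(st[, 3], st[, 1], st[, 2])
  eo <- order(en[, 3], en[, 1], en[, 2])
  st <- st[so, , drop = FALSE]
  en <- en[eo, , drop = FALSE]
  cbind(z = st[, 3] - 1L, y = st[, 1] - 1L,
        start = st[, 2] - 1L, end = en[, 2])
}

#' Create an empty domain
#'
#' @param dim 2 or 3.
#' @param frame optional [frame_spec()].
#' @return An empty `interval_domain`.
#' @export
empty_domain <- function(dim = 2L, frame = NULL) {
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3")
  new_domain(matrix(integer(0), 0, 4), dim, frame)
}

#' Decode an interval domain to a dense logical mask
#'
#' Exact inverse of [interval_domain()] on its range.
#'
#' @param dom an `interval_domain`.
#' @param shape target grid dimensions in array order; defaults to the
#'   domain's frame shape. The domain's bounding box must fit.
#' @return A logical array of dimension `shape`.
#' @export
to_mask <- function(dom, shape = NULL) {
  stopifnot(inherits(dom, "interval_domain"))
  if (is.null(shape)) {
    if (is.null(dom$frame)) stop("shape is required for a frameless domain")
    shape <- dom$frame$shape
  }
  shape <- as.integer(shape)
  if (length(shape) != dom$dim)
    stop("shape dimensionality does not match the domain")
  bb <- dom_bbox(dom)
  if (!is.null(bb)) {
    hi <- bb[2, ]
    if (any(bb[1, ] < 0L) || any(hi >= shape[seq_len(dom$dim)]))
      stop("domain bounding box exceeds the requested shape")
  }
  m <- array(FALSE, shape)
  m[linear_indices(dom$ivs, shape)] <- TRUE
  m
}

# 1-based linear indices into an array of dimension `shape` (array order
# ny, nx[, nz]) covered by the interval rows.
linear_indices <- function(ivs, shape) {
  if (nrow(ivs) == 0L) return(integer(0))
  ny <- shape[1]; nx <- shape[2]
  z <- ivs[, 1]; y <- ivs[, 2]; s <- ivs[, 3]; e <- ivs[, 4]
  lens <- e - s
  base <- (y + 1L) + ny * (s + nx * z)
  sequence(lens, from = base, by = ny)
}

#' Bounding box of a domain
#'
#' @param dom an `interval_domain`.
#' @return `NULL` for an empty domain; otherwise an integer matrix with rows
#'   `min`, `max` (inclusive, 0-based) and columns `y`, `x` (and `z` in 3D).
#' @export
dom_bbox <- function(dom) {
  ivs <- dom$ivs
  if (nrow(ivs) == 0L) return(NULL)
  bb <- cbind(y = range(ivs[, 2]),
              x = c(min(ivs[, 3]), max(ivs[, 4]) - 1L))
  if (dom$dim == 3L) bb <- cbind(bb, z = range(ivs[, 1]))
  rownames(bb) <- c("min", "max")
  bb
}

#' Voxel count of a domain
#'
#' @param dom an `interval_domain`.
#' @return Number of voxels (sum of interval lengths).
#' @export
dom_size <- function(dom) cpp_iv_size(dom$ivs)

#' Number of stored intervals
#'
#' Interval count is the storage and processing cost of a domain; for
#' typical compact regions it scales with one fewer dimension than the
#' voxel count (linearly in the diameter for 2D, quadratically for 3D).
#'
#' @param dom an `interval_domain`.
#' @return Integer interval count.
#' @export
dom_interval_count <- function(dom) nrow(dom$ivs)

#' Set algebra on interval domains
#'
#' Union, intersection and difference computed directly on the interval
#' coding: cost is proportional to the number of intervals, not to the
#' covered area or volume. Operands must share a reference frame (or both
#' be frameless) and dimensionality. Results are canonical. The group
#' generic operators `A | B`, `A & B` and `A - B` are available as
#' shorthand.
#'
#' @param A,B `interval_domain` objects in the same frame.
#' @return An `interval_domain` in the operands' frame.
#' @examples
#' a <- interval_domain(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
#' b <- interval_domain(matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
#' dom_size(dom_union(a, b))
#' dom_size(a & b)
#' @export
dom_union <- function(A, B) {
  check_same_frame(A, B, "union")
  new_domain(cpp_iv_canon(rbind(A$ivs, B$ivs)), A$dim, A$frame)
}

#' @rdname dom_union
#' @export
dom_intersect <- function(A, B) {
  check_same_frame(A, B, "intersect")
  new_domain(cpp_iv_setop(A$ivs, B$ivs, 1L), A$dim, A$frame)
}

#' @rdname dom_union
#' @export
dom_diff <- function(A, B) {
  check_same_frame(A, B, "difference")
  new_domain(cpp_iv_setop(A$ivs, B$ivs, 2L), A$dim, A$frame)
}

#' @export
Ops.interval_domain <- function(e1, e2) {
  switch(.Generic,
         "|" = dom_union(e1, e2),
         "&" = dom_intersect(e1, e2),
         "-" = dom_diff(e1, e2),
         "==" = dom_identical(e1, e2),
         "!=" = !dom_identical(e1, e2),
         stop(sprintf("operator '%s' not defined for interval domains",
                      .Generic)))
}

#' Structural equality of two domains
#'
#' Because the representation is canonical, two domains cover the same
#' voxel set if and only if their interval tables are identical.
#'
#' @param A,B `interval_domain` objects.
#' @return Logical scalar.
#' @export
dom_identical <- function(A, B) {
  A$dim == B$dim && frames_compatible(A$frame, B$frame) &&
    identical(A$ivs, B$ivs)
}

#' Test whether a domain is a subset of another
#'
#' @param A,B `interval_domain` objects in the same frame.
#' @return `TRUE` if every voxel of `A` lies in `B`.
#' @export
dom_is_subset <- function(A, B) {
  check_same_frame(A, B, "subset test")
  nrow(cpp_iv_setop(A$ivs, B$ivs, 2L)) == 0L
}

#' Translate a domain by an integer offset
#'
#' @param dom an `interval_domain` (the frame is dropped, since a shifted
#'   domain no longer refers to frame coordinates unless re-attached).
#' @param dx,dy,dz integer offsets along columns, rows and planes.
#' @param frame optional frame to attach to the result.
#' @return The translated `interval_domain`.
#' @export
dom_shift <- function(dom, dx = 0L, dy = 0L, dz = 0L, frame = NULL) {
  ivs <- dom$ivs
  if (nrow(ivs) > 0L) {
    ivs[, 1] <- ivs[, 1] + as.integer(dz)
    ivs[, 2] <- ivs[, 2] + as.integer(dy)
    ivs[, 3] <- ivs[, 3] + as.integer(dx)
    ivs[, 4] <- ivs[, 4] + as.integer(dx)
  }
  new_domain(ivs, dom$dim, frame)
}

# Filled axis-aligned box [x0,x1) x [y0,y1) (x [z0,z1)) as a domain.
dom_box <- function(x0, x1, y0, y1, z0 = 0L, z1 = 1L, dim = 2L, frame = NULL) {
  ys <- seq.int(y0, y1 - 1L)
  if (dim == 3L) {
    zs <- rep(seq.int(z0, z1 - 1L), each = length(ys))
    ys <- rep(ys, times = z1 - z0)
  } else zs <- rep(0L, length(ys))
  new_domain(cbind(z = zs, y = ys, start = x0, end = x1), dim, frame)
}

# Full-frame domain.
dom_full <- function(frame) {
  sh <- frame$shape
  if (length(sh) == 3L)
    dom_box(0L, sh[2], 0L, sh[1], 0L, sh[3], dim = 3L, frame = frame)
  else
    dom_box(0L, sh[2], 0L, sh[1], dim = 2L, frame = frame)
}

#' Test membership of voxel coordinates in a domain
#'
#' @param dom an `interval_domain`.
#' @param points numeric matrix of 0-based voxel coordinates, one row per
#'   point, columns `(x, y)` for 2D or `(x, y, z)` for 3D.
#' @return Logical vector, one element per row of `points`.
#' @export
dom_contains <- function(dom, points) {
  points <- rbind(points)
  if (ncol(points) != dom$dim) stop("point dimensionality mismatch")
  ivs <- dom$ivs
  if (nrow(ivs) == 0L) return(rep(FALSE, nrow(points)))
  x <- points[, 1]; y <- points[, 2]
  z <- if (dom$dim == 3L) points[, 3] else rep(0, nrow(points))
  vapply(seq_len(nrow(points)), function(i) {
    sel <- ivs[, 1] == z[i] & ivs[, 2] == y[i]
    any(sel & ivs[, 3] <= x[i] & x[i] < ivs[, 4])
  }, logical(1))
}

#' @export
print.interval_domain <- function(x, ...) {
  fr <- if (is.null(x$frame)) "frameless" else
    sprintf("frame '%s' [%s]", x$frame$id, paste(x$frame$shape, collapse = " x "))
  cat(sprintf("<interval domain: %dD, %s voxels in %d intervals, %s>\n",
              x$dim, format(dom_size(x), big.mark = ","), nrow(x$ivs), fr))
  invisible(x)
}

#' @export
format.interval_domain <- function(x, ...) {
  sprintf("interval_domain(%dD, %d voxels)", x$dim, dom_size(x))
}
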