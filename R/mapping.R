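#' Colour thresholds for signal extraction
#'
#' Per-strength-level HSV bands for extracting in-situ hybridisation
#' signal from an RGB assay image. Each level is a band: a hue range in
#' degrees (wrap-around allowed, e.g. `c(330, 30)`), a minimum saturation,
#' and a brightness (value) range. Levels must nest — every pixel passing
#' the `strong` band must also pass `moderate`, `weak` and `detected` —
#' which is validated at construction, so extracted domains are nested by
#' construction. HSV is used because chromogenic ISH signal (e.g. the
#' BCIP/NBT purple) separates cleanly in hue/saturation.
#'
#' @param detected,weak,moderate,strong lists with elements `hue`
#'   (length-2 degrees), `s_min` (scalar), `v` (length-2). `detected` is
#'   required; others optional.
#' @return A `colour_thresholds` object.
#' @seealso [default_thresholds()], [extract_signal()]
#' @export
colour_thresholds <- function(detected, weak = NULL, moderate = NULL,
                              strong = NULL) {
  lv <- list(detected = detected, weak = weak, moderate = moderate,
             strong = strong)
  lv <- Filter(Negate(is.null), lv)
  for (nm in names(lv)) {
    b <- lv[[nm]]
    if (!is.list(b) || length(b$hue) != 2L || length(b$s_min) != 1L ||
        length(b$v) != 2L)
      stop("level '", nm, "' must have hue (2), s_min (1), v (2)")
    if (b$s_min < 0 || b$s_min > 1 || any(b$v < 0) || any(b$v > 1) ||
        b$v[1] > b$v[2])
      stop("level '", nm, "' has out-of-range saturation/value limits")
  }
  ord <- intersect(c("detected", "weak", "moderate", "strong"), names(lv))
  for (i in seq_along(ord)[-1]) {
    strict <- lv[[ord[i]]]; lax <- lv[[ord[i - 1]]]
    if (!hue_contained(strict$hue, lax$hue) ||
        strict$s_min < lax$s_min ||
        strict$v[1] < lax$v[1] || strict$v[2] > lax$v[2])
      stop(sprintf("thresholds do not nest: '%s' must be at least as strict as '%s'",
                   ord[i], ord[i - 1]))
  }
  structure(lv, class = "colour_thresholds")
}

# Membership of hue values (degrees) in a possibly wrapping range.
hue_in <- function(h, range) {
  h <- h %% 360
  lo <- range[1] %% 360; hi <- range[2] %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

# Is hue range `a` contained in range `b`? Checked on a fine angular grid
# (robust across wrap-around configurations).
hue_contained <- function(a, b) {
  g <- seq(0, 359.875, by = 0.125)
  all(!hue_in(g, a) | hue_in(g, b))
}

#' Default purple-signal thresholds
#'
#' Four nested HSV bands tuned for purple chromogenic ISH signal on a pale
#' background: progressively narrower hue, higher saturation and darker
#' value from `detected` to `strong`.
#'
#' @return A [colour_thresholds()] object.
#' @export
default_thresholds <- function() {
  colour_thresholds(
    detected = list(hue = c(230, 330), s_min = 0.30, v = c(0.00, 0.85)),
    weak     = list(hue = c(235, 325), s_min = 0.35, v = c(0.00, 0.80)),
    moderate = list(hue = c(240, 320), s_min = 0.45, v = c(0.00, 0.65)),
    strong   = list(hue = c(245, 315), s_min = 0.60, v = c(0.00, 0.55)))
}

#' Extract signal domains from an RGB assay image
#'
#' Converts the image to HSV and returns, for each configured strength
#' level, the interval domain of pixels inside that level's colour band.
#' Threshold nesting guarantees `strong` \eqn{\subseteq} `moderate`
#' \eqn{\subseteq} `weak` \eqn{\subseteq} `detected`. An optional exclusion
#' domain (e.g. a manually outlined trapping artefact, where stain pools in
#' a cavity without reflecting expression) is subtracted from every level.
#'
#' @param image numeric `[h, w, 3]` RGB array in `[0, 1]` (or 0–255).
#' @param thresholds a [colour_thresholds()].
#' @param exclusion optional 2D `interval_domain` subtracted from all
#'   levels.
#' @return Named list of 2D `interval_domain`s, one per configured level.
#' @export
extract_signal <- function(image, thresholds = default_thresholds(),
                           exclusion = NULL) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an [h, w, 3] RGB array")
  if (!inherits(thresholds, "colour_thresholds"))
    stop("thresholds must be a colour_thresholds object")
  img <- image
  if (max(img) > 1) img <- img / 255
  hsv <- grDevices::rgb2hsv(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
                            as.numeric(img[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]
  out <- list()
  for (nm in names(thresholds)) {
    b <- thresholds[[nm]]
    keep <- hue_in(hue, b$hue) & sat >= b$s_min &
      val >= b$v[1] & val <= b$v[2]
    dom <- interval_domain(matrix(keep, d[1], d[2]))
    if (!is.null(exclusion)) dom <- dom_diff(dom, exclusion)
    out[[nm]] <- dom
  }
  out
}

#' Landmark correspondence set
#'
#' Pairs of morphologically equivalent points on the raw data image
#' (source) and the stage-matched reference model (target), in 0-based
#' pixel coordinates (x = column, y = row, origin top-left).
#'
#' @param source,target numeric `n x 2` matrices of `(x, y)` coordinates;
#'   at least 3 non-collinear pairs, no duplicate source points.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  storage.mode(source) <- "double"
  storage.mode(target) <- "double"
  if (ncol(source) != 2L || ncol(target) != 2L ||
      nrow(source) != nrow(target))
    stop("source and target must be n x 2 matrices of equal length")
  n <- nrow(source)
  if (n < 3L) stop("at least 3 landmark pairs are required")
  if (anyDuplicated(source)) stop("duplicate source landmarks")
  cs <- scale(source, scale = FALSE)
  if (min(svd(cs)$d) < 1e-8 * max(svd(cs)$d, 1))
    stop("source landmarks are collinear")
  structure(list(source = unname(source), target = unname(target), n = n),
            class = "landmark_set")
}

#' Read / write landmark TSV (sx, sy, tx, ty)
#'
#' @param path TSV file with header columns `sx, sy, tx, ty`.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("sx", "sy", "tx", "ty")
  if (!all(need %in% names(tb))) stop("landmark file needs columns sx, sy, tx, ty")
  landmark_set(cbind(tb$sx, tb$sy), cbind(tb$tx, tb$ty))
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  tb <- data.frame(sx = lm$source[, 1], sy = lm$source[, 2],
                   tx = lm$target[, 1], ty = lm$target[, 2])
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a piecewise-affine landmark warp
#'
#' Delaunay-triangulates the source landmarks and fits one affine map per
#' triangle onto the corresponding target triangle. The resulting map is
#' continuous across shared edges and interpolates every landmark pair
#' exactly. (The production constrained-distance-transform warp is
#' deliberately isolated behind this interface so it could be substituted.)
#'
#' @param lm a [landmark_set()].
#' @return A `warp_mesh`: triangle vertex indices (`tri`, m x 3), source
#'   and target coordinates, and per-triangle forward and inverse affine
#'   matrices.
#' @export
build_warp <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  dd <- deldir::deldir(lm$source[, 1], lm$source[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (!length(tl)) stop("triangulation of source landmarks failed")
  tri <- t(vapply(tl, function(tt) as.integer(tt$ptNum), integer(3)))
  m <- nrow(tri)
  fwd <- array(NA_real_, c(2, 3, m))
  inv <- array(NA_real_, c(2, 3, m))
  for (k in seq_len(m)) {
    s <- lm$source[tri[k, ], , drop = FALSE]
    t_ <- lm$target[tri[k, ], , drop = FALSE]
    Sh <- rbind(t(s), 1)
    Th <- rbind(t(t_), 1)
    if (abs(det(Sh)) < 1e-9) stop("degenerate source triangle in warp mesh")
    if (abs(det(Th)) < 1e-9)
      stop("degenerate target triangle: landmarks fold the mesh")
    fwd[, , k] <- t(t_) %*% solve(Sh)
    inv[, , k] <- t(s) %*% solve(Th)
  }
  structure(list(tri = tri, source = lm$source, target = lm$target,
                 fwd = fwd, inv = inv),
            class = "warp_mesh")
}

#' @export
print.warp_mesh <- function(x, ...) {
  cat(sprintf("<warp mesh: %d landmarks, %d triangles>\n",
              nrow(x$source), nrow(x$tri)))
  invisible(x)
}

# Barycentric containment of points in triangle (p1, p2, p3); tol loosens
# the edge test so shared edges belong to both triangles.
bary_inside <- function(px, py, p1, p2, p3, tol = 1e-9) {
  d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
  l1 <- ((p2[2] - p3[2]) * (px - p3[1]) + (p3[1] - p2[1]) * (py - p3[2])) / d
  l2 <- ((p3[2] - p1[2]) * (px - p3[1]) + (p1[1] - p3[1]) * (py - p3[2])) / d
  l3 <- 1 - l1 - l2
  l1 >= -tol & l2 >= -tol & l3 >= -tol
}

# Apply a 2x3 affine to an n x 2 point matrix.
apply_affine <- function(A, pts) {
  cbind(pts, 1) %*% t(A)
}

#' Warp arbitrary points through a mesh
#'
#' @param warp a `warp_mesh`.
#' @param pts numeric `n x 2` source points.
#' @return `n x 2` warped points; rows outside the source hull are `NA`.
#' @export
warp_points <- function(warp, pts) {
  pts <- rbind(pts)
  out <- matrix(NA_real_, nrow(pts), 2)
  todo <- rep(TRUE, nrow(pts))
  for (k in seq_len(nrow(warp$tri))) {
    v <- warp$source[warp$tri[k, ], , drop = FALSE]
    sel <- todo & bary_inside(pts[, 1], pts[, 2], v[1, ], v[2, ], v[3, ])
    if (any(sel)) {
      out[sel, ] <- apply_affine(warp$fwd[, , k],
                                 pts[sel, , drop = FALSE])
      todo[sel] <- FALSE
    }
  }
  out
}

# Ray-casting point-in-polygon (vertices in order, n x 2).
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Warp a 2D domain into a target frame
#'
#' Rasterizes the warped region by inverse mapping: every target pixel
#' centre is pulled back through the per-triangle inverse affine and
#' tested for membership in the source domain (nearest pixel), which
#' avoids holes. Parts of the domain outside the source landmark hull
#' cannot be mapped and are dropped with a warning.
#'
#' @param dom a 2D `interval_domain` in source image coordinates.
#' @param warp a `warp_mesh` from [build_warp()].
#' @param frame target [frame_spec()] (the reference model grid).
#' @return A 2D `interval_domain` in `frame`.
#' @export
apply_warp <- function(dom, warp, frame) {
  if (dom$dim != 2L) stop("apply_warp needs a 2D domain")
  if (!inherits(frame, "frame_spec")) stop("frame must be a frame_spec")
  if (nrow(dom$ivs) == 0L) return(empty_domain(2L, frame))
  sh <- frame$shape
  # source-side coverage check against the landmark hull
  hull <- warp$source[grDevices::chull(warp$source), , drop = FALSE]
  bbs <- dom_bbox(dom)
  src_shape <- c(bbs["max", "y"] + 1L, bbs["max", "x"] + 1L)
  src_mask <- to_mask(dom, src_shape)
  vox <- which(src_mask, arr.ind = TRUE)
  in_hull <- in_polygon(vox[, 2] - 1, vox[, 1] - 1, hull)
  if (!any(in_hull)) {
    warning("entire domain lies outside the landmark hull; nothing mapped")
    return(empty_domain(2L, frame))
  }
  if (!all(in_hull))
    warning(sprintf("%d of %d domain pixels outside the landmark hull were dropped",
                    sum(!in_hull), length(in_hull)))
  # inverse mapping over the target bounding box
  tv <- warp$target
  x0 <- max(0L, floor(min(tv[, 1]))); x1 <- min(sh[2] - 1L, ceiling(max(tv[, 1])))
  y0 <- max(0L, floor(min(tv[, 2]))); y1 <- min(sh[1] - 1L, ceiling(max(tv[, 2])))
  if (x0 > x1 || y0 > y1) stop("warp target lies outside the target frame")
  gx <- rep(seq.int(x0, x1), each = y1 - y0 + 1L)
  gy <- rep(seq.int(y0, y1), times = x1 - x0 + 1L)
  member <- logical(length(gx))
  todo <- rep(TRUE, length(gx))
  for (k in seq_len(nrow(warp$tri))) {
    v <- warp$target[warp$tri[k, ], , drop = FALSE]
    sel <- todo & bary_inside(gx, gy, v[1, ], v[2, ], v[3, ])
    if (!any(sel)) next
    src <- apply_affine(warp$inv[, , k], cbind(gx[sel], gy[sel]))
    sx <- round(src[, 1]); sy <- round(src[, 2])
    ok <- sx >= 0 & sx < src_shape[2] & sy >= 0 & sy < src_shape[1]
    mem <- logical(sum(sel))
    mem[ok] <- src_mask[cbind(sy[ok] + 1, sx[ok] + 1)]
    member[sel] <- mem
    todo[sel] <- FALSE
  }
  mask <- matrix(FALSE, sh[1], sh[2])
  mask[cbind(gy + 1L, gx + 1L)] <- member
  out <- interval_domain(mask, frame = frame)
  if (nrow(out$ivs) == 0L)
    stop("warping a nonempty in-hull domain produced an empty result")
  out
}

#' Map a raw assay image into a reference model frame
#'
#' The full curation step: extract per-level signal domains by colour
#' thresholding, optionally subtract an exclusion region (trapping
#' artefact correction), and warp every level into the model frame through
#' the landmark mesh. Level nesting survives because all levels share one
#' warp.
#'
#' @param image RGB assay image, `[h, w, 3]`.
#' @param landmarks a [landmark_set()] from image to model coordinates.
#' @param thresholds a [colour_thresholds()].
#' @param frame target [frame_spec()] of the reference model.
#' @param entry_id,gene,stage metadata for the resulting pattern.
#' @param exclusion optional 2D exclusion `interval_domain` (image
#'   coordinates).
#' @return An [expression_pattern()] in `frame`.
#' @export
map_entry <- function(image, landmarks, thresholds = default_thresholds(),
                      frame, entry_id = "entry-1", gene = "gene",
                      stage = frame$id, exclusion = NULL) {
  levels_src <- extract_signal(image, thresholds, exclusion = exclusion)
  warp <- build_warp(landmarks)
  mapped <- list()
  for (nm in names(levels_src)) {
    d <- levels_src[[nm]]
    mapped[[nm]] <- if (nrow(d$ivs) == 0L) empty_domain(2L, frame)
                    else apply_warp(d, warp, frame)
  }
  if (is.null(mapped$detected)) stop("thresholds produced no 'detected' level")
  expression_pattern(entry_id, gene, stage, mapped, frame = frame)
}
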