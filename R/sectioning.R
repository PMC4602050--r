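#' 3D grey-level volume
#'
#' A scalar 3D image with physical voxel spacing — the substrate for
#' virtual sectioning. Array order is `[y, x, z]` (rows, columns, planes);
#' voxel `(x, y, z)` is `values[y + 1, x + 1, z + 1]`.
#'
#' @param values numeric 3D array.
#' @param spacing positive numeric length-3, physical units per voxel along
#'   `(x, y, z)`.
#' @param id reference-frame identifier.
#' @return A `grey_volume` with a `frame_spec` attached.
#' @export
grey_volume <- function(values, spacing = c(1, 1, 1), id = "volume") {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || any(d <= 0L))
    stop("values must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  structure(list(values = values, spacing = spacing,
                 frame = frame_spec(id, d)),
            class = "grey_volume")
}

#' @export
print.grey_volume <- function(x, ...) {
  cat(sprintf("<grey volume [%s], spacing (%s), frame '%s'>\n",
              paste(dim(x$values), collapse = " x "),
              paste(x$spacing, collapse = ", "), x$frame$id))
  invisible(x)
}

#' Compound object: named overlapping domain layers
#'
#' An ordered set of named 3D (or 2D) domains sharing one frame, each with
#' a display colour and transparency. Unlike an index (label) image, layers
#' may overlap freely — this is the whole point of the representation, and
#' [export_index_volume()] documents what is lost when flattening one.
#'
#' @param ... layers created with [domain_layer()], or a single list of
#'   them.
#' @return A `compound_object`.
#' @export
compound_object <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "domain_layer"))
    layers <- layers[[1]]
  if (length(layers)) {
    fr <- layers[[1]]$domain$frame
    for (l in layers) {
      if (!inherits(l, "domain_layer")) stop("layers must be domain_layer objects")
      if (!frames_compatible(l$domain$frame, fr))
        stop("all layers must share one reference frame")
    }
  }
  structure(list(layers = layers), class = "compound_object")
}

#' @rdname compound_object
#' @param name layer name (e.g. an anatomy term or gene).
#' @param domain an `interval_domain`.
#' @param colour display colour, `"#RRGGBB"`.
#' @param alpha opacity in `[0, 1]`.
#' @param visible logical display flag.
#' @export
domain_layer <- function(name, domain, colour = "#FF0000", alpha = 0.5,
                         visible = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(name = as.character(name), domain = domain,
                 colour = colour, alpha = alpha, visible = isTRUE(visible)),
            class = "domain_layer")
}

#' @export
print.compound_object <- function(x, ...) {
  cat(sprintf("<compound object: %d layer(s)>\n", length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %s %s alpha=%.2f %s (%d vox)\n", l$name, l$colour, l$alpha,
                if (l$visible) "on" else "off", dom_size(l$domain)))
  invisible(x)
}

#' Cutting-plane specification
#'
#' Parameterizes an arbitrary section through a volume: the viewing plane
#' is obtained by rotating the base axes by `yaw` about z, then `pitch`
#' about the rotated x axis, then `roll` about the resulting view normal,
#' and translating it to pass through `fixed_point + distance * normal`.
#' Section pixel `(u, v)` samples the physical point
#' `origin + ((u - u0) / scale) * e1 + ((v - v0) / scale) * e2`, with the
#' v axis pointing down (image convention). All geometry is in physical
#' units: with unit spacing, distances are voxels.
#'
#' @param pitch,yaw,roll rotation angles in degrees.
#' @param distance offset along the view normal (physical units).
#' @param fixed_point rotation centre, 0-based voxel coordinates `(x, y, z)`.
#' @param scale pixels per physical unit, positive.
#' @param viewport `c(width, height)` of the section image in pixels.
#' @param origin in-plane pixel `c(u0, v0)` that maps to the plane origin.
#' @return A `section_spec`.
#' @export
section_spec <- function(pitch = 0, yaw = 0, roll = 0, distance = 0,
                         fixed_point = c(0, 0, 0), scale = 1,
                         viewport = c(256L, 256L), origin = c(0, 0)) {
  if (scale <= 0) stop("scale must be positive")
  viewport <- as.integer(viewport)
  if (length(viewport) != 2L || any(viewport <= 0L))
    stop("viewport must be positive (width, height)")
  structure(list(pitch = pitch %% 360, yaw = yaw %% 360, roll = roll %% 360,
                 distance = distance, fixed_point = as.numeric(fixed_point),
                 scale = scale, viewport = viewport,
                 origin = as.numeric(origin)),
            class = "section_spec")
}

rot_z <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Section-plane coordinate transform
#'
#' Builds the rigid map between section pixels `(u, v)` and volume voxel
#' coordinates `(x, y, z)`. Intrinsic rotation order yaw (z), pitch
#' (rotated x), roll (view normal) is equivalent to the matrix product
#' `Rz(yaw) %*% Rx(pitch) %*% Rz(roll)`.
#'
#' @param spec a [section_spec()].
#' @param spacing voxel spacing `(x, y, z)`; defaults to isotropic 1.
#' @return A `section_transform`: list with the rotation matrix `R`
#'   (columns `e1`, `e2`, `normal`), plane origin `origin_phys`, and
#'   functions `forward(uv)` (n x 2 pixel matrix to n x 3 voxel
#'   coordinates) and `inverse(xyz)` (n x 3 voxel coordinates to n x 3
#'   `(u, v, w)`, `w` the out-of-plane offset).
#' @export
section_transform <- function(spec, spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "section_spec"))
  d2r <- pi / 180
  R <- rot_z(spec$yaw * d2r) %*% rot_x(spec$pitch * d2r) %*%
    rot_z(spec$roll * d2r)
  spacing <- as.numeric(spacing)
  origin_phys <- spec$fixed_point * spacing + spec$distance * R[, 3]
  sc <- spec$scale
  u0 <- spec$origin[1]; v0 <- spec$origin[2]
  forward <- function(uv) {
    uv <- rbind(uv)
    phys <- outer(rep(1, nrow(uv)), origin_phys) +
      ((uv[, 1] - u0) / sc) %o% R[, 1] + ((uv[, 2] - v0) / sc) %o% R[, 2]
    sweep(phys, 2, spacing, "/")
  }
  inverse <- function(xyz) {
    xyz <- rbind(xyz)
    phys <- sweep(xyz, 2, spacing, "*")
    rel <- sweep(phys, 2, origin_phys, "-")
    pl <- rel %*% R  # components along e1, e2, normal
    cbind(u = pl[, 1] * sc + u0, v = pl[, 2] * sc + v0, w = pl[, 3])
  }
  structure(list(R = R, origin_phys = origin_phys, spacing = spacing,
                 scale = sc, origin_uv = c(u0, v0),
                 forward = forward, inverse = inverse),
            class = "section_transform")
}

sample_nearest <- function(values, xyz) {
  d <- dim(values)
  xi <- round(xyz[, 1]); yi <- round(xyz[, 2]); zi <- round(xyz[, 3])
  ok <- xi >= 0 & xi < d[2] & yi >= 0 & yi < d[1] & zi >= 0 & zi < d[3]
  out <- numeric(nrow(xyz))
  idx <- (yi[ok] + 1) + d[1] * (xi[ok] + d[2] * zi[ok])
  out[ok] <- values[idx]
  out
}

sample_trilinear <- function(values, xyz) {
  d <- dim(values)
  out <- numeric(nrow(xyz))
  x0 <- floor(xyz[, 1]); y0 <- floor(xyz[, 2]); z0 <- floor(xyz[, 3])
  fx <- xyz[, 1] - x0; fy <- xyz[, 2] - y0; fz <- xyz[, 3] - z0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- xi >= 0 & xi < d[2] & yi >= 0 & yi < d[1] & zi >= 0 & zi < d[3] &
      w > 0
    idx <- (yi[ok] + 1) + d[1] * (xi[ok] + d[2] * zi[ok])
    out[ok] <- out[ok] + w[ok] * values[idx]
  }
  out
}

section_grid <- function(spec) {
  w <- spec$viewport[1]; h <- spec$viewport[2]
  cbind(u = rep(seq_len(w) - 1, each = h), v = rep(seq_len(h) - 1, w))
}

#' Cut a virtual section through a volume
#'
#' Resamples the volume on the viewing plane of `spec`. With zero angles,
#' unit spacing, unit scale, zero origin/fixed point and an integer
#' distance `k`, nearest-neighbour sampling returns exactly the stored
#' plane `k`.
#'
#' @param vol a [grey_volume()].
#' @param spec a [section_spec()].
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @param background value for pixels sampling outside the volume.
#' @return Numeric matrix `[height, width]` of sampled intensities.
#' @export
cut_section <- function(vol, spec, interpolation = c("nearest", "trilinear"),
                        background = 0) {
  interpolation <- match.arg(interpolation)
  tr <- section_transform(spec, vol$spacing)
  xyz <- tr$forward(section_grid(spec))
  vals <- if (interpolation == "nearest") sample_nearest(vol$values, xyz)
          else sample_trilinear(vol$values, xyz)
  if (background != 0) {
    d <- dim(vol$values)
    inside <- xyz[, 1] > -0.5 & xyz[, 1] < d[2] - 0.5 &
      xyz[, 2] > -0.5 & xyz[, 2] < d[1] - 0.5 &
      xyz[, 3] > -0.5 & xyz[, 3] < d[3] - 0.5
    vals[!inside] <- background
  }
  matrix(vals, spec$viewport[2], spec$viewport[1])
}

#' Cut a 3D domain with a section plane
#'
#' The 2D domain of section pixels whose pulled-back sample point falls in
#' the 3D domain (nearest-voxel membership), i.e. the intersection of the
#' region with the current section.
#'
#' @param dom a 3D `interval_domain` in the volume frame.
#' @param spec a [section_spec()].
#' @param spacing voxel spacing of the underlying volume.
#' @param shape volume grid dimensions; defaults to `dom`'s frame shape.
#' @return A 2D `interval_domain` on the viewport grid.
#' @export
cut_domain_section <- function(dom, spec, spacing = c(1, 1, 1), shape = NULL) {
  if (dom$dim != 3L) stop("cut_domain_section needs a 3D domain")
  if (is.null(shape)) {
    if (is.null(dom$frame)) stop("shape is required for a frameless domain")
    shape <- dom$frame$shape
  }
  mask <- to_mask(dom, shape)
  tr <- section_transform(spec, spacing)
  xyz <- tr$forward(section_grid(spec))
  xi <- round(xyz[, 1]); yi <- round(xyz[, 2]); zi <- round(xyz[, 3])
  ok <- xi >= 0 & xi < shape[2] & yi >= 0 & yi < shape[1] &
    zi >= 0 & zi < shape[3]
  inside <- logical(nrow(xyz))
  idx <- (yi[ok] + 1) + shape[1] * (xi[ok] + shape[2] * zi[ok])
  inside[ok] <- mask[idx]
  interval_domain(matrix(inside, spec$viewport[2], spec$viewport[1]))
}

parse_colour <- function(colour) {
  as.numeric(grDevices::col2rgb(colour)) / 255
}

#' Composite domain overlays onto a grey section
#'
#' Back-to-front source-over blending: starting from the grey image
#' replicated to RGB, each layer's pixels are blended as
#' `out = alpha * colour + (1 - alpha) * under` in layer order. Layers may
#' overlap arbitrarily.
#'
#' @param grey numeric `[h, w]` matrix in `[0, 1]`.
#' @param layers list of layers, each a list (or [domain_layer()]) with a
#'   2D `domain` on the same `[h, w]` grid, `colour`, `alpha`, and
#'   optional `visible` flag.
#' @return Numeric `[h, w, 3]` RGB array in `[0, 1]`.
#' @export
composite_section <- function(grey, layers = list()) {
  h <- nrow(grey); w <- ncol(grey)
  out <- array(rep(as.numeric(grey), 3L), c(h, w, 3L))
  npx <- h * w
  for (l in layers) {
    if (!is.null(l$visible) && !l$visible) next
    bb <- dom_bbox(l$domain)
    if (!is.null(bb) && (bb["max", "x"] >= w || bb["max", "y"] >= h))
      stop(sprintf("layer %s extends outside the viewport",
                   if (is.null(l$name)) "?" else l$name))
    idx <- linear_indices(l$domain$ivs, c(h, w))
    col <- parse_colour(l$colour)
    for (ch in 1:3) {
      off <- (ch - 1L) * npx
      out[idx + off] <- l$alpha * col[ch] + (1 - l$alpha) * out[idx + off]
    }
  }
  out
}

#' Render and crop one tile of a composited section
#'
#' Cuts the section, intersects and composites the visible compound-object
#' layers, and returns the `tile_size` square at tile grid position
#' `(i, j)` (0-based; `i` horizontal, `j` vertical). Edge tiles are padded
#' with the background value; mosaicking all tiles reproduces the full
#' composited section exactly.
#'
#' @param vol a [grey_volume()].
#' @param compound a [compound_object()] of 3D layers (may be empty).
#' @param spec a [section_spec()].
#' @param tile_index integer `c(i, j)`, non-negative.
#' @param tile_size tile edge in pixels (default 256).
#' @param interpolation passed to [cut_section()].
#' @param background pad value.
#' @return Numeric `[tile_size, tile_size, 3]` RGB array.
#' @export
get_tile <- function(vol, compound, spec, tile_index, tile_size = 256L,
                     interpolation = "nearest", background = 0) {
  tile_index <- as.integer(tile_index)
  if (length(tile_index) != 2L || any(tile_index < 0L))
    stop("tile_index must be two non-negative integers")
  w <- spec$viewport[1]; h <- spec$viewport[2]
  x0 <- tile_index[1] * tile_size; y0 <- tile_index[2] * tile_size
  if (x0 >= w || y0 >= h)
    stop("tile lies entirely outside the viewport")
  full <- render_section(vol, compound, spec, interpolation = interpolation,
                         background = background)
  tile <- array(background, c(tile_size, tile_size, 3L))
  xs <- seq.int(x0 + 1L, min(x0 + tile_size, w))
  ys <- seq.int(y0 + 1L, min(y0 + tile_size, h))
  tile[seq_along(ys), seq_along(xs), ] <- full[ys, xs, , drop = FALSE]
  tile
}

#' Full composited section of a volume plus compound object
#'
#' @inheritParams get_tile
#' @return Numeric `[h, w, 3]` RGB array.
#' @export
render_section <- function(vol, compound = NULL, spec,
                           interpolation = "nearest", background = 0) {
  grey <- cut_section(vol, spec, interpolation = interpolation,
                      background = background)
  rng <- range(vol$values)
  if (rng[2] > 1 || rng[1] < 0)  # normalise display range
    grey <- (grey - min(rng[1], background)) /
      max(rng[2] - min(rng[1], background), .Machine$double.eps)
  layers2d <- list()
  if (!is.null(compound)) {
    for (l in compound$layers) {
      if (!l$visible) next
      d2 <- cut_domain_section(l$domain, spec, spacing = vol$spacing,
                               shape = vol$frame$shape)
      layers2d <- c(layers2d, list(list(name = l$name, domain = d2,
                                        colour = l$colour, alpha = l$alpha)))
    }
  }
  composite_section(grey, layers2d)
}
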