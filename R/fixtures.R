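# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Filled ellipsoid mask on a grid of dimension `shape` (array order
# ny, nx[, nz]); centre/radii in voxel units, (x, y[, z]) order.
ellipsoid_mask <- function(shape, centre, radii) {
  shape <- as.integer(shape)
  y2 <- ((seq_len(shape[1]) - 1 - centre[2]) / radii[2])^2
  x2 <- ((seq_len(shape[2]) - 1 - centre[1]) / radii[1])^2
  if (length(shape) == 3L) {
    z2 <- ((seq_len(shape[3]) - 1 - centre[3]) / radii[3])^2
    outer(outer(y2, x2, "+"), z2, "+") <= 1
  } else {
    outer(y2, x2, "+") <= 1
  }
}

#' Filled disc / ellipsoid as an interval domain
#'
#' @param shape grid dimensions in array order.
#' @param centre `(x, y[, z])` centre, voxel units.
#' @param radii per-axis radii `(rx, ry[, rz])`; a scalar is recycled.
#' @param frame optional [frame_spec()].
#' @return An `interval_domain`.
#' @export
ellipsoid_domain <- function(shape, centre, radii, frame = NULL) {
  radii <- rep(radii, length.out = length(shape))
  interval_domain(ellipsoid_mask(shape, centre, radii), frame = frame)
}

#' Phantom embryo volume with nested anatomy layers
#'
#' A smooth grey-level ellipsoidal phantom standing in for a reconstructed
#' embryo volume, with three nested "tissue" domains (body, organ, core)
#' packaged as a compound object. Deterministic per seed. The spherical
#' variant is exactly rotation-invariant about its centre, which the
#' sectioning tests exploit.
#'
#' @param seed integer seed.
#' @param shape grid dimensions `c(ny, nx, nz)`.
#' @param spherical if `TRUE`, an isotropic, purely radial phantom.
#' @return List with `volume` (a [grey_volume()]), `anatomy` (a
#'   [compound_object()] of 3 nested layers) and `frame`.
#' @export
make_phantom_volume <- function(seed = 1L, shape = c(96L, 80L, 64L),
                                spherical = FALSE) {
  shape <- as.integer(shape)
  fr <- frame_spec(sprintf("phantom-%d%s", seed, if (spherical) "-sph" else ""),
                   shape)
  centre <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2, (shape[3] - 1) / 2)
  radii <- if (spherical) rep(min(shape) / 2 - 2, 3L)
           else c(shape[2], shape[1], shape[3]) * 0.45
  y2 <- ((seq_len(shape[1]) - 1 - centre[2]) / radii[2])^2
  x2 <- ((seq_len(shape[2]) - 1 - centre[1]) / radii[1])^2
  z2 <- ((seq_len(shape[3]) - 1 - centre[3]) / radii[3])^2
  r2 <- outer(outer(y2, x2, "+"), z2, "+")
  # intensity decays to exactly 0 at the phantom surface, so sections never
  # pick up out-of-volume background discontinuities
  vals <- pmax(exp(-1.5 * r2) - exp(-1.5), 0)
  if (!spherical) {
    # low-frequency seeded texture so slices are not featureless
    ph <- with_seed(seed, stats::runif(3, 0, 2 * pi))
    wob <- 0.08 * (sin(outer(outer(
      2 * pi * (seq_len(shape[1]) - 1) / shape[1] + ph[1],
      2 * pi * (seq_len(shape[2]) - 1) / shape[2] + ph[2], "+"),
      2 * pi * (seq_len(shape[3]) - 1) / shape[3] + ph[3], "+")))
    vals <- pmax(vals + wob * (r2 <= 1), 0)
  }
  vol <- grey_volume(vals, spacing = c(1, 1, 1), id = fr$id)
  lay <- function(f, name, col, alpha)
    domain_layer(name, ellipsoid_domain(shape, centre, radii * f, frame = fr),
                 colour = col, alpha = alpha)
  anatomy <- compound_object(lay(1.0, "body", "#4040FF", 0.3),
                             lay(0.65, "organ", "#40C040", 0.5),
                             lay(0.35, "core", "#FF4040", 0.7))
  list(volume = vol, anatomy = anatomy, frame = fr)
}

# Toggle ~frac of a template's voxels, preferring the morphological
# boundary: removals from the inner shell, additions from the outer shell.
jitter_domain <- function(template, frac, frame) {
  if (frac == 0) return(template)
  n <- dom_size(template)
  k <- round(frac * n)
  if (k == 0L) return(template)
  inner <- dom_diff(template, dom_erode(template, 1L))
  outerb <- dom_diff(dom_dilate(template, 1L), template)
  sh <- frame$shape
  pick <- function(dom, m) {
    idx <- linear_indices(dom$ivs, sh)
    if (length(idx) <= m) idx else sample(idx, m)
  }
  drop_idx <- pick(inner, floor(k / 2))
  add_idx <- pick(outerb, k - floor(k / 2))
  mask <- to_mask(template, sh)
  mask[drop_idx] <- FALSE
  mask[add_idx] <- TRUE
  interval_domain(mask, frame = frame)
}

#' Synthetic expression-pattern set with planted syn-expression groups
#'
#' Builds `groups` disjoint template domains (well-separated ellipsoids in
#' the reference frame) and, for each, `per_group` member patterns obtained
#' by toggling a `jitter` fraction of the template's voxels, preferentially
#' at the morphological boundary — mimicking biological boundary variation
#' while keeping within-group overlap provably higher than between-group
#' overlap. The hidden ground-truth group labels are returned.
#'
#' @param seed integer seed.
#' @param shape reference frame dimensions, default `c(120, 100, 80)`
#'   (`ny, nx, nz`, i.e. a 100 x 120 x 80 x/y/z grid).
#' @param groups number of planted groups.
#' @param per_group patterns per group.
#' @param jitter fraction of voxels toggled, in `[0, 0.5)`.
#' @param frame_id identifier of the shared frame.
#' @return List with `patterns` (list of [expression_pattern()]s),
#'   `labels` (integer group of each pattern) and `frame`.
#' @export
make_expression_set <- function(seed = 1L, shape = c(120L, 100L, 80L),
                                groups = 3L, per_group = 5L, jitter = 0.1,
                                frame_id = "model") {
  if (jitter < 0 || jitter >= 0.5) stop("jitter must lie in [0, 0.5)")
  shape <- as.integer(shape)
  fr <- frame_spec(frame_id, shape)
  dimn <- length(shape)
  with_seed(seed, {
    nx <- shape[2]; ny <- shape[1]
    # template centres spread along x, jittered off-axis
    cx <- (seq_len(groups) - 0.5) / groups * nx
    rad <- min(nx / (2.5 * groups), ny / 5, if (dimn == 3L) shape[3] / 5 else Inf)
    templates <- lapply(seq_len(groups), function(g) {
      centre <- c(cx[g], ny / 2 + stats::runif(1, -ny / 12, ny / 12),
                  if (dimn == 3L) shape[3] / 2 + stats::runif(1, -shape[3] / 12,
                                                              shape[3] / 12))
      radii <- rad * stats::runif(dimn, 0.8, 1.0)
      ellipsoid_domain(shape, centre[seq_len(dimn)], radii, frame = fr)
    })
    patterns <- list()
    labels <- integer(0)
    for (g in seq_len(groups)) for (m in seq_len(per_group)) {
      dom <- jitter_domain(templates[[g]], jitter, fr)
      eid <- sprintf("E%02d%02d", g, m)
      patterns[[length(patterns) + 1L]] <-
        expression_pattern(eid, sprintf("G%d-%s", g, letters[m]), frame_id,
                           levels = list(detected = dom))
      labels <- c(labels, g)
    }
    list(patterns = patterns, labels = labels, frame = fr,
         templates = templates)
  })
}

#' Synthetic assay-mapping case with ground truth
#'
#' Draws a purple-signal region (dark core plus lighter annulus on a pale
#' tissue background) in a "data" image that is a known affine deformation
#' of the model frame, samples landmark pairs from that deformation, and
#' rasterizes the ground-truth mapped domain directly from the true
#' deformation. Running [map_entry()] on the returned pieces should
#' recover `truth` up to boundary rasterization.
#'
#' @param seed integer seed.
#' @param size model frame dimensions `c(ny, nx)`.
#' @param n_landmarks number of landmark pairs (grid-sampled, >= 8 for the
#'   recovery guarantee; rounded up to a full grid).
#' @param deformation `"affine"` (random mild rotation/scale/shift) or
#'   `"identity"`.
#' @return List with `image` (`[h, w, 3]`), `landmarks` ([landmark_set()],
#'   image to model), `truth` (detected-domain ground truth in the model
#'   frame), `thresholds`, and `frame`.
#' @export
make_assay_case <- function(seed = 1L, size = c(160L, 160L),
                            n_landmarks = 9L,
                            deformation = c("affine", "identity")) {
  deformation <- match.arg(deformation)
  size <- as.integer(size)
  fr <- frame_spec(sprintf("model-%d", seed), size)
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    # true map: model (target) -> image (source), mild similarity transform
    if (deformation == "affine") {
      th <- stats::runif(1, -12, 12) * pi / 180
      sc <- stats::runif(1, 0.92, 1.08)
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      sh <- stats::runif(2, -6, 6)
      A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      b <- c(cx, cy) - A %*% c(cx, cy) + sh
    } else {
      A <- diag(2); b <- c(0, 0)
    }
    model_to_image <- function(p) sweep(p %*% t(A), 2, as.numeric(b), "+")
    image_to_model <- function(p)
      sweep(p, 2, as.numeric(b), "-") %*% t(solve(A))
    # signal ellipse in MODEL coordinates
    ecx <- w / 2 + stats::runif(1, -10, 10)
    ecy <- h / 2 + stats::runif(1, -10, 10)
    erad <- c(stats::runif(1, 24, 30), stats::runif(1, 24, 30))
    in_sig <- function(p, f = 1) ((p[, 1] - ecx) / (erad[1] * f))^2 +
      ((p[, 2] - ecy) / (erad[2] * f))^2 <= 1
    # draw the data image: pixel centre pulled back to model coordinates
    gx <- rep(seq_len(w) - 1, each = h)
    gy <- rep(seq_len(h) - 1, times = w)
    mp <- image_to_model(cbind(gx, gy))
    sig <- in_sig(mp)
    core <- in_sig(mp, 0.6)
    hh <- ifelse(sig, 280 / 360, 20 / 360)
    ss <- ifelse(core, 0.80, ifelse(sig, 0.55, 0.12))
    vv <- ifelse(core, 0.45, ifelse(sig, 0.70, 0.92))
    cols <- grDevices::col2rgb(grDevices::hsv(hh, ss, vv)) / 255
    image <- array(0, c(h, w, 3L))
    for (ch in 1:3) image[, , ch] <- matrix(cols[ch, ], h, w)
    # landmarks: grid over the model frame margin box, mapped into the image
    side <- max(3L, ceiling(sqrt(n_landmarks)))
    lx <- seq(6, w - 7, length.out = side)
    ly <- seq(6, h - 7, length.out = side)
    tgt <- cbind(rep(lx, each = side), rep(ly, times = side))
    src <- model_to_image(tgt)
    lm <- landmark_set(src, tgt)
    # ground truth: model pixels whose centre lies in the signal ellipse
    truth_mask <- matrix(in_sig(cbind(gx, gy)), h, w)
    truth <- interval_domain(truth_mask, frame = fr)
    list(image = image, landmarks = lm, truth = truth,
         thresholds = default_thresholds(), frame = fr)
  })
}
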