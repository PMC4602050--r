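rodrigues <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

test_that("the rotation convention matches sequential axis-angle rotations", {
  set.seed(91)
  for (i in 1:20) {
    yaw <- stats::runif(1, 0, 360); pitch <- stats::runif(1, 0, 360)
    roll <- stats::runif(1, 0, 360)
    sp <- section_spec(pitch = pitch, yaw = yaw, roll = roll)
    R <- section_transform(sp)$R
    # oracle: rotate world axes about z, then the rotated x, then the
    # resulting view normal
    d2r <- pi / 180
    A1 <- rodrigues(c(0, 0, 1), yaw * d2r)
    A2 <- rodrigues(A1[, 1], pitch * d2r) %*% A1
    A3 <- rodrigues(A2[, 3], roll * d2r) %*% A2
    expect_equal(R, A3, tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("forward/inverse transforms round-trip random probes", {
  set.seed(92)
  sp <- section_spec(pitch = 33, yaw = 120, roll = 71, distance = 13.7,
                     fixed_point = c(10, 20, 5), scale = 1.8,
                     origin = c(12, 7))
  tr <- section_transform(sp, spacing = c(1, 1, 2.5))
  uv <- cbind(stats::runif(1000, -50, 50), stats::runif(1000, -50, 50))
  back <- tr$inverse(tr$forward(uv))
  expect_lt(max(abs(back[, 1:2] - uv)), 1e-9)
  expect_lt(max(abs(back[, 3])), 1e-9)
})

test_that("zero-angle sections reproduce every stored plane voxel-exactly", {
  ph <- make_phantom_volume(seed = 7, shape = c(30, 26, 18))
  vol <- ph$volume
  for (k in 0:17) {
    sp <- section_spec(distance = k, viewport = c(26, 30))
    expect_identical(cut_section(vol, sp, "nearest"), vol$values[, , k + 1])
  }
})

test_that("a section entirely outside the volume is all background", {
  ph <- make_phantom_volume(seed = 8, shape = c(20, 20, 12))
  sp <- section_spec(distance = 500, viewport = c(20, 20))
  expect_true(all(cut_section(ph$volume, sp) == 0))
  sp2 <- section_spec(distance = 500, viewport = c(20, 20))
  expect_true(all(cut_section(ph$volume, sp2, "trilinear",
                              background = -1) == -1))
})

test_that("roll by 180 degrees rotates the section image by 180 degrees", {
  ph <- make_phantom_volume(seed = 9, shape = c(25, 25, 25))
  ctr <- c(12, 12, 12)
  base <- section_spec(pitch = 25, yaw = 40, roll = 0, distance = 0,
                       fixed_point = ctr, viewport = c(25, 25),
                       origin = c(12, 12))
  flip <- section_spec(pitch = 25, yaw = 40, roll = 180, distance = 0,
                       fixed_point = ctr, viewport = c(25, 25),
                       origin = c(12, 12))
  s0 <- cut_section(ph$volume, base, "trilinear")
  s180 <- cut_section(ph$volume, flip, "trilinear")
  expect_equal(s180, s0[25:1, 25:1], tolerance = 1e-9)
})

test_that("sections through a spherical phantom have rotation-invariant mean", {
  ps <- make_phantom_volume(seed = 10, shape = c(48, 48, 48), spherical = TRUE)
  ctr <- rep(23.5, 3)
  ref <- NULL
  for (ang in list(c(0, 0, 0), c(35, 10, 5), c(60, 120, 45), c(18, 275, 301))) {
    sp <- section_spec(pitch = ang[1], yaw = ang[2], roll = ang[3],
                       distance = 0, fixed_point = ctr, viewport = c(48, 48),
                       origin = c(23.5, 23.5))
    m <- mean(cut_section(ps$volume, sp, "trilinear"))
    if (is.null(ref)) ref <- m else expect_equal(m, ref, tolerance = 0.01)
  }
})

test_that("domain sections equal cutting the dense mask with the same transform", {
  ph <- make_phantom_volume(seed = 11, shape = c(30, 28, 20))
  sh <- c(30, 28, 20)
  full <- dom_box(0L, 28L, 0L, 30L, 0L, 20L, dim = 3L, frame = ph$frame)
  sp0 <- section_spec(viewport = c(28, 30))
  expect_equal(dom_size(cut_domain_section(full, sp0)), 28 * 30)
  expect_equal(dom_size(cut_domain_section(
    empty_domain(3L, ph$frame), sp0)), 0)
  set.seed(93)
  for (i in 1:8) {
    m <- random_mask(sh, 0.3)
    dom <- interval_domain(m, ph$frame)
    sp <- section_spec(pitch = stats::runif(1, 0, 360),
                       yaw = stats::runif(1, 0, 360),
                       roll = stats::runif(1, 0, 360),
                       distance = stats::runif(1, -3, 3),
                       fixed_point = c(13, 14, 9), viewport = c(30, 30),
                       origin = c(15, 15))
    got <- cut_domain_section(dom, sp)
    expect_canonical(got)
    tr <- section_transform(sp)
    uv <- cbind(rep(0:29, each = 30), rep(0:29, times = 30))
    xyz <- tr$forward(uv)
    xi <- round(xyz[, 1]); yi <- round(xyz[, 2]); zi <- round(xyz[, 3])
    ok <- xi >= 0 & xi < sh[2] & yi >= 0 & yi < sh[1] & zi >= 0 & zi < sh[3]
    want <- logical(nrow(uv))
    want[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1, zi[ok] + 1)]
    expect_identical(to_mask(got, c(30, 30)), matrix(want, 30, 30))
    # nesting under dilation of the 3D domain
    grown <- cut_domain_section(dom_dilate(dom, 1L), sp)
    expect_true(dom_is_subset(got, grown))
  }
})

test_that("compositing follows source-over blending and ignores hidden layers", {
  grey <- matrix(0.5, 10, 10)
  d <- dom_box(2L, 6L, 3L, 7L)
  m <- to_mask(d, c(10, 10))
  # alpha 0: unchanged
  out0 <- composite_section(grey, list(list(domain = d, colour = "#FF0000",
                                            alpha = 0)))
  expect_equal(out0[, , 1], grey)
  # alpha 1: pure colour inside, grey outside
  out1 <- composite_section(grey, list(list(domain = d, colour = "#00FF00",
                                            alpha = 1)))
  expect_true(all(out1[, , 2][m] == 1) && all(out1[, , 1][m] == 0))
  expect_true(all(out1[, , 2][!m] == 0.5))
  # two overlapping layers compose by the closed-form two-step blend
  d2 <- dom_box(4L, 9L, 5L, 9L)
  out2 <- composite_section(grey, list(
    list(domain = d, colour = "#FF0000", alpha = 0.5),
    list(domain = d2, colour = "#0000FF", alpha = 0.25)))
  both <- m & to_mask(d2, c(10, 10))
  expect_equal(unique(out2[, , 1][both]), 0.75 * (0.5 * 1 + 0.5 * 0.5))
  expect_equal(unique(out2[, , 3][both]), 0.25 * 1 + 0.75 * (0.5 * 0.5))
  # hidden layer is skipped
  outh <- composite_section(grey, list(list(domain = d, colour = "#FF0000",
                                            alpha = 1, visible = FALSE)))
  expect_equal(outh[, , 1], grey)
  # overlapping layers must not error: compound objects, unlike index
  # images, represent co-located patterns
  expect_silent(composite_section(grey, list(
    list(domain = d, colour = "#FF0000", alpha = 0.7),
    list(domain = d, colour = "#00FF00", alpha = 0.7))))
})

test_that("tile mosaics reassemble the full composited section exactly", {
  ph <- make_phantom_volume(seed = 12, shape = c(40, 36, 24))
  sp <- section_spec(pitch = 30, yaw = 10, distance = 1,
                     fixed_point = c(17, 19, 11), viewport = c(36, 40),
                     origin = c(17, 19))
  full <- render_section(ph$volume, ph$anatomy, sp)
  ts <- 12L
  mosaic <- array(0, dim(full))
  for (j in 0:3) for (i in 0:2) {
    tl <- get_tile(ph$volume, ph$anatomy, sp, c(i, j), tile_size = ts)
    ys <- j * ts + seq_len(min(ts, 40 - j * ts))
    xs <- i * ts + seq_len(min(ts, 36 - i * ts))
    mosaic[ys, xs, ] <- tl[seq_along(ys), seq_along(xs), ]
  }
  expect_identical(mosaic, full)
  # 1x1 tiling equals the full section
  one <- get_tile(ph$volume, ph$anatomy, sp, c(0, 0), tile_size = 64)
  expect_identical(one[1:40, 1:36, ], full)
  expect_error(get_tile(ph$volume, ph$anatomy, sp, c(9, 0), tile_size = 12),
               "outside")
  expect_error(get_tile(ph$volume, ph$anatomy, sp, c(-1, 0)), "non-negative")
})
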