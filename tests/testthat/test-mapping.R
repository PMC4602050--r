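test_that("threshold configs must nest strictly", {
  expect_s3_class(default_thresholds(), "colour_thresholds")
  expect_error(colour_thresholds(
    detected = list(hue = c(240, 300), s_min = 0.5, v = c(0, 0.8)),
    strong = list(hue = c(200, 320), s_min = 0.6, v = c(0, 0.5))),
    "nest")
  expect_error(colour_thresholds(
    detected = list(hue = c(240, 300), s_min = 0.5, v = c(0, 0.8)),
    strong = list(hue = c(250, 290), s_min = 0.3, v = c(0, 0.5))),
    "nest")
  # wrap-around hue ranges nest correctly
  ok <- colour_thresholds(
    detected = list(hue = c(330, 30), s_min = 0.3, v = c(0, 0.9)),
    strong = list(hue = c(350, 10), s_min = 0.5, v = c(0, 0.7)))
  expect_s3_class(ok, "colour_thresholds")
})

test_that("signal extraction recovers a pure-colour disc exactly and nests levels", {
  sh <- c(60, 60)
  disc <- to_mask(ellipsoid_domain(sh, c(30, 30), 12), sh)
  img <- array(0, c(sh, 3))
  # background pale pink, disc saturated dark purple
  bg <- grDevices::col2rgb(grDevices::hsv(20 / 360, 0.12, 0.92)) / 255
  fgc <- grDevices::col2rgb(grDevices::hsv(280 / 360, 0.8, 0.45)) / 255
  for (ch in 1:3) img[, , ch] <- ifelse(disc, fgc[ch], bg[ch])
  lv <- extract_signal(img, default_thresholds())
  expect_identical(to_mask(lv$detected, sh), disc)
  expect_true(dom_identical(lv$detected, lv$strong))
  # image with no pixel in any band -> all levels empty
  blank <- array(rep(as.numeric(bg), each = prod(sh)), c(sh, 3))
  lv0 <- extract_signal(blank, default_thresholds())
  expect_true(all(vapply(lv0, dom_size, numeric(1)) == 0))
  # nesting holds on random images
  set.seed(81)
  noise <- array(stats::runif(40 * 40 * 3), c(40, 40, 3))
  lvn <- extract_signal(noise, default_thresholds())
  expect_true(dom_is_subset(lvn$strong, lvn$moderate))
  expect_true(dom_is_subset(lvn$moderate, lvn$weak))
  expect_true(dom_is_subset(lvn$weak, lvn$detected))
})

test_that("landmark validation rejects short, duplicate and collinear sets", {
  expect_error(landmark_set(cbind(0:1, 0:1), cbind(0:1, 0:1)), "at least 3")
  expect_error(landmark_set(cbind(c(0, 0, 1), c(0, 0, 1)),
                            cbind(c(0, 0, 1), c(0, 0, 1))), "duplicate")
  expect_error(landmark_set(cbind(0:2, 0:2), cbind(0:2, 0:2)), "collinear")
  lm <- landmark_set(cbind(c(0, 10, 0, 10), c(0, 0, 10, 10)),
                     cbind(c(1, 11, 1, 11), c(2, 2, 12, 12)))
  expect_s3_class(lm, "landmark_set")
  f <- tempfile(fileext = ".tsv")
  write_landmarks(lm, f)
  expect_identical(read_landmarks(f)$source, lm$source)
})

test_that("identity and translation landmark warps act as expected on probes", {
  src <- as.matrix(expand.grid(x = c(0, 20, 40), y = c(0, 20, 40)))
  lm_id <- landmark_set(src, src)
  w_id <- build_warp(lm_id)
  set.seed(82)
  probes <- cbind(stats::runif(50, 1, 39), stats::runif(50, 1, 39))
  expect_equal(warp_points(w_id, probes), probes, tolerance = 1e-9)
  lm_tr <- landmark_set(src, src + matrix(c(5, -3), nrow(src), 2, byrow = TRUE))
  w_tr <- build_warp(lm_tr)
  moved <- warp_points(w_tr, probes)
  expect_equal(moved[, 1] - probes[, 1], rep(5, 50), tolerance = 1e-9)
  expect_equal(moved[, 2] - probes[, 2], rep(-3, 50), tolerance = 1e-9)
})

test_that("the piecewise warp reproduces a generating affine map at interior probes", {
  A <- matrix(c(0.95, 0.1, -0.08, 1.05), 2, 2)
  b <- c(4, -2)
  src <- as.matrix(expand.grid(x = seq(0, 60, by = 15), y = seq(0, 60, by = 15)))
  tgt <- sweep(src %*% t(A), 2, b, "+")
  w <- build_warp(landmark_set(src, tgt))
  set.seed(83)
  probes <- cbind(stats::runif(1000, 0.5, 59.5), stats::runif(1000, 0.5, 59.5))
  want <- sweep(probes %*% t(A), 2, b, "+")
  expect_equal(warp_points(w, probes), want, tolerance = 1e-8)
  # exact landmark interpolation
  expect_equal(warp_points(w, src), tgt, tolerance = 1e-9)
})

test_that("warp is continuous across shared triangle edges", {
  set.seed(84)
  src <- cbind(stats::runif(12, 0, 50), stats::runif(12, 0, 50))
  tgt <- src + cbind(stats::rnorm(12, 0, 2), stats::rnorm(12, 0, 2))
  w <- build_warp(landmark_set(src, tgt))
  # probe points on shared edges: midpoints of every triangle edge
  for (k in seq_len(nrow(w$tri))) {
    v <- w$source[w$tri[k, ], ]
    mids <- (v + v[c(2, 3, 1), ]) / 2
    m1 <- warp_points(w, mids)
    # evaluate through every triangle whose closure contains the midpoint
    for (kk in seq_len(nrow(w$tri))) {
      vv <- w$source[w$tri[kk, ], ]
      inside <- intervox:::bary_inside(mids[, 1], mids[, 2],
                                       vv[1, ], vv[2, ], vv[3, ], tol = 1e-9)
      if (!any(inside)) next
      m2 <- intervox:::apply_affine(w$fwd[, , kk], mids[inside, , drop = FALSE])
      expect_equal(m1[inside, , drop = FALSE], m2, tolerance = 1e-7)
    }
  }
})

test_that("warping a domain matches the dense-resample oracle for an affine map", {
  sh <- c(80, 80)
  fr <- frame_spec("model", sh)
  disc <- ellipsoid_domain(sh, c(36, 40), c(14, 11))
  A <- matrix(c(1.04, 0.06, -0.05, 0.97), 2, 2)
  b <- c(3, 2)
  src <- as.matrix(expand.grid(x = seq(0, 79, length.out = 4),
                               y = seq(0, 79, length.out = 4)))
  tgt <- sweep(src %*% t(A), 2, b, "+")
  w <- build_warp(landmark_set(src, tgt))
  got <- apply_warp(disc, w, fr)
  # oracle: pull every target pixel back through the closed-form inverse
  gx <- rep(0:(sh[2] - 1), each = sh[1])
  gy <- rep(0:(sh[1] - 1), times = sh[2])
  srcpt <- sweep(cbind(gx, gy), 2, b, "-") %*% t(solve(A))
  sx <- round(srcpt[, 1]); sy <- round(srcpt[, 2])
  dm <- to_mask(disc, sh)
  ok <- sx >= 0 & sx < sh[2] & sy >= 0 & sy < sh[1]
  want <- logical(length(gx))
  want[ok] <- dm[cbind(sy[ok] + 1, sx[ok] + 1)]
  want_mask <- matrix(FALSE, sh[1], sh[2])
  want_mask[cbind(gy + 1, gx + 1)] <- want
  agree <- mean(to_mask(got, sh) == want_mask)
  expect_gte(agree, 0.99)
})

test_that("identity warp keeps a domain unchanged; out-of-hull parts warn", {
  sh <- c(40, 40)
  fr <- frame_spec("m", sh)
  blk <- dom_box(10L, 20L, 12L, 22L)
  src <- as.matrix(expand.grid(x = c(0, 39, 20), y = c(0, 39, 5)))
  src <- rbind(src, c(5, 30), c(35, 30))
  w <- build_warp(landmark_set(src, src))
  out <- apply_warp(blk, w, fr)
  expect_true(dom_identical(out, interval_domain(to_mask(blk, sh), fr)))
  # domain partially outside the hull triggers a warning
  tri <- cbind(c(12, 18, 15), c(14, 14, 20))
  narrow <- landmark_set(tri, tri)
  expect_warning(apply_warp(blk, build_warp(narrow), fr), "hull")
})

test_that("end-to-end mapping recovers the fixture ground truth", {
  for (seed in c(2, 11, 23)) {
    cs <- make_assay_case(seed = seed, n_landmarks = 9)
    p <- suppressWarnings(
      map_entry(cs$image, cs$landmarks, cs$thresholds, cs$frame,
                entry_id = "case", gene = "gene"))
    expect_gte(jaccard(p$levels$detected, cs$truth), 0.95)
    expect_true(dom_is_subset(p$levels$strong, p$levels$moderate))
    expect_true(dom_is_subset(p$levels$moderate, p$levels$weak))
    expect_true(dom_is_subset(p$levels$weak, p$levels$detected))
  }
  # identity deformation: detected equals the thresholded image verbatim
  cs <- make_assay_case(seed = 4, deformation = "identity")
  p <- suppressWarnings(map_entry(cs$image, cs$landmarks, cs$thresholds, cs$frame))
  lv <- extract_signal(cs$image, cs$thresholds)
  expect_true(dom_identical(p$levels$detected,
                            interval_domain(to_mask(lv$detected, cs$frame$shape),
                                            cs$frame)))
})

test_that("exclusion regions (trapping correction) are subtracted from all levels", {
  cs <- make_assay_case(seed = 6, deformation = "identity")
  excl <- dom_box(0L, 40L, 0L, 160L)
  lv <- extract_signal(cs$image, cs$thresholds, exclusion = excl)
  for (nm in names(lv))
    expect_equal(dom_size(dom_intersect(lv[[nm]], excl)), 0)
})
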