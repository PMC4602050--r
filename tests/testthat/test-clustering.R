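test_that("signatures are the rows of the similarity matrix, validated", {
  M <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  S <- jaccard_signatures(M)
  expect_identical(S, M)
  expect_equal(nrow(S), 2)
  expect_error(jaccard_signatures(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
  expect_error(jaccard_signatures(matrix(c(0.9, 0.2, 0.2, 1), 2, 2)), "diagonal")
  ones <- matrix(1, 2, 2)
  expect_identical(jaccard_signatures(ones)[1, ], jaccard_signatures(ones)[2, ])
})

test_that("duplicated patterns yield identical signatures", {
  es <- make_expression_set(seed = 31, shape = c(40, 40), groups = 2,
                            per_group = 2, jitter = 0)
  M <- pairwise_jaccard(c(es$patterns, es$patterns[1]))
  S <- jaccard_signatures(M)
  expect_equal(unname(S[1, ]), unname(S[5, ]))
})

test_that("degenerate trees: one leaf, identical patterns merge at height 0", {
  one <- build_tree(matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_identical(cut_tree(one, 1), list("x"))
  M <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- build_tree(M)
  expect_equal(tr$heights, 0)
  expect_error(cut_tree(tr, 3), "between")
  expect_error(cut_tree(tr, 0), "between")
})

test_that("cutting recovers planted syn-expression groups at the true k", {
  for (seed in c(1, 5, 9)) {
    es <- make_expression_set(seed = seed, shape = c(60, 60, 30),
                              groups = 3, per_group = 5, jitter = 0.1)
    M <- pairwise_jaccard(es$patterns)
    tr <- build_tree(M)
    expect_identical(cut_tree(tr, 3), truth_partition(es$patterns, es$labels))
    expect_length(cut_tree(tr, 1)[[1]], 15)
    expect_length(cut_tree(tr, 15), 15)
  }
})

test_that("permuting the input changes labels only, not the recovered partition", {
  es <- make_expression_set(seed = 41, shape = c(50, 50), groups = 3,
                            per_group = 4, jitter = 0.08)
  M <- pairwise_jaccard(es$patterns)
  p1 <- cut_tree(build_tree(M), 3)
  set.seed(42)
  perm <- sample(length(es$patterns))
  M2 <- pairwise_jaccard(es$patterns[perm])
  p2 <- cut_tree(build_tree(M2), 3)
  expect_identical(p1, p2)
  # identical input => identical tree
  tr_a <- build_tree(M); tr_b <- build_tree(M)
  expect_identical(tr_a$heights, tr_b$heights)
  expect_identical(tr_a$members, tr_b$members)
})

test_that("tree invariants: leaves exactly once, member sets union up, heights monotone", {
  es <- make_expression_set(seed = 51, shape = c(40, 40), groups = 2,
                            per_group = 3, jitter = 0.1)
  M <- pairwise_jaccard(es$patterns)
  tr <- build_tree(M)
  expect_true(all(diff(tr$heights) >= -1e-12))
  n <- length(tr$labels)
  expect_setequal(tr$members[[n - 1]], tr$labels)
  for (k in seq_len(n - 1)) {
    kids <- tr$hc$merge[k, ]
    kid_members <- unlist(lapply(kids, function(ch)
      if (ch < 0) tr$labels[-ch] else tr$members[[ch]]))
    expect_setequal(tr$members[[k]], kid_members)
  }
})

test_that("node heatmaps conserve mass and reduce to indicators", {
  es <- make_expression_set(seed = 61, shape = c(30, 30), groups = 2,
                            per_group = 2, jitter = 0.1)
  d1 <- es$patterns[[1]]$levels$detected
  occ1 <- node_heatmap(NULL, es$patterns[[1]]$entry_id, es$patterns)
  expect_identical(occ1$counts == 1L, to_mask(d1, c(30, 30)))
  two <- occupancy_map(list(d1, d1))
  expect_true(all(two$counts[to_mask(d1, c(30, 30))] == 2L))
  expect_equal(sum(two$counts), 2 * dom_size(d1))
  M <- pairwise_jaccard(es$patterns)
  tr <- build_tree(M)
  for (node in seq_along(tr$members)) {
    occ <- node_heatmap(tr, node, es$patterns)
    sel <- es$patterns[match(tr$members[[node]],
                             vapply(es$patterns, `[[`, character(1), "entry_id"))]
    expect_equal(sum(occ$counts),
                 sum(vapply(sel, function(p) dom_size(p$levels$detected),
                            numeric(1))))
  }
})

test_that("occupancy classes follow the 0/1/2/3+ binning", {
  fr <- frame_spec("f", c(10, 10))
  none <- occupancy_map(list(), shape = c(10, 10))
  expect_true(all(none$classes == 0L))
  d <- dom_box(2L, 6L, 2L, 6L, frame = fr)
  m <- to_mask(d, c(10, 10))
  three <- occupancy_map(list(d, d, d))
  expect_true(all(three$classes[m] == 3L))
  expect_true(all(three$classes[!m] == 0L))
  four <- occupancy_map(list(d, d, d, d))
  expect_identical(three$classes, four$classes)
  single <- occupancy_map(list(d))
  expect_identical(single$classes == 1L, m)
  set.seed(62)
  doms <- lapply(1:5, function(i) random_case(c(8, 9), 0.4))
  occ <- occupancy_map(lapply(doms, `[[`, "dom"), shape = c(8, 9))
  dense <- Reduce(`+`, lapply(doms, function(x) x$mask * 1L))
  expect_identical(occ$counts, array(as.integer(dense), c(8, 9)))
})

test_that("voxel queries report exactly the containing genes and anatomy layers", {
  es <- make_expression_set(seed = 71, shape = c(24, 30, 10), groups = 2,
                            per_group = 3, jitter = 0.05)
  fr <- es$frame
  anat <- compound_object(
    domain_layer("body", dom_box(0L, 30L, 0L, 24L, 0L, 10L, dim = 3L, frame = fr)),
    domain_layer("core", dom_box(10L, 20L, 8L, 16L, 2L, 8L, dim = 3L, frame = fr)))
  set.seed(72)
  for (i in 1:100) {
    pt <- c(sample(0:29, 1), sample(0:23, 1), sample(0:9, 1))
    got <- voxel_query(pt, es$patterns, anat)
    want_genes <- sort(unique(unlist(lapply(es$patterns, function(p)
      if (to_mask(p$levels$detected, fr$shape)[pt[2] + 1, pt[1] + 1, pt[3] + 1])
        p$gene))))
    expect_identical(got$genes, as.character(want_genes))
    in_core <- pt[1] >= 10 && pt[1] < 20 && pt[2] >= 8 && pt[2] < 16 &&
      pt[3] >= 2 && pt[3] < 8
    expect_identical(got$anatomy,
                     if (in_core) c("body", "core") else "body")
  }
  expect_error(voxel_query(c(40, 0, 0), es$patterns), "outside")
  lone <- voxel_query(c(0, 0, 9), list(), anat)
  expect_identical(lone$genes, character(0))
})
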