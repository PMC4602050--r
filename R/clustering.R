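#' Similarity signatures from a pairwise Jaccard matrix
#'
#' The signature of pattern *i* is row *i* of the pairwise similarity
#' matrix: its profile of overlap with every pattern in the set. Two
#' patterns with similar spatial behaviour have similar signatures even
#' when they are not mapped to identical coordinates, which is what makes
#' signature clustering more forgiving than direct overlap clustering.
#'
#' @param M symmetric matrix with unit diagonal, as produced by
#'   [pairwise_jaccard()].
#' @return Numeric matrix of signatures (rows), dimnames preserved.
#' @export
jaccard_signatures <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || !isTRUE(all.equal(M, t(M), tolerance = 1e-12)))
    stop("similarity matrix must be symmetric")
  if (!isTRUE(all.equal(unname(diag(M)), rep(1, nrow(M)))))
    stop("similarity matrix must have unit diagonal")
  M
}

#' Hierarchical syn-expression tree
#'
#' Agglomerative clustering of per-pattern similarity signatures. By
#' default patterns are represented by their rows of the pairwise Jaccard
#' matrix and merged by average linkage (UPGMA) on Euclidean signature
#' distance; a direct mode using `1 - Jaccard` itself as the dissimilarity
#' is available for comparison. Identical signatures merge at height zero.
#'
#' @param M pairwise Jaccard matrix ([pairwise_jaccard()]).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param mode `"signature"` (cluster signature rows, the default
#'   two-step construction) or `"direct"` (cluster on `1 - M`).
#' @param sig_distance distance on signature rows (`"euclidean"` or
#'   `"manhattan"`), used only in signature mode.
#' @return A `cluster_tree`: list with the `hclust` object (`hc`), leaf
#'   `labels`, `heights`, and per-internal-node member lists (`members`,
#'   entry ids under each of the `n - 1` merges).
#' @export
build_tree <- function(M, linkage = "average",
                       mode = c("signature", "direct"),
                       sig_distance = c("euclidean", "manhattan")) {
  mode <- match.arg(mode)
  sig_distance <- match.arg(sig_distance)
  sig <- jaccard_signatures(M)
  n <- nrow(sig)
  labels <- rownames(sig)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    tree <- list(hc = NULL, labels = labels, heights = numeric(0),
                 members = list())
    return(structure(tree, class = "cluster_tree"))
  }
  d <- if (mode == "signature") stats::dist(sig, method = sig_distance)
       else stats::as.dist(1 - sig)
  hc <- stats::hclust(d, method = linkage)
  hc$labels <- labels
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    mem <- unlist(lapply(kids, function(ch)
      if (ch < 0) labels[-ch] else members[[ch]]))
    members[[k]] <- sort(mem)
  }
  structure(list(hc = hc, labels = labels, heights = hc$height,
                 members = members),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<syn-expression tree: %d patterns, %d merges>\n",
              length(x$labels), length(x$heights)))
  invisible(x)
}

#' Cut a syn-expression tree into k groups
#'
#' Removes the `k - 1` highest merges, yielding `k` disjoint groups that
#' cover every pattern.
#'
#' @param tree a `cluster_tree` from [build_tree()].
#' @param k number of groups, between 1 and the leaf count.
#' @return A list of `k` character vectors of entry ids (each sorted);
#'   groups ordered by their first entry id.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of patterns")
  if (n == 1L) return(list(tree$labels))
  cl <- stats::cutree(tree$hc, k = k)
  groups <- lapply(split(names(cl), cl), sort)
  groups <- unname(groups)
  groups[order(vapply(groups, `[`, character(1), 1))]
}

#' Per-voxel occupancy of a set of domains
#'
#' Counts, for every voxel of the reference frame, how many of the given
#' domains contain it, and bins the counts into the four display classes
#' used for co-expression maps: zero occupancy, single, dual, and three or
#' more patterns (rendered blue, green, yellow and red respectively by
#' [render_heatmap()]).
#'
#' @param domains list of `interval_domain`s in one frame.
#' @param shape frame dimensions in array order; defaults to the common
#'   frame of the domains.
#' @return An `occupancy_map`: list with integer array `counts`, factor
#'   array-alike `classes` (levels `zero`, `single`, `dual`, `three-plus`
#'   stored as an integer array 0:3), and `shape`.
#' @export
occupancy_map <- function(domains, shape = NULL) {
  if (is.null(shape)) {
    fr <- NULL
    for (d in domains) if (!is.null(d$frame)) { fr <- d$frame; break }
    if (is.null(fr)) stop("shape is required when domains carry no frame")
    shape <- fr$shape
  }
  shape <- as.integer(shape)
  counts <- array(0L, shape)
  for (d in domains) {
    if (length(shape) != d$dim) stop("domain dimensionality mismatch")
    idx <- linear_indices(d$ivs, shape)
    counts[idx] <- counts[idx] + 1L
  }
  classes <- array(pmin(counts, 3L), shape)
  structure(list(counts = counts, classes = classes, shape = shape,
                 class_labels = c("zero", "single", "dual", "three-plus")),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  tab <- tabulate(as.integer(x$classes) + 1L, 4L)
  cat(sprintf("<occupancy map [%s]: %s>\n",
              paste(x$shape, collapse = " x "),
              paste(sprintf("%s=%d", x$class_labels, tab), collapse = ", ")))
  invisible(x)
}

#' Occupancy heatmap of one tree node
#'
#' The spatial heatmap attached to a node of the syn-expression tree: the
#' occupancy map of the chosen strength level over exactly that node's
#' member patterns, highlighting the region of shared expression.
#'
#' @param tree a `cluster_tree`.
#' @param node internal node index (1-based, in `hc$merge` order), or a
#'   character vector of entry ids to use directly.
#' @param patterns the pattern list the tree was built from.
#' @param level strength level (default `"detected"`).
#' @param shape optional frame dimensions (defaults to the pattern frame).
#' @return An [occupancy_map()] restricted to the node members.
#' @export
node_heatmap <- function(tree, node, patterns, level = "detected",
                         shape = NULL) {
  ids <- vapply(patterns, `[[`, character(1), "entry_id")
  mem <- if (is.character(node)) node else {
    if (node < 1L || node > length(tree$members)) stop("node index out of range")
    tree$members[[node]]
  }
  sel <- patterns[match(mem, ids)]
  if (anyNA(match(mem, ids))) stop("node members missing from pattern list")
  occupancy_map(lapply(sel, pattern_level, level = level), shape = shape)
}

#' Genes and anatomy at one voxel
#'
#' The mouse-over lookup: which mapped expression patterns and which
#' anatomy layers contain a given voxel of the reference model.
#'
#' @param point 0-based voxel coordinate `c(x, y)` or `c(x, y, z)`.
#' @param patterns list of [expression_pattern()]s (detected level tested).
#' @param anatomy optional [compound_object()] of anatomy domains.
#' @param shape frame dimensions used for the bounds check; defaults to the
#'   first available frame.
#' @return List with sorted character vectors `genes` and `anatomy`.
#' @export
voxel_query <- function(point, patterns, anatomy = NULL, shape = NULL) {
  if (is.null(shape)) {
    fr <- NULL
    for (p in patterns) if (!is.null(p$frame)) { fr <- p$frame; break }
    if (is.null(fr) && !is.null(anatomy))
      for (l in anatomy$layers) if (!is.null(l$domain$frame)) { fr <- l$domain$frame; break }
    if (is.null(fr)) stop("shape is required when nothing carries a frame")
    shape <- fr$shape
  }
  shape <- as.integer(shape)
  pt <- as.numeric(point)
  dimn <- length(shape)
  if (length(pt) != dimn) stop("point dimensionality mismatch")
  ext <- shape[c(2L, 1L, if (dimn == 3L) 3L)]  # x, y, z extents
  if (any(pt < 0) || any(pt >= ext)) stop("point lies outside the frame")
  genes <- character(0)
  for (p in patterns) {
    if (dom_contains(p$levels$detected, matrix(pt, 1)))
      genes <- c(genes, p$gene)
  }
  terms <- character(0)
  if (!is.null(anatomy)) {
    for (l in anatomy$layers) {
      if (dom_contains(l$domain, matrix(pt, 1)))
        terms <- c(terms, l$name)
    }
  }
  list(genes = sort(unique(genes)), anatomy = sort(unique(terms)))
}
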