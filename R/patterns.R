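#' A curated, spatially mapped expression pattern
#'
#' One database entry: a gene assayed at one developmental stage, with the
#' extracted signal mapped into a reference model frame at up to four
#' strength levels. The `detected` level is mandatory and must contain
#' every other level's domain (strength annotations are nested readings of
#' one signal).
#'
#' @param entry_id unique entry identifier.
#' @param gene gene symbol.
#' @param stage stage label (e.g. `"TS17"`).
#' @param levels named list of `interval_domain`s; names from
#'   `c("detected", "weak", "moderate", "strong")`; `"detected"` required.
#' @param frame the common [frame_spec()]; defaults to the frame of the
#'   detected domain.
#' @return An `expression_pattern`.
#' @export
expression_pattern <- function(entry_id, gene, stage, levels, frame = NULL) {
  if (!is.list(levels) || is.null(levels$detected))
    stop("levels must be a named list containing a 'detected' domain")
  bad <- setdiff(names(levels), c("detected", "weak", "moderate", "strong"))
  if (length(bad))
    stop("unknown strength level(s): ", paste(bad, collapse = ", "))
  if (is.null(frame)) frame <- levels$detected$frame
  for (nm in names(levels)) {
    d <- levels[[nm]]
    if (!inherits(d, "interval_domain"))
      stop("level '", nm, "' is not an interval_domain")
    if (!frames_compatible(d$frame, frame))
      stop("level '", nm, "' is not in the pattern frame")
    if (nm != "detected" && !dom_is_subset(d, levels$detected))
      stop("level '", nm, "' is not a subset of the detected domain")
  }
  structure(list(entry_id = as.character(entry_id),
                 gene = as.character(gene),
                 stage = as.character(stage),
                 levels = levels, frame = frame),
            class = "expression_pattern")
}

#' @export
print.expression_pattern <- function(x, ...) {
  lv <- vapply(x$levels, dom_size, numeric(1))
  cat(sprintf("<expression pattern %s: %s @ %s; %s>\n", x$entry_id, x$gene,
              x$stage,
              paste(sprintf("%s=%d vox", names(lv), as.integer(lv)),
                    collapse = ", ")))
  invisible(x)
}

pattern_level <- function(p, level) {
  d <- p$levels[[level]]
  if (is.null(d))
    stop(sprintf("entry %s has no '%s' level", p$entry_id, level))
  d
}

#' Jaccard index of two domains
#'
#' The set-overlap similarity |A n B| / |A u B| in `[0, 1]`; 1 exactly
#' when the two domains coincide. Computed from interval sizes without
#' materialising the union.
#'
#' @param A,B `interval_domain`s in the same frame, not both empty.
#' @return Numeric score in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  check_same_frame(A, B, "Jaccard index")
  sa <- cpp_iv_size(A$ivs); sb <- cpp_iv_size(B$ivs)
  if (sa == 0 && sb == 0)
    stop("Jaccard index is undefined for two empty domains")
  si <- cpp_iv_isect_size(A$ivs, B$ivs)
  si / (sa + sb - si)
}

#' Local spatial similarity (LOSSST-style) score
#'
#' A local variant of the Jaccard index for region-of-interest queries:
#' expression lying farther than `r` dilation steps from the query region
#' is ignored rather than penalised, so a query that paints part of a
#' larger expression domain is not swamped by the rest of that domain.
#' The score is
#' \deqn{\frac{|q \cap e|}{|q \cup (e \cap \delta_r(q))|}}
#' where \eqn{\delta_r} is dilation by radius `r`. It is built from the
#' four interval primitives (intersect, union, dilation, difference) and
#' reduces to scoring only near-query expression; the exact published
#' weighting of the production search tool is not reproduced here — this
#' local-Jaccard form is this package's documented stand-in, pinned by a
#' dense-array oracle in the test-suite.
#'
#' @param query nonempty `interval_domain` (the painted region of interest).
#' @param expr the pattern's expression domain, same frame.
#' @param r dilation radius in voxels (default 2).
#' @param connectivity dilation connectivity (default 8 in 2D, 26 in 3D).
#' @return Numeric score in `[0, 1]`; 1 when `expr` equals `query`.
#' @export
lossst <- function(query, expr, r = 2L,
                   connectivity = if (query$dim == 2L) 8L else 26L) {
  check_same_frame(query, expr, "local similarity")
  if (nrow(query$ivs) == 0L) stop("query domain must be nonempty")
  near <- dom_intersect(expr, dom_dilate(query, structuring_spec(r, connectivity)))
  si <- cpp_iv_isect_size(query$ivs, expr$ivs)
  denom <- cpp_iv_size(cpp_iv_canon(rbind(query$ivs, near$ivs)))
  si / denom
}

#' Ranked spatial query over a pattern database
#'
#' Scores every pattern's chosen strength level against the query domain
#' and returns hits in descending score order (ties broken by entry id).
#' Patterns scoring exactly zero are dropped. A database entry whose
#' domain equals the query comes back first with score 1.
#'
#' @param query `interval_domain` in the database frame.
#' @param db list of [expression_pattern()]s sharing the query's frame.
#' @param method `"jaccard"` (global overlap) or `"lossst"` (local overlap).
#' @param r dilation radius for the local method.
#' @param level strength level to score against (default `"detected"`).
#' @return A data.frame with columns `entry_id`, `gene`, `score`, `rank`,
#'   `method`, ordered by decreasing score.
#' @export
rank_query <- function(query, db, method = c("lossst", "jaccard"), r = 2L,
                       level = "detected") {
  method <- match.arg(method)
  if (length(db) == 0L)
    return(data.frame(entry_id = character(0), gene = character(0),
                      score = numeric(0), rank = integer(0),
                      method = character(0), stringsAsFactors = FALSE))
  scores <- vapply(db, function(p) {
    d <- pattern_level(p, level)
    if (method == "jaccard") jaccard(query, d) else lossst(query, d, r = r)
  }, numeric(1))
  ids <- vapply(db, `[[`, character(1), "entry_id")
  genes <- vapply(db, `[[`, character(1), "gene")
  keep <- scores > 0
  ord <- order(-scores[keep], ids[keep])
  out <- data.frame(entry_id = ids[keep][ord], gene = genes[keep][ord],
                    score = scores[keep][ord],
                    rank = seq_along(ord), method = method,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pairwise Jaccard similarity matrix of a pattern set
#'
#' Every pattern compared with every other at one strength level; the
#' matrix rows are the per-pattern similarity signatures that drive
#' syn-expression clustering.
#'
#' @param patterns list of [expression_pattern()]s in one frame.
#' @param level strength level (default `"detected"`).
#' @return Symmetric numeric matrix with unit diagonal, dimnames set to
#'   entry ids.
#' @export
pairwise_jaccard <- function(patterns, level = "detected") {
  n <- length(patterns)
  if (n == 0L) stop("no patterns given")
  doms <- lapply(patterns, pattern_level, level = level)
  ids <- vapply(patterns, `[[`, character(1), "entry_id")
  for (i in seq_len(n)) {
    if (dom_size(doms[[i]]) == 0)
      stop(sprintf("entry %s has an empty '%s' domain", ids[i], level))
    if (i > 1L) check_same_frame(doms[[1]], doms[[i]], "pairwise similarity")
  }
  M <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      M[i, j] <- M[j, i] <- jaccard(doms[[i]], doms[[j]])
    }
  }
  dimnames(M) <- list(ids, ids)
  M
}
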