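ivd_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "ivd_error", "error", "condition")))
}

#' Write / read the interval-domain serialization (.ivd)
#'
#' A JSON document describing a canonical interval-coded domain:
#' `{version, dim, frame:{id, shape}, planes:[{z, rows:[{y,
#' intervals:[[start, end], ...]}]}]}` with 0-based, half-open intervals
#' (the half-open convention is stated in the format so it is explicit).
#' The writer is deterministic: the same domain always produces identical
#' bytes. The reader validates rather than repairs: files whose intervals
#' are unsorted, overlapping or adjacent (non-maximal) are rejected with a
#' `ivd_canonical_error`; intervals outside the declared frame raise an
#' `ivd_bounds_error`; unparseable JSON raises an `ivd_parse_error`. Paths
#' ending in `.ivdz` are gzip-compressed transparently.
#'
#' @param dom an `interval_domain`.
#' @param path output file (`.ivd` or `.ivdz`).
#' @return `write_domain` returns `path`; `read_domain` the domain.
#' @export
write_domain <- function(dom, path) {
  stopifnot(inherits(dom, "interval_domain"))
  ivs <- dom$ivs
  planes <- list()
  if (nrow(ivs) > 0L) {
    for (zi in unique(ivs[, 1])) {
      sel <- ivs[, 1] == zi
      rows <- list()
      for (yi in unique(ivs[sel, 2])) {
        rsel <- sel & ivs[, 2] == yi
        rows[[length(rows) + 1L]] <- list(
          y = yi,
          intervals = lapply(which(rsel), function(i) c(ivs[i, 3], ivs[i, 4])))
      }
      planes[[length(planes) + 1L]] <- list(z = zi, rows = rows)
    }
  }
  doc <- list(version = 1L, coding = "half-open-0-based", dim = dom$dim)
  if (!is.null(dom$frame))
    doc$frame <- list(id = dom$frame$id, shape = as.integer(dom$frame$shape))
  doc$planes <- planes
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  con <- if (grepl("\\.ivdz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(js, con)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  con <- if (grepl("\\.ivdz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    ivd_error("ivd_parse_error", "malformed .ivd JSON: %s",
                              conditionMessage(e)))
  if (is.null(doc$dim) || !doc$dim %in% c(2, 3))
    ivd_error("ivd_parse_error", "missing or invalid 'dim'")
  frame <- NULL
  if (!is.null(doc$frame))
    frame <- frame_spec(doc$frame$id, unlist(doc$frame$shape))
  rows <- list()
  for (pl in doc$planes) {
    if (is.null(pl$z)) ivd_error("ivd_parse_error", "plane without 'z'")
    for (rw in pl$rows) {
      if (is.null(rw$y) || is.null(rw$intervals) || !length(rw$intervals))
        ivd_error("ivd_parse_error", "row without 'y' or empty interval list")
      iv <- do.call(rbind, lapply(rw$intervals, function(p) {
        p <- unlist(p)
        if (length(p) != 2L) ivd_error("ivd_parse_error", "interval not a pair")
        as.integer(p)
      }))
      rows[[length(rows) + 1L]] <-
        cbind(z = as.integer(pl$z), y = as.integer(rw$y),
              start = iv[, 1], end = iv[, 2])
    }
  }
  ivs <- if (length(rows)) do.call(rbind, rows) else matrix(integer(0), 0, 4)
  if (any(ivs[, 4] <= ivs[, 3]))
    ivd_error("ivd_canonical_error", "interval with start >= end")
  if (!cpp_iv_is_canonical(ivs))
    ivd_error("ivd_canonical_error",
              "intervals are not canonical (unsorted, overlapping or adjacent)")
  if (!is.null(frame)) {
    sh <- frame$shape
    nz <- if (doc$dim == 3) sh[3] else 1L
    if (nrow(ivs) && (min(ivs[, 3]) < 0L || max(ivs[, 4]) > sh[2] ||
                      min(ivs[, 2]) < 0L || max(ivs[, 2]) >= sh[1] ||
                      min(ivs[, 1]) < 0L || max(ivs[, 1]) >= nz))
      ivd_error("ivd_bounds_error",
                "domain extends outside the declared frame shape")
  }
  new_domain(ivs, as.integer(doc$dim), frame)
}

#' Read / write a grey volume as NIfTI
#'
#' Single-component scalar volumes only. On disk NIfTI stores the x axis
#' fastest; in memory the package uses `[y, x, z]` array order, so axes
#' are permuted on the way in and out. Voxel spacing maps to the NIfTI
#' pixdim fields.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param id frame identifier for the volume read.
#' @return A [grey_volume()].
#' @export
read_volume <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("only single-component 3D NIfTI volumes are supported (got ",
         length(d), "D)")
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  grey_volume(aperm(as.array(img), c(2, 1, 3)), spacing = sp, id = id)
}

#' @rdname read_volume
#' @param vol a [grey_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "grey_volume"))
  arr <- aperm(vol$values, c(2, 1, 3))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Flatten a compound object to an index (label) volume
#'
#' An index image stores one integer region id per voxel and therefore
#' cannot represent overlapping regions — the very limitation the compound
#' object exists to avoid. Flattening is still needed for interchange with
#' label-volume tools, so the overlap behaviour is an explicit policy:
#' `"error"` (default) aborts on the first voxel claimed by two layers,
#' `"priority"` lets the last-listed layer win and reports how many voxels
#' were overridden.
#'
#' @param compound a [compound_object()] whose layers carry frames.
#' @param policy `"error"` or `"priority"`.
#' @param path optional `.nii` output; a `<path>.labels.tsv` table is
#'   written alongside.
#' @param spacing voxel spacing for the written volume.
#' @return List with integer array `labels`, data.frame `table`
#'   (`id`, `name`), and `overridden` voxel count.
#' @export
export_index_volume <- function(compound, policy = c("error", "priority"),
                                path = NULL, spacing = c(1, 1, 1)) {
  policy <- match.arg(policy)
  layers <- compound$layers
  if (!length(layers)) stop("compound object has no layers")
  fr <- layers[[1]]$domain$frame
  if (is.null(fr)) stop("layers must carry a reference frame")
  shape <- fr$shape
  labels <- array(0L, shape)
  overridden <- 0L
  for (i in seq_along(layers)) {
    idx <- linear_indices(layers[[i]]$domain$ivs, shape)
    clash <- labels[idx] != 0L
    if (any(clash)) {
      if (policy == "error") {
        first <- idx[which(clash)[1]]
        co <- arrayInd(first, shape)
        stop(sprintf(paste0("layers '%s' and '%s' overlap at voxel ",
                            "(x=%d, y=%d%s): an index image cannot represent ",
                            "overlapping patterns; use policy='priority' or ",
                            "keep the compound object"),
                     layers[[labels[first]]]$name,
                     layers[[i]]$name, co[2] - 1L, co[1] - 1L,
                     if (length(shape) == 3L) sprintf(", z=%d", co[3] - 1L) else ""))
      }
      overridden <- overridden + sum(clash)
    }
    labels[idx] <- i
  }
  tab <- data.frame(id = seq_along(layers),
                    name = vapply(layers, `[[`, character(1), "name"),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (length(shape) != 3L) stop("volume export requires 3D layers")
    write_volume(grey_volume(labels, spacing = spacing, id = fr$id), path)
    utils::write.table(tab, paste0(path, ".labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(labels = labels, table = tab, overridden = overridden)
}

#' Default occupancy palette
#'
#' Zero occupancy blue, single green, dual yellow, three-plus red.
#' @return Named character vector of colours.
#' @export
occupancy_palette <- function() {
  c(zero = "#0000FF", single = "#00FF00", dual = "#FFFF00",
    `three-plus` = "#FF0000")
}

#' Render an occupancy map to RGB
#'
#' Maps the four occupancy classes to the display palette (by default
#' blue / green / yellow / red for 0 / 1 / 2 / 3+ patterns per voxel). A
#' continuous mode colours raw counts on a dark-to-hot ramp instead.
#'
#' @param occ an [occupancy_map()].
#' @param palette 4 colours for the classes, or `"counts"` for the
#'   continuous ramp.
#' @param slice 0-based z plane to render when `occ` is 3D.
#' @return Numeric `[h, w, 3]` RGB array in `[0, 1]`.
#' @export
render_heatmap <- function(occ, palette = occupancy_palette(), slice = NULL) {
  cls <- occ$classes
  cnt <- occ$counts
  if (length(occ$shape) == 3L) {
    if (is.null(slice)) stop("a 3D occupancy map needs a slice index")
    cls <- cls[, , slice + 1L]
    cnt <- cnt[, , slice + 1L]
  }
  h <- nrow(cls); w <- ncol(cls)
  out <- array(0, c(h, w, 3L))
  if (identical(palette, "counts")) {
    ramp <- grDevices::colorRamp(c("#000040", "#0000FF", "#00FF00",
                                   "#FFFF00", "#FF0000"))
    mx <- max(cnt, 1L)
    rgb <- ramp(as.numeric(cnt) / mx) / 255
    for (ch in 1:3) out[, , ch] <- matrix(rgb[, ch], h, w)
  } else {
    if (length(palette) != 4L) stop("palette must supply 4 class colours")
    cols <- t(vapply(palette, parse_colour, numeric(3)))
    for (ch in 1:3) out[, , ch] <- matrix(cols[as.integer(cls) + 1L, ch], h, w)
  }
  out
}

#' Write / read a binary mask as PNG
#'
#' @param dom a 2D `interval_domain`.
#' @param path PNG path.
#' @param shape grid shape; defaults to the domain frame.
#' @return `read_mask_png` returns an `interval_domain`.
#' @export
write_mask_png <- function(dom, path, shape = NULL) {
  m <- to_mask(dom, shape)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param frame optional [frame_spec()] attached to the read domain.
#' @export
read_mask_png <- function(path, frame = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  interval_domain(img > 0.5, frame = frame)
}

#' Write an RGB array as PNG
#'
#' @param img numeric `[h, w, 3]` array in `[0, 1]`.
#' @param path PNG path.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write / read a pattern-database manifest
#'
#' A manifest is a TSV with columns `entry_id, gene, stage, level, path`
#' (one row per stored strength level, `(entry_id, level)` unique, paths
#' relative to the manifest). `write_manifest` serializes every level of
#' every pattern as a `.ivd` file next to the manifest; `read_manifest`
#' reassembles the [expression_pattern()] list.
#'
#' @param patterns list of [expression_pattern()]s.
#' @param dir output directory (created if needed).
#' @param compress write `.ivdz` instead of `.ivd`.
#' @return `write_manifest` returns the manifest path; `read_manifest` the
#'   pattern list.
#' @export
write_manifest <- function(patterns, dir, compress = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".ivdz" else ".ivd"
  rows <- list()
  for (p in patterns) {
    for (nm in names(p$levels)) {
      fn <- sprintf("%s_%s%s", p$entry_id, nm, ext)
      write_domain(p$levels[[nm]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(entry_id = p$entry_id, gene = p$gene, stage = p$stage,
                   level = nm, path = fn, stringsAsFactors = FALSE)
    }
  }
  tb <- do.call(rbind, rows)
  man <- file.path(dir, "patterns.tsv")
  utils::write.table(tb, man, sep = "\t", quote = FALSE, row.names = FALSE)
  man
}

#' @rdname write_manifest
#' @param path manifest TSV path.
#' @export
read_manifest <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("entry_id", "gene", "stage", "level", "path")
  if (!all(need %in% names(tb))) stop("manifest needs columns ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(tb[c("entry_id", "level")]))
    stop("duplicate (entry_id, level) rows in manifest")
  base <- dirname(path)
  missing <- !file.exists(file.path(base, tb$path))
  if (any(missing))
    stop("missing domain file(s): ", paste(tb$path[missing], collapse = ", "))
  out <- list()
  for (eid in unique(tb$entry_id)) {
    sel <- tb[tb$entry_id == eid, , drop = FALSE]
    levels <- list()
    for (i in seq_len(nrow(sel)))
      levels[[sel$level[i]]] <- read_domain(file.path(base, sel$path[i]))
    out[[length(out) + 1L]] <-
      expression_pattern(eid, sel$gene[1], sel$stage[1], levels)
  }
  out
}
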