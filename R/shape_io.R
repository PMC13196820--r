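#' Read a ShapeWorks-style particles file
#'
#' The `.particles` interchange format holds one point per line as three
#' whitespace-separated numbers `x y z`. Line order defines the correspondence
#' index. Blank lines and lines starting with `#` are skipped.
#'
#' @param path path to a `.particles` text file.
#' @return a [point_set()].
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("particles file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty particles file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nc <- lengths(toks)
  if (any(nc != 3L)) {
    bad <- which(nc != 3L)[1]
    stop(sprintf("malformed particles line %d in %s: expected 3 columns, got %d",
                 lineno[bad], path, nc[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- lineno[ceiling(which(is.na(vals))[1] / 3)]
    stop(sprintf("non-numeric value on particles line %d in %s", bad, path))
  }
  point_set(matrix(vals, ncol = 3L, byrow = TRUE))
}

#' Write a particles file
#'
#' One `x y z` line per point, preserving index order, printed with 9
#' significant digits so that read/write round-trips are stable.
#'
#' @param shape a [point_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(shape, path) {
  shape <- as_point_set(shape)
  lines <- apply(unclass(shape), 1L, function(r) {
    paste(formatC(r, format = "g", digits = 9), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read and write dataset manifests
#'
#' A manifest is a CSV with columns `id`, `path`, and optionally `side` and
#' `label`; `path` entries are resolved relative to the manifest's directory
#' when not absolute.
#'
#' @param path manifest CSV path.
#' @return `read_manifest`: a `shape_dataset`. `write_manifest`: the manifest
#'   tibble, invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "path") %in% names(df))) stop("manifest must have columns id, path")
  base <- dirname(path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path, file.path(base, df$path))
  shapes <- lapply(paths, read_particles)
  col_or_null <- function(nm) {
    if (!nm %in% names(df) || all(is.na(df[[nm]]))) NULL else df[[nm]]
  }
  shape_dataset(shapes,
                labels = col_or_null("label"),
                ids = df$id,
                side = col_or_null("side"))
}

#' @rdname read_manifest
#' @param data a `shape_dataset` to write.
#' @param dir directory receiving the per-shape `.particles` files and
#'   `manifest.csv`.
#' @export
write_manifest <- function(data, dir) {
  stopifnot(inherits(data, "shape_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(data$ids, ".particles")
  for (i in seq_along(data$shapes)) {
    write_particles(data$shapes[[i]], file.path(dir, files[i]))
  }
  mf <- tibble::tibble(
    id = data$ids,
    path = files,
    side = if (is.null(data$side)) NA_character_ else data$side,
    label = if (is.null(data$labels)) NA_character_ else data$labels
  )
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}

#' Mirror a shape across a coordinate plane
#'
#' Negates one coordinate of every point, e.g. to pool left and flipped right
#' hippocampi in a single model. Point ordering (the correspondence) is
#' unchanged, and all within-shape pairwise distances are preserved.
#'
#' @param shape a [point_set()].
#' @param axis which coordinate to negate: `"x"` (default), `"y"` or `"z"`.
#' @return the mirrored `point_set`.
#' @export
flip_lateral <- function(shape, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  shape <- as_point_set(shape)
  j <- match(axis, c("x", "y", "z"))
  shape[, j] <- -shape[, j]
  shape
}

#' Index-wise mean shape of a population
#'
#' Point i of the result is the arithmetic mean over subjects of each
#' subject's point i — the correspondence makes this meaningful; no
#' nearest-neighbour matching is involved.
#'
#' @param data a `shape_dataset` (or list of point sets).
#' @return a [point_set()].
#' @export
mean_shape <- function(data) {
  if (inherits(data, "shape_dataset")) data <- data$shapes
  if (length(data) < 1L) stop("mean_shape of an empty dataset")
  acc <- Reduce(`+`, lapply(data, unclass))
  point_set(acc / length(data))
}

#' Normalize a dataset to a common centre and scale
#'
#' Subtracts the grand centroid (over all points of all shapes) and divides by
#' the root-mean-square point norm of the centred data. The *same* parameters
#' are applied to every shape, so correspondences and relative geometry are
#' untouched; [denormalize_dataset()] inverts the transform exactly.
#'
#' @param data a `shape_dataset`.
#' @param params optionally, reuse previously computed parameters (e.g. apply
#'   the training-set normalization to held-out data).
#' @return a list with elements `data` (the normalized `shape_dataset`) and
#'   `params` (list with 3-vector `center` and positive scalar `scale`).
#' @export
normalize_dataset <- function(data, params = NULL) {
  stopifnot(inherits(data, "shape_dataset"))
  all_pts <- do.call(rbind, lapply(data$shapes, unclass))
  if (is.null(params)) {
    center <- colMeans(all_pts)
    centred <- sweep(all_pts, 2L, center)
    scale <- sqrt(mean(rowSums(centred^2)))
    if (scale < 1e-12) {
      warning("degenerate dataset (all points coincide); scale floored at 1")
      scale <- 1
    }
    params <- list(center = center, scale = scale)
  }
  out <- lapply(data$shapes, function(s) {
    point_set(sweep(unclass(s), 2L, params$center) / params$scale)
  })
  list(data = shape_dataset(out, labels = data$labels, ids = data$ids, side = data$side),
       params = params)
}

#' @rdname normalize_dataset
#' @export
denormalize_dataset <- function(data, params) {
  stopifnot(inherits(data, "shape_dataset"))
  out <- lapply(data$shapes, function(s) {
    point_set(sweep(unclass(s) * params$scale, 2L, params$center, `+`))
  })
  shape_dataset(out, labels = data$labels, ids = data$ids, side = data$side)
}

#' @rdname normalize_dataset
#' @param shape a single `point_set` to (de)normalize with given `params`.
#' @export
normalize_shape <- function(shape, params) {
  point_set(sweep(unclass(as_point_set(shape)), 2L, params$center) / params$scale)
}

#' @rdname normalize_dataset
#' @export
denormalize_shape <- function(shape, params) {
  point_set(sweep(unclass(as_point_set(shape)) * params$scale, 2L, params$center, `+`))
}
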