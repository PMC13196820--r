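#' Ordered point-set shape representation
#'
#' A `point_set` is an N x 3 numeric matrix of point coordinates in which the
#' row index is semantic: row i of every shape in a population refers to the
#' same anatomical locus (the correspondence). Reordering rows is therefore
#' *not* a no-op.
#'
#' @param coords numeric N x 3 matrix (or coercible), one point per row.
#' @return an object of class `point_set` (an N x 3 matrix).
#' @examples
#' ps <- point_set(rbind(c(0, 0, 0), c(1, 2, 3)))
#' n_points(ps)
#' @export
point_set <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords)) stop("point_set coordinates must be numeric")
  if (ncol(coords) != 3L) stop("point_set requires exactly 3 coordinate columns, got ", ncol(coords))
  if (nrow(coords) < 1L) stop("point_set requires at least one point")
  if (!all(is.finite(coords))) stop("point_set coordinates must all be finite")
  dimnames(coords) <- NULL
  structure(coords, class = c("point_set", "matrix", "array"))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points>\n", nrow(x)))
  utils::str(unclass(x))
  invisible(x)
}

#' Number of points in a shape or dataset
#' @param x a `point_set` or `shape_dataset`.
#' @return integer point count N.
#' @export
n_points <- function(x) UseMethod("n_points")

#' @export
n_points.point_set <- function(x) nrow(x)

#' @export
n_points.shape_dataset <- function(x) nrow(x$shapes[[1]])

is_point_set <- function(x) inherits(x, "point_set")

as_point_set <- function(x) {
  if (is_point_set(x)) x else point_set(x)
}

#' A population of corresponding shapes
#'
#' Bundles a list of [point_set()] objects sharing the same point count and
#' ordering semantics, with optional per-shape class labels, identifiers and
#' laterality.
#'
#' @param shapes list of `point_set` (or N x 3 matrices), all with identical N.
#' @param labels optional per-shape class labels (character or factor),
#'   aligned 1:1 with `shapes`.
#' @param ids optional per-shape identifiers; defaults to `"s1" ... "sS"`.
#' @param side optional per-shape laterality, e.g. `"left"`/`"right"`.
#' @return an object of class `shape_dataset`.
#' @export
shape_dataset <- function(shapes, labels = NULL, ids = NULL, side = NULL) {
  if (length(shapes) < 1L) stop("shape_dataset requires at least one shape")
  shapes <- lapply(shapes, as_point_set)
  n <- vapply(shapes, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    stop("all shapes in a shape_dataset must share the same point count; saw N in {",
         paste(unique(n), collapse = ", "), "}")
  }
  if (!is.null(labels)) {
    if (length(labels) != length(shapes)) stop("labels must align 1:1 with shapes")
    labels <- as.character(labels)
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(shapes))
  if (length(ids) != length(shapes)) stop("ids must align 1:1 with shapes")
  if (!is.null(side) && length(side) != length(shapes)) stop("side must align 1:1 with shapes")
  structure(list(shapes = shapes, labels = labels, ids = as.character(ids), side = side),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("<shape_dataset: %d shapes x %d points>\n", length(x$shapes), n_points(x)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.shape_dataset <- function(x) length(x$shapes)

#' Subset a shape dataset by shape index
#' @param x a `shape_dataset`.
#' @param i index vector of shapes to keep.
#' @param ... unused.
#' @export
`[.shape_dataset` <- function(x, i, ...) {
  shape_dataset(x$shapes[i],
                labels = if (!is.null(x$labels)) x$labels[i],
                ids = x$ids[i],
                side = if (!is.null(x$side)) x$side[i])
}

#' Stack a dataset into an S x N x 3 array
#' @param x a `shape_dataset`.
#' @return numeric array with dimensions (shapes, points, coordinates).
#' @export
as_array <- function(x) {
  stopifnot(inherits(x, "shape_dataset"))
  aperm(simplify2array(lapply(x$shapes, unclass)), c(3, 1, 2))
}

#' Flatten a dataset into an S x 3N matrix
#'
#' Rows are shapes; columns interleave per point as (x1, y1, z1, x2, ...),
#' the layout assumed by the PCA baseline.
#' @param x a `shape_dataset`.
#' @return numeric S x 3N matrix.
#' @export
flatten_shapes <- function(x) {
  stopifnot(inherits(x, "shape_dataset"))
  t(vapply(x$shapes, function(s) as.numeric(t(unclass(s))), numeric(3L * n_points(x))))
}

unflatten_shape <- function(v) {
  point_set(matrix(v, ncol = 3L, byrow = TRUE))
}

#' Convert a point set or dataset to a tibble
#'
#' Long format: one row per point per shape, with `id`, `label`, `point`
#' (the correspondence index) and `x`, `y`, `z` columns.
#' @param x a `shape_dataset` or `point_set`.
#' @param ... unused.
#' @return a tibble.
#' @export
as_tibble_shapes <- function(x, ...) {
  if (is_point_set(x)) x <- shape_dataset(list(x))
  n <- n_points(x)
  s <- length(x$shapes)
  m <- do.call(rbind, lapply(x$shapes, unclass))
  tibble::tibble(
    id = rep(x$ids, each = n),
    label = if (is.null(x$labels)) NA_character_ else rep(x$labels, each = n),
    point = rep(seq_len(n), times = s),
    x = m[, 1], y = m[, 2], z = m[, 3]
  )
}
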