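dist_kind <- function(dist) {
  d <- tolower(dist)
  kind <- match(d, c("cd", "emd", "l2"))
  if (is.na(kind)) stop("unknown distance kind '", dist, "' (use cd, emd or l2)")
  kind
}

#' Point-set distances
#'
#' Three distances between N x 3 point sets:
#' * `l2_distance`: per-point RMS of the *index-wise* differences,
#'   `sqrt(sum((a - b)^2) / N)` — the only one of the three that sees the
#'   correspondence; permuting one argument's rows changes it.
#' * `chamfer_distance`: symmetric sum of mean squared nearest-neighbour
#'   distances; permutation invariant; point counts may differ.
#' * `earth_movers_distance`: minimal mean Euclidean distance under an optimal
#'   one-to-one matching (exact assignment solver); permutation invariant;
#'   requires equal N.
#'
#' @param a,b point sets ([point_set()] or N x 3 matrices).
#' @return a nonnegative scalar.
#' @export
l2_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("l2_distance requires matching N")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' @rdname l2_distance
#' @export
chamfer_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("chamfer_distance of an empty point set")
  .cpp_chamfer(a, b)
}

#' @rdname l2_distance
#' @param return_assignment if `TRUE`, also return the optimal matching
#'   (integer vector: `assignment[j]` is the row of `a` matched to row j of
#'   `b`).
#' @export
earth_movers_distance <- function(a, b, return_assignment = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("earth_movers_distance requires equal N")
  res <- .cpp_emd(a, b)
  if (return_assignment) res else res$value
}

#' Pairwise distance matrix between two shape populations
#'
#' @param a,b `shape_dataset`s with a common point count.
#' @param dist `"cd"`, `"emd"` or `"l2"`.
#' @return a `length(a)` x `length(b)` matrix.
#' @export
pairwise_shape_distances <- function(a, b, dist = "cd") {
  stopifnot(inherits(a, "shape_dataset"), inherits(b, "shape_dataset"))
  n <- n_points(a)
  if (n_points(b) != n) stop("populations must share a point count")
  .cpp_pairwise(do.call(rbind, lapply(a$shapes, unclass)),
                do.call(rbind, lapply(b$shapes, unclass)),
                n, dist_kind(dist))
}

#' Minimum matching distance (MMD)
#'
#' The mean over real shapes of the distance to the closest generated shape —
#' a fidelity measure, lower is better.
#'
#' @param real,gen `shape_dataset`s.
#' @param dist underlying distance kind (`"cd"`, `"emd"`, `"l2"`).
#' @param D optional precomputed [pairwise_shape_distances()] matrix
#'   (real x gen).
#' @return nonnegative scalar.
#' @export
mmd <- function(real, gen, dist = "cd", D = NULL) {
  if (is.null(D)) D <- pairwise_shape_distances(real, gen, dist)
  mean(apply(D, 1L, min))
}

#' k-nearest-neighbour ball radii of the real sample
#'
#' `radius[i]` is the distance from real shape i to its k-th nearest *other*
#' real shape; ties are resolved by lower index (which leaves the radius
#' value unchanged).
#'
#' @param real a `shape_dataset` with more than k shapes.
#' @param k neighbour count (default 7).
#' @param dist distance kind.
#' @param D optional precomputed real x real distance matrix.
#' @return numeric vector of radii, one per real shape.
#' @export
knn_ball_radii <- function(real, k = 7L, dist = "cd", D = NULL) {
  if (is.null(D)) D <- pairwise_shape_distances(real, real, dist)
  nr <- nrow(D)
  if (nr <= k) stop("knn_ball_radii needs more than k real samples")
  diag(D) <- Inf
  apply(D, 1L, function(r) sort(r, partial = k)[k])
}

#' Coverage and density of a generated sample
#'
#' Both fit a k-NN ball around each real shape ([knn_ball_radii()]).
#' `coverage` is the fraction of real balls containing at least one generated
#' shape (diversity; in \[0, 1\]). `density` counts every (generated, ball)
#' containment and divides by k * M, M the generated count (concentration;
#' near 1 for a matched distribution, above 1 when samples pile into dense
#' regions). Containment uses `<=`. Between two large disjoint samples of the
#' same distribution both approach 1.
#'
#' @inheritParams knn_ball_radii
#' @param gen the generated `shape_dataset`.
#' @param D_rg optional precomputed real x gen distance matrix.
#' @param radii optional precomputed [knn_ball_radii()].
#' @return scalar.
#' @export
coverage <- function(real, gen, k = 7L, dist = "cd", D_rg = NULL, radii = NULL) {
  if (is.null(radii)) radii <- knn_ball_radii(real, k, dist)
  if (is.null(D_rg)) D_rg <- pairwise_shape_distances(real, gen, dist)
  mean(apply(D_rg <= radii, 1L, any))
}

#' @rdname coverage
#' @export
density_score <- function(real, gen, k = 7L, dist = "cd", D_rg = NULL, radii = NULL) {
  if (is.null(radii)) radii <- knn_ball_radii(real, k, dist)
  if (is.null(D_rg)) D_rg <- pairwise_shape_distances(real, gen, dist)
  sum(D_rg <= radii) / (k * ncol(D_rg))
}

#' Evaluate a generated population against a real one
#'
#' Computes MMD, coverage and density under each requested distance, reusing
#' one pairwise computation per distance.
#'
#' @param real,gen `shape_dataset`s.
#' @param k ball neighbour count (default 7).
#' @param distances character vector among `"cd"`, `"emd"`, `"l2"`.
#' @return a `metric_report` tibble with columns `distance`, `mmd`,
#'   `coverage`, `density`, `k`, `n_real`, `n_gen`.
#' @export
evaluate_generation <- function(real, gen, k = 7L, distances = c("cd", "emd", "l2")) {
  rows <- lapply(distances, function(d) {
    D_rr <- pairwise_shape_distances(real, real, d)
    radii <- knn_ball_radii(real, k, d, D = D_rr)
    D_rg <- pairwise_shape_distances(real, gen, d)
    tibble::tibble(
      distance = toupper(d),
      mmd = mmd(real, gen, d, D = D_rg),
      coverage = coverage(real, gen, k, d, D_rg = D_rg, radii = radii),
      density = density_score(real, gen, k, d, D_rg = D_rg, radii = radii),
      k = as.integer(k),
      n_real = length(real$shapes),
      n_gen = length(gen$shapes)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
tidy.metric_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(n_real = x$n_real[1], n_gen = x$n_gen[1], k = x$k[1],
                 n_distances = nrow(x))
}
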