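#' Fit the PCA shape-model baseline
#'
#' Flattens every shape to a 3N-vector, mean-centres, and extracts the top
#' `n_components` principal components by SVD. Component signs follow a
#' deterministic convention (largest-magnitude loading positive). Because a
#' flattened shape keeps its index layout, PCA generation preserves
#' correspondence by construction.
#'
#' @param data a [shape_dataset()] of S shapes.
#' @param n_components number of components to retain (default 128, capped at
#'   `min(S - 1, 3N)`).
#' @return a `pca_model` with `mean_vector`, row-orthonormal `components`
#'   (n_components x 3N), per-component `variances` (eigenvalues),
#'   `explained_variance_ratio` (cumulative), and the shape size `n_points`.
#' @export
pca_fit <- function(data, n_components = 128L) {
  stopifnot(inherits(data, "shape_dataset"))
  x <- flatten_shapes(data)
  s <- nrow(x)
  limit <- min(s - 1L, ncol(x))
  if (n_components > limit) {
    stop("n_components = ", n_components, " exceeds min(S - 1, 3N) = ", limit)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0, nv = n_components)
  comp <- t(sv$v)
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(nrow(comp))) {
    i <- which.max(abs(comp[j, ]))
    if (comp[j, i] < 0) comp[j, ] <- -comp[j, ]
  }
  ev_all <- sv$d^2 / (s - 1L)
  vars <- ev_all[seq_len(n_components)]
  structure(list(mean_vector = mu, components = comp, variances = vars,
                 n_components = as.integer(n_components),
                 explained_variance_ratio = cumsum(vars) / sum(ev_all),
                 n_points = n_points(data), n_train = s),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components over %d-point shapes, %.2f%% variance>\n",
              x$n_components, x$n_points,
              100 * x$explained_variance_ratio[x$n_components]))
  invisible(x)
}

#' Sample shapes from a fitted PCA model
#'
#' Draws each component score from a zero-mean Gaussian with the component's
#' empirical eigenvalue variance and maps back to shape space
#' (`mean + scores %*% components`), i.e. PCA run in reverse. Generated
#' shapes inherit the training point ordering.
#'
#' @param model a [pca_fit()] result.
#' @param n number of shapes to generate.
#' @param scores optional n x n_components matrix of scores to use instead of
#'   random draws (e.g. zeros to get the mean shape).
#' @return a [shape_dataset()].
#' @export
pca_sample <- function(model, n, scores = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(scores)) {
    scores <- matrix(stats::rnorm(n * model$n_components), n) %*%
      diag(sqrt(model$variances), model$n_components)
  }
  flat <- sweep(scores %*% model$components, 2L, model$mean_vector, `+`)
  shape_dataset(lapply(seq_len(n), function(i) unflatten_shape(flat[i, ])),
                ids = sprintf("pca_%04d", seq_len(n)))
}

#' Reconstruct shapes through the retained components
#'
#' Projects each shape onto the retained subspace and back; with all
#' components retained this is the identity up to numerical error.
#'
#' @param model a `pca_model`.
#' @param data a `shape_dataset`.
#' @return a `shape_dataset` of reconstructions.
#' @export
pca_reconstruct <- function(model, data) {
  x <- flatten_shapes(data)
  xc <- sweep(x, 2L, model$mean_vector)
  rec <- sweep((xc %*% t(model$components)) %*% model$components, 2L,
               model$mean_vector, `+`)
  shape_dataset(lapply(seq_len(nrow(rec)), function(i) unflatten_shape(rec[i, ])),
                labels = data$labels, ids = data$ids, side = data$side)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 variance = x$variances,
                 cumulative_variance_ratio = x$explained_variance_ratio)
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, n_points = x$n_points,
                 n_train = x$n_train,
                 explained_variance_ratio = x$explained_variance_ratio[x$n_components])
}
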