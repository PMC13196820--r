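adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       step = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  c1 <- 1 - beta1^state$step
  c2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

#' Train the correspondence-preserving diffusion model
#'
#' Standard epsilon-prediction training: for each shape in a minibatch draw a
#' uniform timestep t and a standard-normal noise field, form the noisy shape
#' with the closed-form forward marginal, and regress the backbone's output
#' onto the injected noise (mean-squared error). Optimized with Adam and
#' global gradient-norm clipping.
#'
#' The dataset is normalized first (grand-centroid centring, RMS-norm
#' scaling) and the normalization parameters are stored on the returned
#' predictor so that [sample_shapes()] emits shapes in the original frame.
#'
#' @param data a [shape_dataset()]; its labels are used when `conditional`.
#' @param net_config a [network_config()]; built from defaults when `NULL`.
#' @param diff_config a [diffusion_config()].
#' @param epochs full passes over the data.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip (Inf disables).
#' @param conditional train a class-conditional model on `data$labels`.
#' @param seed RNG seed covering initialization and the whole run.
#' @param normalize normalize the data before training (recommended).
#' @param verbose print per-epoch mean loss every `verbose` epochs (0 = quiet).
#' @return a trained [noise_predictor()] with `norm_params` and a
#'   `loss_history` tibble (`epoch`, `loss`) attached.
#' @export
train_diffusion <- function(data,
                            net_config = NULL,
                            diff_config = diffusion_config(),
                            epochs = 200L,
                            batch_size = 32L,
                            lr = 2e-3,
                            clip = 1,
                            conditional = FALSE,
                            seed = 1L,
                            normalize = TRUE,
                            verbose = 0L) {
  stopifnot(inherits(data, "shape_dataset"))
  if (conditional && is.null(data$labels)) stop("conditional training requires labels")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  norm_params <- NULL
  if (normalize) {
    nd <- normalize_dataset(data)
    data <- nd$data
    norm_params <- nd$params
  }
  n <- n_points(data)
  if (is.null(net_config)) {
    net_config <- network_config(n, conditional = conditional,
                                 classes = if (conditional) sort(unique(data$labels)))
  }
  sched <- make_schedule(diff_config)
  net <- noise_predictor(net_config, mean_shape(data), sched, seed = seed)
  net$norm_params <- norm_params

  xs_all <- lapply(data$shapes, unclass)
  s <- length(xs_all)
  opt <- adam_init(net$params)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(s)
    ep_loss <- 0; nb_seen <- 0L
    for (start in seq(1L, s, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, s)]
      xs <- xs_all[idx]
      bl <- if (net_config$conditional) data$labels[idx]
      tvec <- sample.int(sched$n_steps, length(idx), replace = TRUE)
      eps <- matrix(stats::rnorm(length(idx) * n * 3L), length(idx) * n, 3L)
      ab <- sched$alpha_bars[tvec]
      sa <- sqrt(ab)[rep(seq_along(idx), each = n)]
      sb <- sqrt(1 - ab)[rep(seq_along(idx), each = n)]
      x0 <- do.call(rbind, xs)
      xt <- sa * x0 + sb * eps
      xt_list <- lapply(seq_along(idx), function(b) xt[((b - 1L) * n + 1L):(b * n), , drop = FALSE])
      fwd <- nn_forward(net, xt_list, tvec, bl, keep = TRUE)
      resid <- fwd$out - eps
      loss <- mean(resid^2)
      grads <- nn_backward(net, fwd$cache, 2 * resid / length(resid))
      grads <- clip_grads(grads, clip)
      upd <- adam_step(net$params, grads, opt, lr)
      net$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss; nb_seen <- nb_seen + 1L
    }
    hist[ep] <- ep_loss / nb_seen
    if (verbose > 0 && (ep %% verbose == 0 || ep == 1L)) {
      message(sprintf("epoch %4d  loss %.5f", ep, hist[ep]))
    }
  }
  net$loss_history <- tibble::tibble(epoch = seq_len(epochs), loss = hist)
  net
}

#' Save or load a model checkpoint
#'
#' The checkpoint bundles everything needed to reproduce sampling: weights,
#' network config, attention mask and its source mean shape, the variance
#' schedule, and the normalization parameters.
#'
#' @param object a `noise_predictor`, `shape_classifier` or `pca_model`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(format = "pdmdiffuse-checkpoint", version = 1L, object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pdmdiffuse-checkpoint")) stop("not a pdmdiffuse checkpoint: ", path)
  x$object
}

#' Tidy the training curve of a fitted predictor
#' @param x a trained [noise_predictor()].
#' @param ... unused.
#' @return tibble with `epoch` and `loss`.
#' @export
tidy.noise_predictor <- function(x, ...) {
  if (is.null(x$loss_history)) stop("predictor has no recorded training history")
  x$loss_history
}

#' @rdname tidy.noise_predictor
#' @export
glance.noise_predictor <- function(x, ...) {
  tibble::tibble(
    n_points = x$config$n_points,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    n_steps = if (!is.null(x$schedule)) x$schedule$n_steps else NA_integer_,
    conditional = x$config$conditional,
    correspondence_embeddings = x$config$use_correspondence_embeddings,
    final_loss = if (is.null(x$loss_history)) NA_real_ else utils::tail(x$loss_history$loss, 1)
  )
}
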