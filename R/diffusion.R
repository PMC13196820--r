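#' Diffusion process configuration
#'
#' @param n_steps number of diffusion steps T.
#' @param schedule_kind `"linear"` (betas interpolated from `beta_start` to
#'   `beta_end`) or `"cosine"` (squared-cosine cumulative signal schedule).
#' @param beta_start,beta_end endpoints of the linear schedule; defaults are
#'   the standard T = 1000 DDPM values. When running a shorter chain, scale
#'   `beta_end` up (roughly by 1000 / T) so the terminal marginal is still
#'   close to a standard normal.
#' @param sampler_final_noise_off if `TRUE` (default) no noise is added on the
#'   final t = 1 -> 0 reverse step.
#' @return a `diffusion_config` list.
#' @export
diffusion_config <- function(n_steps = 1000L,
                             schedule_kind = c("linear", "cosine"),
                             beta_start = 1e-4, beta_end = 0.02,
                             sampler_final_noise_off = TRUE) {
  schedule_kind <- match.arg(schedule_kind)
  stopifnot(n_steps >= 1L)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("need 0 < beta_start <= beta_end < 1")
  }
  structure(list(n_steps = as.integer(n_steps), schedule_kind = schedule_kind,
                 beta_start = beta_start, beta_end = beta_end,
                 sampler_final_noise_off = isTRUE(sampler_final_noise_off)),
            class = "diffusion_config")
}

#' Build a variance schedule
#'
#' Produces the per-step noise rates beta_t of the forward Markov kernel
#' q(X(t) | X(t-1)) = N(sqrt(1 - beta_t) X(t-1), beta_t I), together with
#' alpha_t = 1 - beta_t and the cumulative products alpha_bar_t used by the
#' closed-form marginal.
#'
#' @param config a [diffusion_config()].
#' @return a `variance_schedule` list with `n_steps`, `betas`, `alphas`,
#'   `alpha_bars` (all length T; `alpha_bar[0] = 1` by convention is implicit)
#'   and the originating `config`.
#' @export
make_schedule <- function(config) {
  stopifnot(inherits(config, "diffusion_config"))
  n <- config$n_steps
  if (config$schedule_kind == "linear") {
    betas <- if (n == 1L) config$beta_end else seq(config$beta_start, config$beta_end, length.out = n)
  } else {
    s <- 0.008
    f <- function(t) cos((t / n + s) / (1 + s) * pi / 2)^2
    abar <- f(0:n) / f(0)
    betas <- pmin(1 - abar[-1] / abar[-(n + 1)], 0.999)
    betas <- pmax(betas, 1e-8)
  }
  alphas <- 1 - betas
  structure(list(n_steps = n, betas = betas, alphas = alphas,
                 alpha_bars = cumprod(alphas), config = config),
            class = "variance_schedule")
}

check_t <- function(t, sched) {
  if (length(t) != 1L || t < 1L || t > sched$n_steps) {
    stop("timestep t must lie in 1..", sched$n_steps, ", got ", t)
  }
  as.integer(t)
}

#' Closed-form forward (noising) sample
#'
#' Composing the one-step Gaussian kernel t times gives the marginal
#' q(X(t) | X(0)) = N(sqrt(alpha_bar_t) X(0), (1 - alpha_bar_t) I); this
#' returns `sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps` with `eps`
#' a supplied standard-normal draw. Point ordering is preserved.
#'
#' @param x0 clean shape, a [point_set()] or N x 3 matrix.
#' @param t timestep in 1..T.
#' @param eps N x 3 standard normal draw (matching `x0`).
#' @param sched a [make_schedule()] result.
#' @return noisy N x 3 matrix of class `point_set`.
#' @export
forward_sample <- function(x0, t, eps, sched) {
  t <- check_t(t, sched)
  x0 <- unclass(as_point_set(x0))
  eps <- as.matrix(eps)
  if (!all(dim(eps) == dim(x0))) stop("eps shape must match x0")
  ab <- sched$alpha_bars[t]
  point_set(sqrt(ab) * x0 + sqrt(1 - ab) * eps)
}

#' Single reverse (denoising) transition
#'
#' Applies the learned reverse kernel p(X(t-1) | X(t)) = N(mu, beta_t I) with
#' mu = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t).
#' When `t == 1` and the schedule's config sets `sampler_final_noise_off`,
#' the added noise is forced to zero.
#'
#' @param xt current noisy shape (N x 3).
#' @param t timestep in 1..T.
#' @param eps_hat N x 3 noise prediction.
#' @param sched a [make_schedule()] result.
#' @param noise optional N x 3 standard normal draw; drawn from the current
#'   RNG stream when `NULL`.
#' @return N x 3 `point_set` at time t - 1.
#' @export
reverse_step <- function(xt, t, eps_hat, sched, noise = NULL) {
  t <- check_t(t, sched)
  xt <- unclass(as_point_set(xt))
  eps_hat <- as.matrix(eps_hat)
  if (!all(dim(eps_hat) == dim(xt))) stop("eps_hat shape must match xt")
  mu <- (xt - sched$betas[t] / sqrt(1 - sched$alpha_bars[t]) * eps_hat) / sqrt(sched$alphas[t])
  if (t == 1L && isTRUE(sched$config$sampler_final_noise_off)) {
    noise <- 0
  } else if (is.null(noise)) {
    noise <- matrix(stats::rnorm(length(xt)), nrow = nrow(xt))
  }
  point_set(mu + sqrt(sched$betas[t]) * noise)
}

#' Denoising training loss for one draw
#'
#' The epsilon-prediction objective: noise `x0` to timestep t with the given
#' draw, ask the predictor for the noise, and return the mean squared error
#' per coordinate, `mean((eps - eps_hat)^2)`. The mean reduction keeps the
#' loss scale independent of N and T.
#'
#' @param predictor a [noise_predictor()], or a function
#'   `(xt, t, label) -> N x 3` (useful for oracle predictors in checks).
#' @param x0 clean shape.
#' @param t timestep in 1..T.
#' @param eps N x 3 standard normal draw.
#' @param sched a [make_schedule()] result.
#' @param label optional class label for a conditional predictor.
#' @return nonnegative scalar loss.
#' @export
training_loss <- function(predictor, x0, t, eps, sched, label = NULL) {
  xt <- forward_sample(x0, t, eps, sched)
  eps_hat <- if (is.function(predictor)) predictor(xt, t, label)
             else predict_noise(predictor, xt, t, label)
  if (!all(dim(as.matrix(eps_hat)) == dim(as.matrix(eps)))) {
    stop("predictor output shape does not match eps")
  }
  mean((as.matrix(eps) - eps_hat)^2)
}

#' Ancestral sampling from a trained predictor
#'
#' Starts each sample at X(T) ~ N(0, I) and applies [reverse_step()] for
#' t = T..1. Sampling is reproducible for a fixed RNG state.
#'
#' @param predictor a trained [noise_predictor()].
#' @param n_samples number of shapes to generate.
#' @param sched the [make_schedule()] the predictor was trained with (defaults
#'   to the schedule stored in the predictor).
#' @param label optional class label (single value or vector of length
#'   `n_samples`) for conditional generation.
#' @param trace if `TRUE`, also return the full reverse trajectories.
#' @return a [shape_dataset()] of generated shapes (labels attached when
#'   `label` is given), mapped back to the original coordinate frame when the
#'   predictor carries normalization parameters.
#' @export
sample_shapes <- function(predictor, n_samples, sched = predictor$schedule,
                          label = NULL, trace = FALSE) {
  stopifnot(inherits(predictor, "noise_predictor"))
  if (is.null(sched)) stop("no schedule supplied or stored in the predictor")
  n <- predictor$config$n_points
  labels <- if (!is.null(label)) rep(label, length.out = n_samples)
  xs <- lapply(seq_len(n_samples), function(i) matrix(stats::rnorm(n * 3L), n, 3L))
  traj <- if (trace) list()
  for (t in seq(sched$n_steps, 1L)) {
    eps_hat <- predict_noise_batch(predictor, xs, rep(t, n_samples), labels)
    noise <- lapply(seq_len(n_samples), function(i) {
      if (t == 1L && isTRUE(sched$config$sampler_final_noise_off)) 0
      else matrix(stats::rnorm(n * 3L), n, 3L)
    })
    xs <- lapply(seq_len(n_samples), function(i) {
      unclass(reverse_step(xs[[i]], t, eps_hat[[i]], sched, noise[[i]]))
    })
    if (trace) traj[[as.character(t)]] <- xs
  }
  out <- shape_dataset(lapply(xs, point_set), labels = labels,
                       ids = sprintf("gen_%04d", seq_len(n_samples)))
  if (!is.null(predictor$norm_params)) {
    out <- denormalize_dataset(out, predictor$norm_params)
  }
  if (trace) attr(out, "trajectory") <- traj
  out
}
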