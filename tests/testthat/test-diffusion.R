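test_that("schedules satisfy their invariants", {
  s1 <- make_schedule(diffusion_config(n_steps = 1, beta_start = 0.5, beta_end = 0.5))
  expect_equal(s1$betas, 0.5)
  expect_equal(s1$alpha_bars, 0.5)

  s <- make_schedule(diffusion_config(n_steps = 50))
  expect_true(all(s$betas > 0 & s$betas < 1))
  expect_true(all(diff(s$alpha_bars) < 0))
  # brute-force loop product oracle
  ab <- numeric(50); acc <- 1
  for (t in 1:50) { acc <- acc * (1 - s$betas[t]); ab[t] <- acc }
  expect_equal(s$alpha_bars, ab, tolerance = 1e-12)

  sc <- make_schedule(diffusion_config(n_steps = 50, schedule_kind = "cosine"))
  expect_true(all(sc$betas > 0 & sc$betas < 1))
  expect_true(all(diff(sc$alpha_bars) < 0))

  expect_error(diffusion_config(beta_start = 0.3, beta_end = 0.2))
  expect_error(diffusion_config(beta_start = 0))
})

test_that("forward_sample matches its closed form in the limits", {
  s <- make_schedule(diffusion_config(n_steps = 10, beta_end = 0.1))
  set.seed(1)
  x0 <- rand_shape(6)
  z <- matrix(0, 6, 3)
  for (t in c(1, 5, 10)) {
    expect_equal(unclass(forward_sample(x0, t, z, s)),
                 sqrt(s$alpha_bars[t]) * unclass(x0), tolerance = 1e-12)
  }
  # near-degenerate schedule: alpha_bar ~ 0 so the output is (almost) pure noise
  sdeg <- make_schedule(diffusion_config(n_steps = 1, beta_start = 1 - 1e-12,
                                         beta_end = 1 - 1e-12))
  eps <- matrix(rnorm(18), 6, 3)
  expect_equal(unclass(forward_sample(x0, 1, eps, sdeg)), eps, tolerance = 1e-5)
  expect_error(forward_sample(x0, 11, z, s), "1..10")
  expect_error(forward_sample(x0, 3, matrix(0, 5, 3), s), "match")
})

test_that("sequential one-step kernels compose to the closed-form marginal", {
  # moment test of the Markov kernel composition at T = 10, one point
  s <- make_schedule(diffusion_config(n_steps = 10, beta_start = 0.05, beta_end = 0.3))
  set.seed(2)
  n_mc <- 20000
  x0 <- c(1.5, -0.7, 0.3)
  x <- matrix(rep(x0, each = n_mc), n_mc, 3)
  for (t in 1:10) {
    x <- sqrt(1 - s$betas[t]) * x +
      sqrt(s$betas[t]) * matrix(rnorm(n_mc * 3), n_mc, 3)
  }
  ab <- s$alpha_bars[10]
  se_mean <- sqrt(1 - ab) / sqrt(n_mc)
  expect_true(all(abs(colMeans(x) - sqrt(ab) * x0) < 4 * se_mean))
  se_var <- (1 - ab) * sqrt(2 / (n_mc - 1))
  expect_true(all(abs(apply(x, 2, var) - (1 - ab)) < 4 * se_var))
})

test_that("training_loss is the mean squared noise-prediction error", {
  s <- make_schedule(diffusion_config(n_steps = 10, beta_end = 0.1))
  set.seed(3)
  x0 <- rand_shape(6)
  eps <- matrix(rnorm(18), 6, 3)
  oracle <- local({ e <- eps; function(xt, t, label) e })
  expect_equal(training_loss(oracle, x0, 4, eps, s), 0)
  zero <- function(xt, t, label) matrix(0, 6, 3)
  # E ||eps||^2 / dim = 1 for standard normal draws
  losses <- replicate(500, training_loss(zero, x0, 4, matrix(rnorm(18), 6, 3), s))
  expect_equal(mean(losses), 1, tolerance = 0.15)
  # loss of a constant predictor is minimized at c = 0
  cost <- vapply(c(-1, -0.5, 0, 0.5, 1), function(cc) {
    set.seed(4)
    mean(replicate(300, training_loss(function(xt, t, label) matrix(cc, 6, 3),
                                      x0, 4, matrix(rnorm(18), 6, 3), s)))
  }, numeric(1))
  expect_equal(which.min(cost), 3L)
  # a freshly initialized predictor has zero final layer -> predicts zeros
  net <- tiny_net(n = 6)
  expect_equal(predict_noise(net, unclass(x0), 3), matrix(0, 6, 3))
})

test_that("reverse_step inverts the forward step given the true noise", {
  s1 <- make_schedule(diffusion_config(n_steps = 1, beta_start = 0.5, beta_end = 0.5))
  set.seed(5)
  x0 <- rand_shape(7)
  eps <- matrix(rnorm(21), 7, 3)
  xt <- forward_sample(x0, 1, eps, s1)
  rec <- reverse_step(xt, 1, eps, s1)   # final-step noise forced off
  expect_equal(unclass(rec), unclass(x0), tolerance = 1e-9)

  s <- make_schedule(diffusion_config(n_steps = 5, beta_end = 0.1))
  xt <- rand_shape(7)
  # eps_hat = 0, noise = 0: pure 1/sqrt(alpha_t) rescaling
  out <- reverse_step(xt, 3, matrix(0, 7, 3), s, noise = matrix(0, 7, 3))
  expect_equal(unclass(out), unclass(xt) / sqrt(s$alphas[3]), tolerance = 1e-12)
  # shift equivariance: reverse_step(xt + c) = reverse_step(xt) + c / sqrt(alpha_t)
  cshift <- c(1, -2, 0.5)
  eh <- matrix(rnorm(21), 7, 3)
  o1 <- reverse_step(xt, 3, eh, s, noise = matrix(0, 7, 3))
  o2 <- reverse_step(point_set(sweep(unclass(xt), 2, cshift, `+`)), 3, eh, s,
                     noise = matrix(0, 7, 3))
  expect_equal(unclass(o2), sweep(unclass(o1), 2, cshift / sqrt(s$alphas[3]), `+`),
               tolerance = 1e-12)
})

test_that("sampling is reproducible and a point-mass model concentrates", {
  net <- tiny_net(n = 8, n_steps = 10)
  set.seed(11); g1 <- sample_shapes(net, 3)
  set.seed(11); g2 <- sample_shapes(net, 3)
  expect_identical(lapply(g1$shapes, unclass), lapply(g2$shapes, unclass))

  # train a tiny model on a single shape; samples should concentrate near it
  target <- point_set(sweep(unclass(sphere_parameterization(16)), 2,
                            c(1, 0.7, 0.5), `*`))
  ds <- shape_dataset(rep(list(target), 8))
  net <- train_diffusion(
    ds,
    net_config = network_config(16, level_widths = c(8L, 16L), attention_k = 8,
                                n_heads = 2, time_embed_dim = 16),
    diff_config = diffusion_config(n_steps = 40, beta_start = 1e-3, beta_end = 0.35),
    epochs = 600, batch_size = 8, lr = 5e-3, seed = 6)
  set.seed(12)
  gen <- sample_shapes(net, 10)
  errs <- vapply(gen$shapes, l2_distance, numeric(1), b = target)
  # shapes live on a unit-ish scale; reconstruction well under that scale
  expect_lt(mean(errs), 0.25)
  expect_lt(min(errs), 0.2)
})
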