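# Shared fixtures, built in code. Heavyweight trained models are cached per
# test run so several test files can reuse them.

rand_shape <- function(n, sd = 1) point_set(matrix(rnorm(n * 3, 0, sd), n, 3))

rand_dataset <- function(s, n, sd = 1) {
  shape_dataset(lapply(seq_len(s), function(i) rand_shape(n, sd)))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

apply_rigid <- function(shape, R, tr) {
  point_set(sweep(unclass(shape) %*% R, 2L, tr, `+`))
}

# Exhaustive permutations for the factorial EMD oracle (n <= 6).
all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Tiny network fixture used across network/diffusion tests.
tiny_net <- function(n = 8, widths = c(6, 8), n_heads = 2, seed = 3,
                     conditional = FALSE, classes = NULL,
                     use_embeddings = TRUE, n_steps = 10) {
  cfg <- network_config(n, level_widths = widths, attention_k = 3,
                        n_heads = n_heads, time_embed_dim = 8,
                        use_correspondence_embeddings = use_embeddings,
                        conditional = conditional, classes = classes)
  sched <- make_schedule(diffusion_config(n_steps = n_steps, beta_end = 0.1))
  set.seed(seed + 1)
  noise_predictor(cfg, rand_shape(n), sched, seed = seed)
}

# One small trained conditional model + population, trained once per run.
.fixture_env <- new.env(parent = emptyenv())

small_trained_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  pop <- generate_population(synthetic_config(
    n_points = 32L, n_per_class = c(healthy = 80L, AD = 80L),
    effect_indices = 1:4, seed = 21))
  net <- train_diffusion(
    pop$dataset,
    net_config = network_config(32, level_widths = c(16L, 32L), attention_k = 20,
                                n_heads = 4, conditional = TRUE,
                                classes = c("AD", "healthy")),
    diff_config = diffusion_config(n_steps = 60, beta_start = 1e-3, beta_end = 0.3),
    epochs = 60, batch_size = 32, lr = 3e-3, conditional = TRUE, seed = 9)
  .fixture_env$model <- list(pop = pop, net = net)
  .fixture_env$model
}
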