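test_that("rft_block shares one affine map across rows", {
  set.seed(1)
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(3)
  x <- matrix(rnorm(24), 6, 4)
  sc <- rnorm(3); sh <- rnorm(3)
  out <- rft_block(x, W, b, sc, sh)
  # per-row loop oracle: the same single-point map applied row by row
  oracle <- t(vapply(seq_len(6), function(i) {
    drop(rft_block(x[i, , drop = FALSE], W, b, sc, sh))
  }, numeric(3)))
  expect_equal(out, oracle, tolerance = 1e-12)
  # permutation equivariance
  p <- sample(6)
  expect_equal(rft_block(x[p, ], W, b, sc, sh), out[p, ], tolerance = 1e-12)
  # zero weights, zero scale: every row is activation(shift)
  out0 <- rft_block(x, matrix(0, 4, 3), rep(0, 3), rep(0, 3), sh)
  sig <- 1 / (1 + exp(-sh))
  expect_equal(out0, matrix(rep(sh * sig, each = 6), 6), tolerance = 1e-12)
  expect_error(rft_block(x, matrix(0, 5, 3), rep(0, 3)), "mismatch")
})

test_that("correspondence embeddings break permutation equivariance", {
  set.seed(2)
  f <- matrix(rnorm(20), 5, 4)
  expect_equal(add_correspondence_embedding(f, matrix(0, 5, 4)), f)
  E <- matrix(rnorm(20), 5, 4)
  # two identical rows become distinguishable
  f2 <- f; f2[2, ] <- f2[1, ]
  out <- add_correspondence_embedding(f2, E)
  expect_false(isTRUE(all.equal(out[1, ], out[2, ])))
  # swapping input rows without swapping E differs from swapping both
  p <- c(2, 1, 3, 4, 5)
  swapped_input_only <- add_correspondence_embedding(f[p, ], E)
  swapped_both <- add_correspondence_embedding(f, E)[p, ]
  expect_false(isTRUE(all.equal(swapped_input_only, swapped_both)))
  expect_error(add_correspondence_embedding(f, matrix(0, 4, 4)), "match")
})

test_that("the attention mask is the k-NN graph of the mean shape", {
  mean3 <- point_set(cbind(c(0, 1, 3), 0, 0))
  m <- build_attention_mask(mean3, k = 1)
  expect_equal(which(m[1, ]), c(1L, 2L))  # self + nearest
  expect_equal(which(m[2, ]), c(1L, 2L))
  expect_equal(which(m[3, ]), c(2L, 3L))
  expect_false(isSymmetric(unclass(m) * 1))  # kNN graphs are directed

  set.seed(3)
  mean10 <- rand_shape(10)
  mk <- build_attention_mask(mean10, k = 4)
  expect_equal(unname(rowSums(mk)), rep(5, 10))  # k + self
  # pure function of (mean, k)
  expect_identical(unclass(mk), unclass(build_attention_mask(mean10, k = 4)))
  # brute-force neighbour check for one row
  d <- as.matrix(dist(unclass(mean10))); diag(d) <- Inf
  expect_setequal(setdiff(which(mk[7, ]), 7L), order(d[7, ])[1:4])
  expect_error(build_attention_mask(mean10, k = 10), "k < N")
})

test_that("masked self-attention matches a dense softmax oracle", {
  set.seed(4)
  d <- 8; n <- 6; nh <- 2
  prm <- list(Wq = matrix(rnorm(64), d), Wk = matrix(rnorm(64), d),
              Wv = matrix(rnorm(64), d), Wo = matrix(rnorm(64), d), bo = rnorm(d))
  f <- matrix(rnorm(n * d), n, d)
  full <- matrix(TRUE, n, n)
  out <- masked_self_attention(f, full, prm, nh)
  # independent dense oracle: heads split the projected feature columns
  dh <- d / nh
  cmat <- matrix(0, n, d)
  q <- f %*% prm$Wq; k <- f %*% prm$Wk; v <- f %*% prm$Wv
  for (h in 1:nh) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    s <- q[, cols] %*% t(k[, cols]) / sqrt(dh)
    a <- exp(s) / rowSums(exp(s))
    cmat[, cols] <- a %*% v[, cols]
  }
  oracle <- f + sweep(cmat %*% prm$Wo, 2, prm$bo, `+`)
  expect_equal(out, oracle, tolerance = 1e-10)

  # self-only mask: output = residual + value projection of self
  eye <- diag(n) > 0
  out_self <- masked_self_attention(f, eye, prm, nh)
  expect_equal(out_self, f + sweep((f %*% prm$Wv) %*% prm$Wo, 2, prm$bo, `+`),
               tolerance = 1e-10)

  # masked pairs carry exactly zero weight: moving a masked point changes nothing
  msk <- build_attention_mask(rand_shape(n), 2)
  f2 <- f
  target_row <- which(!msk[1, ])[1]
  f2[target_row, ] <- f2[target_row, ] + 100
  o1 <- masked_self_attention(f, unclass(msk), prm, nh)
  o2 <- masked_self_attention(f2, unclass(msk), prm, nh)
  expect_equal(o1[1, ], o2[1, ], tolerance = 1e-10)
})

test_that("the full network is equivariant exactly when embeddings are off", {
  set.seed(5)
  n <- 8
  net_off <- tiny_net(n = n, use_embeddings = FALSE)
  net_off$mask[, ] <- TRUE
  # give the zero-initialized output layer signal so effects are visible
  net_off$params[["final.W"]][] <- rnorm(length(net_off$params[["final.W"]]))
  x <- matrix(rnorm(n * 3), n, 3)
  p <- sample(n)
  out <- predict_noise(net_off, x, 3)
  out_p <- predict_noise(net_off, x[p, ], 3)
  expect_equal(out_p, out[p, ], tolerance = 1e-10)

  net_on <- tiny_net(n = n, use_embeddings = TRUE)
  net_on$mask[, ] <- TRUE
  net_on$params[["final.W"]][] <- rnorm(length(net_on$params[["final.W"]]))
  net_on$params[["corr.E"]] <- net_on$params[["corr.E"]] * 50  # visible identity signal
  out2 <- predict_noise(net_on, x, 3)
  out2_p <- predict_noise(net_on, x[p, ], 3)
  expect_gt(max(abs(out2_p - out2[p, ])), 1e-4)

  expect_equal(dim(out), c(n, 3L))
  expect_error(predict_noise(net_on, matrix(0, n + 1, 3), 3), "N does not match")
})

test_that("ablation differs from the full model only by the embedding block", {
  full <- tiny_net(n = 8, use_embeddings = TRUE, seed = 4)
  abl <- tiny_net(n = 8, use_embeddings = FALSE, seed = 4)
  expect_setequal(setdiff(names(full$params), names(abl$params)), "corr.E")
  shared <- intersect(names(full$params), names(abl$params))
  expect_equal(vapply(full$params[shared], length, integer(1)),
               vapply(abl$params[shared], length, integer(1)))
})

test_that("analytic gradients match finite differences everywhere", {
  net <- tiny_net(n = 8, conditional = TRUE, classes = c("a", "b"), seed = 3)
  set.seed(6)
  net$params[["final.W"]][] <- rnorm(length(net$params[["final.W"]]), 0, 0.3)
  xs <- list(matrix(rnorm(24), 8), matrix(rnorm(24), 8))
  tv <- c(3, 7); labs <- c("a", "b")
  eps <- matrix(rnorm(48), 16)
  lossfun <- function(nn) mean((pdmdiffuse:::nn_forward(nn, xs, tv, labs)$out - eps)^2)
  fwd <- pdmdiffuse:::nn_forward(net, xs, tv, labs, keep = TRUE)
  g <- pdmdiffuse:::nn_backward(net, fwd$cache, 2 * (fwd$out - eps) / length(eps))
  h <- 1e-6
  for (nm in names(net$params)) {
    pm <- net$params[[nm]]
    for (i in sample(length(pm), min(3, length(pm)))) {
      n2 <- net
      n2$params[[nm]][i] <- pm[i] + h; up <- lossfun(n2)
      n2$params[[nm]][i] <- pm[i] - h; dn <- lossfun(n2)
      fd <- (up - dn) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
  # gradient flows to the correspondence embeddings: finite and nonzero
  expect_true(all(is.finite(g[["corr.E"]])))
  expect_gt(max(abs(g[["corr.E"]])), 0)
})
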