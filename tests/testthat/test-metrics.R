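test_that("ordered L2 distance sees the correspondence", {
  a <- point_set(matrix(c(0, 0, 0), 1))
  b <- point_set(matrix(c(3, 4, 0), 1))
  expect_equal(l2_distance(a, b), 5)
  expect_equal(l2_distance(a, a), 0)
  set.seed(1)
  x <- rand_shape(10); y <- rand_shape(10)
  expect_false(isTRUE(all.equal(l2_distance(x, y),
                                l2_distance(x, point_set(unclass(y)[10:1, ])))))
  expect_error(l2_distance(x, rand_shape(9)), "matching N")
})

test_that("Chamfer distance matches a brute-force nearest-neighbour oracle", {
  a <- point_set(rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- point_set(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(chamfer_distance(a, b), 1)   # (0+1)/2 + (0+1)/2
  set.seed(2)
  for (i in 1:20) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    x <- rand_shape(na); y <- rand_shape(nb)
    d2 <- outer(seq_len(na), seq_len(nb),
                Vectorize(function(i, j) sum((unclass(x)[i, ] - unclass(y)[j, ])^2)))
    oracle <- mean(apply(d2, 1, min)) + mean(apply(d2, 2, min))
    expect_equal(chamfer_distance(x, y), oracle, tolerance = 1e-12)
    expect_equal(chamfer_distance(x, point_set(unclass(y)[sample(nb), ])),
                 chamfer_distance(x, y), tolerance = 1e-12)
  }
  expect_equal(chamfer_distance(a, point_set(unclass(a)[2:1, ])), 0)
})

test_that("EMD equals the factorial assignment oracle for N <= 6", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    a <- rand_shape(n); b <- rand_shape(n)
    brute <- min(vapply(all_permutations(seq_len(n)), function(p) {
      mean(sqrt(rowSums((unclass(a) - unclass(b)[p, , drop = FALSE])^2)))
    }, numeric(1)))
    expect_equal(earth_movers_distance(a, b), brute, tolerance = 1e-9)
    # feasibility bound: EMD <= mean index-wise distance
    expect_lte(earth_movers_distance(a, b),
               mean(sqrt(rowSums((unclass(a) - unclass(b))^2))) + 1e-12)
  }
  # permuted copies are at distance zero
  x <- rand_shape(6)
  expect_equal(earth_movers_distance(x, point_set(unclass(x)[sample(6), ])), 0,
               tolerance = 1e-12)
  res <- earth_movers_distance(x, x, return_assignment = TRUE)
  expect_equal(res$assignment, 1:6)
})

test_that("metric axioms: symmetry, rigid-motion invariance, permutation behaviour", {
  set.seed(4)
  for (i in 1:10) {
    a <- rand_shape(8); b <- rand_shape(8)
    R <- random_rotation(); tr <- rnorm(3)
    ar <- apply_rigid(a, R, tr); br <- apply_rigid(b, R, tr)
    expect_equal(chamfer_distance(a, b), chamfer_distance(b, a), tolerance = 1e-12)
    expect_equal(earth_movers_distance(a, b), earth_movers_distance(b, a),
                 tolerance = 1e-9)
    expect_equal(chamfer_distance(ar, br), chamfer_distance(a, b), tolerance = 1e-9)
    expect_equal(earth_movers_distance(ar, br), earth_movers_distance(a, b),
                 tolerance = 1e-9)
    expect_equal(l2_distance(ar, br), l2_distance(a, b), tolerance = 1e-9)
  }
})

test_that("MMD is the mean nearest-generated distance", {
  set.seed(5)
  real <- rand_dataset(5, 6)
  gen <- rand_dataset(5, 6)
  for (d in c("cd", "emd", "l2")) {
    # brute-force double loop oracle
    fun <- switch(d, cd = chamfer_distance, emd = earth_movers_distance,
                  l2 = l2_distance)
    oracle <- mean(vapply(real$shapes, function(r) {
      min(vapply(gen$shapes, fun, numeric(1), a = r))
    }, numeric(1)))
    expect_equal(mmd(real, gen, d), oracle, tolerance = 1e-12)
    # generated superset of real: every real shape matches itself
    expect_equal(mmd(real, shape_dataset(c(gen$shapes, real$shapes)), d), 0,
                 tolerance = 1e-12)
  }
  single <- real[1]
  two <- gen[1:2]
  expect_equal(mmd(single, two, "l2"),
               min(l2_distance(single$shapes[[1]], two$shapes[[1]]),
                   l2_distance(single$shapes[[1]], two$shapes[[2]])))
})

test_that("knn ball radii follow the order statistics of the distance matrix", {
  # three reals with pairwise distances 1 (1-2), 2 (2-3), 3 (1-3) under L2
  r <- shape_dataset(list(point_set(matrix(c(0, 0, 0), 1)),
                          point_set(matrix(c(1, 0, 0), 1)),
                          point_set(matrix(c(3, 0, 0), 1))))
  expect_equal(unname(knn_ball_radii(r, 1, "l2")), c(1, 1, 2))
  expect_equal(unname(knn_ball_radii(r, 2, "l2")), c(3, 2, 3))  # k = n-1: max
  set.seed(6)
  ds <- rand_dataset(10, 4)
  radii <- vapply(1:9, function(k) unname(knn_ball_radii(ds, k, "cd"))[1], numeric(1))
  expect_true(all(diff(radii) >= 0))
  expect_error(knn_ball_radii(ds, 10, "cd"), "more than k")
})

test_that("coverage and density match brute-force containment tables", {
  # identical populations: full coverage, density 1 at any k < n
  set.seed(7)
  ds <- rand_dataset(6, 5)
  expect_equal(coverage(ds, ds, 2, "cd"), 1)
  # generated samples far outside every ball
  far <- shape_dataset(lapply(ds$shapes, function(s) point_set(unclass(s) + 100)))
  expect_equal(coverage(ds, far, 2, "cd"), 0)
  expect_equal(density_score(ds, far, 2, "cd"), 0)

  # small instance vs hand enumeration (4 real, 3 gen, k = 1)
  real <- rand_dataset(4, 3)
  gen <- rand_dataset(3, 3)
  radii <- knn_ball_radii(real, 1, "l2")
  D <- pairwise_shape_distances(real, gen, "l2")
  contain <- D <= radii
  expect_equal(coverage(real, gen, 1, "l2"), mean(apply(contain, 1, any)))
  expect_equal(density_score(real, gen, 1, "l2"), sum(contain) / (1 * 3))

  # one generated sample inside exactly k balls, M = 1 -> density 1
  one <- real[1]  # duplicates real_1, so it is inside ball 1 plus its neighbours
  d1 <- density_score(real, one, 1, "l2")
  inside <- sum(pairwise_shape_distances(real, one, "l2") <= radii)
  expect_equal(d1, inside / 1)
})

test_that("evaluate_generation bundles the three metrics per distance", {
  set.seed(8)
  real <- rand_dataset(10, 5)
  rep <- evaluate_generation(real, real, k = 3)
  expect_s3_class(rep, "metric_report")
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$coverage, rep(1, 3))
  expect_equal(rep$mmd, rep(0, 3), tolerance = 1e-12)
  expect_true(all(rep$density >= 1))  # self-matches inflate containment
  expect_named(tidy(rep), c("distance", "mmd", "coverage", "density",
                            "k", "n_real", "n_gen"))
})

test_that("index-shuffling inflates L2-MMD but leaves CD/EMD-MMD unchanged", {
  cfg <- synthetic_config(n_points = 32, n_per_class = c(healthy = 60L),
                          effect_indices = integer(0), seed = 9)
  pop <- generate_population(cfg)
  real <- pop$dataset[1:30]
  gen <- pop$dataset[31:60]
  set.seed(10)
  p <- sample(32)
  gen_shuf <- shape_dataset(lapply(gen$shapes, function(s) point_set(unclass(s)[p, ])))
  # permutation-invariant metrics cannot tell the difference ...
  expect_equal(mmd(real, gen_shuf, "cd"), mmd(real, gen, "cd"), tolerance = 1e-10)
  expect_equal(mmd(real, gen_shuf, "emd"), mmd(real, gen, "emd"), tolerance = 1e-9)
  # ... while the ordered metric collapses: the unordered-generator signature
  expect_gt(mmd(real, gen_shuf, "l2"), 5 * mmd(real, gen_shuf, "emd"))
  expect_lt(mmd(real, gen, "l2"), 2 * mmd(real, gen, "emd"))
})
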