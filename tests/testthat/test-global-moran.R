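test_that("Moran's I matches the brute-force double sum", {
  set.seed(3)
  for (rep in 1:20) {
    lat <- random_lattice(sample(4:15, 1))
    x <- rnorm(length(lat$region_ids))
    w <- weights_matrix(lat)
    expect_equal(moran_i(x, w), brute_moran(x, adjacency_of(lat)),
                 tolerance = 1e-12)
  }
})

test_that("row-standardised Moran's I agrees with the ape reference", {
  skip_if_not_installed("ape")
  set.seed(4)
  for (rep in 1:10) {
    lat <- random_lattice(sample(5:15, 1))
    x <- rnorm(length(lat$region_ids))
    w <- weights_matrix(lat, style = "row")
    expect_equal(moran_i(x, w),
                 ape::Moran.I(x, adjacency_of(lat))$observed,
                 tolerance = 1e-10)
  }
})

test_that("alternating values on a 4-ring give I = -1", {
  w <- weights_matrix(ring_lattice(4))
  expect_equal(moran_i(c(1, -1, 1, -1), w), -1, tolerance = 1e-12)
})

test_that("I is invariant to shifts and positive rescalings", {
  set.seed(9)
  lat <- random_lattice(10)
  w <- weights_matrix(lat)
  x <- rnorm(10)
  i0 <- moran_i(x, w)
  for (rep in 1:20) {
    a <- runif(1, 0.01, 50)
    b <- rnorm(1, sd = 100)
    expect_equal(moran_i(a * x + b, w), i0, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  w <- weights_matrix(ring_lattice(4))
  expect_error(moran_i(rep(2, 4), w), "degenerate")
  expect_error(moran_i(1:3, w), "length")
  expect_error(moran_null_moments(w, n = 3), "n >= 4")
})

test_that("null moments: closed-form expectation and enumeration/simulation variance", {
  w <- weights_matrix(ring_lattice(4))
  mom <- moran_null_moments(w)
  expect_equal(mom$expected, -1 / 3)
  expect_equal(moran_null_moments(weights_matrix(iraq_governorates()$lattice))$expected,
               -1 / 17, tolerance = 1e-12)

  # mean of I over all exhaustive relabelings is exactly -1/(n-1)
  set.seed(13)
  for (lat in list(ring_lattice(5), path_lattice(6))) {
    n <- length(lat$region_ids)
    x <- rnorm(n)
    a <- adjacency_of(lat)
    vals <- vapply(permutations_of(n), function(p) brute_moran(x[p], a),
                   numeric(1))
    expect_equal(mean(vals), -1 / (n - 1), tolerance = 1e-10)
  }

  # normality-assumption variance against a large i.i.d. Gaussian simulation
  n_sim <- 40000
  sims <- vapply(seq_len(n_sim),
                 function(k) moran_i(rnorm(4), w), numeric(1))
  expect_equal(var(sims), mom$variance, tolerance = 0.05)
})

test_that("the z test is centred and two-sided", {
  mom <- list(expected = -0.25, variance = 0.04)
  zt <- moran_z_test(-0.25, mom)
  expect_equal(zt$z, 0)
  expect_equal(zt$p_normal, 1)
  zt2 <- moran_z_test(0.15, mom)
  expect_equal(zt2$z, 2)
  expect_equal(zt2$p_normal, 2 * pnorm(-2), tolerance = 1e-12)
})

test_that("permutation p converges to the exhaustive-enumeration p", {
  set.seed(17)
  lat <- path_lattice(4)
  a <- adjacency_of(lat)
  x <- c(2.3, -1.1, 0.4, -0.9)
  i_obs <- brute_moran(x, a)
  e <- -1 / 3
  vals <- vapply(permutations_of(4), function(p) brute_moran(x[p], a),
                 numeric(1))
  p_exact <- mean(abs(vals - e) >= abs(i_obs - e) - 1e-12)
  w <- weights_matrix(lat)
  p_mc <- moran_permutation_test(x, w, n_perm = 10000, seed = 99)$p_perm
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("permutation test is reproducible under a seed", {
  fx <- iraq_governorates()
  w <- weights_matrix(fx$lattice)
  p1 <- moran_permutation_test(fx$data$ur_transformed, w, 500, seed = 8)
  p2 <- moran_permutation_test(fx$data$ur_transformed, w, 500, seed = 8)
  expect_identical(p1$p_perm, p2$p_perm)
})

test_that("moran_test bundles all result fields coherently", {
  fx <- iraq_governorates()
  w <- weights_matrix(fx$lattice)
  res <- moran_test(fx$data$ur_transformed, w, n_perm = 500, seed = 2)
  expect_s3_class(res, "global_moran")
  expect_equal(res$expected, -1 / 17)
  expect_gt(res$variance, 0)
  expect_equal(res$z, (res$I - res$expected) / sqrt(res$variance))
  expect_true(res$p_normal > 0 && res$p_normal <= 1)
  expect_true(res$p_perm > 0 && res$p_perm <= 1)
})
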