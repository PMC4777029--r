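test_that("two-region lattice reproduces the hand computation", {
  lat <- region_lattice(rbind(c("A", "B")), c("A", "B"))
  x <- c(A = 1, B = -1)
  # z = (x - 0)/sd, sd = sqrt(2); I_A = z_A * z_B = -1/2
  li <- local_moran(x, lat)
  expect_equal(unname(li), c(-0.5, -0.5), tolerance = 1e-12)
})

test_that("fixture local Moran values reproduce the published table cells", {
  fx <- iraq_governorates()
  li <- local_moran(fx$data$ur_transformed, fx$lattice)
  expect_equal(unname(round(li["4"], 2)), 1.49)
  expect_equal(unname(round(li["16"], 2)), 0.91)
})

test_that("sign semantics: I_i > 0 iff own and neighbour-mean deviations agree", {
  set.seed(31)
  for (rep in 1:25) {
    lat <- random_lattice(sample(5:12, 1))
    n <- length(lat$region_ids)
    x <- rnorm(n)
    z <- (x - mean(x)) / sd(x)
    names(z) <- lat$region_ids
    li <- local_moran(x, lat)
    for (i in lat$region_ids) {
      nbm <- mean(z[lat$neighbors[[i]]])
      expect_equal(sign(li[[i]]), sign(z[[i]] * nbm))
    }
  }
})

test_that("isolated regions yield NA, not a number", {
  lat <- suppressWarnings(
    region_lattice(rbind(c("A", "B")), c("A", "B", "C")))
  li <- local_moran(c(1, 2, 5), lat)
  expect_true(is.na(li[["C"]]))
  expect_false(anyNA(li[c("A", "B")]))
})

test_that("conditional MC p-values converge to the exhaustive conditional p", {
  lat <- path_lattice(4)
  x <- c(1.6, -0.2, -1.3, 0.7)
  z <- (x - mean(x)) / sd(x)
  i_obs <- local_moran(x, lat)
  # exact conditional p for each region: enumerate all 3! arrangements of
  # the remaining values over the other regions
  p_exact <- numeric(4)
  for (k in 1:4) {
    nb <- match(lat$neighbors[[as.character(k)]], lat$region_ids)
    rest <- z[-k]
    vals <- vapply(permutations_of(3), function(p) {
      zz <- numeric(4)
      zz[-k] <- rest[p]
      zz[k] <- z[k]
      z[k] * mean(zz[nb])
    }, numeric(1))
    p_exact[k] <- mean(vals >= i_obs[k] - 1e-12)
  }
  res <- local_moran_mc(x, lat, n_sim = 10000, seed = 5,
                        method = "conditional")
  expect_true(all(abs(res$p_mc - p_exact) < 0.02))
})

test_that("total-permutation MC p-values converge to the exhaustive total p", {
  lat <- ring_lattice(5)
  set.seed(77)
  x <- rnorm(5)
  z <- (x - mean(x)) / sd(x)
  i_obs <- local_moran(x, lat)
  p_exact <- numeric(5)
  perms <- permutations_of(5)
  for (k in 1:5) {
    nb <- match(lat$neighbors[[as.character(k)]], lat$region_ids)
    vals <- vapply(perms, function(p) z[p][k] * mean(z[p][nb]), numeric(1))
    p_exact[k] <- mean(vals >= i_obs[k] - 1e-12)
  }
  res <- local_moran_mc(x, lat, n_sim = 10000, seed = 6, method = "total")
  expect_true(all(abs(res$p_mc - p_exact) < 0.02))
})

test_that("cluster detection respects alpha and sorts by lattice order", {
  fx <- iraq_governorates()
  res <- local_moran_mc(fx$data$ur_transformed, fx$lattice,
                        n_sim = 2000, seed = 12)
  expect_identical(detect_clusters(res, alpha = 1), as.character(1:18))
  cl <- detect_clusters(res, alpha = 0.10)
  expect_identical(cl, res$id[res$p_mc <= 0.10])
  expect_error(detect_clusters(res, alpha = 0), "alpha")
  expect_error(detect_clusters(res, alpha = 1.5), "alpha")
})

test_that("local MC results are reproducible under a seed and flag clusters", {
  fx <- iraq_governorates()
  r1 <- local_moran_mc(fx$data$ci_transformed, fx$lattice,
                       n_sim = 500, seed = 3)
  r2 <- local_moran_mc(fx$data$ci_transformed, fx$lattice,
                       n_sim = 500, seed = 3)
  expect_identical(r1$p_mc, r2$p_mc)
  expect_identical(r1$cluster, r1$p_mc <= attr(r1, "alpha"))
})
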