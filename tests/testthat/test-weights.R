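test_that("lattice construction takes the symmetric closure of edges", {
  lat <- region_lattice(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(lat$neighbors$A, "B")
  expect_equal(lat$neighbors$B, c("A", "C"))
  expect_equal(lat$neighbors$C, "B")
  expect_equal(unname(neighbor_counts(lat)), c(1L, 2L, 1L))
})

test_that("degenerate and invalid edge inputs are handled", {
  expect_warning(region_lattice(NULL, c("A", "B")), "without neighbors")
  expect_error(region_lattice(rbind(c("A", "Z")), c("A", "B")),
               "unknown region id")
  expect_error(region_lattice(rbind(c("A", "A")), c("A", "B")),
               "self-pair")
  expect_error(region_lattice(rbind(c("A", "B")), c("A", "B", "A")),
               "duplicated")
})

test_that("weights totals match hand counts and brute-force sums", {
  ring <- ring_lattice(4)
  w <- weights_matrix(ring)
  expect_equal(w$s0, 8)    # 4 undirected edges
  expect_equal(w$s1, 16)
  expect_equal(w$s2, 64)   # 4 * (4 * 2^2)

  single <- region_lattice(rbind(c("A", "B")), c("A", "B", "C")) |>
    suppressWarnings()
  expect_equal(weights_matrix(single)$s0, 2)

  set.seed(11)
  for (rep in 1:10) {
    lat <- random_lattice(sample(4:20, 1))
    w <- weights_matrix(lat)
    a <- adjacency_of(lat)
    bs <- brute_s1s2(a)
    expect_equal(w$s0, sum(a))
    expect_equal(w$s1, bs$s1)
    expect_equal(w$s2, bs$s2)
    expect_equal(w$s1, 2 * w$s0)  # binary symmetric identity
    expect_true(all(diag(w$w) == 0))
    expect_identical(w$w, t(w$w))
  }
})

test_that("row-standardised weights have unit row sums", {
  lat <- random_lattice(8)
  w <- weights_matrix(lat, style = "row")
  expect_equal(unname(rowSums(w$w)), rep(1, 8))
  expect_equal(w$s0, 8)
})

test_that("GAL round trip is lossless on random lattices", {
  set.seed(42)
  for (rep in 1:100) {
    lat <- random_lattice(sample(3:15, 1))
    path <- withr::local_tempfile(fileext = ".gal")
    write_gal(lat, path)
    back <- read_gal(path)
    expect_identical(back$region_ids, lat$region_ids)
    expect_identical(back$neighbors[lat$region_ids],
                     lat$neighbors[lat$region_ids])
  }
})

test_that("malformed GAL files are rejected with the offending region named", {
  path <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("3", "A 1", "B", "B 1", "A"), path)
  expect_error(read_gal(path), "declares 3 regions")

  writeLines(c("2", "A 1", "B", "B 0"), path)
  expect_error(read_gal(path), "asymmetric.*A.*B|asymmetric.*B.*A")

  writeLines(c("2", "A 2", "B", "B 1", "A"), path)
  expect_error(read_gal(path), "declares 2 neighbors but lists 1")
})

test_that("the Iraq fixture is calibrated against the published local Moran table", {
  fx <- iraq_governorates()
  expect_length(fx$lattice$region_ids, 18)
  expect_identical(fx$lattice$region_ids, as.character(1:18))
  expect_equal(mean(fx$data$ur_transformed), 11.71, tolerance = 0.0005)

  pub <- iraq_published()
  iu <- local_moran(fx$data$ur_transformed, fx$lattice)
  ic <- local_moran(fx$data$ci_transformed, fx$lattice)
  expect_true(all(abs(iu - pub$i_ur) <= 0.02))
  expect_true(all(abs(ic - pub$i_ci) <= 0.02))
  expect_equal(unname(iu["4"]), 1.49, tolerance = 0.005)
})
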