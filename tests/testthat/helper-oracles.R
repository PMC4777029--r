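# Independent oracles used across the suite.  Everything here is written
# as plainly as possible (double loops, explicit enumeration) so that it
# cannot share a bug with the vectorised package code it checks.

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Moran's I by explicit double sum over a plain 0/1 matrix
brute_moran <- function(x, a) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + a[i, j] * z[i] * z[j]
    }
  }
  (n / sum(a)) * num / sum(z^2)
}

# cross-Moran by explicit double sum
brute_ixy <- function(x, y, a) {
  n <- length(x)
  zx <- x - mean(x)
  zy <- y - mean(y)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + a[i, j] * zx[i] * zy[j]
    }
  }
  (n / sum(a)) * num / sqrt(sum(zx^2) * sum(zy^2))
}

# s1/s2 by explicit double sums
brute_s1s2 <- function(a) {
  n <- nrow(a)
  s1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s1 <- s1 + (a[i, j] + a[j, i])^2
  }
  s2 <- 0
  for (i in seq_len(n)) {
    s2 <- s2 + (sum(a[i, ]) + sum(a[, i]))^2
  }
  list(s1 = s1 / 2, s2 = s2)
}

# a random connected-ish symmetric lattice on n regions
random_lattice <- function(n, p = 0.4) {
  ids <- as.character(seq_len(n))
  edges <- list()
  # spanning path guarantees no isolates
  for (k in seq_len(n - 1)) edges[[k]] <- c(ids[k], ids[k + 1])
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (j > i + 1 && stats::runif(1) < p) {
        edges[[length(edges) + 1]] <- c(ids[i], ids[j])
      }
    }
  }
  region_lattice(do.call(rbind, edges), ids)
}

adjacency_of <- function(lattice) {
  ids <- lattice$region_ids
  n <- length(ids)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a[i, match(lattice$neighbors[[ids[i]]], ids)] <- 1
  }
  a
}

# ring lattice on n regions
ring_lattice <- function(n) {
  ids <- as.character(seq_len(n))
  region_lattice(cbind(ids, ids[c(2:n, 1)]), ids)
}

# path lattice on n regions
path_lattice <- function(n) {
  ids <- as.character(seq_len(n))
  region_lattice(cbind(ids[-n], ids[-1]), ids)
}

# published per-governorate local Moran values and p-values (UR, CI)
iraq_published <- function() {
  list(
    i_ur = c(0.09, -0.65, 0.95, 1.49, 0.93, -1.01, 0.03, -0.01, -0.01,
             -0.08, -0.15, 0.32, 0.00, 0.17, 0.45, 0.91, 0.73, 0.34),
    i_ci = c(0.10, -0.07, -1.86, -0.84, -0.11, 0.01, 0.04, 0.09, -0.01,
             -0.16, -0.05, 0.11, 0.06, 0.28, 0.23, 0.02, -0.31, -0.31),
    p_ur = c(.344, .925, .011, .004, .007, .975, .342, .493, .480, .613,
             .717, .058, .462, .181, .076, .006, .046, .135),
    p_ci = c(.333, .615, .999, .940, .666, .431, .312, .260, .500, .703,
             .587, .201, .301, .112, .167, .396, .788, .785))
}
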