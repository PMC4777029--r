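#' Build a region lattice from an edge list
#'
#' A region lattice is the contiguity graph of a set of areal units: an
#' ordered vector of region identifiers together with a symmetric
#' neighbour list.  It is the structure every spatial statistic in this
#' package consumes, either directly (local Moran) or through the binary
#' weights matrix derived by [weights_matrix()].
#'
#' @param edges a two-column matrix or data frame of unordered region-id
#'   pairs, one row per shared boundary.  Ids are coerced to character.
#' @param region_ids ordered character vector of all region identifiers.
#'   The order is preserved everywhere downstream (vectors and matrices
#'   align to it).
#' @param labels optional named character vector of display names,
#'   names being region ids.  Labels are carried along but never used in
#'   computation.
#'
#' @return An object of class `region_lattice`: a list with elements
#'   `region_ids`, `neighbors` (named list of character vectors, the
#'   symmetric closure of `edges`) and `labels`.
#'
#' @details Self-pairs are rejected.  Regions without any neighbour are
#'   permitted but trigger a warning, since every statistic that averages
#'   over neighbours is undefined there.
#'
#' @examples
#' lat <- region_lattice(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
#' lat$neighbors$B
#' @export
region_lattice <- function(edges, region_ids, labels = NULL) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) {
    stop("duplicated region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  nbr <- stats::setNames(vector("list", length(region_ids)), region_ids)
  nbr[] <- list(character(0))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("`edges` must have two columns")
    mode(edges) <- "character"
    unknown <- setdiff(unique(as.vector(edges)), region_ids)
    if (length(unknown) > 0) {
      stop("edge refers to unknown region id(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(edges[, 1] == edges[, 2])) {
      bad <- edges[edges[, 1] == edges[, 2], 1]
      stop("self-pair not allowed for region(s): ",
           paste(unique(bad), collapse = ", "))
    }
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nbr[[i]] <- union(nbr[[i]], j)
      nbr[[j]] <- union(nbr[[j]], i)
    }
    nbr <- lapply(nbr, function(v) v[order(match(v, region_ids))])
  }
  lat <- structure(
    list(region_ids = region_ids, neighbors = nbr, labels = labels),
    class = "region_lattice")
  validate_lattice(lat)
  lat
}

#' Validate a region lattice
#'
#' Checks the structural invariants: the neighbour relation is symmetric,
#' has no self-loops, and refers only to known ids.  Isolated regions
#' (no neighbours) produce a warning, not an error.
#'
#' @param lattice a `region_lattice`.
#' @return `lattice`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "region_lattice"))
  ids <- lattice$region_ids
  nbr <- lattice$neighbors
  if (!identical(sort(names(nbr)), sort(ids))) {
    stop("neighbor list names do not match region ids")
  }
  for (i in ids) {
    if (i %in% nbr[[i]]) stop("self-loop at region ", i)
    for (j in nbr[[i]]) {
      if (!j %in% ids) stop("region ", i, " lists unknown neighbor ", j)
      if (!i %in% nbr[[j]]) {
        stop("asymmetric neighbor listing: ", i, " lists ", j,
             " but ", j, " does not list ", i)
      }
    }
  }
  iso <- ids[vapply(nbr[ids], length, integer(1)) == 0]
  if (length(iso) > 0) {
    warning("region(s) without neighbors: ", paste(iso, collapse = ", "))
  }
  invisible(lattice)
}

#' Neighbour counts of a lattice
#'
#' @param lattice a `region_lattice`.
#' @return named integer vector of neighbour counts (graph degrees), in
#'   lattice order.
#' @export
neighbor_counts <- function(lattice) {
  stopifnot(inherits(lattice, "region_lattice"))
  vapply(lattice$neighbors[lattice$region_ids], length, integer(1))
}

#' @export
print.region_lattice <- function(x, ...) {
  d <- neighbor_counts(x)
  cat("Region lattice:", length(x$region_ids), "regions,",
      sum(d) / 2, "undirected edges\n")
  cat("Neighbour counts: min", min(d), "/ median", stats::median(d),
      "/ max", max(d), "\n")
  invisible(x)
}

#' Binary contiguity weights matrix
#'
#' Converts a lattice into the N x N binary connection matrix
#' \eqn{w_{ij} \in \{0, 1\}} (1 when regions i and j share a boundary)
#' together with the weight totals needed by the normal-theory variance
#' of Moran's I:
#' \deqn{S_0 = \sum_i\sum_j w_{ij}, \quad
#'       S_1 = \tfrac12 \sum_i\sum_j (w_{ij} + w_{ji})^2, \quad
#'       S_2 = \sum_i \big(\textstyle\sum_j w_{ij} + \sum_j w_{ji}\big)^2.}
#'
#' @param lattice a `region_lattice`.
#' @param style `"binary"` (the default, used throughout the packaged
#'   reproduction) or `"row"` for row-standardised weights
#'   \eqn{w_{ij}/\sum_j w_{ij}}.
#' @return An object of class `weights_matrix`: list with `order` (the
#'   region id sequence), `w` (the matrix, dimnames = ids), `style`, and
#'   the scalars `s0`, `s1`, `s2`.
#' @examples
#' ring <- region_lattice(cbind(c("1","2","3","4"), c("2","3","4","1")),
#'                        as.character(1:4))
#' weights_matrix(ring)$s0   # 8: twice the number of undirected edges
#' @export
weights_matrix <- function(lattice, style = c("binary", "row")) {
  style <- match.arg(style)
  validate_lattice_quiet(lattice)
  ids <- lattice$region_ids
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    w[i, match(lattice$neighbors[[ids[i]]], ids)] <- 1
  }
  if (style == "row") {
    d <- rowSums(w)
    w[d > 0, ] <- w[d > 0, , drop = FALSE] / d[d > 0]
  }
  rs <- rowSums(w); cs <- colSums(w)
  structure(
    list(order = ids, w = w, style = style,
         s0 = sum(w),
         s1 = 0.5 * sum((w + t(w))^2),
         s2 = sum((rs + cs)^2)),
    class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  cat("Spatial weights (", x$style, "): ", length(x$order), " regions, S0 = ",
      x$s0, ", S1 = ", x$s1, ", S2 = ", x$s2, "\n", sep = "")
  invisible(x)
}

# validation without the isolated-region warning (callers that tolerate
# isolates must already have warned at construction time)
validate_lattice_quiet <- function(lattice) {
  withCallingHandlers(
    validate_lattice(lattice),
    warning = function(w) invokeRestart("muffleWarning"))
}

# Align a regional variable to a weights matrix / lattice order.
# Accepts a bare numeric vector (length-checked) or a named vector
# (reordered by name).
align_variable <- function(x, order, what = "x") {
  if (!is.numeric(x)) stop("`", what, "` must be numeric")
  if (length(x) != length(order)) {
    stop("`", what, "` has length ", length(x),
         " but the lattice has ", length(order), " regions")
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), order)) {
      stop("names of `", what, "` do not match the region ids: offenders ",
           paste(c(setdiff(names(x), order), setdiff(order, names(x))),
                 collapse = ", "))
    }
    x <- x[order]
  }
  if (any(!is.finite(x))) stop("`", what, "` contains non-finite values")
  unname(x)
}
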