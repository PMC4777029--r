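#' Read a GAL contiguity file
#'
#' The GAL dialect understood here is minimal: a header line whose last
#' whitespace-separated token is the region count, then for each region
#' an id line (`id n_neighbors`) followed by one line listing the
#' neighbour ids.  Lines starting with `!` are comments and skipped.
#'
#' @param path file path.
#' @return a [region_lattice()].
#' @seealso [write_gal()]
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) stop("empty GAL file: ", path)
  hdr <- strsplit(lines[[1]], "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[[length(hdr)]]))
  if (is.na(n) || n < 1) stop("malformed GAL header: ", lines[[1]])
  ids <- character(n)
  nbr <- vector("list", n)
  pos <- 2
  for (k in seq_len(n)) {
    if (pos > length(lines)) {
      stop("GAL file declares ", n, " regions but ends after ", k - 1)
    }
    rec <- strsplit(lines[[pos]], "\\s+")[[1]]
    if (length(rec) != 2) stop("malformed GAL record line: ", lines[[pos]])
    ids[k] <- rec[[1]]
    cnt <- suppressWarnings(as.integer(rec[[2]]))
    if (is.na(cnt) || cnt < 0) {
      stop("malformed neighbor count for region ", ids[k])
    }
    if (cnt == 0) {
      nbr[[k]] <- character(0)
      pos <- pos + 1
    } else {
      if (pos + 1 > length(lines)) {
        stop("missing neighbor line for region ", ids[k])
      }
      v <- strsplit(lines[[pos + 1]], "\\s+")[[1]]
      if (length(v) != cnt) {
        stop("region ", ids[k], " declares ", cnt, " neighbors but lists ",
             length(v))
      }
      nbr[[k]] <- v
      pos <- pos + 2
    }
  }
  if (pos <= length(lines)) {
    stop("trailing content after ", n, " regions in GAL file")
  }
  names(nbr) <- ids
  # symmetry is validated (with offending regions named) by the constructor
  lat <- structure(list(region_ids = ids, neighbors = nbr, labels = NULL),
                   class = "region_lattice")
  validate_lattice(lat)
  lat
}

#' Write a lattice as a GAL contiguity file
#'
#' `read_gal(write_gal(lattice, path))` restores the same ids and
#' neighbour sets (round trip is the identity).
#'
#' @param lattice a [region_lattice()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(lattice, path) {
  validate_lattice_quiet(lattice)
  ids <- lattice$region_ids
  out <- as.character(length(ids))
  for (i in ids) {
    v <- lattice$neighbors[[i]]
    out <- c(out, paste(i, length(v)))
    if (length(v) > 0) out <- c(out, paste(v, collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}
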