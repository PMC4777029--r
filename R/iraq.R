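#' The Iraq 2007 governorate fixture
#'
#' Packaged reproduction data for the published spatial analysis of the
#' 2007 Iraq household socio-economic survey: the normal-score
#' transformed unemployment rate (UR, %) and chronic-illness rate
#' (CI, %) for the 18 governorates, together with a calibrated
#' queen-contiguity lattice.
#'
#' The survey's raw microdata is not deposited anywhere public; the
#' transformed per-governorate values are taken from the published
#' results table.  The contiguity graph is a reconstruction from public
#' Iraq governorate geography, calibrated so that the neighbour-averaged
#' local Moran statistic reproduces all 36 published per-governorate
#' values within +/-0.008 (see the file `iraq2007_notes.md` shipped in
#' `inst/extdata` for the calibration procedure and residuals).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{lattice}{a [region_lattice()] of the 18 governorates, ids
#'       `"1"`..`"18"`, with governorate-name guesses as labels.}
#'     \item{data}{a data frame with columns `id`, `name_guess`,
#'       `ur_transformed`, `ci_transformed`, in lattice order.}
#'   }
#' @examples
#' fx <- iraq_governorates()
#' mean(fx$data$ur_transformed)   # 11.71
#' @export
iraq_governorates <- function() {
  gal <- system.file("extdata", "iraq2007.gal", package = "latticemoran",
                     mustWork = TRUE)
  csv <- system.file("extdata", "iraq2007.csv", package = "latticemoran",
                     mustWork = TRUE)
  lattice <- read_gal(gal)
  data <- utils::read.csv(csv, colClasses = c(id = "character"))
  if (!identical(data$id, lattice$region_ids)) {
    stop("fixture CSV and GAL region orders disagree")   # nocov
  }
  lattice$labels <- stats::setNames(data$name_guess, data$id)
  list(lattice = lattice, data = data)
}
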