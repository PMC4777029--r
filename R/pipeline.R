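#' Configure a five-step lattice autocorrelation analysis
#'
#' Bundles the inputs and tuning parameters of [run_analysis()]: the
#' data source, the contiguity structure, which variables to analyse,
#' the replication counts of the three Monte-Carlo stages, the cluster
#' significance level, and the master seed from which all randomness is
#' derived.
#'
#' @param data `"iraq2007"` for the packaged fixture, or the path to a
#'   CSV file with an `id` column plus one numeric column per variable.
#' @param weights path to a GAL file; ignored (and not required) for the
#'   fixture.
#' @param variables character vector of variable (column) names to
#'   analyse; default: all numeric columns.
#' @param transform apply the normal-score transformation before
#'   analysis?  Default `NULL` means automatic: `FALSE` for the fixture
#'   (whose columns are already normal scores) and `TRUE` otherwise.
#' @param n_perm global Moran permutation count, default 1000.
#' @param n_local_sim conditional draws per region for local Moran
#'   p-values, default 10000.
#' @param n_bivar_sim simulated datasets for the bivariate test,
#'   default 9999.
#' @param alpha significance level for cluster flagging, default 0.10.
#' @param seed master integer seed, default 42.
#' @param out_dir optional directory: when set, [run_analysis()] writes
#'   the JSON report and per-variable CSV tables there.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(data = "iraq2007", weights = NULL,
                            variables = NULL, transform = NULL,
                            n_perm = 1000, n_local_sim = 10000,
                            n_bivar_sim = 9999, alpha = 0.10,
                            seed = 42, out_dir = NULL) {
  if (n_perm < 99 || n_local_sim < 99 || n_bivar_sim < 99) {
    stop("all replication counts must be at least 99")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  structure(
    list(data = data, weights = weights, variables = variables,
         transform = transform, n_perm = n_perm,
         n_local_sim = n_local_sim, n_bivar_sim = n_bivar_sim,
         alpha = alpha, seed = seed, out_dir = out_dir),
    class = "analysis_config")
}

load_analysis_inputs <- function(config) {
  if (identical(config$data, "iraq2007")) {
    fx <- iraq_governorates()
    df <- fx$data
    vars <- config$variables
    if (is.null(vars)) vars <- c("ur_transformed", "ci_transformed")
    transform <- isTRUE(config$transform)   # fixture default: no re-transform
    list(lattice = fx$lattice, data = df, variables = vars,
         transform = transform)
  } else {
    df <- utils::read.csv(config$data, colClasses = c(id = "character"))
    if (is.null(config$weights)) {
      stop("a GAL weights file is required for CSV input")
    }
    lattice <- read_gal(config$weights)
    if (!setequal(df$id, lattice$region_ids)) {
      off <- c(setdiff(df$id, lattice$region_ids),
               setdiff(lattice$region_ids, df$id))
      stop("region ids of data and weights disagree: ",
           paste(off, collapse = ", "))
    }
    df <- df[match(lattice$region_ids, df$id), , drop = FALSE]
    vars <- config$variables
    if (is.null(vars)) {
      vars <- names(df)[vapply(df, is.numeric, logical(1))]
    }
    transform <- if (is.null(config$transform)) TRUE else config$transform
    list(lattice = lattice, data = df, variables = vars,
         transform = transform)
  }
}

#' Run the five-step spatial autocorrelation analysis
#'
#' Executes, for every configured variable: (1) normal-score
#' transformation (when configured) with normality diagnostics, (2)
#' five-number summary and quartile choropleth classification, (3)
#' global Moran's I with normal-theory z test and permutation test, (4)
#' local Moran statistics with conditional Monte-Carlo p-values and
#' hot-spot flagging; and for every variable pair: (5) Pearson and
#' Wartenberg bivariate spatial correlation with Monte-Carlo inference.
#' All randomness is derived from `config$seed`; the same configuration
#' always yields the identical report.
#'
#' @param config an [analysis_config()].
#' @return An object of class `analysis_report`: list with one entry
#'   per variable under `$variables` (fields `descriptives`,
#'   `normality`, `classes`, `global`, `local`) and one per pair under
#'   `$pairs`, plus `$config_echo` and `$package_version`.  When
#'   `config$out_dir` is set the report is also serialised as
#'   `report.json` plus one `local_<variable>.csv` table per variable
#'   (mirroring the published per-governorate table layout) and a
#'   `classes_<variable>.csv` choropleth classification per variable.
#' @examples
#' \donttest{
#' rep <- run_analysis(analysis_config(n_perm = 199, n_local_sim = 199,
#'                                     n_bivar_sim = 199, seed = 42))
#' rep$variables$ur_transformed$global$I
#' }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inp <- load_analysis_inputs(config)
  set.seed(config$seed)
  vars <- list()
  for (v in inp$variables) {
    x <- inp$data[[v]]
    if (is.null(x)) stop("variable not found in data: ", v)
    names(x) <- inp$data$id
    res <- tryCatch({
      if (inp$transform) x <- normal_scores(x)
      w <- weights_matrix(inp$lattice)
      fn <- five_number(x)
      list(
        transformed = isTRUE(inp$transform),
        descriptives = list(
          mean = mean(x), sd = stats::sd(x),
          five_number = as.list(fn$summary),
          quarter_spreads = unname(fn$quarter_spreads)),
        normality = as.list(skew_kurtosis(x)),
        classes = quartile_classify(x),
        values = x,
        global = moran_test(x, w, n_perm = config$n_perm),
        local = local_moran_mc(x, inp$lattice,
                               n_sim = config$n_local_sim,
                               alpha = config$alpha))
    }, error = function(e) list(error = conditionMessage(e)))
    vars[[v]] <- res
  }
  pairs <- list()
  ok <- names(vars)[!vapply(vars, function(v) !is.null(v$error), logical(1))]
  if (length(ok) >= 2) {
    w <- weights_matrix(inp$lattice)
    for (a in seq_along(ok)[-length(ok)]) {
      for (b in seq((a + 1), length(ok))) {
        key <- paste(ok[a], ok[b], sep = ":")
        pairs[[key]] <- bivariate_test(
          vars[[ok[a]]]$values, vars[[ok[b]]]$values, w,
          n_sim = config$n_bivar_sim)
      }
    }
  }
  report <- structure(
    list(variables = vars, pairs = pairs,
         config_echo = unclass(config),
         package_version = as.character(utils::packageVersion("latticemoran"))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Serialise an analysis report
#'
#' Writes `report.json` (the full report; deterministic for a fixed
#' configuration and seed) and, per variable, a `local_<variable>.csv`
#' table with columns `id`, `value`, `i_local`, `p_mc`, `cluster` and a
#' `classes_<variable>.csv` quartile classification.
#'
#' @param report an `analysis_report`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(x) {
    if (is.data.frame(x)) return(lapply(as.list(x), strip))
    if (is.list(x)) return(lapply(unclass(x), strip))
    unname(x)
  }
  ser <- strip(report)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  for (v in names(report$variables)) {
    res <- report$variables[[v]]
    if (!is.null(res$error)) next
    loc <- as.data.frame(res$local)
    utils::write.csv(loc[, c("id", "value", "i_local", "p_mc", "cluster")],
                     file.path(dir, paste0("local_", v, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(id = names(res$classes), value = unname(res$values),
                 class = unname(res$classes)),
      file.path(dir, paste0("classes_", v, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Lattice spatial autocorrelation report (package version",
      x$package_version, ")\n")
  for (v in names(x$variables)) {
    res <- x$variables[[v]]
    if (!is.null(res$error)) {
      cat("\n--", v, ": ERROR:", res$error, "\n")
      next
    }
    cat("\n--", v, "--\n")
    d <- res$descriptives
    cat("  mean", round(d$mean, 2), " sd", round(d$sd, 2),
        " five-number:", paste(round(unlist(d$five_number), 2),
                               collapse = " / "), "\n")
    cat("  skewness", round(res$normality$skewness, 2),
        " excess kurtosis", round(res$normality$excess_kurtosis, 2), "\n")
    g <- res$global
    cat("  global I", round(g$I, 4), " z", round(g$z, 2),
        " p_normal", round(g$p_normal, 3),
        " p_perm", round(g$p_perm, 3), "\n")
    cl <- detect_clusters(res$local)
    cat("  clusters (alpha ", attr(res$local, "alpha"), "): ",
        if (length(cl)) paste(cl, collapse = ", ") else "none", "\n",
        sep = "")
  }
  for (p in names(x$pairs)) {
    b <- x$pairs[[p]]
    cat("\n--", p, "--\n")
    cat("  Pearson r", round(b$pearson_r, 4),
        " p", round(b$pearson_p, 3), "\n")
    cat("  I_xy", round(b$i_xy, 4), " z", round(b$z_xy, 2),
        " p", round(b$p_xy, 3), "\n")
  }
  invisible(x)
}
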