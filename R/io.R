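#' @include AllClasses.R
NULL

#' Write trajectories to a wide CSV file
#'
#' Format: header \code{series_id,time,<var1>,<var2>,...}, one row per
#' (series, time point). A JSON provenance sidecar (\code{<path>.json}) with
#' the seed and config snapshot is written for datasets unless disabled.
#'
#' @param x a [TimeSeriesDataset-class] or a single [Trajectory-class].
#' @param path output CSV path.
#' @param sidecar write the JSON provenance sidecar? (datasets only)
#' @return \code{path}, invisibly.
#' @export
writeTimeSeriesCSV <- function(x, path, sidecar = TRUE) {
  if (is(x, "Trajectory")) {
    trajs <- list(x)
    meta <- list(provenance = x@provenance)
  } else if (is(x, "TimeSeriesDataset")) {
    trajs <- x@trajectories
    meta <- list(system = x@systemName, seed = x@seed, config = x@config)
  } else stop("x must be a Trajectory or TimeSeriesDataset")
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(series_id = tr@seriesId, time = tr@time,
               tr@values, check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  invisible(path)
}

#' Read a wide time-series CSV
#'
#' Expects the header \code{series_id,time,<vars...>}; rows are sorted by
#' (series_id, time). Malformed input (missing columns, non-numeric cells,
#' duplicated time points within a series) raises a parse error naming the
#' offending column or rows.
#'
#' @param path CSV path.
#' @param as return a \code{"dataset"} ([TimeSeriesDataset-class]) or, for
#'   single-series files, a \code{"trajectory"}.
#' @return see \code{as}.
#' @export
readTimeSeriesCSV <- function(path, as = c("dataset", "trajectory")) {
  as <- match.arg(as)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  for (col in c("series_id", "time"))
    if (!col %in% names(df))
      stop("parse error in '", path, "': missing required column '", col, "'")
  vars <- setdiff(names(df), c("series_id", "time"))
  if (length(vars) == 0L)
    stop("parse error in '", path, "': no variable columns")
  for (col in c("time", vars)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("parse error in '", path, "': non-numeric values in column '",
           col, "' at rows ", paste(utils::head(bad, 5L), collapse = ", "))
    if (anyNA(v))
      stop("parse error in '", path, "': missing values in column '", col, "'")
    df[[col]] <- v
  }
  df <- df[order(df$series_id, df$time), , drop = FALSE]
  ids <- unique(df$series_id)
  trajs <- lapply(ids, function(id) {
    sub <- df[df$series_id == id, , drop = FALSE]
    if (any(diff(sub$time) <= 0))
      stop("parse error in '", path, "': non-monotone or duplicated time in ",
           "series '", id, "'")
    vals <- as.matrix(sub[, vars, drop = FALSE])
    rownames(vals) <- NULL
    new("Trajectory", seriesId = as.character(id), time = sub$time,
        values = vals, provenance = list(source = path))
  })
  grid <- trajs[[1L]]@time
  for (tr in trajs)
    if (!isTRUE(all.equal(tr@time, grid)))
      stop("parse error in '", path, "': series do not share one time grid")
  if (as == "trajectory") {
    if (length(trajs) != 1L)
      stop("file contains ", length(trajs),
           " series; cannot return a single trajectory")
    return(trajs[[1L]])
  }
  new("TimeSeriesDataset", systemName = "observed", time = grid,
      variables = vars, trajectories = trajs,
      config = list(source = path), seed = NA_real_)
}
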