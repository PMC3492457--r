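#' @include AllClasses.R
NULL

## All delimited files are comma-separated with "." as decimal point and no
## locale handling, so that numeric round-trips are bit-faithful at >= 15
## significant digits. Lines starting with "#" are provenance headers and
## are skipped on read.

.numFmt <- function(x) sprintf("%.15g", x)

#' Read a plate map from CSV
#'
#' Expects header columns `well`, `concentration_uM`, `fluence_J_cm2`,
#' `replicate`; optional `gadolinium_uM` and `label` plus any extra metadata
#' columns are preserved. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return a validated [PlateMap]. An empty file (header only) yields an
#'   empty map with a warning.
#' @export
readPlateMap <- function(path) {
  if (!file.exists(path)) stop("plate map file not found: ", path)
  m <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.plateRequired, names(m))
  if (length(miss))
    stop(sprintf("plate map format error: missing column '%s'", miss[1L]))
  if (nrow(m) == 0L)
    warning("plate map '", basename(path), "' has a header but no wells")
  PlateMap(m)
}

#' Write a plate map to CSV
#'
#' @param plate a [PlateMap].
#' @param path output file.
#' @param provenance optional named character vector written as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
writePlateMap <- function(plate, path, provenance = NULL) {
  stopifnot(is(plate, "PlateMap"))
  .writeCsvProv(as.data.frame(plate), path, provenance)
}

.writeCsvProv <- function(df, path, provenance = NULL) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .numFmt)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format CI traces
#'
#' Long format with columns `well`, `time_h`, `ci` and optionally `clock`.
#' Every well must appear in `plate`; wells of `plate` with no data are
#' reported with a warning. Times are sorted ascending per well; a duplicated
#' time stamp within a well is an error.
#'
#' @param path CSV file path.
#' @param plate a [PlateMap] the wells are checked against.
#' @return a [TraceSet].
#' @export
readTraces <- function(path, plate) {
  stopifnot(is(plate, "PlateMap"))
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("well", "time_h", "ci")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("trace format error: missing column '%s'", miss[1L]))
  unknown <- setdiff(unique(d$well), wells(plate))
  if (length(unknown))
    stop("traces contain wells absent from the plate map: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(wells(plate), unique(d$well))
  if (length(absent))
    warning("wells in plate map but absent from data: ",
            paste(absent, collapse = ", "))
  traces <- lapply(split(d, d$well), function(dw) {
    o <- order(dw$time_h)
    dw <- dw[o, ]
    if (anyDuplicated(dw$time_h))
      stop(sprintf("well %s has duplicated time stamp(s) at %s h",
                   dw$well[1L],
                   paste(unique(dw$time_h[duplicated(dw$time_h)]), collapse = ", ")))
    clock <- if ("clock" %in% names(dw)) dw$clock[1L] else "exposure"
    CITrace(dw$well[1L], dw$time_h, dw$ci, clock = clock)
  })
  ## keep plate order for the wells that have data
  TraceSet(traces[intersect(wells(plate), names(traces))])
}

#' Write traces to long-format CSV
#'
#' The clock is recorded per well in a `clock` column; a read/write round-trip
#' reproduces times and values to at least 15 significant digits.
#'
#' @param traces a non-empty [TraceSet].
#' @param path output file.
#' @param provenance optional named character vector of `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path, provenance = NULL) {
  stopifnot(is(traces, "TraceSet"))
  if (length(traces) == 0L) stop("cannot write an empty TraceSet")
  long <- do.call(rbind, lapply(as.list(traces), function(tr)
    data.frame(well = tr@well, time_h = tr@times, ci = tr@values,
               clock = tr@clock)))
  .writeCsvProv(long, path, provenance)
}
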