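## Single-molecule intensity traces: delimited text with columns
## trace id, frame index, intensity.

#' Intensity trace
#'
#' @param id trace identifier.
#' @param intensity numeric vector of camera counts at uniform frame spacing.
#' @param frame optional frame indices (default `seq_along(intensity) - 1`).
#' @return a `trace` object.
#' @export
trace <- function(id, intensity, frame = seq_along(intensity) - 1) {
  stopifnot(length(intensity) == length(frame))
  if (!all(is.finite(intensity))) stop("trace ", id, ": non-finite intensity")
  if (is.unsorted(frame, strictly = TRUE))
    stop("trace ", id, ": frame index not strictly increasing")
  d <- diff(frame)
  if (length(d) > 0 && length(unique(d)) > 1)
    stop("trace ", id, ": non-uniform frame spacing")
  structure(list(id = id, frame = as.integer(frame),
                 intensity = as.numeric(intensity)),
            class = "trace")
}

#' @export
length.trace <- function(x) length(x$intensity)

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> id=%s: %d frames, range [%.1f, %.1f]\n",
              x$id, length(x$intensity), min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Read traces from delimited text
#'
#' Expects columns `trace`, `frame`, `intensity` (tab- or comma-separated,
#' header required). Rows are grouped by trace id and ordered by frame
#' index; non-monotone frame indices or non-numeric intensities are errors.
#'
#' @param path input file.
#' @return list of `trace` objects, ordered by first appearance.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "integer", "character"),
                          stringsAsFactors = FALSE)
  names(df) <- c("trace", "frame", "intensity")
  intensity <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(intensity)) {
    bad <- which(is.na(intensity))[1]
    stop("non-numeric intensity '", df$intensity[bad], "' at data row ", bad)
  }
  df$intensity <- intensity
  ids <- unique(df$trace)
  lapply(ids, function(id) {
    rows <- df[df$trace == id, ]
    if (is.unsorted(rows$frame, strictly = TRUE))
      stop("trace ", id, ": frame index not strictly increasing in file")
    trace(id, rows$intensity, rows$frame)
  })
}

#' Write traces as tab-delimited text
#'
#' @param traces list of `trace` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace = tr$id, frame = tr$frame,
               intensity = sprintf("%.17g", tr$intensity),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
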