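#' Construct a position stream
#'
#' A position stream is the package's container for raw RTLS tag emissions:
#' one row per emission with a tag identifier, a UTC timestamp and planar
#' coordinates in meters. An optional height coordinate `z` is carried along
#' but ignored by all planar analyses (grids, distances); the unit is
#' single-storey. Rows are sorted by `(tag_id, time)` and duplicate
#' `(tag_id, time)` pairs are resolved deterministically by keeping the first
#' occurrence.
#'
#' @param tag_id character vector of tag identifiers.
#' @param time `POSIXct` timestamps (coerced to UTC).
#' @param x,y numeric coordinates in meters; must be finite.
#' @param z optional numeric height in meters.
#' @return A `position_stream`, a `data.frame` with columns `tag_id`, `time`,
#'   `x`, `y` (and `z` if supplied), sorted and de-duplicated. The number of
#'   duplicates dropped is recorded in attribute `n_duplicates`.
#' @export
position_stream <- function(tag_id, time, x, y, z = NULL) {
  stopifnot(length(tag_id) == length(time), length(x) == length(time),
            length(y) == length(time))
  if (!inherits(time, "POSIXct"))
    stop("'time' must be POSIXct")
  attr(time, "tzone") <- "UTC"
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  df <- data.frame(tag_id = as.character(tag_id), time = time,
                   x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  if (!is.null(z)) df$z <- as.numeric(z)
  ord <- order(df$tag_id, as.numeric(df$time))
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[c("tag_id", "time")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_duplicates = n_dup,
            class = c("position_stream", "data.frame"))
}

as_position_stream <- function(df) {
  position_stream(df$tag_id, df$time, df$x, df$y, z = df$z)
}

#' @export
print.position_stream <- function(x, ...) {
  tags <- unique(x$tag_id)
  cat(sprintf("<position_stream> %d emissions, %d tag(s)\n",
              nrow(x), length(tags)))
  if (nrow(x)) {
    cat(sprintf("  span: %s -- %s (UTC)\n",
                format(min(x$time)), format(max(x$time))))
  }
  nd <- attr(x, "n_duplicates")
  if (!is.null(nd) && nd > 0)
    cat(sprintf("  %d duplicate (tag, time) row(s) dropped\n", nd))
  invisible(x)
}

#' Read a position stream from delimited text
#'
#' Expects a header with columns `tag_id,timestamp,x,y[,z]` (remappable via
#' `col_map`), timestamps in ISO-8601. Rows with unparseable timestamps or
#' non-finite coordinates are dropped and counted (attribute `n_dropped`);
#' the count of duplicate `(tag, time)` rows kept-first is in
#' `n_duplicates`.
#'
#' @param path file path.
#' @param col_map named character vector mapping the canonical names
#'   `tag_id`, `timestamp`, `x`, `y`, `z` to the file's column names.
#' @param tz time zone of the input timestamps (normalized to UTC
#'   internally).
#' @param sep field separator.
#' @return A [position_stream].
#' @export
read_positions <- function(path,
                           col_map = c(tag_id = "tag_id",
                                       timestamp = "timestamp",
                                       x = "x", y = "y", z = "z"),
                           tz = "UTC", sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L)
    stop("empty position file: ", path)
  need <- c("tag_id", "timestamp", "x", "y")
  for (nm in need) {
    if (!col_map[[nm]] %in% names(raw))
      stop("missing column '", col_map[[nm]], "' in ", path)
  }
  t <- parse_iso_time(raw[[col_map[["timestamp"]]]], tz = tz)
  x <- suppressWarnings(as.numeric(raw[[col_map[["x"]]]]))
  y <- suppressWarnings(as.numeric(raw[[col_map[["y"]]]]))
  z <- NULL
  has_z <- !is.na(col_map["z"]) && col_map[["z"]] %in% names(raw)
  if (has_z) z <- suppressWarnings(as.numeric(raw[[col_map[["z"]]]]))
  bad <- is.na(t) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) (lines %s)", sum(bad),
                    paste(utils::head(which(bad) + 1L, 5L), collapse = ", ")))
  }
  keep <- !bad
  if (!any(keep))
    stop("no well-formed rows in ", path)
  s <- position_stream(raw[[col_map[["tag_id"]]]][keep], t[keep],
                       x[keep], y[keep],
                       z = if (has_z) z[keep] else NULL)
  attr(s, "n_dropped") <- sum(bad)
  s
}

parse_iso_time <- function(txt, tz = "UTC") {
  txt <- sub("T", " ", txt, fixed = TRUE)
  txt <- sub("Z$", "", txt)
  # per-format strptime so one malformed row cannot poison the column
  t <- as.POSIXct(strptime(txt, "%Y-%m-%d %H:%M:%OS", tz = tz))
  miss <- is.na(t)
  if (any(miss))
    t[miss] <- as.POSIXct(strptime(txt[miss], "%Y-%m-%d %H:%M", tz = tz))
  attr(t, "tzone") <- "UTC"
  t
}

#' Write a position stream to CSV
#'
#' Inverse of [read_positions()]; timestamps are written as ISO-8601 UTC with
#' fractional seconds preserved, so a read/write/read round trip reproduces
#' every field.
#'
#' @param stream a [position_stream].
#' @param path output file path.
#' @export
write_positions <- function(stream, path) {
  out <- as.data.frame(stream)
  out$timestamp <- format_iso_time(out$time)
  out$time <- NULL
  cols <- c("tag_id", "timestamp", "x", "y", if ("z" %in% names(out)) "z")
  utils::write.csv(out[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_iso_time <- function(t) {
  sec <- as.numeric(t)
  frac <- sec - floor(sec)
  base <- format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ifelse(frac > 1e-9,
         paste0(base, sub("^0", "", sprintf("%.3f", frac))),
         base)
}
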