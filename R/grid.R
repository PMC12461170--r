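#' Discretize the unit into a square-cell grid
#'
#' The unit floor plan is partitioned into square cells (default 1 m by
#' 1 m). Cells are half-open intervals `[k*s, (k+1)*s)` on each axis, with
#' the grid origin at the minimum corner of the boundary's bounding box; a
#' cell belongs to the unit when its center falls inside the boundary.
#'
#' @param boundary either a length-2 numeric `c(width, height)` describing a
#'   rectangle anchored at the origin, or a two-column matrix/data.frame of
#'   polygon vertices (meters, planar).
#' @param cell_size cell edge length in meters (default 1).
#' @return A `unit_grid`: list with `origin`, `cell_size`, `n_rows`,
#'   `n_cols`, `inside` (logical `n_rows x n_cols` matrix, rows indexing y),
#'   `n_inside`, `area` (m²) and `boundary`.
#' @examples
#' g <- build_grid(c(20, 20))   # the 400 m^2 default unit
#' g$area                       # 400
#' @export
build_grid <- function(boundary, cell_size = 1) {
  stopifnot(cell_size > 0)
  if (is.numeric(boundary) && length(boundary) == 2L) {
    w <- boundary[1]; h <- boundary[2]
    stopifnot(w > 0, h > 0)
    poly <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  } else {
    poly <- as.matrix(boundary)
    if (ncol(poly) != 2L || nrow(poly) < 3L)
      stop("boundary polygon needs >= 3 vertices with 2 columns")
    if (abs(polygon_area(poly)) < .Machine$double.eps)
      stop("degenerate boundary polygon (zero area)")
  }
  origin <- c(min(poly[, 1]), min(poly[, 2]))
  n_cols <- ceiling((max(poly[, 1]) - origin[1]) / cell_size - 1e-9)
  n_rows <- ceiling((max(poly[, 2]) - origin[2]) / cell_size - 1e-9)
  cx <- origin[1] + (seq_len(n_cols) - 0.5) * cell_size
  cy <- origin[2] + (seq_len(n_rows) - 0.5) * cell_size
  centers <- cbind(rep(cx, each = n_rows), rep(cy, times = n_cols))
  inside_vec <- mgcv::in.out(rbind(poly, poly[1, ]), centers)
  inside <- matrix(inside_vec, nrow = n_rows, ncol = n_cols)
  structure(list(origin = origin, cell_size = cell_size,
                 n_rows = n_rows, n_cols = n_cols, inside = inside,
                 n_inside = sum(inside),
                 area = sum(inside) * cell_size^2,
                 boundary = poly),
            class = "unit_grid")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @export
print.unit_grid <- function(x, ...) {
  cat(sprintf("<unit_grid> %d x %d cells of %.2g m, %d inside (%.0f m^2)\n",
              x$n_rows, x$n_cols, x$cell_size, x$n_inside, x$area))
  invisible(x)
}

#' Map positions to grid cells
#'
#' Uses the half-open cell convention: a position at exactly a cell
#' boundary belongs to the higher-index cell. Positions outside the unit
#' boundary (or in a cell whose center is outside the polygon) map to
#' "outside" and contribute no coverage.
#'
#' @param pos numeric length-2 `c(x, y)` or a two-column matrix of
#'   positions (meters).
#' @param grid a [build_grid()] result.
#' @return Integer matrix with columns `ix`, `iy` of zero-based cell
#'   indices; `NA` for outside positions. For a single position a named
#'   length-2 vector.
#' @export
occupied_cell <- function(pos, grid) {
  single <- is.null(dim(pos))
  p <- if (single) matrix(pos, ncol = 2) else as.matrix(pos)
  ix <- floor((p[, 1] - grid$origin[1]) / grid$cell_size)
  iy <- floor((p[, 2] - grid$origin[2]) / grid$cell_size)
  ok <- ix >= 0 & ix < grid$n_cols & iy >= 0 & iy < grid$n_rows
  ok[ok] <- grid$inside[cbind(iy[ok] + 1L, ix[ok] + 1L)]
  ix[!ok] <- NA_integer_; iy[!ok] <- NA_integer_
  out <- cbind(ix = as.integer(ix), iy = as.integer(iy))
  if (single) out[1, ] else out
}

# linear (column-major over [iy, ix]) index of zero-based cells; NA passes
cell_linear <- function(ix, iy, grid) {
  as.integer(ix) * grid$n_rows + as.integer(iy) + 1L
}

#' Chebyshev dilation of occupied cells
#'
#' Expands each occupied cell by `d_cells` in all cardinal and diagonal
#' directions — the Chebyshev ball, a `(2d+1) x (2d+1)` square block —
#' approximating the visual/functional range of a caregiver around a
#' workstation, then intersects with the unit mask. At 1 m cells a dilation
#' of `d` meters maps to `d` cells; other cell sizes scale as
#' `round(d_m / cell_size)`.
#'
#' @param cells two-column matrix (or length-2 vector) of zero-based
#'   `(ix, iy)` cell indices; `NA` rows are ignored.
#' @param d_cells nonnegative integer dilation radius in cells.
#' @param grid a [build_grid()] result.
#' @return Logical `n_rows x n_cols` coverage raster.
#' @export
dilate <- function(cells, d_cells, grid) {
  stopifnot(d_cells >= 0)
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (k in seq_len(nrow(cells))) {
    if (is.na(cells[k, 1])) next
    cxr <- max(0L, cells[k, 1] - d_cells):min(grid$n_cols - 1L,
                                              cells[k, 1] + d_cells)
    cyr <- max(0L, cells[k, 2] - d_cells):min(grid$n_rows - 1L,
                                              cells[k, 2] + d_cells)
    out[cyr + 1L, cxr + 1L] <- TRUE
  }
  out & grid$inside
}

# Precompute, for every cell of the grid, the linear indices of its dilated
# neighbourhood restricted to inside cells. Returned as a list indexed by
# linear cell index; the per-minute coverage loop unions these.
cell_neighborhoods <- function(grid, d_cells) {
  nr <- grid$n_rows; nc <- grid$n_cols
  inside_lin <- which(as.vector(grid$inside))
  out <- vector("list", nr * nc)
  for (ix in 0:(nc - 1L)) {
    cxr <- max(0L, ix - d_cells):min(nc - 1L, ix + d_cells)
    for (iy in 0:(nr - 1L)) {
      cyr <- max(0L, iy - d_cells):min(nr - 1L, iy + d_cells)
      lin <- as.vector(outer(cyr + 1L, cxr * nr, `+`))
      out[[ix * nr + iy + 1L]] <- lin[as.vector(grid$inside)[lin]]
    }
  }
  out
}

#' Resample a stream to a per-minute time base
#'
#' The shadow statistic is defined on calendar minutes. For each minute
#' (stamped at its end) a tag's position is its last emission at or before
#' the minute end, carried forward while the emission is at most
#' `max_staleness` minutes old — tolerating one missed stationary beacon;
#' staler tags are absent that minute and contribute no coverage.
#'
#' @param stream a (filtered) [position_stream].
#' @param grid a [build_grid()] result.
#' @param max_staleness carry-forward limit in minutes (default 2).
#' @param start,end optional `POSIXct` overrides of the frame span; defaults
#'   to the stream span rounded to calendar minutes.
#' @return A `minute_frames` object: list with `minute` (1-based index),
#'   `time` (minute-end `POSIXct`), `tags`, matrices `cell` (linear cell
#'   index, `NA` when absent or outside), `x`, `y`, `stale` (minutes), and
#'   the `grid`.
#' @export
resample_per_minute <- function(stream, grid, max_staleness = 2,
                                start = NULL, end = NULL) {
  stopifnot(inherits(grid, "unit_grid"))
  tsec <- as.numeric(stream$time)
  if (is.null(start)) {
    if (!nrow(stream)) stop("empty stream needs explicit 'start' and 'end'")
    start <- floor(min(tsec) / 60) * 60
  } else start <- as.numeric(start)
  if (is.null(end)) end <- max(tsec) else end <- as.numeric(end)
  n_min <- max(1L, ceiling((end - start) / 60 - 1e-9))
  ends <- start + 60 * seq_len(n_min)
  tags <- sort(unique(stream$tag_id))
  nt <- length(tags)
  cellm <- matrix(NA_integer_, n_min, nt)
  xm <- matrix(NA_real_, n_min, nt)
  ym <- matrix(NA_real_, n_min, nt)
  stale <- matrix(NA_real_, n_min, nt)
  for (j in seq_len(nt)) {
    idx <- which(stream$tag_id == tags[j])
    ti <- tsec[idx]
    last <- findInterval(ends, ti)
    has <- last >= 1L
    st <- rep(NA_real_, n_min)
    st[has] <- (ends[has] - ti[last[has]]) / 60
    ok <- has & st <= max_staleness
    stale[, j] <- st
    if (any(ok)) {
      rows <- idx[last[ok]]
      xm[ok, j] <- stream$x[rows]
      ym[ok, j] <- stream$y[rows]
      cells <- occupied_cell(cbind(stream$x[rows], stream$y[rows]), grid)
      cellm[ok, j] <- cell_linear(cells[, 1], cells[, 2], grid)
    }
  }
  structure(list(minute = seq_len(n_min),
                 time = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
                 tags = tags, cell = cellm, x = xm, y = ym, stale = stale,
                 grid = grid, max_staleness = max_staleness),
            class = "minute_frames")
}

#' @export
print.minute_frames <- function(x, ...) {
  cat(sprintf("<minute_frames> %d minutes x %d tag(s), %s -- %s\n",
              length(x$minute), length(x$tags),
              format(x$time[1] - 60), format(x$time[length(x$time)])))
  invisible(x)
}

#' Coverage raster of one minute frame
#'
#' Union of the dilated occupied cells of every tag present that minute;
#' tags absent (stale or outside the boundary) contribute nothing. Coverage
#' is invariant to tag order and labels.
#'
#' @param frames a [resample_per_minute()] result.
#' @param minute 1-based minute index into `frames`.
#' @param d_cells dilation radius in cells (default 2).
#' @return Logical coverage raster aligned to the grid.
#' @export
coverage_at_minute <- function(frames, minute, d_cells = 2) {
  grid <- frames$grid
  lin <- frames$cell[minute, ]
  lin <- lin[!is.na(lin)]
  if (!length(lin)) return(matrix(FALSE, grid$n_rows, grid$n_cols))
  iy <- (lin - 1L) %% grid$n_rows
  ix <- (lin - 1L) %/% grid$n_rows
  dilate(cbind(ix, iy), d_cells, grid)
}
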