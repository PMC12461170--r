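#' Shadow-zone parameters
#'
#' A cell is a spatial shadow zone at minute `t` when it has been outside
#' every workstation's dilated coverage area for at least `T_minutes`
#' consecutive minutes ending at `t`; it leaves shadow the minute it is
#' covered again. Uncovered-minute counters start at zero at stream start
#' (cells presumed recently visited); `warmup = "mask_first_T"` instead
#' reports `NA` for the first `T_minutes` minutes, during which no cell can
#' yet have accumulated a full uncovered run.
#'
#' @param d_cells dilation radius in cells (default 2, i.e. 2 m at 1 m
#'   cells).
#' @param T_minutes persistence threshold in minutes (default 60, the
#'   conventional rounding interval).
#' @param warmup `"report_all"` (default) or `"mask_first_T"`.
#' @return list of class `shadow_params`.
#' @export
shadow_params <- function(d_cells = 2, T_minutes = 60,
                          warmup = c("report_all", "mask_first_T")) {
  stopifnot(d_cells >= 0, T_minutes >= 1)
  structure(list(d_cells = as.integer(d_cells),
                 T_minutes = as.integer(T_minutes),
                 warmup = match.arg(warmup)),
            class = "shadow_params")
}

#' Advance the shadow state by one minute of coverage
#'
#' Incremental update of the per-cell uncovered-minute counters: a covered
#' cell resets to zero, an uncovered inside cell increments; the shadow
#' mask is the counter reaching the persistence threshold. Minutes with no
#' present tags still advance every counter — absence is precisely what
#' shadow measures.
#'
#' @param state list with integer raster `uncovered_minutes` (or `NULL` to
#'   initialize at zero).
#' @param coverage logical coverage raster for the minute, aligned to
#'   `grid`.
#' @param params a [shadow_params()].
#' @param grid the [build_grid()] the rasters are aligned to.
#' @return list with `uncovered_minutes` and `shadow_mask` rasters.
#' @export
update_shadow <- function(state, coverage, params, grid) {
  if (!identical(dim(coverage), dim(grid$inside)))
    stop("coverage raster does not match the grid")
  cnt <- if (is.null(state))
    matrix(0L, grid$n_rows, grid$n_cols) else state$uncovered_minutes
  if (!identical(dim(cnt), dim(grid$inside)))
    stop("shadow state does not match the grid")
  cnt <- cnt + 1L
  cnt[coverage] <- 0L
  cnt[!grid$inside] <- 0L
  list(uncovered_minutes = cnt,
       shadow_mask = cnt >= params$T_minutes & grid$inside)
}

# Core incremental pass over per-minute occupied cells.
# cell_list: list over minutes of linear occupied-cell indices (may be
# empty); nbr: cell_neighborhoods(grid, d). Returns percent matrix
# (minutes x length(T_list)).
shadow_percent_pass <- function(cell_list, nbr, grid, T_list) {
  n_min <- length(cell_list)
  inside_lin <- which(as.vector(grid$inside))
  n_inside <- length(inside_lin)
  cnt <- integer(grid$n_rows * grid$n_cols)
  out <- matrix(NA_real_, n_min, length(T_list))
  prev_cells <- NULL
  covered <- integer(0)
  for (i in seq_len(n_min)) {
    cells <- cell_list[[i]]
    if (!identical(cells, prev_cells)) {
      covered <- if (length(cells))
        unique(unlist(nbr[cells], use.names = FALSE)) else integer(0)
      prev_cells <- cells
    }
    cnt <- cnt + 1L
    if (length(covered)) cnt[covered] <- 0L
    ci <- cnt[inside_lin]
    for (j in seq_along(T_list))
      out[i, j] <- 100 * sum(ci >= T_list[j]) / n_inside
  }
  out
}

frames_cell_list <- function(frames) {
  cellm <- frames$cell
  lapply(seq_len(nrow(cellm)), function(i) {
    v <- cellm[i, ]
    sort(unique(v[!is.na(v)]))
  })
}

#' Per-minute percentage of spatial shadow zone
#'
#' Streams the incremental counter update across all minute frames and
#' reports, for each minute, the shadow-cell area divided by the total unit
#' area, times 100.
#'
#' @param frames a [resample_per_minute()] result.
#' @param params a [shadow_params()].
#' @return A `shadow_series`: data.frame with `minute`, `time`, `percent`
#'   and `warmup` (logical, first `T_minutes` minutes); parameters attached
#'   as attribute `params`.
#' @export
shadow_series <- function(frames, params = shadow_params()) {
  stopifnot(inherits(frames, "minute_frames"),
            inherits(params, "shadow_params"))
  grid <- frames$grid
  nbr <- cell_neighborhoods(grid, params$d_cells)
  pct <- shadow_percent_pass(frames_cell_list(frames), nbr, grid,
                             params$T_minutes)[, 1]
  warm <- frames$minute <= params$T_minutes
  if (params$warmup == "mask_first_T") pct[warm] <- NA_real_
  structure(data.frame(minute = frames$minute, time = frames$time,
                       percent = pct, warmup = warm),
            params = params, n_inside = grid$n_inside,
            class = c("shadow_series", "data.frame"))
}

#' Percentage-of-shadow series from an explicit coverage history
#'
#' Low-level entry point operating on a minutes-by-cells logical coverage
#' matrix rather than on trajectory frames; used for raster workflows and
#' for checking the incremental tracker against windowed recomputation.
#'
#' @param covered logical matrix, one row per minute, one column per cell.
#' @param T_minutes persistence threshold in minutes.
#' @param inside optional logical vector marking cells that belong to the
#'   unit (default: all).
#' @return numeric vector of per-minute shadow percentages.
#' @export
shadow_percent_matrix <- function(covered, T_minutes, inside = NULL) {
  stopifnot(is.matrix(covered), T_minutes >= 1)
  if (is.null(inside)) inside <- rep(TRUE, ncol(covered))
  n_inside <- sum(inside)
  cnt <- integer(ncol(covered))
  out <- numeric(nrow(covered))
  for (i in seq_len(nrow(covered))) {
    cnt <- cnt + 1L
    cnt[covered[i, ]] <- 0L
    out[i] <- 100 * sum(cnt[inside] >= T_minutes) / n_inside
  }
  out
}

#' @export
print.shadow_series <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<shadow_series> %d minutes, d = %d cell(s), T = %d min\n",
              nrow(x), p$d_cells, p$T_minutes))
  ok <- !is.na(x$percent)
  if (any(ok))
    cat(sprintf("  percent shadow: mean %.1f, range %.1f--%.1f\n",
                mean(x$percent[ok]), min(x$percent[ok]),
                max(x$percent[ok])))
  invisible(x)
}

#' @export
plot.shadow_series <- function(x, ...) {
  graphics::plot(x$time, x$percent, type = "l",
                 xlab = "time", ylab = "% of unit in shadow",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Shadow series over a grid of dilation and persistence parameters
#'
#' Recomputes the shadow percentage for every combination of dilation
#' radius and persistence threshold. A single pass is made per dilation
#' value: the uncovered-run counters do not depend on `T`, so all
#' thresholds share one counter stream.
#'
#' @param frames a [resample_per_minute()] result.
#' @param d_list dilation radii in cells (default 1:4).
#' @param T_list persistence thresholds in minutes (default 15, 30, ..., 90).
#' @return A `shadow_surface`: long data.frame with `d_cells`, `T_minutes`,
#'   `minute`, `time`, `percent`.
#' @export
sensitivity_surface <- function(frames, d_list = 1:4,
                                T_list = c(15, 30, 45, 60, 75, 90)) {
  stopifnot(inherits(frames, "minute_frames"))
  grid <- frames$grid
  cl <- frames_cell_list(frames)
  parts <- list()
  for (d in d_list) {
    nbr <- cell_neighborhoods(grid, d)
    pct <- shadow_percent_pass(cl, nbr, grid, T_list)
    for (j in seq_along(T_list)) {
      parts[[length(parts) + 1L]] <-
        data.frame(d_cells = d, T_minutes = T_list[j],
                   minute = frames$minute, time = frames$time,
                   percent = pct[, j])
    }
  }
  structure(do.call(rbind, parts), d_list = d_list, T_list = T_list,
            n_inside = grid$n_inside,
            class = c("shadow_surface", "data.frame"))
}

#' Extract one (d, T) series from a sensitivity surface
#'
#' @param surface a [sensitivity_surface()] result.
#' @param d_cells,T_minutes the parameter pair to extract.
#' @return a `shadow_series`.
#' @export
surface_slice <- function(surface, d_cells, T_minutes) {
  sel <- surface$d_cells == d_cells & surface$T_minutes == T_minutes
  if (!any(sel)) stop("pair (", d_cells, ", ", T_minutes,
                      ") not in the surface")
  s <- surface[sel, c("minute", "time", "percent")]
  rownames(s) <- NULL
  s$warmup <- s$minute <= T_minutes
  structure(s, params = shadow_params(d_cells, T_minutes),
            n_inside = attr(surface, "n_inside"),
            class = c("shadow_series", "data.frame"))
}

#' Write a shadow series (or surface) as CSV
#'
#' @param x a `shadow_series` or `shadow_surface`.
#' @param path output path.
#' @export
write_shadow_csv <- function(x, path) {
  if (inherits(x, "shadow_series")) {
    p <- attr(x, "params")
    out <- data.frame(minute = x$minute,
                      timestamp = format_iso_time(x$time),
                      percent_shadow = x$percent,
                      d_cells = p$d_cells, T_minutes = p$T_minutes)
  } else {
    out <- data.frame(d_cells = x$d_cells, T_minutes = x$T_minutes,
                      minute = x$minute,
                      timestamp = format_iso_time(x$time),
                      percent_shadow = x$percent)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
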