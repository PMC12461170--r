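#' Read a ground-truth route polyline
#'
#' @param path CSV of `x,y` vertices in meters, in route order.
#' @return two-column matrix of vertices.
#' @export
read_route <- function(path) {
  df <- utils::read.csv(path)
  route <- as.matrix(df[, c("x", "y")])
  validate_route(route)
  route
}

validate_route <- function(route) {
  if (!is.matrix(route) || ncol(route) != 2 || nrow(route) < 2)
    stop("route must be a matrix of >= 2 (x, y) vertices")
  d <- sqrt(rowSums((route[-1, , drop = FALSE] -
                       route[-nrow(route), , drop = FALSE])^2))
  if (any(d == 0)) stop("route has coincident consecutive vertices")
  invisible(route)
}

#' Minimum distance from points to a route polyline
#'
#' For each point, the minimum Euclidean distance to any segment of the
#' open polyline, with the orthogonal projection clamped to segment
#' endpoints (so a point beyond a terminal vertex measures its distance to
#' that vertex).
#'
#' @param p length-2 `c(x, y)` or a two-column matrix of points (meters).
#' @param route two-column matrix of polyline vertices.
#' @return numeric vector of distances in meters.
#' @export
point_to_polyline_distance <- function(p, route) {
  validate_route(route)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  p <- as.matrix(p)
  best <- rep(Inf, nrow(p))
  for (k in seq_len(nrow(route) - 1L)) {
    a <- route[k, ]; b <- route[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}

#' Positional-error distribution against a ground-truth route
#'
#' Each position estimate is scored by its distance to the nearest point on
#' the route polyline (no time alignment: the validation route records no
#' per-point timestamps). Reports mean, sample SD, a normal-approximation
#' 95% CI of the mean, empirical quantiles (linear interpolation between
#' order statistics, R's default type 7 — the convention the 80th-percentile
#' figure depends on) and the empirical CDF.
#'
#' @param estimates a [position_stream] or a two-column matrix of estimated
#'   positions (meters). When a stream is given it should normally be
#'   noise-filtered first; pass the raw stream to score pre-filter
#'   accuracy.
#' @param route two-column matrix of route vertices.
#' @return An `error_distribution`: list with `errors`, `n`, `mean`, `sd`,
#'   `ci95`, `quantiles` (5/25/50/75/80/95%).
#' @export
error_distribution <- function(estimates, route) {
  p <- if (inherits(estimates, "position_stream"))
    cbind(estimates$x, estimates$y) else as.matrix(estimates)
  if (is.null(nrow(p)) || nrow(p) < 2)
    stop("need at least 2 position estimates")
  errors <- point_to_polyline_distance(p, route)
  m <- mean(errors)
  s <- stats::sd(errors)
  ci <- m + c(-1, 1) * stats::qnorm(0.975) * s / sqrt(length(errors))
  qs <- stats::quantile(errors, c(0.05, 0.25, 0.5, 0.75, 0.8, 0.95),
                        type = 7)
  structure(list(errors = errors, n = length(errors), mean = m, sd = s,
                 ci95 = ci, quantiles = qs),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf("<error_distribution> n = %d\n", x$n))
  cat(sprintf("  mean error %.3f m (95%% CI %.3f to %.3f), SD %.3f\n",
              x$mean, x$ci95[1], x$ci95[2], x$sd))
  cat(sprintf("  80%% of estimates within %.3f m\n",
              x$quantiles[["80%"]]))
  invisible(x)
}

#' @export
quantile.error_distribution <- function(x, probs = seq(0, 1, 0.25), ...) {
  stats::quantile(x$errors, probs = probs, type = 7, ...)
}

#' Empirical CDF table of positional errors
#'
#' @param x an [error_distribution()].
#' @return data.frame `error`, `cum_prob`, nondecreasing and reaching 1 at
#'   the maximum error.
#' @export
cdf_table <- function(x) {
  stopifnot(inherits(x, "error_distribution"))
  e <- sort(x$errors)
  data.frame(error = e, cum_prob = seq_along(e) / length(e))
}

#' @export
plot.error_distribution <- function(x, q_mark = 0.8, ...) {
  tab <- cdf_table(x)
  graphics::plot(tab$error, tab$cum_prob, type = "s",
                 xlab = "positional error (m)",
                 ylab = "cumulative probability", ylim = c(0, 1), ...)
  if (!is.null(q_mark)) {
    qv <- stats::quantile(x$errors, q_mark, type = 7)
    graphics::abline(v = qv, h = q_mark, lty = 2, col = "grey40")
  }
  invisible(x)
}
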