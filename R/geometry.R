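#' Piecewise-linear track path
#'
#' The track skeleton used to convert room-frame `(x, y)` coordinates into a
#' single arc-length coordinate. Vertices are the path's corner points; arc
#' length runs from the first vertex (one food well) to the last (the other).
#'
#' @param vertices two-column matrix (or data.frame) of x/y cm coordinates.
#' @return An object of class `track_path` with the vertex matrix, per-segment
#'   lengths and cumulative arc length.
#' @export
track_path <- function(vertices) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 2)
  d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(d <= 0)) stop("degenerate track geometry: zero-length segment")
  structure(list(vertices = v, seg_len = d, cum_len = c(0, cumsum(d)),
                 length = sum(d)),
            class = "track_path")
}

#' Default C-shaped track
#'
#' A 300-cm C-shaped path with four corners and a long middle segment,
#' mimicking a curtained C-shaped running track.
#'
#' @return A [track_path()] of total length 300 cm.
#' @export
default_c_track <- function() {
  track_path(rbind(c(45, 0), c(100, 0), c(100, 45), c(0, 45),
                   c(0, 90), c(55, 90)))
}

# arc-length position -> (x, y) on the path, plus segment heading (deg)
path_point <- function(path, s) {
  s <- pmin(pmax(s, 0), path$length)
  seg <- findInterval(s, path$cum_len, rightmost.closed = TRUE)
  seg <- pmin(seg, length(path$seg_len))
  frac <- (s - path$cum_len[seg]) / path$seg_len[seg]
  a <- path$vertices[seg, , drop = FALSE]
  b <- path$vertices[seg + 1, , drop = FALSE]
  xy <- a + frac * (b - a)
  heading <- atan2(b[, 2] - a[, 2], b[, 1] - a[, 1]) * 180 / pi
  list(x = xy[, 1], y = xy[, 2], heading = heading %% 360)
}

# project (x, y) points onto the path; returns arc length of nearest point
project_to_path <- function(path, x, y) {
  n_seg <- length(path$seg_len)
  best_d2 <- rep(Inf, length(x))
  best_s <- numeric(length(x))
  for (k in seq_len(n_seg)) {
    a <- path$vertices[k, ]
    b <- path$vertices[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- path$cum_len[k] + t[upd] * path$seg_len[k]
  }
  best_s
}
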