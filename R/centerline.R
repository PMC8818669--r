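#' Arc-length-parameterized vessel centerline
#'
#' An ordered 3D polyline with cumulative arc length and per-point
#' orthonormal frames (tangent, normal1, normal2). Frames are
#' rotation-minimizing (parallel transport by the double-reflection method),
#' not Frenet frames, so they are defined on straight segments and do not
#' flip between stations.
#'
#' @param points numeric matrix, n x 3, ordered positions (mm).
#' @param s optional cumulative arc length per point (mm); when omitted it is
#'   recomputed from the chord lengths of `points`.
#' @return object of class `centerline` with `points`, `s`, `tangent`,
#'   `normal1`, `normal2` (each n x 3).
#' @export
centerline <- function(points, s = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be n x 3")
  n <- nrow(points)
  if (n < 2L) stop("centerline needs at least 2 points")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  if (any(seg <= 0)) stop("coincident consecutive centerline points")
  if (is.null(s)) s <- c(0, cumsum(seg))
  if (any(diff(s) <= 0)) stop("arc length must be strictly increasing")
  fr <- rmf_frames(points)
  structure(list(points = points, s = as.numeric(s),
                 tangent = fr$tangent, normal1 = fr$normal1,
                 normal2 = fr$normal2),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f mm\n",
              nrow(x$points), total_length(x)))
  invisible(x)
}

#' Total arc length of a centerline (mm)
#' @param cl a `centerline`.
#' @return numeric scalar.
#' @export
total_length <- function(cl) cl$s[length(cl$s)] - cl$s[1L]

unit <- function(v) v / sqrt(sum(v^2))

# any unit vector orthogonal to t
orthogonal_to <- function(t) {
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(a - sum(a * t) * t)
}

# Rotation-minimizing frames by the double reflection method
# (Wang, Juettler, Zheng, Liu 2008).
rmf_frames <- function(points) {
  n <- nrow(points)
  tangent <- matrix(0, n, 3L)
  d <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  d <- d / sqrt(rowSums(d^2))
  tangent[1L, ] <- d[1L, ]
  tangent[n, ] <- d[n - 1L, ]
  if (n > 2L) {
    mid <- d[-(n - 1L), , drop = FALSE] + d[-1L, , drop = FALSE]
    tangent[2:(n - 1L), ] <- mid / sqrt(rowSums(mid^2))
  }
  normal1 <- matrix(0, n, 3L)
  normal1[1L, ] <- orthogonal_to(tangent[1L, ])
  for (i in seq_len(n - 1L)) {
    v1 <- points[i + 1L, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rL <- normal1[i, ] - (2 / c1) * sum(v1 * normal1[i, ]) * v1
    tL <- tangent[i, ] - (2 / c1) * sum(v1 * tangent[i, ]) * v1
    v2 <- tangent[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    r2 <- if (c2 < 1e-30) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against accumulated drift
    r2 <- r2 - sum(r2 * tangent[i + 1L, ]) * tangent[i + 1L, ]
    normal1[i + 1L, ] <- unit(r2)
  }
  normal2 <- cbind(
    tangent[, 2] * normal1[, 3] - tangent[, 3] * normal1[, 2],
    tangent[, 3] * normal1[, 1] - tangent[, 1] * normal1[, 3],
    tangent[, 1] * normal1[, 2] - tangent[, 2] * normal1[, 1])
  list(tangent = tangent, normal1 = normal1, normal2 = normal2)
}

#' Resample a centerline at uniform arc-length spacing
#'
#' New points are placed on the existing polyline at uniform values of the
#' stored arc-length coordinate; endpoints are preserved exactly and the new
#' points inherit the parent parameterization (the s-range is preserved to
#' machine precision rather than re-measured from the coarser chords).
#'
#' @param cl a `centerline`.
#' @param spacing target spacing (mm); the actual spacing is the nearest
#'   value that divides the total length into whole segments.
#' @return a new `centerline`.
#' @export
resample_centerline <- function(cl, spacing) {
  if (spacing <= 0) stop("spacing must be positive")
  L <- total_length(cl)
  if (spacing >= L) stop("spacing too coarse")
  n_seg <- max(1L, round(L / spacing))
  s_new <- cl$s[1L] + seq(0, L, length.out = n_seg + 1L)
  pts <- cbind(approx(cl$s, cl$points[, 1], xout = s_new)$y,
               approx(cl$s, cl$points[, 2], xout = s_new)$y,
               approx(cl$s, cl$points[, 3], xout = s_new)$y)
  pts[1L, ] <- cl$points[1L, ]
  pts[nrow(pts), ] <- cl$points[nrow(cl$points), ]
  centerline(pts, s = s_new)
}

#' Local orthonormal frame at an arc-length station
#'
#' The tangent is interpolated between bracketing stations and normalized;
#' the transported normal of the previous station is projected into the new
#' tangent plane, so adjacent frames never flip.
#'
#' @param cl a `centerline`.
#' @param s arc-length station (mm), within `[min(s), max(s)]`.
#' @return object of class `frame`: list(origin, tangent, normal1, normal2).
#' @export
local_frame <- function(cl, s) {
  if (s < cl$s[1L] - 1e-9 || s > cl$s[length(cl$s)] + 1e-9)
    stop("s out of range")
  s <- min(max(s, cl$s[1L]), cl$s[length(cl$s)])
  i <- findInterval(s, cl$s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(cl$s) - 1L)
  w <- (s - cl$s[i]) / (cl$s[i + 1L] - cl$s[i])
  origin <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1L, ]
  tangent <- unit((1 - w) * cl$tangent[i, ] + w * cl$tangent[i + 1L, ])
  n1 <- cl$normal1[i, ]
  n1 <- unit(n1 - sum(n1 * tangent) * tangent)
  n2 <- c(tangent[2] * n1[3] - tangent[3] * n1[2],
          tangent[3] * n1[1] - tangent[1] * n1[3],
          tangent[1] * n1[2] - tangent[2] * n1[1])
  structure(list(origin = origin, tangent = tangent,
                 normal1 = n1, normal2 = n2),
            class = "frame")
}

#' Equivalent diameter of a cross-section area
#'
#' Diameter of the circle with the same area: `2 * sqrt(area / pi)`.
#'
#' @param area cross-section area (mm^2), non-negative (vectorized).
#' @return equivalent diameter (mm).
#' @export
equivalent_diameter <- function(area) {
  if (any(area < 0)) stop("area must be non-negative")
  2 * sqrt(area / pi)
}

#' Read a centerline from a CSV file with columns x,y,z
#'
#' Arc length is recomputed from the loaded points.
#'
#' @param path CSV path with header containing x, y, z columns (mm).
#' @return a `centerline`.
#' @export
read_centerline <- function(path) {
  df <- read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) stop("centerline CSV needs x,y,z columns")
  centerline(as.matrix(df[, need]))
}

#' Write a centerline to CSV (x,y,z[,s])
#' @param cl a `centerline`.
#' @param path output path.
#' @param with_s include the arc-length column.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cl, path, with_s = TRUE) {
  df <- data.frame(x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3])
  if (with_s) df$s <- cl$s
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
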