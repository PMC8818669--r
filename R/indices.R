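#' Time-resolved wall shear stress series
#'
#' Wall shear vectors (Pa) on a fixed set of wall element centres over a
#' cardiac cycle. Raw solver exports may span several cycles; the index
#' operations require a single period (use [last_cycle()] to drop warm-up
#' cycles, matching the convention of simulating two cycles and discarding
#' the first).
#'
#' @param centers n x 3 matrix of element centres (mm).
#' @param tau array n x 3 x nt of WSS vectors (Pa).
#' @param times timestep times (s), strictly increasing.
#' @param T cardiac period (s).
#' @param areas optional element areas (mm^2) for weighted summaries.
#' @return object of class `wall_series`.
#' @export
wall_series <- function(centers, tau, times, T, areas = NULL) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (!is.array(tau) || length(dim(tau)) != 3L ||
      dim(tau)[1L] != n || dim(tau)[2L] != 3L)
    stop("tau must be an n x 3 x nt array matching the element centres")
  nt <- dim(tau)[3L]
  if (length(times) != nt) stop("times length must match timesteps")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (T <= 0) stop("period must be positive")
  structure(list(centers = centers, tau = tau, times = as.numeric(times),
                 T = T, areas = areas),
            class = "wall_series")
}

#' Time-resolved volumetric velocity series
#'
#' @param points n x 3 matrix of sample points (mm).
#' @param v array n x 3 x nt of velocity vectors (m/s).
#' @param times timestep times (s), strictly increasing.
#' @param T cardiac period (s).
#' @param rho blood density (kg/m^3), default 1055.
#' @param weights optional point weights (mm^3 cell volumes) for summaries.
#' @return object of class `volume_series`.
#' @export
volume_series <- function(points, v, times, T, rho = 1055, weights = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.array(v) || length(dim(v)) != 3L ||
      dim(v)[1L] != n || dim(v)[2L] != 3L)
    stop("v must be an n x 3 x nt array matching the sample points")
  if (length(times) != dim(v)[3L]) stop("times length must match timesteps")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (rho <= 0) stop("density must be positive")
  structure(list(points = points, v = v, times = as.numeric(times),
                 T = T, rho = rho, weights = weights),
            class = "volume_series")
}

#' Keep only the final cardiac cycle of a field series
#'
#' Drops all timesteps before the last full period, reproducing the
#' convention of simulating two cycles and discarding the first.
#'
#' @param series a `wall_series` or `volume_series` spanning >= 1 period.
#' @return the trimmed series (times span one period).
#' @export
last_cycle <- function(series) {
  t <- series$times
  keep <- t > t[length(t)] - series$T + 1e-12
  if (sum(keep) < 3L) stop("fewer than 3 timesteps in the final cycle")
  if (inherits(series, "wall_series")) {
    wall_series(series$centers, series$tau[, , keep, drop = FALSE],
                t[keep], series$T, areas = series$areas)
  } else {
    volume_series(series$points, series$v[, , keep, drop = FALSE],
                  t[keep], series$T, rho = series$rho,
                  weights = series$weights)
  }
}

check_one_cycle <- function(series) {
  span <- series$times[length(series$times)] - series$times[1L]
  if (span >= series$T - 1e-12 * series$T)
    stop("series spans more than one period; apply last_cycle() first")
  if (length(series$times) < 3L) stop("need at least 3 timesteps")
  invisible(series)
}

# periodic trapezoid: integral over one period of each row of M,
# where columns are timesteps at `times` spanning [t0, t0 + T)
trapz_periodic <- function(times, T, M) {
  nt <- length(times)
  t_ext <- c(times, times[1L] + T)
  w <- diff(t_ext)
  Me <- cbind(M, M[, 1L])
  acc <- numeric(nrow(M))
  for (i in seq_len(nt))
    acc <- acc + 0.5 * w[i] * (Me[, i] + Me[, i + 1L])
  acc
}

vec_mag <- function(a) sqrt(a[, 1L, ]^2 + a[, 2L, ]^2 + a[, 3L, ]^2)

new_index_field <- function(values, name, units, weights = NULL,
                            flags = NULL) {
  structure(list(values = as.numeric(values), name = name, units = units,
                 weights = weights, flags = flags),
            class = "index_field")
}

#' @export
print.index_field <- function(x, ...) {
  cat(sprintf("<index_field> %s [%s]: n=%d, mean %.4g, max %.4g\n",
              x$name, x$units, length(x$values), mean(x$values),
              max(x$values)))
  invisible(x)
}

#' Time-averaged wall shear stress (AWSS)
#'
#' `AWSS = (1/T) * int_0^T |tau| dt`, trapezoidal integration with periodic
#' closure (the first timestep is reused at `t0 + T`).
#'
#' @param ws a `wall_series` spanning one period.
#' @return `index_field` (Pa).
#' @export
awss <- function(ws) {
  check_one_cycle(ws)
  mag <- vec_mag(ws$tau)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1L)
  new_index_field(trapz_periodic(ws$times, ws$T, mag) / ws$T,
                  "AWSS", "Pa", weights = ws$areas)
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |int tau dt| / int |tau| dt)`; elements with zero
#' shear over the whole cycle get OSI = 0 by convention.
#'
#' @param ws a `wall_series` spanning one period.
#' @return `index_field` (dimensionless, in [0, 0.5]).
#' @export
osi <- function(ws) {
  check_one_cycle(ws)
  new_index_field(
    oscillatory_index(ws$tau, ws$times, ws$T), "OSI", "-",
    weights = ws$areas)
}

oscillatory_index <- function(a, times, T) {
  n <- dim(a)[1L]
  comp <- function(j) {
    M <- a[, j, , drop = FALSE]
    dim(M) <- c(n, dim(a)[3L])
    trapz_periodic(times, T, M)
  }
  ix <- comp(1L); iy <- comp(2L); iz <- comp(3L)
  mag <- vec_mag(a)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = n)
  den <- trapz_periodic(times, T, mag)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time (RRT)
#'
#' `RRT = 1 / ((1 - 2*OSI) * AWSS)`. Where the denominator falls below
#' `eps` (default 1e-9 Pa) the value is capped at `1/eps` and flagged.
#'
#' @param awss_f AWSS `index_field`.
#' @param osi_f OSI `index_field` over the same elements.
#' @param eps denominator floor (Pa).
#' @return `index_field` (1/Pa) with logical `flags` marking capped values.
#' @export
rrt <- function(awss_f, osi_f, eps = 1e-9) {
  if (length(awss_f$values) != length(osi_f$values))
    stop("AWSS and OSI fields have mismatched element sets")
  den <- (1 - 2 * osi_f$values) * awss_f$values
  capped <- den < eps
  vals <- ifelse(capped, 1 / eps, 1 / pmax(den, eps))
  new_index_field(vals, "RRT", "1/Pa", weights = awss_f$weights,
                  flags = capped)
}

#' Oscillatory velocity index (OVI)
#'
#' OSI-analogue on the volumetric velocity field:
#' `OVI = 0.5 * (1 - |int v dt| / int |v| dt)` per sample point; points with
#' zero velocity over the whole cycle get 0.
#'
#' @param vs a `volume_series` spanning one period.
#' @return `index_field` (dimensionless, in [0, 0.5]).
#' @export
ovi <- function(vs) {
  check_one_cycle(vs)
  new_index_field(
    oscillatory_index(vs$v, vs$times, vs$T), "OVI", "-",
    weights = vs$weights)
}

#' Kinetic energy density (KE)
#'
#' `e_k = 0.5 * rho * |v|^2` per point and timestep, plus the periodic
#' trapezoid time-average.
#'
#' @param vs a `volume_series` spanning one period.
#' @return list of class `ke_field`: `avg` (`index_field`, J/m^3), `series`
#'   (n x nt matrix), `times`.
#' @export
kinetic_energy <- function(vs) {
  check_one_cycle(vs)
  mag2 <- vs$v[, 1L, ]^2 + vs$v[, 2L, ]^2 + vs$v[, 3L, ]^2
  if (is.null(dim(mag2))) mag2 <- matrix(mag2, nrow = dim(vs$v)[1L])
  ek <- 0.5 * vs$rho * mag2
  avg <- new_index_field(trapz_periodic(vs$times, vs$T, ek) / vs$T,
                         "KE", "J/m^3", weights = vs$weights)
  structure(list(avg = avg, series = ek, times = vs$times),
            class = "ke_field")
}

#' Weighted summary statistics of an index field
#'
#' @param field an `index_field`.
#' @param region_mask optional logical/integer mask selecting elements.
#' @return list(mean, max, p95, wmean) where `wmean` and `p95` use the
#'   field's element areas / point weights (uniform when absent).
#' @export
index_summary <- function(field, region_mask = NULL) {
  v <- field$values
  w <- field$weights %||% rep(1, length(v))
  if (!is.null(region_mask)) {
    v <- v[region_mask]
    w <- w[region_mask]
  }
  if (length(v) == 0L) stop("empty region mask")
  ord <- order(v)
  cw <- cumsum(w[ord]) / sum(w)
  p95 <- v[ord][which(cw >= 0.95)[1L]]
  list(mean = mean(v), max = max(v), p95 = p95,
       wmean = sum(w * v) / sum(w))
}
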