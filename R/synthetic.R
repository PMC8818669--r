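#' Parametric fusiform-vessel specification
#'
#' Describes a synthetic vessel: a centerline curve (straight, circular arc
#' or helix), a base lumen radius, an optional Gaussian circumferential
#' dilation and an optional linear taper. The dilation radius law is
#' `r(s) = r0 + (r_p - r0) * exp(-(s - s_c)^2 / (2 sigma^2))`, so a spec
#' with `r_p / r0 = 1.6` produces a lesion on the aneurysmal side of the
#' 1.5x nominal-diameter criterion and `r_p / r0 = 1.3` one below it.
#'
#' @param curve list: `type` one of "straight", "arc", "helix"; `length`
#'   (mm along the curve); for "arc" also `bend_radius` (mm); for "helix"
#'   also `helix_radius` and `pitch` (mm per turn).
#' @param r0 base lumen radius (mm).
#' @param dilation `NULL` (healthy tube) or list(`s_c` center station mm,
#'   `r_p` peak radius mm, `sigma` Gaussian width mm).
#' @param edge_length target mesh edge length (mm); must be < `r0 / 4`.
#' @param taper optional linear radius rate (mm per mm of arc length,
#'   negative narrows distally); default 0.
#' @param jitter vertex jitter amplitude as a fraction of `edge_length`
#'   (<= 0.05); default 0 (exact surface of revolution).
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(curve = list(type = "straight", length = 40),
                        r0 = 2, dilation = NULL, edge_length = 0.25,
                        taper = 0, jitter = 0) {
  if (edge_length >= r0 / 4) stop("edge_length must be < r0/4")
  if (!is.null(dilation)) {
    if (dilation$sigma <= 0) stop("dilation sigma must be positive")
    if (dilation$r_p <= r0)
      stop("dilation peak radius must exceed the base radius")
  }
  if (jitter < 0 || jitter > 0.05) stop("jitter must be in [0, 0.05]")
  structure(list(curve = curve, r0 = r0, dilation = dilation,
                 edge_length = edge_length, taper = taper, jitter = jitter),
            class = "vessel_spec")
}

vessel_radius_law <- function(spec) {
  force(spec)
  function(s) {
    r <- spec$r0 + spec$taper * s
    if (!is.null(spec$dilation)) {
      d <- spec$dilation
      r <- r + (d$r_p - spec$r0) * exp(-(s - d$s_c)^2 / (2 * d$sigma^2))
    }
    r
  }
}

synthetic_curve_points <- function(curve, ds) {
  L <- curve$length
  n <- max(2L, ceiling(L / ds) + 1L)
  s <- seq(0, L, length.out = n)
  switch(curve$type,
    straight = cbind(0, 0, s),
    arc = {
      Rb <- curve$bend_radius
      th <- s / Rb
      cbind(Rb * sin(th), 0, Rb * (1 - cos(th)))
    },
    helix = {
      a <- curve$helix_radius
      c2 <- curve$pitch / (2 * pi)
      # arc length per unit angle
      k <- sqrt(a^2 + c2^2)
      th <- s / k
      cbind(a * cos(th), a * sin(th), c2 * th)
    },
    stop("unknown curve type: ", curve$type))
}

#' Generate a synthetic vessel phantom with ground truth
#'
#' Builds a surface of revolution around the requested centerline with the
#' spec's radius law, returning the mesh, the ground-truth centerline and
#' the analytic radius/area profile. All randomness (vertex jitter) is
#' seeded; identical seeds give bit-identical fixtures.
#'
#' @param spec a `vessel_spec`.
#' @param seed integer seed for the jitter stream (ignored when
#'   `spec$jitter == 0` apart from determinism bookkeeping).
#' @return list with `mesh` (`surface_mesh`), `centerline` (`centerline`),
#'   `truth` (data.frame s, r, area of the generated radius law),
#'   `radius_law` (function of s), `spec`, `seed`.
#' @export
make_vessel <- function(spec, seed = 1L) {
  rl <- vessel_radius_law(spec)
  L <- spec$curve$length
  r_max <- max(rl(seq(0, L, length.out = 512L)))
  if (identical(spec$curve$type, "arc") && spec$curve$bend_radius <= r_max)
    stop("self-intersecting spec: bend radius below peak lumen radius")
  if (identical(spec$curve$type, "helix") &&
      spec$curve$helix_radius <= r_max)
    stop("self-intersecting spec: helix radius below peak lumen radius")
  ds <- spec$edge_length
  pts <- synthetic_curve_points(spec$curve, ds)
  cl <- centerline(pts)
  n_ax <- nrow(pts)
  n_circ <- max(12L, ceiling(2 * pi * spec$r0 / spec$edge_length))
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  r_s <- rl(cl$s)
  verts <- matrix(0, n_ax * n_circ, 3L)
  for (i in seq_len(n_ax)) {
    ring <- matrix(cl$points[i, ], n_circ, 3L, byrow = TRUE) +
      r_s[i] * (outer(cos(theta), cl$normal1[i, ]) +
                outer(sin(theta), cl$normal2[i, ]))
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }
  if (spec$jitter > 0) {
    amp <- spec$jitter * spec$edge_length
    verts <- verts + with_seed(seed, matrix(
      stats::runif(length(verts), -amp, amp), nrow(verts), 3L))
  }
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  tris <- matrix(0L, 2L * (n_ax - 1L) * n_circ, 3L)
  k <- 1L
  for (i in seq_len(n_ax - 1L)) {
    j <- seq_len(n_circ)
    a <- idx(i, j); b <- idx(i, j + 1L)
    cc <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
    rows <- k:(k + 2L * n_circ - 1L)
    tris[rows, ] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
    k <- k + 2L * n_circ
  }
  mesh <- surface_mesh(verts, tris, validate = FALSE)
  truth <- data.frame(s = cl$s, r = r_s, area = pi * r_s^2)
  list(mesh = mesh, centerline = cl, truth = truth, radius_law = rl,
       spec = spec, seed = seed)
}

#' Synthetic representative cardiac inflow waveform
#'
#' Two-harmonic stand-in for a measured cerebral inflow curve:
#' `Q(t) = Q0 * (1 + a1 sin(2 pi t / T + phi1) + a2 sin(4 pi t / T + phi2))`.
#' This is explicitly a synthetic waveform, not a published measurement;
#' the default amplitudes give a realistic pulsatility index (~1.1) while
#' keeping the flow strictly positive.
#'
#' @param T cardiac period (s), default 1.0.
#' @param Q0 mean flow (mL/s), default 3 (vertebral/basilar scale).
#' @param a1,a2 relative harmonic amplitudes (defaults 0.4, 0.15).
#' @param phi1,phi2 harmonic phases (defaults 0, pi/4).
#' @param n samples per period (uniform, spanning [0, T)).
#' @param profile waveform family; only "two_harmonic_cardiac" is defined.
#' @return object of class `waveform`: list(times, values, T).
#' @export
reference_waveform <- function(T = 1.0, Q0 = 3.0, a1 = 0.4, a2 = 0.15,
                               phi1 = 0, phi2 = pi / 4, n = 64L,
                               profile = "two_harmonic_cardiac") {
  if (T <= 0) stop("period must be positive")
  if (!identical(profile, "two_harmonic_cardiac"))
    stop("unknown waveform profile")
  t <- T * (seq_len(n) - 1L) / n
  q <- Q0 * (1 + a1 * sin(2 * pi * t / T + phi1) +
                 a2 * sin(4 * pi * t / T + phi2))
  if (any(q <= 0)) stop("waveform parameters drive the flow non-positive")
  waveform(t, q, T)
}

#' Pulsatile straight-tube flow specification (Womersley)
#'
#' @param R tube radius (mm).
#' @param T period (s).
#' @param Q0 mean flow (mL/s).
#' @param harmonics list of list(k = harmonic number, amp = relative
#'   amplitude of Q0, phase = radians), matching the reference-waveform
#'   convention `amp * sin(2 pi k t / T + phase)`.
#' @param rho blood density (kg/m^3), default 1055.
#' @param mu dynamic viscosity (Pa s), default 0.004.
#' @return object of class `pulsatile_spec` with derived Womersley number
#'   `alpha = R * sqrt(2 pi rho / (T mu))` (fundamental harmonic).
#' @export
pulsatile_spec <- function(R = 2, T = 1.0, Q0 = 3.0,
                           harmonics = list(list(k = 1, amp = 0.4, phase = 0),
                                            list(k = 2, amp = 0.15,
                                                 phase = pi / 4)),
                           rho = 1055, mu = 0.004) {
  if (Q0 <= 0) stop("mean flow must be positive")
  R_m <- R * 1e-3
  alpha <- R_m * sqrt(2 * pi * rho / (T * mu))
  structure(list(R = R, T = T, Q0 = Q0, harmonics = harmonics,
                 rho = rho, mu = mu, alpha = alpha),
            class = "pulsatile_spec")
}

# complex Bessel J0/J1 by power series (|z| <= ~21 in double precision)
besselJ0c <- function(z) {
  out <- term <- rep(1 + 0i, length(z))
  m <- -z^2 / 4
  for (k in 1:200) {
    term <- term * m / k^2
    out <- out + term
    if (max(abs(term)) < 1e-17 * max(abs(out))) break
  }
  out
}

besselJ1c <- function(z) {
  term <- z / 2
  out <- term
  m <- -z^2 / 4
  for (k in 1:200) {
    term <- term * m / (k * (k + 1))
    out <- out + term
    if (max(abs(term)) < 1e-17 * max(abs(out))) break
  }
  out
}

# Womersley velocity shape factor f(y) with int f dA = pi R^2, i.e.
# u = (Q/(pi R^2)) f(y).  For alpha > 21 the power series loses precision
# and the Stokes-layer asymptotic form is used instead.
womersley_shape <- function(y, alpha) {
  lam <- alpha * exp(3i * pi / 4)
  if (alpha <= 21) {
    j0l <- besselJ0c(lam)
    den <- 1 - 2 * besselJ1c(lam) / (lam * j0l)
    (1 - besselJ0c(lam * y) / j0l) / den
  } else {
    den <- 1 - 2i / lam
    core <- 1 - ifelse(y > 0, y^(-1 / 2), 0) *
      exp(-(1 - y) * alpha * (1 + 1i) / sqrt(2))
    core[y == 0] <- 1
    core / den
  }
}

# d f/dy at y = 1 (wall), same normalization
womersley_wall_slope <- function(alpha) {
  lam <- alpha * exp(3i * pi / 4)
  if (alpha <= 21) {
    j0l <- besselJ0c(lam)
    den <- 1 - 2 * besselJ1c(lam) / (lam * j0l)
    (lam * besselJ1c(lam) / j0l) / den
  } else {
    den <- 1 - 2i / lam
    (lam * 1i) / den
  }
}

#' Analytic Womersley pulsatile fields in a straight rigid tube
#'
#' Produces a `volume_series` (axial velocity sampled on a polar grid over
#' the tube cross-section, replicated at a few axial stations) and a
#' `wall_series` (the matching analytic wall shear stress) for the given
#' pulsatile specification. The steady harmonic is the Poiseuille profile;
#' each oscillatory harmonic uses the analytic Womersley solution. Two full
#' cardiac cycles are emitted so the discard-first-cycle adapter
#' ([last_cycle()]) is exercised exactly as in a solver hand-off.
#'
#' @param p a `pulsatile_spec`; its Womersley number must lie in (0, 50].
#' @param n_r radial samples (cell-centred), default 24.
#' @param n_theta circumferential samples, default 16.
#' @param n_axial axial stations, default 3 (fields are axially invariant).
#' @param timesteps timesteps per cycle (>= 16), default 32.
#' @return list(`volume` = `volume_series`, `wall` = `wall_series`,
#'   `waveform` = the flow waveform Q(t) (mL/s) over the two cycles,
#'   `alpha`).  Velocities are in m/s, WSS in Pa, coordinates in mm.
#' @export
womersley_fields <- function(p, n_r = 24L, n_theta = 16L, n_axial = 3L,
                             timesteps = 32L) {
  if (timesteps < 16L) stop("timesteps must be >= 16")
  if (p$alpha <= 0 || p$alpha > 50)
    stop("alpha outside validated range (0, 50]")
  R_m <- p$R * 1e-3
  nt <- 2L * timesteps
  times <- p$T * (seq_len(nt) - 1L) / timesteps
  # complex flow amplitudes: amp*Q0*sin(k w t + phase) (mL/s -> m^3/s)
  Q0_si <- p$Q0 * 1e-6
  y <- ((seq_len(n_r) - 0.5) / n_r)             # cell-centred radii
  r_mm <- y * p$R
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  z_mm <- seq(0, 2 * p$R, length.out = n_axial)
  # volume sample points (mm) and quadrature weights (mm^3)
  pts <- as.matrix(expand.grid(ir = seq_len(n_r), it = seq_len(n_theta),
                               iz = seq_len(n_axial)))
  px <- r_mm[pts[, 1]] * cos(theta[pts[, 2]])
  py <- r_mm[pts[, 1]] * sin(theta[pts[, 2]])
  pz <- z_mm[pts[, 3]]
  points <- cbind(x = px, y = py, z = pz)
  dz <- if (n_axial > 1L) diff(z_mm)[1L] else 1
  w_area <- r_mm[pts[, 1]] * (p$R / n_r) * (2 * pi / n_theta)   # mm^2
  weights <- w_area * dz                                         # mm^3
  # per-point complex velocity amplitude per harmonic
  npts <- nrow(points)
  u_steady <- (2 * Q0_si / (pi * R_m^2)) * (1 - y[pts[, 1]]^2)   # m/s
  v <- array(0, dim = c(npts, 3L, nt))
  tau0 <- 4 * p$mu * Q0_si / (pi * R_m^3)                        # Pa
  wall_n <- n_theta * n_axial
  wpts <- as.matrix(expand.grid(it = seq_len(n_theta), iz = seq_len(n_axial)))
  wall_centers <- cbind(p$R * cos(theta[wpts[, 1]]),
                        p$R * sin(theta[wpts[, 1]]),
                        z_mm[wpts[, 2]])
  wall_areas <- rep(p$R * (2 * pi / n_theta) * dz, wall_n)       # mm^2
  tau <- array(0, dim = c(wall_n, 3L, nt))
  u_t <- matrix(rep(u_steady, nt), npts, nt)
  tau_t <- matrix(tau0, wall_n, nt)
  q_t <- rep(p$Q0, nt)
  for (h in p$harmonics) {
    w_k <- 2 * pi * h$k / p$T
    alpha_k <- R_m * sqrt(w_k * p$rho / p$mu)
    if (alpha_k > 50) stop("alpha outside validated range (0, 50]")
    Qc <- h$amp * Q0_si * exp(1i * (h$phase - pi / 2))
    shape <- womersley_shape(y[pts[, 1]], alpha_k)
    slope <- womersley_wall_slope(alpha_k)
    phase_t <- exp(1i * w_k * times)
    u_t <- u_t + Re(outer((Qc / (pi * R_m^2)) * shape, phase_t))
    tau_t <- tau_t +
      Re(outer(rep(-p$mu * (Qc / (pi * R_m^2)) * slope / R_m, wall_n),
               phase_t))
    q_t <- q_t + Re(Qc * phase_t) * 1e6
  }
  v[, 3L, ] <- u_t
  tau[, 3L, ] <- tau_t
  vol <- volume_series(points, v, times, T = p$T, rho = p$rho,
                       weights = weights)
  wall <- wall_series(wall_centers, tau, times, T = p$T,
                      areas = wall_areas)
  list(volume = vol, wall = wall,
       waveform = waveform(times, q_t, 2 * p$T),
       alpha = p$alpha)
}
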