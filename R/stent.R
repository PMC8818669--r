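#' Braided flow-diverter specification
#'
#' Nominal device parameters. The braid angle `beta0` (to the stent axis)
#' is not part of published sizing tables and defaults to 75 degrees, a
#' typical value for densely braided flow diverters; it controls the
#' pitch/diameter coupling `p(d)^2 + (pi d)^2 = l_t^2`.
#'
#' @param L_nom nominal length (mm).
#' @param D_nom nominal diameter (mm).
#' @param N_w number of wires (even).
#' @param t_s strut thickness (micrometres).
#' @param beta0 nominal braid angle to the axis (degrees, 0 < beta0 < 90).
#' @return object of class `stent_spec` with derived `p0` (nominal pitch
#'   per turn, mm), `l_t` (wire length per turn, mm), `d_max = l_t / pi`
#'   (over-expansion limit, mm) and `N_t = L_nom / p0` (turn count).
#' @export
stent_spec <- function(L_nom, D_nom, N_w, t_s, beta0 = 75) {
  if (L_nom <= 0 || D_nom <= 0) stop("L_nom and D_nom must be positive")
  if (N_w %% 2L != 0L || N_w < 2L) stop("N_w must be even and >= 2")
  if (t_s <= 0) stop("strut thickness must be positive")
  if (beta0 <= 0 || beta0 >= 90) stop("beta0 must be in (0, 90) degrees")
  b <- beta0 * pi / 180
  p0 <- pi * D_nom / tan(b)
  l_t <- pi * D_nom / sin(b)
  structure(list(L_nom = L_nom, D_nom = D_nom, N_w = as.integer(N_w),
                 t_s = t_s, t_s_mm = t_s * 1e-3, beta0 = beta0,
                 p0 = p0, l_t = l_t, d_max = l_t / pi, N_t = L_nom / p0),
            class = "stent_spec")
}

#' @export
print.stent_spec <- function(x, ...) {
  cat(sprintf(
    "<stent_spec> L %.4g mm, D %.4g mm, %d wires, %g um struts, beta0 %g deg (p0 %.3f mm, l_t %.3f mm)\n",
    x$L_nom, x$D_nom, x$N_w, x$t_s, x$beta0, x$p0, x$l_t))
  invisible(x)
}

# shared wire construction: given per-sample axial station s_j (mm along a
# centerline), diameter d_j (mm) and braid phase phi_j, build N_w helical
# wire polylines in the frames of `cl` (or on the straight +z axis when
# cl is NULL). Wire centerlines sit exactly on the d/2 cylinder so the
# pitch/diameter kinematics and the wire-length budget are consistent; the
# 42 um strut radius is accounted for in the apposition gap instead.
build_wires <- function(spec, s_samp, d_samp, phi_samp, cl = NULL) {
  half <- spec$N_w %/% 2L
  offs <- 2 * pi * (seq_len(half) - 1L) / half
  r_w <- d_samp / 2
  if (is.null(cl)) {
    origin <- cbind(0, 0, s_samp)
    n1 <- matrix(c(1, 0, 0), length(s_samp), 3L, byrow = TRUE)
    n2 <- matrix(c(0, 1, 0), length(s_samp), 3L, byrow = TRUE)
  } else {
    frames <- lapply(s_samp, function(s) local_frame(cl, s))
    origin <- t(vapply(frames, `[[`, numeric(3), "origin"))
    n1 <- t(vapply(frames, `[[`, numeric(3), "normal1"))
    n2 <- t(vapply(frames, `[[`, numeric(3), "normal2"))
  }
  wires <- vector("list", spec$N_w)
  sign_of <- integer(spec$N_w)
  for (i in seq_len(spec$N_w)) {
    hand <- if (i <= half) 1 else -1
    off <- offs[((i - 1L) %% half) + 1L]
    ang <- hand * phi_samp + off
    wires[[i]] <- origin + r_w * (cos(ang) * n1 + sin(ang) * n2)
    sign_of[i] <- hand
  }
  list(wires = wires, sign = sign_of, origin = origin)
}

polyline_length <- function(m) {
  d <- m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Nominal (straight, fully expanded) stent template
#'
#' `N_w` helical wires on a cylinder of diameter `D_nom`, half of each
#' handedness, spanning exactly `L_nom` axially with nominal pitch
#' `p0 = pi D / tan(beta0)` and wire length per turn `l_t = pi D /
#' sin(beta0)`.
#'
#' @param spec a `stent_spec`.
#' @param points_per_turn helix sampling density (default 72; length
#'   discretization error ~ (2 pi / ppt)^2 / 24).
#' @return object of class `deployed_stent`; see [deploy_stent()].
#' @export
stent_template <- function(spec, points_per_turn = 72L) {
  n_samp <- max(2L, ceiling(spec$N_t * points_per_turn) + 1L)
  phi <- seq(0, 2 * pi * spec$N_t, length.out = n_samp)
  z <- spec$p0 * phi / (2 * pi)
  # template wires sit exactly on the D_nom cylinder (no strut offset):
  # the nominal configuration is the manufacturer's free-expansion state
  bw <- build_wires(spec, s_samp = z, d_samp = rep(spec$D_nom, n_samp),
                    phi_samp = phi, cl = NULL)
  turns <- data.frame(s = z, d = spec$D_nom, p = spec$p0)
  structure(list(spec = spec, wire_paths = bw$wires, wire_sign = bw$sign,
                 s_samp = z, d_samp = rep(spec$D_nom, n_samp),
                 p_samp = rep(spec$p0, n_samp),
                 L_dep = spec$L_nom, l_t = spec$l_t, p0 = spec$p0,
                 N_t = spec$N_t, points_per_turn = points_per_turn,
                 nominal = TRUE),
            class = "deployed_stent")
}

#' @export
print.deployed_stent <- function(x, ...) {
  cat(sprintf(
    "<deployed_stent> %d wires, %.2f turns, L_dep %.2f mm, d in [%.2f, %.2f] mm\n",
    length(x$wire_paths), x$N_t, x$L_dep, min(x$d_samp), max(x$d_samp)))
  invisible(x)
}

#' Total discrete wire length of a stent (mm)
#' @param stent a `deployed_stent`.
#' @return numeric scalar.
#' @export
wire_length <- function(stent) {
  sum(vapply(stent$wire_paths, polyline_length, numeric(1)))
}

#' Deploy a braided stent in a vessel (fast virtual stenting)
#'
#' Centerline-sweep deployment with wire-length conservation. Marching
#' proximally from the distal landing station `s_distal`, each braid turn
#' takes the local deployed diameter `d = min(lumen d_eq, D_nom)` and the
#' pitch `p(d) = sqrt(l_t^2 - (pi d)^2)` that conserves the wire length per
#' turn, until the template's turn count `N_t = L_nom / p0` is exhausted.
#' Narrow lumina therefore elongate the device and wide lumina shorten it
#' (vessel-induced shortening/elongation). Wires are generated as helices
#' of the locally-sized tube following the rotation-minimizing centerline
#' frames, with wire centerlines exactly on the `d/2` cylinder (the strut
#' radius enters the apposition gap, not the kinematics).
#'
#' @param spec a `stent_spec`.
#' @param mesh `surface_mesh` of the lumen (used to profile `d_eq(s)`
#'   unless `profile` is given).
#' @param cl matching `centerline`.
#' @param s_distal distal landing station (mm arc length).
#' @param profile optional precomputed `csa_profile` (saves the ray-cast).
#' @param spacing,n_rays profiling parameters when `profile` is NULL.
#' @param points_per_turn helix sampling density (default 72).
#' @param on_overexpansion behavior when the lumen exceeds the braid's
#'   over-expansion limit `d_max = l_t / pi` somewhere in the landing zone:
#'   `"error"` (the strict contract) or `"cap"` (deploy at `D_nom` and let
#'   [apposition_map()] report the malapposition - the realistic treatment
#'   scenario for a wide fusiform bulge).
#' @return object of class `deployed_stent`: wire polylines (`wire_paths`),
#'   per-sample station `s_samp`, local diameter `d_samp`, local pitch
#'   `p_samp`, deployed length `L_dep`, and the kinematic constants `l_t`,
#'   `p0`, `N_t`.
#' @export
deploy_stent <- function(spec, mesh, cl, s_distal, profile = NULL,
                         spacing = 0.25, n_rays = 90L,
                         points_per_turn = 72L,
                         on_overexpansion = c("error", "cap")) {
  on_overexpansion <- match.arg(on_overexpansion)
  if (is.null(profile))
    profile <- csa_profile(mesh, cl, spacing = spacing, n_rays = n_rays)
  d_eq_at <- function(s) approx(profile$s, profile$d_eq, xout = s,
                                rule = 2)$y
  if (s_distal > max(profile$s) + profile$spacing ||
      s_distal < min(profile$s))
    stop("s_distal outside the profiled vessel")
  n_samp <- max(2L, ceiling(spec$N_t * points_per_turn) + 1L)
  phi <- seq(0, 2 * pi * spec$N_t, length.out = n_samp)
  dphi <- diff(phi)[1L]
  s_samp <- numeric(n_samp)
  d_samp <- numeric(n_samp)
  p_samp <- numeric(n_samp)
  s_cur <- s_distal
  for (j in seq_len(n_samp)) {
    d_lum <- d_eq_at(s_cur)
    if (d_lum >= spec$d_max && on_overexpansion == "error")
      stop("stent cannot appose: over-expansion limit")
    d_j <- min(d_lum, spec$D_nom)
    p_j <- sqrt(spec$l_t^2 - (pi * d_j)^2)
    s_samp[j] <- s_cur
    d_samp[j] <- d_j
    p_samp[j] <- p_j
    if (j < n_samp) {
      s_cur <- s_cur - p_j * dphi / (2 * pi)
      if (s_cur < min(profile$s) - profile$spacing)
        stop("landing zone shorter than achievable deployed length")
    }
  }
  L_dep <- s_samp[1L] - s_samp[n_samp]
  bw <- build_wires(spec, s_samp = rev(s_samp), d_samp = rev(d_samp),
                    phi_samp = rev(max(phi) - phi), cl = cl)
  structure(list(spec = spec, wire_paths = bw$wires, wire_sign = bw$sign,
                 s_samp = rev(s_samp), d_samp = rev(d_samp),
                 p_samp = rev(p_samp), L_dep = L_dep, l_t = spec$l_t,
                 p0 = spec$p0, N_t = spec$N_t,
                 points_per_turn = points_per_turn,
                 s_distal = s_distal, nominal = FALSE),
            class = "deployed_stent")
}

#' Wall apposition map of a deployed stent
#'
#' For every wire point, the gap to the wall is the distance to the nearest
#' wall vertex minus half the strut thickness (wire-surface to wall).
#' Points with gap above `threshold` are flagged malapposed. The search is
#' exact over wall vertices, pre-filtered by axial station bins for speed.
#'
#' @param stent a `deployed_stent` from [deploy_stent()].
#' @param mesh the `surface_mesh` it was deployed in.
#' @param cl matching `centerline` (for the axial binning).
#' @param threshold malapposition threshold (mm), default 0.25 (order of
#'   the imaging resolution).
#' @param stride evaluate every `stride`-th wire point (default 1L).
#' @return list(gaps (per evaluated point, mm), malapposed (logical),
#'   max_gap, malapposed_fraction, threshold, s (station per point)).
#' @export
apposition_map <- function(stent, mesh, cl, threshold = 0.25, stride = 1L) {
  feet <- centerline_feet(mesh$vertices, cl)
  pick <- seq(1L, length(stent$s_samp), by = stride)
  wp <- do.call(rbind, lapply(stent$wire_paths, function(w)
    w[pick, , drop = FALSE]))
  wp_s <- rep(stent$s_samp[pick], times = length(stent$wire_paths))
  bin_w <- 1.0   # mm axial bins
  vbin <- floor(feet$s / bin_w)
  pbin <- floor(wp_s / bin_w)
  gaps <- rep(NA_real_, nrow(wp))
  for (b in sort(unique(pbin))) {
    pi_ <- which(pbin == b)
    vi <- which(vbin >= b - 2L & vbin <= b + 2L)
    if (length(vi) == 0L) vi <- seq_len(nrow(mesh$vertices))
    vv <- mesh$vertices[vi, , drop = FALSE]
    for (k in pi_) {
      d2 <- (vv[, 1] - wp[k, 1])^2 + (vv[, 2] - wp[k, 2])^2 +
            (vv[, 3] - wp[k, 3])^2
      gaps[k] <- sqrt(min(d2))
    }
  }
  # wire-surface to wall gap; a negative raw value means the strut radius
  # overlaps the wall sample, i.e. contact -> physical gap zero
  gaps <- pmax(gaps - stent$spec$t_s_mm / 2, 0)
  mal <- gaps > threshold
  list(gaps = gaps, malapposed = mal, max_gap = max(gaps),
       malapposed_fraction = mean(mal), threshold = threshold, s = wp_s)
}

#' Metal coverage fraction of a deployed stent segment
#'
#' Strut footprint area (wire length x strut width, corrected for the
#' rhombic overlap at wire crossings) divided by the lateral surface of the
#' covered tube segment. The crossing overlap of two struts of width `t_s`
#' meeting at the local braid crossing angle `gamma = pi - 2 beta(d)` is
#' `t_s^2 / sin(2 beta)`; each braid turn carries `N_w^2 / 2` crossings.
#'
#' @param stent a `deployed_stent`.
#' @param s_start,s_end axial segment (mm stations, within the stent).
#' @return coverage fraction in (0, 1).
#' @export
metal_coverage <- function(stent, s_start, s_end) {
  s <- stent$s_samp
  if (s_start < min(s) - 1e-9 || s_end > max(s) + 1e-9 || s_start >= s_end)
    stop("segment outside stent")
  mid <- (s[-1L] + s[-length(s)]) / 2
  dseg <- abs(diff(s))
  inseg <- mid >= s_start & mid <= s_end
  if (!any(inseg)) stop("segment outside stent")
  d_mid <- (stent$d_samp[-1L] + stent$d_samp[-length(s)]) / 2
  p_mid <- (stent$p_samp[-1L] + stent$p_samp[-length(s)]) / 2
  spec <- stent$spec
  t_s <- spec$t_s_mm
  # per axial slice ds: wire length = N_w * l_t * ds / p; crossings
  # = (N_w^2/2) * ds / p; local braid angle from sin(beta) = pi d / l_t
  ds <- dseg[inseg]
  dm <- d_mid[inseg]; pm <- p_mid[inseg]
  wl <- sum(spec$N_w * stent$l_t * ds / pm)
  sin_beta <- pi * dm / stent$l_t
  sin_2beta <- 2 * sin_beta * sqrt(pmax(1 - sin_beta^2, 1e-12))
  ncross_ds <- (spec$N_w^2 / 2) * ds / pm
  overlap <- sum(ncross_ds * t_s^2 / sin_2beta)
  lateral <- sum(pi * dm * ds)
  cov <- (wl * t_s - overlap) / lateral
  min(max(cov, 0), 1)
}

#' Export stent wires as a long CSV (wire, x, y, z)
#' @param stent a `deployed_stent`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stent_csv <- function(stent, path) {
  dt <- data.table::rbindlist(lapply(seq_along(stent$wire_paths), function(i) {
    w <- stent$wire_paths[[i]]
    data.table::data.table(wire = i, x = w[, 1], y = w[, 2], z = w[, 3])
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Render stent wires as a tube surface mesh
#'
#' Sweeps a polygonal tube of diameter `t_s` along every wire; intended for
#' visualization/export (STL/OBJ), not for analysis.
#'
#' @param stent a `deployed_stent`.
#' @param sides tube cross-section sides (default 6).
#' @param stride use every `stride`-th wire sample (default 2).
#' @return a `surface_mesh` (unvalidated union of open tubes).
#' @export
stent_tube_mesh <- function(stent, sides = 6L, stride = 2L) {
  r <- stent$spec$t_s_mm / 2
  all_v <- list(); all_t <- list(); off <- 0L
  th <- 2 * pi * (seq_len(sides) - 1L) / sides
  for (w in stent$wire_paths) {
    pts <- w[seq(1L, nrow(w), by = stride), , drop = FALSE]
    fr <- rmf_frames(pts)
    n <- nrow(pts)
    verts <- matrix(0, n * sides, 3L)
    for (i in seq_len(n)) {
      verts[(i - 1L) * sides + seq_len(sides), ] <-
        matrix(pts[i, ], sides, 3L, byrow = TRUE) +
        r * (outer(cos(th), fr$normal1[i, ]) +
             outer(sin(th), fr$normal2[i, ]))
    }
    idx <- function(i, j) off + (i - 1L) * sides + ((j - 1L) %% sides) + 1L
    tris <- list()
    for (i in seq_len(n - 1L)) {
      j <- seq_len(sides)
      tris[[i]] <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
                         cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
    }
    all_v[[length(all_v) + 1L]] <- verts
    all_t[[length(all_t) + 1L]] <- do.call(rbind, tris)
    off <- off + n * sides
  }
  surface_mesh(do.call(rbind, all_v), do.call(rbind, all_t),
               validate = FALSE)
}

#' JSON deployment summary (deployed length, diameter range, apposition,
#' coverage)
#' @param stent a `deployed_stent`.
#' @param path output JSON path.
#' @param apposition optional result of [apposition_map()].
#' @param coverage optional result of [metal_coverage()].
#' @return `path`, invisibly.
#' @export
write_stent_json <- function(stent, path, apposition = NULL,
                             coverage = NULL) {
  jsonlite::write_json(
    list(L_dep = stent$L_dep, d_min = min(stent$d_samp),
         d_max = max(stent$d_samp), N_t = stent$N_t, l_t = stent$l_t,
         p0 = stent$p0,
         malapposed_fraction = apposition$malapposed_fraction,
         max_gap = apposition$max_gap, coverage = coverage),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
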