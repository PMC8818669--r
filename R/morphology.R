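#' Cross-sectional area by perpendicular ray casting
#'
#' Casts `n_rays` rays from the frame origin, uniformly spaced in angle
#' within the plane perpendicular to the centerline tangent, records the
#' first outward intersection of each ray with the lumen wall, and computes
#' the enclosed area as the fan polygon of the ordered hit points about the
#' origin. This follows the elliptic-section-aware convention of profiling
#' the lumen by rays rather than by a mesh/plane contour, so nearby side
#' branches do not contaminate the section.
#'
#' @param mesh a `surface_mesh` (outward-oriented lumen wall).
#' @param frame a `frame` from [local_frame()] whose origin lies strictly
#'   inside the lumen.
#' @param n_rays number of rays (>= 8; default 360).
#' @return object of class `cross_section`: list(s = NA or station,
#'   hit_points (n_rays x 3), radii, area (mm^2), d_eq (mm)).
#' @export
cross_section_area <- function(mesh, frame, n_rays = 360L) {
  if (n_rays < 8L) stop("n_rays must be >= 8")
  v <- mesh$vertices
  tr <- mesh$triangles
  o <- frame$origin
  # plane prefilter: only triangles straddling the section plane can be hit
  dist <- (v[, 1] - o[1]) * frame$tangent[1] +
          (v[, 2] - o[2]) * frame$tangent[2] +
          (v[, 3] - o[3]) * frame$tangent[3]
  d1 <- dist[tr[, 1L]]; d2 <- dist[tr[, 2L]]; d3 <- dist[tr[, 3L]]
  eps <- 1e-9
  keep <- (pmin(d1, d2, d3) <= eps) & (pmax(d1, d2, d3) >= -eps)
  if (!any(keep)) stop("section crosses open boundary")
  tk <- tr[keep, , drop = FALSE]
  p0 <- v[tk[, 1L], , drop = FALSE]
  e1 <- v[tk[, 2L], , drop = FALSE] - p0
  e2 <- v[tk[, 3L], , drop = FALSE] - p0
  # outward triangle normals of candidates (orientation sign for interiority)
  ncand <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  dirs <- outer(cos(theta), frame$normal1) + outer(sin(theta), frame$normal2)
  hits <- matrix(NA_real_, n_rays, 3L)
  radii <- rep(NA_real_, n_rays)
  to_o <- cbind(o[1] - p0[, 1], o[2] - p0[, 2], o[3] - p0[, 3])
  for (k in seq_len(n_rays)) {
    d <- dirs[k, ]
    # Moller-Trumbore, vectorized over candidate triangles
    h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    a <- rowSums(e1 * h)
    ok <- abs(a) > 1e-14
    f <- ifelse(ok, 1 / a, NA_real_)
    u <- f * rowSums(to_o * h)
    q <- cbind(to_o[, 2] * e1[, 3] - to_o[, 3] * e1[, 2],
               to_o[, 3] * e1[, 1] - to_o[, 1] * e1[, 3],
               to_o[, 1] * e1[, 2] - to_o[, 2] * e1[, 1])
    vv <- f * (d[1] * q[, 1] + d[2] * q[, 2] + d[3] * q[, 3])
    tt <- f * rowSums(e2 * q)
    valid <- ok & !is.na(u) & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 &
      tt > 1e-9
    if (!any(valid)) next    # miss: classified after the loop
    i <- which(valid)[which.min(tt[valid])]
    if (sum(ncand[i, ] * d) < 0) stop("origin not interior")
    radii[k] <- tt[i]
    hits[k, ] <- o + tt[i] * d
  }
  if (anyNA(radii)) {
    # a miss means either the origin is outside the lumen or the ray left
    # through an open inlet/outlet; disambiguate by whether a boundary ring
    # comes near the section plane at the scale of the hit radii
    bverts <- unlist(mesh$boundary_loops)
    r_scale <- if (all(is.na(radii))) Inf else
      2 * median(radii, na.rm = TRUE)
    near_bnd <- length(bverts) > 0L &&
      min(abs(dist[bverts])) < r_scale
    if (is.finite(r_scale) && near_bnd)
      stop("section crosses open boundary")
    stop("origin not interior")
  }
  # planar polygon area in frame coordinates (hits lie exactly in the plane)
  x <- radii * cos(theta)
  y <- radii * sin(theta)
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  area <- 0.5 * abs(sum(x * yn - xn * y))
  structure(list(s = NA_real_, hit_points = hits, radii = radii,
                 area = area, d_eq = equivalent_diameter(area)),
            class = "cross_section")
}

#' Cross-sectional-area profile along a centerline
#'
#' Stations are placed at uniform `spacing` along the centerline; stations
#' within one spacing of either centerline end are skipped (open-boundary
#' guard). Individual station failures are tolerated and logged; more than
#' 20% failures aborts.
#'
#' @param mesh a `surface_mesh`.
#' @param cl a `centerline` interior to the mesh.
#' @param spacing station spacing (mm; default 0.25).
#' @param n_rays rays per station (default 360).
#' @param keep_hits retain per-station hit points (default FALSE to save
#'   memory on long vessels).
#' @return object of class `csa_profile`: list(s, area, d_eq vectors ordered
#'   by s; spacing; n_rays; skipped (stations that failed, with messages);
#'   sections (optional list of `cross_section`)).
#' @export
csa_profile <- function(mesh, cl, spacing = 0.25, n_rays = 360L,
                        keep_hits = FALSE) {
  clr <- resample_centerline(cl, spacing)
  L <- total_length(clr)
  s_all <- clr$s
  use <- s_all >= (s_all[1L] + spacing - 1e-9) &
         s_all <= (s_all[length(s_all)] - spacing + 1e-9)
  s_st <- s_all[use]
  if (length(s_st) == 0L) stop("centerline too short for spacing")
  res_s <- res_a <- numeric(0)
  sections <- list()
  skipped <- character(0)
  for (s in s_st) {
    fr <- local_frame(clr, s)
    cs <- tryCatch(cross_section_area(mesh, fr, n_rays = n_rays),
                   error = function(e) e)
    if (inherits(cs, "error")) {
      skipped <- c(skipped, sprintf("s=%.3f: %s", s, conditionMessage(cs)))
      next
    }
    cs$s <- s
    res_s <- c(res_s, s)
    res_a <- c(res_a, cs$area)
    if (keep_hits) sections[[length(sections) + 1L]] <- cs
  }
  if (length(skipped) > 0.2 * length(s_st)) stop("centerline/mesh mismatch")
  structure(list(s = res_s, area = res_a, d_eq = equivalent_diameter(res_a),
                 spacing = spacing, n_rays = n_rays, skipped = skipped,
                 sections = if (keep_hits) sections else NULL),
            class = "csa_profile")
}

#' Build a CSA profile from precomputed station values
#'
#' For profiles that come from an external tool or from analytic ground
#' truth rather than from ray casting (e.g. deploying a stent in a lumen of
#' exactly known diameter).
#'
#' @param s stations (mm), strictly increasing.
#' @param area areas (mm^2).
#' @param n_rays bookkeeping value (default NA).
#' @return a `csa_profile`.
#' @export
csa_profile_from_values <- function(s, area, n_rays = NA_integer_) {
  if (any(diff(s) <= 0)) stop("stations must be strictly increasing")
  if (any(area < 0)) stop("areas must be non-negative")
  structure(list(s = as.numeric(s), area = as.numeric(area),
                 d_eq = equivalent_diameter(area),
                 spacing = median(diff(s)), n_rays = n_rays,
                 skipped = character(0), sections = NULL),
            class = "csa_profile")
}

#' @export
print.csa_profile <- function(x, ...) {
  cat(sprintf(
    "<csa_profile> %d stations, s in [%.2f, %.2f] mm, CSA in [%.3f, %.3f] mm^2\n",
    length(x$s), min(x$s), max(x$s), min(x$area), max(x$area)))
  invisible(x)
}

#' Nominal (healthy parent-vessel) diameter from a profile
#'
#' Median equivalent diameter over the union of a proximal and a distal
#' window at the ends of the profile. The median makes the estimate robust
#' against a dilation that leaks into a window edge.
#'
#' @param profile a `csa_profile`.
#' @param proximal_window,distal_window window lengths (mm) measured inward
#'   from the first/last profiled station.
#' @return nominal diameter (mm).
#' @export
nominal_diameter <- function(profile, proximal_window, distal_window) {
  s <- profile$s
  sel <- s <= s[1L] + proximal_window | s >= s[length(s)] - distal_window
  if (!any(sel)) stop("empty nominal-diameter windows")
  median(profile$d_eq[sel])
}

#' Detect a fusiform dilation (Huber criterion)
#'
#' Finds contiguous runs of stations whose equivalent diameter exceeds
#' `huber_ratio` times the nominal diameter (default 1.5, the Huber
#' definition of an aneurysmal dilation). The run with the largest maximal
#' CSA is selected and extended outward to the stations where the diameter
#' first falls below `1.1 * d_nominal` (region bounds).
#'
#' @param profile a `csa_profile`.
#' @param d_nominal nominal vessel diameter (mm), > 0.
#' @param huber_ratio detection threshold ratio (default 1.5).
#' @return object of class `dilation_region`
#'   (s_start, s_end, s_max, ratio_max, i_start, i_end, other_runs),
#'   or `NULL` when no station exceeds the threshold.
#' @export
detect_fusiform <- function(profile, d_nominal, huber_ratio = 1.5) {
  if (d_nominal <= 0) stop("d_nominal must be positive")
  over <- profile$d_eq > huber_ratio * d_nominal
  if (!any(over)) return(NULL)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak_area <- vapply(runs, function(j)
    max(profile$area[starts[j]:ends[j]]), numeric(1))
  best <- runs[which.max(peak_area)]
  other <- setdiff(runs, best)
  lo <- starts[best]; hi <- ends[best]
  sub_thresh <- profile$d_eq < 1.1 * d_nominal
  i_start <- lo
  while (i_start > 1L && !sub_thresh[i_start]) i_start <- i_start - 1L
  i_end <- hi
  n <- length(profile$s)
  while (i_end < n && !sub_thresh[i_end]) i_end <- i_end + 1L
  i_pk <- lo - 1L + which.max(profile$area[lo:hi])
  structure(list(
    s_start = profile$s[i_start], s_end = profile$s[i_end],
    s_max = profile$s[i_pk],
    ratio_max = profile$d_eq[i_pk] / d_nominal,
    i_start = i_start, i_end = i_end, i_max = i_pk,
    d_nominal = d_nominal, huber_ratio = huber_ratio,
    other_runs = lapply(other, function(j)
      c(s_start = profile$s[starts[j]], s_end = profile$s[ends[j]]))),
    class = "dilation_region")
}

#' @export
print.dilation_region <- function(x, ...) {
  cat(sprintf(
    "<dilation_region> s in [%.2f, %.2f] mm, apex at s=%.2f, max d-ratio %.2f\n",
    x$s_start, x$s_end, x$s_max, x$ratio_max))
  invisible(x)
}

#' Morphology report (maximal CSA, parent-vessel CSA, relative increase)
#'
#' `CSA_A` is the maximal cross-sectional area inside the dilation region;
#' `CSA_PV` is the cross-sectional area of the parent vessel at the station
#' immediately proximal to the region (or the mean over a proximal window);
#' `RI = 100 * CSA_A / CSA_PV` is the relative increase in percent, reported
#' rounded to integer percent and stored unrounded.
#'
#' @param profile a `csa_profile`.
#' @param region a `dilation_region` within the profile.
#' @param reference `"proximal"` (single adjacent station, default) or
#'   `"proximal_mean"` (mean over `window` mm proximal to the region).
#' @param window window length (mm) for `"proximal_mean"`.
#' @return object of class `morphology_report`:
#'   list(CSA_A, CSA_PV, RI (unrounded %), RI_pct (integer %), s_max, s_ref).
#' @export
morphology_report <- function(profile, region,
                              reference = c("proximal", "proximal_mean"),
                              window = 2) {
  reference <- match.arg(reference)
  in_region <- profile$s >= region$s_start & profile$s <= region$s_end
  if (!any(in_region)) stop("region not within profile")
  CSA_A <- max(profile$area[in_region])
  i_ref_max <- region$i_start - 1L
  if (region$i_start <= 1L || i_ref_max < 1L) stop("no proximal reference")
  if (reference == "proximal") {
    CSA_PV <- profile$area[i_ref_max]
    s_ref <- profile$s[i_ref_max]
  } else {
    sel <- profile$s < region$s_start &
      profile$s >= region$s_start - window
    if (!any(sel)) stop("no proximal reference")
    CSA_PV <- mean(profile$area[sel])
    s_ref <- mean(profile$s[sel])
  }
  RI <- 100 * CSA_A / CSA_PV
  structure(list(CSA_A = CSA_A, CSA_PV = CSA_PV, RI = RI,
                 RI_pct = as.integer(round(RI)),
                 s_max = profile$s[region$i_max], s_ref = s_ref),
            class = "morphology_report")
}

#' @export
print.morphology_report <- function(x, ...) {
  cat(sprintf(
    "<morphology_report> max CSA_A %.2f mm^2, CSA_PV %.2f mm^2, RI %d%%\n",
    x$CSA_A, x$CSA_PV, x$RI_pct))
  invisible(x)
}

#' Export a CSA profile to CSV (s, CSA, d_eq)
#' @param profile a `csa_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(data.frame(s = profile$s, CSA = profile$area,
                       d_eq = profile$d_eq),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a morphology report as JSON (case, max CSA_A, CSA_PV, RI)
#' @param report a `morphology_report`.
#' @param path output JSON path.
#' @param case case label.
#' @return `path`, invisibly.
#' @export
write_morphology_json <- function(report, path, case = "case") {
  jsonlite::write_json(
    list(case = case, max_CSA_A_mm2 = report$CSA_A,
         CSA_PV_mm2 = report$CSA_PV, RI_pct = report$RI_pct,
         RI_unrounded = report$RI),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
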