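#' Target healthy-radius profile across a dilation region
#'
#' The target radius is a monotone cubic Hermite (smoothstep)
#' interpolation between measured equivalent radii at two anchor stations,
#' and equals the measured radius outside the anchored span, so the
#' profile is continuous at the anchors to machine precision.
#'
#' With `anchor = "nominal"` (default) the anchors are placed where the
#' measured diameter first comes within `anchor_tol` of the region's
#' nominal diameter, walking outward from the region bounds - i.e. the
#' vessel is shrunk toward the proximal and distal diameter of the
#' *healthy parent vessel*, and the modification span covers the full
#' support of the dilation. With `anchor = "region"` the anchors are the
#' dilation-region bounds themselves (which sit near 1.1x the nominal
#' diameter by construction, so the restored lumen retains that residual
#' dilation).
#'
#' @param profile a `csa_profile` of the diseased vessel.
#' @param region a `dilation_region` strictly inside the profile.
#' @param blend_margin margin (mm) around the span inside which smoothing
#'   may act during reconstruction (stored, default 0.5).
#' @param anchor `"nominal"` or `"region"` (see above).
#' @param anchor_tol relative diameter tolerance for `"nominal"` anchoring
#'   (default 0.015).
#' @return object of class `target_radius_profile`: list(s, r_target,
#'   region, s_mod_start, s_mod_end, blend_margin, anchor).
#' @export
target_radius_profile <- function(profile, region, blend_margin = 0.5,
                                  anchor = c("nominal", "region"),
                                  anchor_tol = 0.015) {
  anchor <- match.arg(anchor)
  s <- profile$s
  if (region$i_start <= 1L || region$i_end >= length(s))
    stop("region at profile end")
  r_meas <- profile$d_eq / 2
  ia <- region$i_start
  ib <- region$i_end
  if (anchor == "nominal") {
    thr <- (1 + anchor_tol) * region$d_nominal
    while (ia > 1L && profile$d_eq[ia] > thr) ia <- ia - 1L
    while (ib < length(s) && profile$d_eq[ib] > thr) ib <- ib + 1L
    if (profile$d_eq[ia] > thr || profile$d_eq[ib] > thr)
      stop("region at profile end")
  }
  r_p <- r_meas[ia]
  r_d <- r_meas[ib]
  r_t <- r_meas
  inside <- s > s[ia] & s < s[ib]
  u <- (s[inside] - s[ia]) / (s[ib] - s[ia])
  h <- u * u * (3 - 2 * u)           # monotone C1 smoothstep
  r_t[inside] <- r_p + (r_d - r_p) * h
  structure(list(s = s, r_target = r_t, region = region,
                 s_mod_start = s[ia], s_mod_end = s[ib],
                 blend_margin = blend_margin, anchor = anchor),
            class = "target_radius_profile")
}

# orthogonal foot points of a vertex set on a centerline polyline:
# returns station s, radius (distance), and the foot point per vertex.
# Equidistant ties resolve to the smaller-s segment (first wins).
centerline_feet <- function(verts, cl) {
  n <- nrow(verts)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  foot <- matrix(0, n, 3L)
  p <- cl$points
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((verts[, 1] - a[1]) * ab[1] + (verts[, 2] - a[2]) * ab[2] +
          (verts[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    fx <- a[1] + t * ab[1]; fy <- a[2] + t * ab[2]; fz <- a[3] + t * ab[3]
    d2 <- (verts[, 1] - fx)^2 + (verts[, 2] - fy)^2 + (verts[, 3] - fz)^2
    upd <- d2 < best_d2 - 1e-15
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- cl$s[i] + t[upd] * (cl$s[i + 1L] - cl$s[i])
      foot[upd, ] <- cbind(fx, fy, fz)[upd, , drop = FALSE]
    }
  }
  list(s = best_s, radius = sqrt(best_d2), foot = foot)
}

#' Remove a fusiform dilation (virtual healthy counterpart)
#'
#' Automated counterpart of the manual sculpt-and-shrink procedure: every
#' wall vertex whose orthogonal foot point on the centerline falls inside
#' the target's modification span (the dilation region, or its
#' nominal-anchored extension) is displaced radially onto the target
#' healthy radius at its station, then `iterations` rounds of Laplacian relaxation (factor
#' `lambda`) are applied to the region vertices against a fixed two-ring
#' collar, with the radius reprojected onto the target profile after each
#' round (plain Laplacian smoothing is a discrete mean-curvature flow that
#' shrinks tubes; the constraint keeps the restored lumen on the target).
#' Vertices outside the region are returned bit-identical. The output is
#' checked for manifoldness, degenerate triangles and self-intersections in
#' the modified region.
#'
#' @param mesh `surface_mesh` of the diseased vessel.
#' @param cl matching `centerline` (reused for the healthy model: the
#'   dilation is circumferential so the centerline is approximately
#'   preserved).
#' @param region `dilation_region` from [detect_fusiform()].
#' @param target `target_radius_profile` from [target_radius_profile()].
#' @param lambda Laplacian factor in (0, 1], default 0.5.
#' @param iterations smoothing rounds, default 20.
#' @return a new `surface_mesh` (same topology).
#' @export
remove_dilation <- function(mesh, cl, region, target, lambda = 0.5,
                            iterations = 20L) {
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  v <- mesh$vertices
  feet <- centerline_feet(v, cl)
  r_tgt_at <- function(s) approx(target$s, target$r_target, xout = s,
                                 rule = 2)$y
  s_lo <- target$s_mod_start %||% region$s_start
  s_hi <- target$s_mod_end %||% region$s_end
  in_region <- feet$s > s_lo & feet$s < s_hi
  if (!any(in_region)) stop("no vertices in region")
  vin <- which(in_region)
  dir <- v[vin, , drop = FALSE] - feet$foot[vin, , drop = FALSE]
  dirn <- dir / pmax(feet$radius[vin], 1e-12)
  r_new <- r_tgt_at(feet$s[vin])
  v2 <- v
  v2[vin, ] <- feet$foot[vin, , drop = FALSE] + dirn * r_new
  de <- mesh_directed_edges(mesh)
  sel <- de[, 1L] %in% vin
  ei <- de[sel, 1L]; ej <- de[sel, 2L]
  deg <- as.numeric(table(factor(ei, levels = vin)))
  for (it in seq_len(iterations)) {
    sums <- rowsum(v2[ej, , drop = FALSE], group = factor(ei, levels = vin))
    cent <- sums / deg
    v2[vin, ] <- v2[vin, ] + lambda * (cent - v2[vin, , drop = FALSE])
    # radial reprojection onto the target profile
    d <- v2[vin, , drop = FALSE] - feet$foot[vin, , drop = FALSE]
    dn <- d / pmax(sqrt(rowSums(d^2)), 1e-12)
    v2[vin, ] <- feet$foot[vin, , drop = FALSE] + dn * r_new
  }
  out <- mesh
  out$vertices <- v2
  validate_surface_mesh(out)
  moved_tri <- which(matrix(mesh$triangles %in% vin,
                            nrow(mesh$triangles), 3L) |>
                       rowSums() > 0)
  bad <- find_self_intersections(out, moved_tri)
  if (!is.null(bad))
    stop(sprintf(
      "self-intersection after smoothing: triangles %d and %d overlap",
      bad[1L], bad[2L]))
  out
}

# exact triangle/triangle intersection restricted to a triangle subset,
# uniform-grid broad phase; pairs sharing a vertex are skipped; the
# (measure-zero) exactly-coplanar overlap case is not detected.
find_self_intersections <- function(mesh, tri_idx) {
  if (length(tri_idx) < 2L) return(NULL)
  v <- mesh$vertices
  tr <- mesh$triangles[tri_idx, , drop = FALSE]
  tx <- cbind(v[tr[, 1], 1], v[tr[, 2], 1], v[tr[, 3], 1])
  ty <- cbind(v[tr[, 1], 2], v[tr[, 2], 2], v[tr[, 3], 2])
  tz <- cbind(v[tr[, 1], 3], v[tr[, 2], 3], v[tr[, 3], 3])
  lo <- cbind(apply(tx, 1, min), apply(ty, 1, min), apply(tz, 1, min))
  hi <- cbind(apply(tx, 1, max), apply(ty, 1, max), apply(tz, 1, max))
  cell <- max(stats::quantile(hi - lo, 0.9), 1e-6)
  key_of <- function(ix, iy, iz) paste(ix, iy, iz)
  buckets <- new.env(parent = emptyenv())
  nT <- nrow(tr)
  for (i in seq_len(nT)) {
    rng <- expand.grid(ix = floor(lo[i, 1] / cell):floor(hi[i, 1] / cell),
                       iy = floor(lo[i, 2] / cell):floor(hi[i, 2] / cell),
                       iz = floor(lo[i, 3] / cell):floor(hi[i, 3] / cell))
    for (k in seq_len(nrow(rng))) {
      key <- key_of(rng$ix[k], rng$iy[k], rng$iz[k])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  seen <- new.env(parent = emptyenv())
  for (key in ls(buckets)) {
    ids <- unique(buckets[[key]])
    if (length(ids) < 2L) next
    for (a in seq_len(length(ids) - 1L)) {
      for (b in (a + 1L):length(ids)) {
        i <- ids[a]; j <- ids[b]
        pk <- paste(min(i, j), max(i, j))
        if (!is.null(seen[[pk]])) next
        seen[[pk]] <- TRUE
        if (length(intersect(tr[i, ], tr[j, ])) > 0L) next
        if (any(lo[i, ] > hi[j, ]) || any(lo[j, ] > hi[i, ])) next
        if (tri_tri_intersect(v[tr[i, ], ], v[tr[j, ], ]))
          return(c(tri_idx[i], tri_idx[j]))
      }
    }
  }
  NULL
}

# segment-vs-triangle based triangle intersection test
tri_tri_intersect <- function(A, B) {
  seg_hits_tri <- function(p, q, T3) {
    d <- q - p
    e1 <- T3[2, ] - T3[1, ]
    e2 <- T3[3, ] - T3[1, ]
    h <- c(d[2] * e2[3] - d[3] * e2[2],
           d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-14) return(FALSE)
    f <- 1 / a
    sv <- p - T3[1, ]
    u <- f * sum(sv * h)
    if (u < -1e-12 || u > 1 + 1e-12) return(FALSE)
    qv <- c(sv[2] * e1[3] - sv[3] * e1[2],
            sv[3] * e1[1] - sv[1] * e1[3],
            sv[1] * e1[2] - sv[2] * e1[1])
    vv <- f * sum(d * qv)
    if (vv < -1e-12 || u + vv > 1 + 1e-12) return(FALSE)
    t <- f * sum(e2 * qv)
    t > 1e-12 && t < 1 - 1e-12
  }
  for (k in 1:3) {
    k2 <- k %% 3L + 1L
    if (seg_hits_tri(A[k, ], A[k2, ], B)) return(TRUE)
    if (seg_hits_tri(B[k, ], B[k2, ], A)) return(TRUE)
  }
  FALSE
}

#' Write a provenance sidecar for a reconstruction
#' @param region `dilation_region` used.
#' @param target `target_radius_profile` used.
#' @param params list of smoothing parameters.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_reconstruction_json <- function(region, target, params, path) {
  jsonlite::write_json(
    list(s_start = region$s_start, s_end = region$s_end,
         s_max = region$s_max, ratio_max = region$ratio_max,
         blend_margin = target$blend_margin, params = params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
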