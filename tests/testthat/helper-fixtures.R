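# shared fixtures, built once per test run and cached
.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# straight circular tube, radius 2 mm
fx_tube <- function() fx_cached("tube", function() {
  make_vessel(vessel_spec(curve = list(type = "straight", length = 20),
                          r0 = 2, edge_length = 0.25), seed = 1)
})

# standard fusiform phantom: ratio 1.6 Gaussian bump on a 2 mm-radius tube
fx_fusiform_spec <- function(r_p = 3.2, length = 44, sigma = 3,
                             edge_length = 0.25, jitter = 0) {
  vessel_spec(curve = list(type = "straight", length = length), r0 = 2,
              dilation = list(s_c = length / 2, r_p = r_p, sigma = sigma),
              edge_length = edge_length, jitter = jitter)
}

fx_fusiform <- function() fx_cached("fusiform", function() {
  make_vessel(fx_fusiform_spec(), seed = 7)
})

fx_fusiform_profile <- function() fx_cached("fusiform_profile", function() {
  v <- fx_fusiform()
  csa_profile(v$mesh, v$centerline, spacing = 0.5, n_rays = 120)
})

# elliptic cylinder along +z, semi-axes a, b (mm)
elliptic_tube <- function(a = 2, b = 1, length = 4, n_circ = 180L,
                          n_ax = 25L) {
  z <- seq(0, length, length.out = n_ax)
  th <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  verts <- do.call(rbind, lapply(z, function(zz)
    cbind(a * cos(th), b * sin(th), zz)))
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  tris <- do.call(rbind, lapply(seq_len(n_ax - 1L), function(i) {
    j <- seq_len(n_circ)
    rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
          cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  }))
  surface_mesh(verts, tris, validate = FALSE)
}

# wall series from a function tau(t) -> length-3 vector, on n dummy elements
wall_series_from_fun <- function(fun, n_elem = 5L, nt = 128L, T = 1) {
  times <- T * (seq_len(nt) - 1L) / nt
  tau <- array(0, dim = c(n_elem, 3L, nt))
  for (k in seq_len(nt)) tau[, , k] <- matrix(fun(times[k]), n_elem, 3L,
                                              byrow = TRUE)
  wall_series(matrix(0, n_elem, 3L), tau, times, T)
}

volume_series_from_fun <- function(fun, n_pts = 5L, nt = 128L, T = 1,
                                   rho = 1055) {
  times <- T * (seq_len(nt) - 1L) / nt
  v <- array(0, dim = c(n_pts, 3L, nt))
  for (k in seq_len(nt)) v[, , k] <- matrix(fun(times[k]), n_pts, 3L,
                                            byrow = TRUE)
  volume_series(matrix(0, n_pts, 3L), v, times, T, rho = rho)
}

# three-state pulsatile fields: fusiform = strong oscillation, treated =
# damped oscillation, healthy = mild pulsation (same mean flow)
fx_state_fields <- function() fx_cached("state_fields", function() {
  mk <- function(amp) womersley_fields(
    pulsatile_spec(R = 2, T = 1, Q0 = 2,
                   harmonics = list(list(k = 1, amp = amp, phase = 0))),
    n_r = 10L, n_theta = 8L, n_axial = 1L, timesteps = 32L)
  list(fusiform = mk(2.5), treated = mk(0.9), healthy = mk(0.3))
})

fx_case_cfg <- function(outdir = NULL) {
  vf <- fx_fusiform()
  flds <- fx_state_fields()
  list(case_id = "synthetic-1",
       mesh = vf$mesh, centerline = vf$centerline,
       morphology = list(spacing = 0.5, n_rays = 120L,
                         proximal_window = 5, distal_window = 5),
       smoothing = list(lambda = 0.5, iterations = 10L),
       stent = list(L_nom = 16, D_nom = 4.6, N_w = 48L, t_s = 42,
                    s_distal = 31),
       fields = lapply(flds, function(f)
         list(wall = f$wall, volume = f$volume)),
       outdir = outdir, seed = 1L)
}
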