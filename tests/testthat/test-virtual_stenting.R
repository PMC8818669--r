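test_that("stent_spec derives the braid kinematics (closed-form helix)", {
  spec <- stent_spec(20, 3, 48, 42, beta0 = 75)
  expect_equal(spec$p0, pi * 3 / tan(75 * pi / 180), tolerance = 1e-12)
  expect_equal(spec$l_t, pi * 3 / sin(75 * pi / 180), tolerance = 1e-12)
  expect_equal(round(spec$p0, 3), 2.525)
  expect_equal(round(spec$l_t, 3), 9.757)
  expect_equal(spec$d_max, spec$l_t / pi)
  expect_error(stent_spec(20, 3, 47, 42), "even")
  expect_error(stent_spec(20, 3, 48, 42, beta0 = 95), "beta0")
  expect_error(stent_spec(-1, 3, 48, 42), "positive")
})

test_that("stent_template builds N_w helices spanning L_nom on the D_nom cylinder", {
  spec <- stent_spec(20, 3, 48, 42)
  tpl <- stent_template(spec)
  expect_length(tpl$wire_paths, 48L)
  expect_identical(sum(tpl$wire_sign > 0), 24L)   # half each handedness
  # all wire points on the radius-D/2 cylinder
  for (w in tpl$wire_paths[c(1L, 25L)]) {
    rr <- sqrt(w[, 1]^2 + w[, 2]^2)
    expect_lt(max(abs(rr - 1.5)), 1e-9)
    expect_equal(range(w[, 3]), c(0, 20), tolerance = 1e-9)
  }
  # wire-point count scales linearly with L_nom
  tpl2 <- stent_template(stent_spec(40, 3, 48, 42))
  n1 <- nrow(tpl$wire_paths[[1L]])
  n2 <- nrow(tpl2$wire_paths[[1L]])
  expect_equal(n2 / n1, 2, tolerance = 0.02)
  # discrete wire length close to the analytic N_t * l_t per wire
  expect_equal(wire_length(tpl), 48 * spec$N_t * spec$l_t,
               tolerance = 1e-3)
})

test_that("deployment conserves wire length and obeys p(d) kinematics", {
  spec <- stent_spec(20, 3, 48, 42, beta0 = 75)
  tpl <- stent_template(spec)
  # analytic uniform lumen profiles (exactly known diameter)
  s <- seq(0, 60, by = 0.5)
  mk_prof <- function(d) csa_profile_from_values(s, rep(pi * d^2 / 4,
                                                        length(s)))
  tube <- fx_tube()   # mesh only needed for the signature
  cl60 <- centerline(cbind(0, 0, seq(0, 60, by = 0.5)))
  # nominal: lumen exactly D_nom -> L_dep = L_nom
  dep_nom <- deploy_stent(spec, tube$mesh, cl60, s_distal = 40,
                          profile = mk_prof(3))
  expect_equal(dep_nom$L_dep, 20, tolerance = 0.005 * 20)
  # 2.5 mm lumen: elongation factor p/p0 = 2.29
  dep <- deploy_stent(spec, tube$mesh, cl60, s_distal = 55,
                      profile = mk_prof(2.5))
  p_expected <- sqrt(spec$l_t^2 - (pi * 2.5)^2)
  expect_lt(abs(p_expected - 5.789), 1e-3)   # closed form, 5.7895
  expect_equal(unique(round(dep$p_samp, 9)), round(p_expected, 9))
  expect_equal((dep$L_dep / spec$N_t) / spec$p0, 2.29, tolerance = 0.01)
  # wire-length conservation within 0.1%
  expect_lt(abs(wire_length(dep) - wire_length(tpl)) / wire_length(tpl),
            1e-3)
  # p(d)^2 + (pi d)^2 = l_t^2 at every sample
  expect_lt(max(abs(dep$p_samp^2 + (pi * dep$d_samp)^2 - spec$l_t^2)) /
              spec$l_t^2, 1e-9)
  # monotonicity: narrower lumen -> strictly longer deployment
  dep2 <- deploy_stent(spec, tube$mesh, cl60, s_distal = 58,
                       profile = mk_prof(2.2))
  expect_gt(dep2$L_dep, dep$L_dep)
  # over-expansion guard
  expect_error(deploy_stent(spec, tube$mesh, cl60,
                            s_distal = 40, profile = mk_prof(3.2)),
               "over-expansion")
  # landing zone too short
  expect_error(deploy_stent(spec, tube$mesh, cl60,
                            s_distal = 20, profile = mk_prof(2.5)),
               "landing zone")
})

test_that("deployment on a meshed vessel is deterministic and conserves length", {
  spec <- stent_spec(10, 4.6, 48, 42)
  vf <- fx_fusiform()
  prf <- fx_fusiform_profile()
  dep1 <- deploy_stent(spec, vf$mesh, vf$centerline, s_distal = 30,
                       profile = prf, on_overexpansion = "cap")
  dep2 <- deploy_stent(spec, vf$mesh, vf$centerline, s_distal = 30,
                       profile = prf, on_overexpansion = "cap")
  expect_identical(dep1$wire_paths, dep2$wire_paths)   # bit-identical
  tpl <- stent_template(spec)
  expect_lt(abs(wire_length(dep1) - wire_length(tpl)) / wire_length(tpl),
            1e-3)
})

test_that("apposition map flags gaps only where the stent underfills", {
  vf <- fx_fusiform()
  prf <- fx_fusiform_profile()
  # D_nom 4.6 stent in a vessel bulging to 6.4 mm: malapposed in the bulge
  spec <- stent_spec(16, 4.6, 48, 42)
  dep <- deploy_stent(spec, vf$mesh, vf$centerline, s_distal = 31,
                      profile = prf, on_overexpansion = "cap")
  app <- apposition_map(dep, vf$mesh, vf$centerline, stride = 3L)
  expect_gt(app$malapposed_fraction, 0)
  expect_gt(app$max_gap, 0.25)
  expect_true(all(app$gaps >= -1e-6))
  # gaps flagged only around the dilation
  reg <- detect_fusiform(prf, 4)
  expect_true(all(app$s[app$malapposed] > reg$s_start - 1))
  expect_true(all(app$s[app$malapposed] < reg$s_end + 1))
  # stent opened to the local lumen diameter everywhere -> no malapposition
  tube <- fx_tube()
  pr_t <- csa_profile(tube$mesh, tube$centerline, spacing = 0.5,
                      n_rays = 90L)
  spec2 <- stent_spec(8, 4.2, 48, 42)
  dep2 <- deploy_stent(spec2, tube$mesh, tube$centerline, s_distal = 16,
                       profile = pr_t)
  app2 <- apposition_map(dep2, tube$mesh, tube$centerline, stride = 3L)
  expect_equal(app2$malapposed_fraction, 0)
})

test_that("metal coverage matches a brute-force rasterization of the braid", {
  spec <- stent_spec(20, 3, 48, 42)   # densest listed device
  tpl <- stent_template(spec)
  cov <- metal_coverage(tpl, 2, 18)
  expect_gt(cov, 0); expect_lt(cov, 1)
  # rasterization oracle on the unrolled periodic braid cell
  rasterize_braid <- function(D, p, N_w, t_mm, n = 900L) {
    C <- pi * D
    x <- (seq_len(n) - 0.5) / n * C
    y <- (seq_len(n) - 0.5) / n * p
    g <- expand.grid(x = x, y = y)
    hyp <- sqrt(C^2 + p^2)
    dperp <- (C / (N_w / 2)) * p / hyp     # same-family line spacing
    fold <- function(v) {
      m <- abs(v) %% dperp
      pmin(m, dperp - m)
    }
    d_right <- fold((g$y * C - p * g$x) / hyp)
    d_left <- fold((g$y * C + p * g$x) / hyp)
    mean(d_right < t_mm / 2 | d_left < t_mm / 2)
  }
  cov_oracle <- rasterize_braid(3, spec$p0, 48, 42e-3)
  expect_equal(cov, cov_oracle, tolerance = 0.10 * cov_oracle)
  # doubling strut thickness ~ doubles a small coverage
  thin <- stent_spec(20, 3, 16, 20)
  thick <- stent_spec(20, 3, 16, 40)
  c1 <- metal_coverage(stent_template(thin), 2, 18)
  c2 <- metal_coverage(stent_template(thick), 2, 18)
  expect_equal(c2 / c1, 2, tolerance = 0.1 * 2)
  expect_error(metal_coverage(tpl, -5, -1), "outside stent")
})

test_that("stent exports round-trip and the tube mesh is well-formed", {
  spec <- stent_spec(10, 3, 16, 42)
  tpl <- stent_template(spec, points_per_turn = 24L)
  p <- file.path(tempdir(), "stent.csv")
  write_stent_csv(tpl, p)
  df <- data.table::fread(p)
  expect_identical(length(unique(df$wire)), 16L)
  tm <- stent_tube_mesh(tpl, sides = 4L, stride = 4L)
  expect_gt(nrow(tm$triangles), 0)
  expect_true(all(tri_areas(tm) > 0))
  j <- file.path(tempdir(), "stent.json")
  write_stent_json(tpl, j, coverage = 0.25)
  expect_equal(jsonlite::read_json(j)$L_dep, 10)
})
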