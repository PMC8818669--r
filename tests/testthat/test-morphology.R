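test_that("ray-cast section area matches analytic circle and ellipse", {
  v <- fx_tube()
  fr <- local_frame(v$centerline, 10)
  cs <- cross_section_area(v$mesh, fr, n_rays = 360L)
  expect_equal(cs$area, 4 * pi, tolerance = 5e-3)
  expect_equal(cs$d_eq, equivalent_diameter(cs$area))
  expect_equal(nrow(cs$hit_points), 360L)
  # elliptic lumen: pi * a * b
  em <- elliptic_tube(a = 2, b = 1, length = 4)
  ecl <- centerline(cbind(0, 0, seq(0, 4, by = 0.5)))
  ecs <- cross_section_area(em, local_frame(ecl, 2), n_rays = 360L)
  expect_equal(ecs$area, 2 * pi, tolerance = 0.01)
  # ray-count convergence on a smooth convex section
  a180 <- cross_section_area(v$mesh, fr, n_rays = 180L)$area
  a360 <- cs$area
  expect_lt(abs(a360 - a180) / a360, 1e-3)
  expect_error(cross_section_area(v$mesh, fr, n_rays = 4L), "n_rays")
})

test_that("section errors identify exterior origins and open boundaries", {
  v <- fx_tube()
  fr <- local_frame(v$centerline, 10)
  fr_out <- fr
  fr_out$origin <- fr$origin + c(3.5, 0, 0)   # outside the 2 mm lumen
  expect_error(cross_section_area(v$mesh, fr_out, 64L), "not interior")
  fr_end <- local_frame(v$centerline, 0)      # plane at the open inlet
  fr_end$origin <- fr_end$origin - c(0, 0, 1)
  expect_error(cross_section_area(v$mesh, fr_end, 64L), "open boundary")
})

test_that("csa_profile is flat on a cylinder and peaks at the bump apex", {
  v <- fx_tube()
  pr <- csa_profile(v$mesh, v$centerline, spacing = 0.5, n_rays = 90L)
  expect_true(all(abs(pr$area - 4 * pi) / (4 * pi) < 5e-3))
  expect_true(all(diff(pr$s) > 0))
  expect_true(all(pr$s >= 0.5 - 1e-9 & pr$s <= 19.5 + 1e-9))
  # fusiform: apex area ~ pi * r_p^2, profile unimodal over the dilation
  vf <- fx_fusiform()
  prf <- fx_fusiform_profile()
  apex <- prf$s[which.max(prf$area)]
  expect_equal(apex, 22, tolerance = 0.5)
  expect_equal(max(prf$area), pi * 3.2^2, tolerance = 0.01)
  mid <- prf$s > 14 & prf$s < 30
  d2 <- diff(sign(diff(prf$area[mid])))
  expect_lte(sum(d2 != 0), 1L)   # single interior extremum
})

test_that("nominal_diameter is robust to the dilation and taper-bounded", {
  v <- fx_tube()
  pr <- csa_profile(v$mesh, v$centerline, spacing = 0.5, n_rays = 90L)
  expect_equal(nominal_diameter(pr, 3, 3), 4, tolerance = 0.01 * 4)
  prf <- fx_fusiform_profile()
  expect_equal(nominal_diameter(prf, 5, 5), 4, tolerance = 0.01 * 4)
  # tapered tube: result bounded by the end diameters
  vt <- make_vessel(vessel_spec(curve = list(type = "straight", length = 20),
                                r0 = 2, taper = -0.025, edge_length = 0.25),
                    seed = 1)
  prt <- csa_profile(vt$mesh, vt$centerline, spacing = 0.5, n_rays = 90L)
  dn <- nominal_diameter(prt, 4, 4)
  expect_gt(dn, 3.0); expect_lt(dn, 4.0)
  expect_error(nominal_diameter(pr, -1, -1), "empty")
})

test_that("detect_fusiform applies the 1.5x criterion with 1.1x bounds", {
  prf <- fx_fusiform_profile()
  reg <- detect_fusiform(prf, 4)
  expect_s3_class(reg, "dilation_region")
  expect_lt(reg$s_start, reg$s_max); expect_gt(reg$s_end, reg$s_max)
  expect_gt(reg$ratio_max, 1.5)
  expect_equal(reg$ratio_max, 1.6, tolerance = 0.01)
  # bounds sit where d_eq first drops below 1.1 * d_nominal
  expect_lt(prf$d_eq[reg$i_start], 1.1 * 4)
  expect_lt(prf$d_eq[reg$i_end], 1.1 * 4)
  # sub-threshold bump not detected
  v13 <- make_vessel(fx_fusiform_spec(r_p = 2.6, length = 40), seed = 2)
  pr13 <- csa_profile(v13$mesh, v13$centerline, spacing = 0.5, n_rays = 90L)
  expect_null(detect_fusiform(pr13, nominal_diameter(pr13, 5, 5)))
  # monotone in huber_ratio: larger ratio never enlarges the region
  reg17 <- detect_fusiform(prf, 4, huber_ratio = 1.55)
  expect_gte(reg17$s_start, reg$s_start)
  expect_lte(reg17$s_end, reg$s_end)
  expect_error(detect_fusiform(prf, -2), "positive")
})

test_that("two disjoint supra-threshold runs select the larger-CSA one", {
  s <- seq(0, 40, by = 0.5)
  r <- 2 + 1.4 * exp(-(s - 12)^2 / 8) + 1.1 * exp(-(s - 30)^2 / 8)
  pr <- csa_profile_from_values(s, pi * r^2)
  reg <- detect_fusiform(pr, 4)
  expect_equal(reg$s_max, 12, tolerance = 0.5)
  expect_length(reg$other_runs, 1L)
  expect_gt(reg$other_runs[[1L]]["s_start"], 25)
})

test_that("morphology_report reproduces the reference relative increases", {
  # compact-support bump so the parent-vessel reference area is exact
  mk2 <- function(csa_pv, csa_a) {
    s <- seq(0, 20, by = 0.25)
    bump <- ifelse(abs(s - 10) < 1.25, cos(pi * (s - 10) / 2.5)^2, 0)
    pr <- csa_profile_from_values(s, csa_pv + (csa_a - csa_pv) * bump)
    reg <- detect_fusiform(pr, equivalent_diameter(csa_pv))
    morphology_report(pr, reg)
  }
  r1 <- mk2(4.21, 14.53)   # vertebral-artery worked example
  expect_equal(r1$CSA_A, 14.53)
  expect_equal(r1$CSA_PV, 4.21)
  expect_identical(r1$RI_pct, 345L)
  r3 <- mk2(22.61, 70.51)  # basilar-artery worked example
  expect_identical(r3$RI_pct, 312L)
  # equal areas give RI exactly 100%
  expect_equal(100 * 4.21 / 4.21, 100)
})

test_that("morphology_report uses the adjacent proximal station and errors at ends", {
  prf <- fx_fusiform_profile()
  reg <- detect_fusiform(prf, 4)
  mr <- morphology_report(prf, reg)
  expect_equal(mr$CSA_PV, prf$area[reg$i_start - 1L])
  expect_equal(mr$CSA_A, max(prf$area))
  expect_equal(mr$RI, 100 * mr$CSA_A / mr$CSA_PV)
  expect_equal(mr$RI_pct, as.integer(round(mr$RI)))
  mr2 <- morphology_report(prf, reg, reference = "proximal_mean", window = 2)
  expect_gt(mr2$CSA_PV, 0)
  # region touching the profile start -> no proximal reference
  s <- seq(0, 20, by = 0.5)
  r <- 2 + 1.4 * exp(-(s - 1)^2 / (2 * 3^2))
  pr <- csa_profile_from_values(s, pi * r^2)
  reg2 <- detect_fusiform(pr, 4)
  expect_error(morphology_report(pr, reg2), "proximal reference")
})

test_that("RI is invariant under uniform geometric scaling", {
  prf <- fx_fusiform_profile()
  reg <- detect_fusiform(prf, 4)
  mr <- morphology_report(prf, reg)
  for (k in c(0.5, 2, 3.7)) {
    prk <- csa_profile_from_values(prf$s * k, prf$area * k^2)
    regk <- detect_fusiform(prk, 4 * k)
    mrk <- morphology_report(prk, regk)
    expect_equal(mrk$RI, mr$RI, tolerance = 1e-9)
  }
})

test_that("profile CSV and report JSON exports round-trip", {
  prf <- fx_fusiform_profile()
  p <- file.path(tempdir(), "prof.csv")
  write_profile_csv(prf, p)
  df <- read.csv(p)
  expect_named(df, c("s", "CSA", "d_eq"))
  expect_equal(df$CSA, prf$area, tolerance = 1e-9)
  reg <- detect_fusiform(prf, 4)
  mr <- morphology_report(prf, reg)
  j <- file.path(tempdir(), "rep.json")
  write_morphology_json(mr, j, case = "synthetic-1")
  jj <- jsonlite::read_json(j)
  expect_equal(jj$RI_pct, mr$RI_pct)
  expect_equal(jj$max_CSA_A_mm2, mr$CSA_A, tolerance = 1e-12)
})
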