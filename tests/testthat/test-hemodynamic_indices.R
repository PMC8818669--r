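test_that("AWSS matches closed forms", {
  # constant magnitude
  ws <- wall_series_from_fun(function(t) c(0.9, 1.2, 0), nt = 16L)
  expect_equal(awss(ws)$values, rep(1.5, 5L), tolerance = 1e-12)
  # rectified sinusoid: mean |sin| = 2/pi
  ws2 <- wall_series_from_fun(function(t) c(sin(2 * pi * t), 0, 0),
                              nt = 256L)
  expect_equal(awss(ws2)$values, rep(2 / pi, 5L), tolerance = 1e-3)
  # Poiseuille: 4 mu Q / (pi R^3), from the analytic field generator
  p0 <- pulsatile_spec(R = 2, T = 1, Q0 = 5, harmonics = list())
  w0 <- womersley_fields(p0, timesteps = 16L)
  a <- awss(last_cycle(w0$wall))
  expect_equal(a$values,
               rep(4 * 0.004 * 5e-6 / (pi * 0.002^3), length(a$values)),
               tolerance = 5e-3)
  expect_error(awss(wall_series_from_fun(function(t) c(1, 0, 0), nt = 2L)),
               "3 timesteps")
})

test_that("OSI matches closed forms and stays in [0, 0.5]", {
  # steady unidirectional -> 0
  ws <- wall_series_from_fun(function(t) c(2, 0, 0), nt = 16L)
  expect_equal(osi(ws)$values, rep(0, 5L))
  # zero-mean sinusoid along a fixed axis -> 0.5
  ws2 <- wall_series_from_fun(function(t) c(sin(2 * pi * t), 0, 0),
                              nt = 256L)
  expect_equal(osi(ws2)$values, rep(0.5, 5L), tolerance = 1e-6)
  # two-phase orthogonal: 0.5 * (1 - sqrt(2)/2)
  ws3 <- wall_series_from_fun(function(t)
    if (t < 0.5) c(1, 0, 0) else c(0, 1, 0), nt = 512L)
  expect_equal(osi(ws3)$values, rep(0.5 * (1 - sqrt(2) / 2), 5L),
               tolerance = 2e-3)
  # zero shear -> OSI defined as 0
  ws4 <- wall_series_from_fun(function(t) c(0, 0, 0), nt = 16L)
  expect_equal(osi(ws4)$values, rep(0, 5L))
  # property: random fields stay within [0, 0.5]
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 7L; nt <- 24L
    tau <- array(rnorm(n * 3L * nt), dim = c(n, 3L, nt))
    ws5 <- wall_series(matrix(0, n, 3L), tau, (seq_len(nt) - 1L) / nt, 1)
    o <- osi(ws5)$values
    expect_true(all(o >= 0 & o <= 0.5))
  }
})

test_that("RRT obeys its identity and degenerate capping", {
  a <- fusiflow:::new_index_field(c(2, 1, 0.5), "AWSS", "Pa")
  o <- fusiflow:::new_index_field(c(0, 0.25, 0.4999999999), "OSI", "-")
  r <- rrt(a, o)
  expect_equal(r$values[1L], 0.5)
  # identity at uncapped elements
  un <- !r$flags
  expect_equal(r$values[un] * (1 - 2 * o$values[un]) * a$values[un],
               rep(1, sum(un)), tolerance = 1e-9)
  # capped at 1/eps when OSI -> 0.5
  expect_equal(r$values[3L], 1e9)
  expect_true(r$flags[3L])
  b <- fusiflow:::new_index_field(c(1, 1), "OSI", "-")
  expect_error(rrt(a, b), "mismatched")
})

test_that("OVI matches the OSI construction on velocity fields", {
  vs <- volume_series_from_fun(function(t) c(0, 0, 0.8), nt = 16L)
  expect_equal(ovi(vs)$values, rep(0, 5L))
  vs2 <- volume_series_from_fun(function(t) c(0, 0, sin(2 * pi * t)),
                                nt = 256L)
  expect_equal(ovi(vs2)$values, rep(0.5, 5L), tolerance = 1e-6)
  vs3 <- volume_series_from_fun(function(t)
    if (t < 0.5) c(1, 0, 0) else c(0, 1, 0), nt = 512L)
  expect_equal(ovi(vs3)$values, rep(0.5 * (1 - sqrt(2) / 2), 5L),
               tolerance = 2e-3)
})

test_that("kinetic energy density matches 0.5 rho |v|^2", {
  vs <- volume_series_from_fun(function(t) c(1, 0, 0), nt = 16L,
                               rho = 1055)
  ke <- kinetic_energy(vs)
  expect_equal(ke$avg$values, rep(527.5, 5L), tolerance = 1e-12)
  expect_equal(ke$series[1L, ], rep(527.5, 16L), tolerance = 1e-12)
  vs0 <- volume_series_from_fun(function(t) c(0, 0, 0), nt = 16L)
  expect_equal(kinetic_energy(vs0)$avg$values, rep(0, 5L))
  # |v| = sin(wt): time-average of sin^2 is 1/2
  vs2 <- volume_series_from_fun(function(t) c(0, 0, sin(2 * pi * t)),
                                nt = 256L, rho = 1055)
  expect_equal(kinetic_energy(vs2)$avg$values, rep(263.75, 5L),
               tolerance = 1e-6)
})

test_that("periodic integration is cyclic-shift invariant and 2nd-order", {
  set.seed(11)
  n <- 4L; nt <- 32L
  times <- (seq_len(nt) - 1L) / nt
  tau <- array(0, dim = c(n, 3L, nt))
  for (k in seq_len(nt))
    tau[, , k] <- outer(seq_len(n) / n,
                        c(sin(2 * pi * times[k]) + 0.3,
                          cos(4 * pi * times[k]), 0.1))
  ws <- wall_series(matrix(0, n, 3L), tau, times, 1)
  a0 <- awss(ws)$values
  sh <- 7L
  ws_sh <- wall_series(matrix(0, n, 3L),
                       tau[, , c((sh + 1L):nt, 1L:sh), drop = FALSE],
                       times, 1)
  expect_equal(awss(ws_sh)$values, a0, tolerance = 1e-12)
  # halving the timestep changes smooth-field indices by < 0.5%
  f <- function(t) c(1 + 0.5 * sin(2 * pi * t), 0.3 * cos(2 * pi * t), 0)
  a_c <- awss(wall_series_from_fun(f, nt = 16L))$values[1L]
  a_f <- awss(wall_series_from_fun(f, nt = 32L))$values[1L]
  expect_lt(abs(a_f - a_c) / a_f, 5e-3)
  o_c <- osi(wall_series_from_fun(f, nt = 16L))$values[1L]
  o_f <- osi(wall_series_from_fun(f, nt = 32L))$values[1L]
  expect_lt(abs(o_f - o_c), 5e-3 * 0.5)
})

test_that("last_cycle drops warm-up timesteps", {
  p <- pulsatile_spec(R = 2, T = 1, Q0 = 3)
  wf <- womersley_fields(p, timesteps = 16L)   # two cycles emitted
  expect_length(wf$wall$times, 32L)
  ws1 <- last_cycle(wf$wall)
  expect_length(ws1$times, 16L)
  expect_true(all(ws1$times >= 1))
  expect_error(awss(wf$wall), "more than one period")
  vs1 <- last_cycle(wf$volume)
  expect_length(vs1$times, 16L)
})

test_that("index_summary computes weighted statistics correctly", {
  f <- fusiflow:::new_index_field(c(1, 2, 3, 4), "X", "-",
                                  weights = c(1, 1, 1, 1))
  sm <- index_summary(f)
  expect_equal(sm$mean, 2.5)
  expect_equal(sm$wmean, 2.5)
  expect_equal(sm$max, 4)
  # constant field: every statistic equals the constant
  fc <- fusiflow:::new_index_field(rep(7, 10L), "X", "-")
  smc <- index_summary(fc)
  expect_true(all(unlist(smc) == 7))
  # p95 of a linear ramp matches a brute-force weighted quantile
  set.seed(3)
  v <- seq(0, 1, length.out = 200L)
  w <- runif(200L, 0.5, 2)
  fr <- fusiflow:::new_index_field(v, "X", "-", weights = w)
  p95 <- index_summary(fr)$p95
  ord <- order(v); cw <- cumsum(w[ord]) / sum(w)
  expect_equal(p95, v[ord][which(cw >= 0.95)[1L]])
  # non-uniform weights shift the weighted mean
  fw <- fusiflow:::new_index_field(c(0, 1), "X", "-", weights = c(1, 3))
  expect_equal(index_summary(fw)$wmean, 0.75)
  expect_error(index_summary(f, region_mask = logical(4)), "empty")
})
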