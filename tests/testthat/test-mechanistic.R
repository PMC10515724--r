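# Fed-batch material balances and fixed-step RK4 integration.

test_that("dilution rates are feed rate over volume, summed across streams", {
  s1 <- feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 10, rate = 0.1),
                    id = "f1")
  s2 <- feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 10, rate = 0.3),
                    id = "f2")
  z <- feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 10, rate = 0))

  expect_equal(dilution_rate(list(z), 5, 2)$total, 0)
  expect_equal(dilution_rate(list(feed_stream(
    c(0, 0), data.frame(t_start = 0, t_end = 10, rate = 0.5))), 5, 2)$total,
    0.25)
  d <- dilution_rate(list(s1, s2), 5, 2)
  expect_equal(unname(d$per_stream), c(0.05, 0.15))
  expect_equal(d$total, 0.2)
  # outside every schedule segment the rate is zero
  expect_equal(dilution_rate(list(s1), 11, 2)$total, 0)
  expect_error(dilution_rate(list(s1), 5, 0), "volume")
})

test_that("hybrid_rhs implements the material balances", {
  sp <- species_set(c("Xv", "A"), cmax = c(1, 1))
  st <- list(feed_stream(c(0.5, 2),
                         data.frame(t_start = 0, t_end = 10, rate = 0.2)))
  state <- list(c = c(0.5, 2), V = 1, t = 1)

  # no reaction, no feed
  z <- list(feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 1, rate = 0)))
  r0 <- hybrid_rhs(state, c(0, 0), z, sp)
  expect_equal(r0$dc, c(0, 0))
  expect_equal(r0$dV, 0)

  # feeding at the current composition only changes the volume
  r1 <- hybrid_rhs(state, c(0, 0), st, sp)
  expect_equal(r1$dc, c(0, 0))
  expect_equal(r1$dV, 0.2)

  # growth-only rate vector: dXv/dt = mu * Xv, other species unchanged
  r2 <- hybrid_rhs(state, c(0.04, 0), z, sp)
  expect_equal(r2$dc, c(0.04 * 0.5, 0))

  expect_error(hybrid_rhs(state, c(1, 2, 3), z, sp), "one entry per species")
})

test_that("RK4 shows 4th-order global error decay on dc/dt = -c", {
  # single species acting as Xv with specific rate -1: dXv/dt = -Xv
  sp <- species_set("Xv", cmax = 10)
  lo <- network_layout(1, integer(), 1, "tanh")
  st <- list(feed_stream(0, data.frame(t_start = 0, t_end = 1, rate = 0)))
  errs <- vapply(c(0.5, 0.25, 0.125), function(h) {
    m <- hybrid_model(sp, lo, c(0, -1), substep = h)
    tr <- integrate_rk4(m, list(c = 1, V = 1), st, c(0, 1))
    abs(tr$conc[2, 1] - exp(-1))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 12)
  expect_lt(errs[1] / errs[2], 24)
  expect_gt(errs[2] / errs[3], 12)
  expect_lt(errs[2] / errs[3], 24)
})

test_that("dilution-only run matches the analytic washout solution", {
  sp <- species_set(c("Xv", "A"), cmax = c(10, 10))
  lo <- network_layout(2, integer(), 2, "tanh")
  m <- hybrid_model(sp, lo, rep(0, count_weights(lo)), substep = 0.1)
  Fc <- 0.05; V0 <- 2; cin <- c(0, 3); c0 <- c(1, 8)
  st <- list(feed_stream(cin, data.frame(t_start = 0, t_end = 24, rate = Fc)))
  tt <- seq(0, 24, 4)
  tr <- integrate_rk4(m, list(c = c0, V = V0), st, tt)
  Vt <- V0 + Fc * tt
  exact <- outer(V0 / Vt, c0 - cin) + matrix(cin, length(tt), 2, byrow = TRUE)
  expect_lt(max(abs(tr$conc - exact) / pmax(abs(exact), 1e-12)), 1e-6)
})

test_that("volume balance is exact for piecewise-constant schedules", {
  sp <- species_set(c("Xv", "A"), cmax = c(10, 10))
  lo <- network_layout(2, integer(), 2, "tanh")
  m <- hybrid_model(sp, lo, rep(0, count_weights(lo)), substep = 0.5)
  st <- list(
    feed_stream(c(0, 1), data.frame(t_start = c(0, 10), t_end = c(6, 20),
                                    rate = c(0.02, 0.05))),
    feed_stream(c(0, 0), data.frame(t_start = 3, t_end = 15, rate = 0.01)))
  tr <- integrate_rk4(m, list(c = c(1, 1), V = 1), st, seq(0, 24, 4))
  fed <- function(t) {
    0.02 * (pmin(t, 6)) + 0.05 * pmax(pmin(t, 20) - 10, 0) +
      0.01 * pmax(pmin(t, 15) - 3, 0)
  }
  expect_equal(tr$V, 1 + fed(seq(0, 24, 4)), tolerance = 1e-10)
})

test_that("total moles are conserved for unfed species under pure dilution", {
  sp <- species_set(c("Xv", "A"), cmax = c(10, 10))
  lo <- network_layout(2, integer(), 2, "tanh")
  m <- hybrid_model(sp, lo, rep(0, count_weights(lo)), substep = 0.25)
  st <- list(feed_stream(c(0, 0),
                         data.frame(t_start = 0, t_end = 24, rate = 0.03)))
  tr <- integrate_rk4(m, list(c = c(2, 5), V = 1.5), st, seq(0, 24, 6))
  moles <- tr$conc * tr$V
  expect_equal(moles[, 1], rep(2 * 1.5, 5), tolerance = 1e-8)
  expect_equal(moles[, 2], rep(5 * 1.5, 5), tolerance = 1e-8)
})

test_that("a trajectory with v = 0 and no feed is constant", {
  sp <- species_set(c("Xv", "A"), cmax = c(10, 10))
  lo <- network_layout(2, integer(), 2, "relu")
  m <- hybrid_model(sp, lo, rep(0, count_weights(lo)))
  st <- list(feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 1, rate = 0)))
  tr <- integrate_rk4(m, list(c = c(3, 7), V = 2), st, seq(0, 48, 24))
  expect_true(all(tr$conc[, 1] == 3) && all(tr$conc[, 2] == 7))
  expect_true(all(tr$V == 2))
})

test_that("compiled and reference R integrators agree on a hybrid model", {
  tp <- tiny_problem(7)
  m <- tp$model
  v_fun <- function(c, V, t) {
    H0 <- normalize_inputs(c, tp$species, extras = c(volume = V),
                           extras_max = c(volume = 2), layout = tp$layout)
    nn_forward(tp$layout, m$weights, H0)
  }
  tr_cpp <- integrate_rk4(m, list(c = c(1, 4, 2), V = 1.2), tp$streams,
                          tp$times)
  tr_r <- integrate_rk4(v_fun, list(c = c(1, 4, 2), V = 1.2), tp$streams,
                        tp$times, substep = 0.5, species = tp$species)
  expect_equal(tr_cpp$conc, tr_r$conc, tolerance = 1e-12)
  expect_equal(tr_cpp$V, tr_r$V, tolerance = 1e-12)
})

test_that("divergence raises a classed error carrying the failing time", {
  sp <- species_set(c("Xv", "A"), cmax = c(1, 1))
  lo <- network_layout(2, integer(), 2, "tanh")
  # huge positive growth rate: exponential blow-up to Inf
  m <- hybrid_model(sp, lo, c(0, 0, 0, 0, 50, 0), substep = 0.5)
  st <- list(feed_stream(c(0, 0), data.frame(t_start = 0, t_end = 1, rate = 0)))
  err <- tryCatch(
    integrate_rk4(m, list(c = c(1, 1), V = 1), st, seq(0, 100, 10)),
    hybridfb_divergence = function(e) e)
  expect_s3_class(err, "hybridfb_divergence")
  expect_true(is.finite(err$t_fail))
})

test_that("feed schedule breakpoints need not align with output times", {
  sp <- species_set(c("Xv", "A"), cmax = c(10, 10))
  lo <- network_layout(2, integer(), 2, "tanh")
  m <- hybrid_model(sp, lo, rep(0, count_weights(lo)), substep = 0.5)
  # breakpoint at t = 5.3, outputs every 4 h; volume must still be exact
  st <- list(feed_stream(c(0, 0),
                         data.frame(t_start = 1.1, t_end = 5.3, rate = 0.07)))
  tr <- integrate_rk4(m, list(c = c(1, 1), V = 1), st, seq(0, 8, 4))
  expect_equal(tr$V[3], 1 + 0.07 * (5.3 - 1.1), tolerance = 1e-10)
})
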