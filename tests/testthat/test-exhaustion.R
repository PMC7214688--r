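test_that("exhaustion time follows the decay criterion closed forms", {
  tr <- list(time_s = seq(0, 10, 0.01), force_N = rep(5, 1001))
  expect_equal(exhaustion_time(tr), Inf)
  # linear decay F0*(1 - 0.1 t) crosses the 5% criterion at t = 0.5
  t <- seq(0, 10, 0.001)
  tr2 <- list(time_s = t, force_N = 20 * (1 - 0.1 * t))
  # strict ">5% decayed" criterion: first grid point below the threshold
  expect_equal(exhaustion_time(tr2, 0.05, ref = "initial"), 0.5,
               tolerance = 5e-3)
  # monotone in the threshold: larger threshold, later or equal time
  thr <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  times <- vapply(thr, function(h) exhaustion_time(tr2, h), numeric(1))
  expect_true(all(diff(times) >= 0))
  # horizon truncation gives the infinity sentinel
  expect_equal(exhaustion_time(tr2, 0.05, horizon = 0.3), Inf)
  expect_error(exhaustion_time(list(time_s = numeric(0),
                                    force_N = numeric(0))), "empty")
})

test_that("steady decay rate is the Fmax-normalized window slope", {
  p <- gas_plus()
  t <- seq(0, 1.2, 0.001)
  const <- list(time_s = t, force_N = rep(40, length(t)))
  expect_equal(steady_decay_rate(const, p), 0)
  lin <- list(time_s = t, force_N = 100 - 7 * t)
  expect_equal(steady_decay_rate(lin, p), -7 / p$Fmax, tolerance = 1e-10)
  expect_error(steady_decay_rate(lin, p, window = c(1.1, 1.5)), "window")
})

test_that("theoretical decay rate and kappa fit invert each other", {
  p <- gas_plus()
  expect_equal(theoretical_decay_rate(p$lCEopt, 0.2, p), -0.2)
  expect_equal(theoretical_decay_rate(p$lCEopt, 0, p), 0)
  # noiseless rates generated at kappa = 0.163 are recovered exactly
  lces <- seq(0.8, 1.3, length.out = 6) * p$lCEopt
  rates <- theoretical_decay_rate(lces, 0.163, p)
  expect_equal(fit_kappa(rates, lces, p)$kappa, 0.163, tolerance = 1e-12)
  # same for the PLA value 0.165
  pp <- pla_plus()
  lces2 <- seq(0.9, 1.5, length.out = 6) * pp$lCEopt
  expect_equal(fit_kappa(theoretical_decay_rate(lces2, 0.165, pp),
                         lces2, pp)$kappa, 0.165, tolerance = 1e-12)
  # trivial cases
  expect_equal(fit_kappa(rep(0, 4), lces[1:4], p)$kappa, 0)
  expect_equal(fit_kappa(-0.2, p$lCEopt, p)$kappa, 0.2)
  # closed form agrees with a dense 1-D grid search
  set.seed(9)
  noisy <- rates + rnorm(6, 0, 0.01)
  grid <- seq(0, 1, length.out = 200001)
  sse <- vapply(grid, function(k)
    sum((noisy + k * isometric_force_length(lces, p) * p$lCEopt /
           lces)^2), numeric(1))
  expect_equal(fit_kappa(noisy, lces, p)$kappa, grid[which.min(sse)],
               tolerance = 1e-5)
  # non-negativity clamp
  expect_equal(fit_kappa(0.3, p$lCEopt, p)$kappa, 0)
})

test_that("steady-state force closed form matches its anchors", {
  p <- gas_plus()
  expect_equal(steady_state_force(1, 1, p$lCEopt, p),
               p$Fmax + pee_force(p$lCEopt, p))
  lce_long <- 1.3 * p$lCEopt
  expect_equal(steady_state_force(0.5, 0, lce_long, p),
               pee_force(lce_long, p))
})

test_that("steady-state force reproduces the simulator mid-plateau", {
  p <- gas_plus(); mc <- met_const()
  tr <- simulate_constant(p, mc, 0.122, u = 0.3, horizon = 2.5,
                          sample_rate = 200, stop_threshold = NULL)
  i <- which.min(abs(tr$time_s - 2.0))
  f_closed <- steady_state_force(tr$q[i], tr$mu_rel[i], tr$lce_m[i], p)
  expect_lt(abs(f_closed - tr$force_N[i]), 0.005 * p$Fmax)
})

test_that("quasi-steady window rates of the GAS batch show exhaustion", {
  p <- gas_plus(); mc <- met_const()
  sims <- simulate_batch(p, mc, default_lengths("GAS"))
  rates <- vapply(sims, steady_decay_rate, numeric(1), p = p)
  lces <- vapply(sims, function(s) {
    mean(s$lce_m[s$time_s >= 0.58 & s$time_s <= 0.68])
  }, numeric(1))
  # away from the extremes of the length series the window rates are
  # negative (exhaustion); at the shortest/longest lengths the
  # length-dependent calcium sensitivity still compensates in this window
  expect_true(all(rates[2:6] < 0))
  # strongest decay where the theoretical basis Fisom * lCEopt / lCE
  # peaks (slightly below the optimal CE length); the top two basis
  # values are near-ties, so accept either
  basis <- isometric_force_length(lces, p) * p$lCEopt / lces
  expect_true(which.min(rates) %in% order(basis, decreasing = TRUE)[1:2])
  expect_lt(min(rates), -0.01)
  # fitting the theoretical shape to the interior rates yields a
  # positive decay-rate scale
  kf <- fit_kappa(rates[2:6], lces[2:6], p)
  expect_gt(kf$kappa, 0)
})

test_that("activated-steady-state initialization starts at the held force", {
  p <- gas_plus(); mc <- met_const()
  u <- 0.5
  tr <- simulate_constant(p, mc, 0.122, u = u, horizon = 0.2,
                          sample_rate = 200, stop_threshold = NULL,
                          init = "active")
  lce0 <- active_equilibrium(0.122, u, p)
  expect_equal(tr$lce_m[1], lce0, tolerance = 1e-9)
  expect_equal(tr$gamma[1], u)
  q0 <- troponin_activity(u, lce0 / p$lCEopt, p)
  expect_equal(tr$force_N[1], steady_state_force(q0, 1, lce0, p),
               tolerance = 1e-6)
  # the active balance residual is below the static tolerance
  resid <- see_force(0.122 - lce0, p) -
    q0 * p$Fmax * isometric_force_length(lce0, p) - pee_force(lce0, p)
  expect_lt(abs(resid), 1e-10 * p$Fmax)
})

test_that("exhaustion map records cells, sentinels and steady forces", {
  p <- gas_plus(); mc <- met_const()
  map <- exhaustion_map(p, mc, lmtu_grid = c(0.117, 0.127),
                        u_grid = c(0.3, 0.7), horizon = 12,
                        sample_rate = 50)
  expect_s3_class(map, "exhaustion_map")
  expect_equal(nrow(map), 4)
  expect_true(all(is.finite(map$f_steady_N)))
  expect_true(all(map$t_exh_s > 0))
  # higher stimulation exhausts faster at both lengths
  for (l in unique(map$lmtu_m)) {
    sub <- map[map$lmtu_m == l, ]
    expect_lte(sub$t_exh_s[sub$u == 0.7], sub$t_exh_s[sub$u == 0.3])
  }
  expect_output(print(map), "Exhaustion map")
})
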