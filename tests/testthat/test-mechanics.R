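test_that("isometric force-length bell has the documented shape", {
  p <- gas_plus()
  expect_equal(isometric_force_length(p$lCEopt, p), 1)
  expect_equal(isometric_force_length(p$lCEopt * (1 - p$dW_asc), p),
               exp(-1), tolerance = 1e-12)
  expect_equal(isometric_force_length(p$lCEopt * (1 + p$dW_des), p),
               exp(-1), tolerance = 1e-12)
  # frozen high-precision oracle: exp(-(0.2/0.330)^2.36) at lCE = 1.2 lCEopt
  expect_equal(isometric_force_length(0.02376, p), 0.7358588,
               tolerance = 1e-6)
  # continuous at the optimum, maximum exactly there, range (0, 1]
  lces <- seq(0.4, 1.8, by = 0.01) * p$lCEopt
  v <- isometric_force_length(lces, p)
  expect_true(all(v > 0 & v <= 1))
  expect_equal(lces[which.max(v)], p$lCEopt)
  eps <- 1e-10
  expect_equal(isometric_force_length(p$lCEopt - eps, p),
               isometric_force_length(p$lCEopt + eps, p), tolerance = 1e-6)
  expect_error(isometric_force_length(0, p), "positive")
})

test_that("PEE power law is slack below threshold and normalized above", {
  p <- gas_plus()
  slack <- p$L_PEE * p$lCEopt
  ref <- p$lCEopt * (1 + p$dW_des)
  expect_equal(pee_force(slack, p), 0)
  expect_equal(pee_force(slack * 0.9, p), 0)
  expect_equal(pee_force(ref, p), p$F_PEE * p$Fmax, tolerance = 1e-12)
  # halfway point follows the closed-form power law
  expect_equal(pee_force(0.5 * (slack + ref), p),
               p$F_PEE * p$Fmax * 0.5^p$nu_PEE, tolerance = 1e-12)
  lces <- seq(0.5 * slack, 1.5 * ref, length.out = 200)
  expect_true(all(diff(pee_force(lces, p)) >= 0))
})

test_that("SEE toe/linear law is continuous, C1, with printed stiffness", {
  p <- pla_plus()
  l0 <- p$lSEE0
  lnll <- (1 + p$dU_SEE_nll) * l0
  expect_equal(see_force(l0, p), 0)
  expect_equal(see_force(0.9 * l0, p), 0)
  expect_equal(see_force(lnll, p), p$dF_SEE0, tolerance = 1e-12)
  # linear-region stiffness matches the printed 15.6 kN/m within 0.5%
  expect_equal(see_stiffness_linear(p) / 1000, 15.6, tolerance = 0.005)
  # C1 at the toe/linear transition: numerical derivative jump < 1e-6 rel
  h <- 1e-8
  d_lo <- (see_force(lnll, p) - see_force(lnll - h, p)) / h
  d_hi <- (see_force(lnll + h, p) - see_force(lnll, p)) / h
  expect_lt(abs(d_hi - d_lo) / d_hi, 1e-6)
  lsees <- seq(0.95 * l0, 1.2 * l0, length.out = 300)
  expect_true(all(diff(see_force(lsees, p)) >= 0))
})

test_that("Hill coefficients scale with activity and length as specified", {
  p <- gas_plus()
  hc <- hill_coefficients(1, 1, p)
  expect_equal(hc$Arel, p$Arel0)
  expect_equal(hc$Brel, p$Brel0)
  hc0 <- hill_coefficients(0, 1, p)
  expect_equal(hc0$Arel, p$Arel0 / 4)
  expect_equal(hc0$Brel, 3 * p$Brel0 / 7)
  # descending limb scales Arel by the force-length value
  hc_d <- hill_coefficients(1, 1.2, p)
  expect_equal(hc_d$Arel, p$Arel0 * isometric_force_length(1.2 * p$lCEopt, p))
  # maximum shortening velocity ratio printed for GAS-: ~80 lCEopt/s
  pm <- gas_minus()
  expect_equal(pm$Brel0 / pm$Arel0, 80, tolerance = 0.01)
  # scaling can be disabled
  p2 <- mtu_params(unclass(p)[hillphos:::.mtu_param_names],
                   hill_activity_scaling = FALSE)
  expect_equal(hill_coefficients(0.3, 1, p2)$Arel, p$Arel0)
})

test_that("CE force follows the Hill hyperbola on both branches", {
  p <- gas_plus()
  a <- 1; lce <- p$lCEopt
  expect_equal(ce_force(0, a, lce, p), a * p$Fmax, tolerance = 1e-12)
  # concentric grid matches the closed-form hyperbola
  hc <- hill_coefficients(a, 1, p)
  vmax <- hc$Brel / hc$Arel * p$lCEopt
  vs <- seq(-0.9 * vmax, 0, length.out = 100)
  oracle <- p$Fmax * ((a + hc$Arel) / (1 - vs / (hc$Brel * p$lCEopt)) -
                        hc$Arel)
  expect_equal(ce_force(vs, a, lce, p), oracle, tolerance = 1e-12)
  # eccentric branch: bounded above by and approaching F_e * a * Fmax
  f_inf <- p$F_e * a * p$Fmax
  expect_lt(ce_force(1, a, lce, p), f_inf)
  expect_equal(ce_force(1e6, a, lce, p), f_inf, tolerance = 1e-3)
  # continuity at v = 0 and monotone increasing in signed velocity
  grid <- seq(-0.5 * vmax, 0.02, length.out = 400)
  f <- ce_force(grid, 0.7, 0.9 * p$lCEopt, p)
  expect_true(all(diff(f) > 0))
  expect_equal(ce_force(-1e-10, 0.7, lce, p), ce_force(1e-10, 0.7, lce, p),
               tolerance = 1e-6)
  # slope ratio S_e at v = 0
  h <- 1e-9
  s_con <- (ce_force(0, a, lce, p) - ce_force(-h, a, lce, p)) / h
  s_ecc <- (ce_force(h, a, lce, p) - ce_force(0, a, lce, p)) / h
  expect_equal(s_ecc / s_con, p$S_e, tolerance = 1e-4)
})

test_that("serial damping coefficient follows the force-dependent law", {
  p <- gas_plus()
  p1 <- p; p1$R_SDE <- 1
  d1 <- serial_damping_coefficient(0, p1)
  expect_equal(d1, serial_damping_coefficient(100, p1))
  # frozen arithmetic oracle for GAS+ values with R_SDE = 1
  expect_equal(d1, 22.53, tolerance = 1e-3)
  p0 <- p; p0$R_SDE <- 0
  expect_equal(serial_damping_coefficient(0, p0), 0)
  expect_error(serial_damping_coefficient(-1, p), "non-negative")
})

test_that("contraction velocity solves the force balance exactly", {
  p <- gas_plus()
  # isometric steady state: lce such that SEE balances CE + PEE -> vce = 0
  a <- 0.5
  lmtu <- 0.126
  bal <- function(lce) {
    see_force(lmtu - lce, p) - a * p$Fmax * isometric_force_length(lce, p) -
      pee_force(lce, p)
  }
  lce_eq <- uniroot(bal, c(0.01, lmtu - p$lSEE0), tol = 1e-14)$root
  expect_equal(contraction_velocity(mtu_kinematics(lmtu, 0, lce_eq), a, p),
               0, tolerance = 1e-8)
  # every returned root satisfies the residual bound, vs bisection oracle
  oracle_vce <- function(kin, a, p) {
    fis <- isometric_force_length(kin$lce, p)
    fpee <- pee_force(kin$lce, p)
    fsee <- see_force(kin$lsee, p)
    dse <- serial_damping_coefficient(max(a * fis * p$Fmax + fpee, 0), p)
    g <- function(v) ce_force(v, a, kin$lce, p) + fpee - fsee -
      dse * (kin$vmtu - v)
    uniroot(g, c(-50, 50), tol = 1e-13, extendInt = "upX")$root
  }
  set.seed(42)
  for (i in 1:1000) {
    pp <- if (i %% 2) gas_plus() else pla_plus()
    lmtu <- runif(1, pp$lSEE0 + 0.5 * pp$lCEopt, pp$lSEE0 + 2.5 * pp$lCEopt)
    lce <- runif(1, 0.5, 1.6) * pp$lCEopt
    if (lce >= lmtu) next
    a <- runif(1)
    kin <- mtu_kinematics(lmtu, 0, lce)
    v <- contraction_velocity(kin, a, pp)
    expect_equal(v, oracle_vce(kin, a, pp), tolerance = 1e-8)
  }
})

test_that("passive equilibrium balances statics and behaves monotonically", {
  p <- pla_plus()
  # static balance residual below 1e-10 * Fmax
  lce <- passive_equilibrium(0.124, p$q_min, p)
  resid <- see_force(0.124 - lce, p) -
    p$q_min * p$Fmax * isometric_force_length(lce, p) - pee_force(lce, p)
  expect_lt(abs(resid), 1e-10 * p$Fmax)
  # passive force at the longest PLA length stays below 10% Fmax
  expect_lt(see_force(0.124 - lce, p), 0.10 * p$Fmax)
  # equilibrium MTU force never decreases when the MTU is lengthened
  lmtus <- seq(0.108, 0.132, length.out = 50)
  forces <- vapply(lmtus, function(l) {
    lc <- passive_equilibrium(l, p$q_min, p)
    see_force(l - lc, p)
  }, numeric(1))
  expect_true(all(diff(forces) >= -1e-9))
  # degenerate slack case: infimum of the slack interval, SEE just slack
  g <- gas_plus()
  lmtu_short <- g$lSEE0 + 0.5 * g$L_PEE * g$lCEopt
  expect_equal(passive_equilibrium(lmtu_short, 0, g),
               lmtu_short - g$lSEE0)
  expect_error(passive_equilibrium(g$lSEE0 * 0.99, 0, g), "slack")
})
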