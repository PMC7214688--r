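# Fast scalar core for the coupled ODE right-hand side. All parameter
# accesses are hoisted into the closure environment and the equilibrium
# projection uses an analytic-derivative Newton, so the integrator's many
# RHS evaluations stay cheap. The public element-wise functions
# (see_force, pee_force, equilibrate_pools, contraction_velocity, ...)
# define the model; this core must agree with them to solver precision and
# is cross-checked against them in the test suite.

.make_model_fns <- function(p, metabolic, lmtu, use_phos) {
  # mechanical constants
  lCEopt <- p$lCEopt; Fmax <- p$Fmax
  dW_asc <- p$dW_asc; dW_des <- p$dW_des
  nu_asc <- p$nu_asc; nu_des <- p$nu_des
  slack_pee <- p$L_PEE * lCEopt
  K_PEE <- p$F_PEE * Fmax / (lCEopt * (1 + p$dW_des) - slack_pee)^p$nu_PEE
  nu_PEE <- p$nu_PEE
  l0 <- p$lSEE0; lnll <- (1 + p$dU_SEE_nll) * l0
  nu_SEE <- p$dU_SEE_nll / p$dU_SEE_l
  Klin <- p$dF_SEE0 / (p$dU_SEE_l * l0); dF0 <- p$dF_SEE0
  Arel0 <- p$Arel0; Brel0 <- p$Brel0
  R_SDE <- p$R_SDE; S_e <- p$S_e; F_e <- p$F_e
  dmax <- p$D_SDE * Fmax * Arel0 / (lCEopt * Brel0)
  q_min <- p$q_min; omega_opt <- p$omega_opt
  nu_act <- p$nu_act; gamma_rho <- p$gamma_rho; m_act <- p$m_act
  khyd_hat <- p$khyd_hat
  qscale <- p$hill_activity_scaling

  fisom <- function(lce) {
    rel <- lce / lCEopt - 1
    if (rel < 0) exp(-(-rel / dW_asc)^nu_asc)
    else exp(-(rel / dW_des)^nu_des)
  }
  fpee <- function(lce) {
    if (lce > slack_pee) K_PEE * (lce - slack_pee)^nu_PEE else 0
  }
  fsee <- function(lsee) {
    if (lsee <= l0) 0
    else if (lsee <= lnll) dF0 * ((lsee - l0) / (lnll - l0))^nu_SEE
    else dF0 + Klin * (lsee - lnll)
  }

  # metabolic constants (only touched when use_phos)
  if (use_phos) {
    c_ad <- metabolic$c_ad; c_cr <- metabolic$c_cr
    c_ph <- metabolic$c_ph
    K_adk <- metabolic$K_adk; K_ck <- metabolic$K_ck
    k_con <- metabolic$k_con; c0 <- metabolic$c0
    RT <- metabolic$R_gas * metabolic$temperature
    mu_max <- metabolic$mu_ATP_max; dG0 <- metabolic$dG0_ATP
    ATPmin <- metabolic$ATPmin
    nucl <- metabolic$accounting == "nucleotide"
    floor_state <- .atp_floor_state(metabolic)
    fs_mu <- (-metabolic$dG0_ATP +
                metabolic$R_gas * metabolic$temperature *
                log(floor_state$ATP * metabolic$c0 /
                      (floor_state$ADP * floor_state$Pi))) /
      metabolic$mu_ATP_max
    cache <- new.env(parent = emptyenv())
    cache$d <- metabolic$ADP0

    # analytic-derivative Newton for the [ADP] root of the projection
    project <- function(Pi) {
      # guard against integrator trial states outside the domain
      if (!is.finite(Pi) || Pi <= 0) Pi <- 1e-12
      if (Pi >= floor_state$Pi) {
        fs <- floor_state
        return(list(ATP = fs$ATP, ADP = fs$ADP, AMP = fs$AMP, Pi = fs$Pi,
                    PCr = fs$PCr, Cr = fs$Cr, mu = fs_mu, clamped = TRUE))
      }
      lo <- 1e-12; hi <- floor_state$ADP
      d <- cache$d
      if (!is.finite(d) || d <= lo || d >= hi) d <- 0.5 * (lo + hi)
      for (it in 1:60) {
        s <- c_ad - d
        disc <- s * s - 4 * K_adk * d * d
        if (disc <= 0) { hi <- d; d <- 0.5 * (lo + hi); next }
        sq <- sqrt(disc)
        ATP <- 0.5 * (s + sq)
        dATP <- 0.5 * (-1 - (s + 4 * K_adk * d) / sq)
        AMP <- K_adk * d * d / ATP
        dAMP <- K_adk * (2 * d * ATP - d * d * dATP) / (ATP * ATP)
        r <- K_ck * d / ATP
        PCr <- c_cr / (1 + r)
        dr <- K_ck * (ATP - d * dATP) / (ATP * ATP)
        dPCr <- -c_cr * dr / (1 + r)^2
        f <- Pi + PCr - c_ph
        fp <- dPCr
        if (nucl) {
          f <- f + 3 * ATP + 2 * d + AMP
          fp <- fp + 3 * dATP + 2 + dAMP
        }
        if (f > 0) lo <- d else hi <- d
        step <- -f / fp
        dn <- d + step
        if (!is.finite(dn) || dn <= lo || dn >= hi) dn <- 0.5 * (lo + hi)
        if (abs(dn - d) < 1e-13 * c_ad) { d <- dn; break }
        d <- dn
      }
      cache$d <- d
      s <- c_ad - d
      ATP <- 0.5 * (s + sqrt(max(s * s - 4 * K_adk * d * d, 0)))
      AMP <- K_adk * d * d / ATP
      PCr <- c_cr / (1 + K_ck * d / ATP)
      mu <- (-dG0 + RT * log(ATP * c0 / (d * Pi))) / mu_max
      list(ATP = ATP, ADP = d, AMP = AMP, Pi = Pi, PCr = PCr,
           Cr = c_cr - PCr, mu = mu, clamped = FALSE)
    }
  } else {
    project <- NULL
  }

  # CE velocity from the per-branch quadratic; slow-path fallback
  vce_solve <- function(lce, a) {
    fis <- fisom(lce)
    af <- a * fis
    fsee_v <- fsee(lmtu - lce)
    fpee_v <- fpee(lce)
    LA <- if (lce <= lCEopt) 1 else fis
    if (qscale) {
      QA <- (1 + 3 * a) / 4; QB <- (3 + 4 * a) / 7
    } else QA <- QB <- 1
    Arel <- Arel0 * LA * QA; Brel <- Brel0 * QB
    dse <- dmax * ((1 - R_SDE) * max(af * Fmax + fpee_v, 0) / Fmax + R_SDE)
    g0 <- af * Fmax + fpee_v - fsee_v
    tol <- 1e-9 * Fmax
    if (abs(g0) <= tol) {
      return(list(vce = 0, fsee = fsee_v, dse = dse, fisom = fis))
    }
    if (g0 > 0) { A <- Arel; B <- Brel } else {
      A <- -F_e * af
      B <- af * (1 - F_e) * Brel / (S_e * (af + Arel))
    }
    lB <- B * lCEopt
    r0 <- fpee_v - fsee_v - A * Fmax
    a2 <- -dse / lB
    a1 <- dse - r0 / lB
    a0 <- Fmax * (af + A) + r0
    v <- NA_real_
    for (root in .quad_roots(a2, a1, a0)) {
      if (!is.finite(root)) next
      if ((g0 > 0 && root <= 0) || (g0 < 0 && root >= 0)) {
        gres <- Fmax * ((af + A) / (1 - root / lB) - A) + fpee_v -
          fsee_v + dse * root
        if (abs(gres) <= tol) { v <- root; break }
      }
    }
    if (is.na(v)) {
      v <- contraction_velocity(mtu_kinematics(lmtu, 0, lce), a, p)
    }
    list(vce = v, fsee = fsee_v, dse = dse, fisom = fis)
  }

  qact <- function(gamma, lce) {
    s <- (omega_opt * (lce / lCEopt)^gamma_rho * gamma)^nu_act
    (q_min + s) / (1 + s)
  }

  deriv <- function(t, y, parms, u) {
    gamma <- min(max(y[1], 0), 1)
    lce <- y[2]
    q <- qact(gamma, lce)
    if (use_phos) {
      st <- project(y[3])
      mu <- max(st$mu, 0)
      a <- min(q * mu, 1)
      khyd <- if (st$clamped) 0 else khyd_hat * q / (lce / lCEopt)
      dPi <- khyd * st$ATP - k_con * st$ADP * st$Pi / c0
      vs <- vce_solve(lce, a)
      list(c(m_act * (u - gamma), vs$vce, dPi))
    } else {
      a <- min(q, 1)
      vs <- vce_solve(lce, a)
      list(c(m_act * (u - gamma), vs$vce))
    }
  }

  # full observable set at one state (for output assembly)
  evaluate <- function(y) {
    gamma <- min(max(y[1], 0), 1)
    lce <- y[2]
    q <- qact(gamma, lce)
    if (use_phos) {
      st <- project(y[3])
      mu <- max(st$mu, 0)
    } else {
      st <- NULL
      mu <- 1
    }
    a <- min(q * mu, 1)
    vs <- vce_solve(lce, a)
    force <- vs$fsee + vs$dse * (0 - vs$vce)
    c(force = force, lce = lce, gamma = gamma, q = q, a = a,
      atp = if (use_phos) st$ATP else NA_real_,
      adp = if (use_phos) st$ADP else NA_real_,
      amp = if (use_phos) st$AMP else NA_real_,
      pi = if (use_phos) st$Pi else NA_real_,
      pcr = if (use_phos) st$PCr else NA_real_,
      cr = if (use_phos) st$Cr else NA_real_,
      mu = mu)
  }

  list(deriv = deriv, evaluate = evaluate)
}
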