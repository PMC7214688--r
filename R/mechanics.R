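# Force laws of the four MTU elements (CE, SEE, PEE, SDE) and the
# contraction dynamics that yield the CE velocity from force balance.
#
# Topology: CE parallel PEE, in series with SEE parallel SDE.
# lMTU = lCE + lSEE, force balance F_CE + F_PEE = F_SEE + F_SDE.

#' Normalized isometric force-length relation
#'
#' Bell-shaped force-length curve of the contractile element,
#' \code{exp(-|(lCE/lCEopt - 1)/dW|^nu)}, with separate width/exponent pairs
#' for the ascending (\code{dW_asc}, \code{nu_asc}; \code{lCE < lCEopt}) and
#' descending (\code{dW_des}, \code{nu_des}) branches. Value 1 exactly at
#' optimal CE length.
#'
#' @param lce CE length, m (vectorized).
#' @param p an [mtu_params()] object.
#' @return normalized force in (0, 1].
#' @export
isometric_force_length <- function(lce, p) {
  if (any(lce <= 0)) stop("lce must be strictly positive")
  rel <- lce / p$lCEopt - 1
  dW <- ifelse(rel < 0, p$dW_asc, p$dW_des)
  nu <- ifelse(rel < 0, p$nu_asc, p$nu_des)
  exp(-abs(rel / dW)^nu)
}

#' Parallel elastic element force
#'
#' Power-law spring, slack below \code{L_PEE * lCEopt}:
#' \code{F = K_PEE * (lCE - L_PEE*lCEopt)^nu_PEE} above slack, with
#' \code{K_PEE} normalized so that the force equals \code{F_PEE * Fmax} at
#' the end of the descending force-length branch,
#' \code{lCE = lCEopt * (1 + dW_des)}.
#'
#' @inheritParams isometric_force_length
#' @return force, N (non-negative, non-decreasing in \code{lce}).
#' @export
pee_force <- function(lce, p) {
  if (any(lce <= 0)) stop("lce must be strictly positive")
  slack <- p$L_PEE * p$lCEopt
  ref <- p$lCEopt * (1 + p$dW_des)
  if (ref <= slack) stop("PEE normalization point lies below slack length")
  K <- p$F_PEE * p$Fmax / (ref - slack)^p$nu_PEE
  ifelse(lce > slack, K * (lce - slack)^p$nu_PEE, 0)
}

#' Serial elastic element force
#'
#' Piecewise tendon force-extension law: slack below \code{lSEE0}, a
#' nonlinear toe region up to \code{lSEE_nll = (1 + dU_SEE_nll) * lSEE0}
#' where the force reaches \code{dF_SEE0}, and a linear region above with
#' stiffness \code{K_SEE_l = dF_SEE0 / (dU_SEE_l * lSEE0)}. The toe exponent
#' \code{nu_SEE = dU_SEE_nll / dU_SEE_l} makes the transition continuously
#' differentiable.
#'
#' @param lsee SEE length, m (vectorized).
#' @param p an [mtu_params()] object.
#' @return force, N.
#' @export
see_force <- function(lsee, p) {
  if (any(lsee < 0)) stop("lsee must be non-negative")
  l0 <- p$lSEE0
  lnll <- (1 + p$dU_SEE_nll) * l0
  nu <- p$dU_SEE_nll / p$dU_SEE_l
  Klin <- p$dF_SEE0 / (p$dU_SEE_l * l0)
  out <- numeric(length(lsee))
  toe <- lsee > l0 & lsee <= lnll
  lin <- lsee > lnll
  out[toe] <- p$dF_SEE0 * ((lsee[toe] - l0) / (lnll - l0))^nu
  out[lin] <- p$dF_SEE0 + Klin * (lsee[lin] - lnll)
  out
}

#' Linear-region SEE stiffness
#'
#' @param p an [mtu_params()] object.
#' @return stiffness \code{dF_SEE0 / (dU_SEE_l * lSEE0)}, N/m.
#' @export
see_stiffness_linear <- function(p) p$dF_SEE0 / (p$dU_SEE_l * p$lSEE0)

#' Activity-scaled Hill constants
#'
#' Hill force-velocity constants scaled by CE length and muscle activity:
#' \code{Arel = Arel0 * L_A(lCE_rel) * Q_A(a)} and
#' \code{Brel = Brel0 * Q_B(a)}, where \code{L_A} is 1 on the ascending limb
#' and the normalized isometric force on the descending limb, and
#' \code{Q_A(a) = (1+3a)/4}, \code{Q_B(a) = (3+4a)/7} (disabled when the
#' parameter set was built with \code{hill_activity_scaling = FALSE}).
#'
#' @param a muscle activity in [0, 1].
#' @param lce_rel CE length relative to optimal, dimensionless.
#' @param p an [mtu_params()] object.
#' @return list with elements \code{Arel} (dimensionless) and \code{Brel}
#'   (1/s).
#' @export
hill_coefficients <- function(a, lce_rel, p) {
  stopifnot(a >= 0, a <= 1 + 1e-12)
  LA <- if (lce_rel <= 1) 1 else isometric_force_length(lce_rel * p$lCEopt, p)
  if (p$hill_activity_scaling) {
    QA <- (1 + 3 * a) / 4
    QB <- (3 + 4 * a) / 7
  } else {
    QA <- QB <- 1
  }
  list(Arel = p$Arel0 * LA * QA, Brel = p$Brel0 * QB)
}

#' Contractile element force
#'
#' Hill's hyperbolic force-velocity relation on the concentric branch
#' (\code{vCE <= 0}, shortening negative) and the mirrored eccentric
#' hyperbola for lengthening, constructed so that force and slope ratio
#' \code{S_e} are continuous at \code{vCE = 0} and the eccentric force
#' saturates at \code{F_e * a * Fisom * Fmax}.
#'
#' @param vce CE velocity, m/s (negative = shortening).
#' @param a muscle activity in [0, 1].
#' @param lce CE length, m.
#' @param p an [mtu_params()] object.
#' @return force, N.
#' @export
ce_force <- function(vce, a, lce, p) {
  stopifnot(a >= 0, a <= 1 + 1e-12)
  fis <- isometric_force_length(lce, p)
  hc <- hill_coefficients(a, lce / p$lCEopt, p)
  vapply(vce, function(v) {
    if (v <= 0) {
      .ce_force_con(v, a * fis, hc$Arel, hc$Brel, p)
    } else {
      .ce_force_ecc(v, a * fis, hc$Arel, hc$Brel, p)
    }
  }, numeric(1))
}

# concentric branch: F = Fmax * ((af + Arel)/(1 - v/(Brel*lCEopt)) - Arel)
.ce_force_con <- function(v, af, Arel, Brel, p) {
  p$Fmax * ((af + Arel) / (1 - v / (Brel * p$lCEopt)) - Arel)
}

# eccentric branch parameters: negative hyperbola with asymptote F_e*af*Fmax
# and slope at v = 0 equal to S_e times the concentric slope.
.ecc_coefficients <- function(af, Arel, Brel, p) {
  Ae <- -p$F_e * af
  Be <- af * (1 - p$F_e) * Brel / (p$S_e * (af + Arel))
  list(Ae = Ae, Be = Be)
}

.ce_force_ecc <- function(v, af, Arel, Brel, p) {
  ec <- .ecc_coefficients(af, Arel, Brel, p)
  p$Fmax * ((af + ec$Ae) / (1 - v / (ec$Be * p$lCEopt)) - ec$Ae)
}

#' Serial damping coefficient
#'
#' Force-dependent damping of the serial damping element,
#' \code{d_SE = D_SDE * (Fmax*Arel0)/(lCEopt*Brel0) *
#' ((1 - R_SDE) * F_ce_pee/Fmax + R_SDE)}. With \code{R_SDE = 1} the damping
#' is force independent.
#'
#' @param F_ce_pee force carried by CE plus PEE, N (non-negative).
#' @param p an [mtu_params()] object.
#' @return damping coefficient, N s/m.
#' @export
serial_damping_coefficient <- function(F_ce_pee, p) {
  if (any(F_ce_pee < 0)) stop("F_ce_pee must be non-negative")
  dmax <- p$D_SDE * p$Fmax * p$Arel0 / (p$lCEopt * p$Brel0)
  dmax * ((1 - p$R_SDE) * F_ce_pee / p$Fmax + p$R_SDE)
}

#' MTU kinematic state
#'
#' @param lmtu MTU length, m.
#' @param vmtu MTU lengthening rate, m/s.
#' @param lce CE length, m (must satisfy \code{0 < lce < lmtu}).
#' @return a list with class \code{mtu_kinematics}; \code{lsee} is derived
#'   as \code{lmtu - lce}.
#' @export
mtu_kinematics <- function(lmtu, vmtu = 0, lce) {
  if (lce <= 0 || lce >= lmtu) stop("require 0 < lce < lmtu")
  structure(list(lmtu = lmtu, vmtu = vmtu, lce = lce, lsee = lmtu - lce),
            class = "mtu_kinematics")
}

#' CE contraction velocity from force balance
#'
#' Solves \code{F_SEE(lSEE) + d_SE * (vMTU - vCE) = F_CE(vCE) + F_PEE(lCE)}
#' for \code{vCE}. Because the damping force is linear and the CE force
#' hyperbolic in \code{vCE}, the balance is quadratic on each branch; the
#' analytic root is used, with a bracketed \code{uniroot} fallback. Branch
#' choice is by sign consistency: the residual at \code{vCE = 0} decides
#' concentric vs eccentric, with the concentric branch preferred at exact
#' ties. The damping coefficient is evaluated at the isometric CE+PEE force
#' (see [serial_damping_coefficient()]), keeping the damper linear in
#' \code{vCE}.
#'
#' @param kin an [mtu_kinematics()] object.
#' @param a muscle activity in [0, 1].
#' @param p an [mtu_params()] object.
#' @return CE velocity \code{vCE}, m/s; the balance residual at the returned
#'   root is below \code{1e-9 * Fmax}.
#' @export
contraction_velocity <- function(kin, a, p) {
  fis <- isometric_force_length(kin$lce, p)
  af <- a * fis
  hc <- hill_coefficients(a, kin$lce / p$lCEopt, p)
  fsee <- see_force(kin$lsee, p)
  fpee <- pee_force(kin$lce, p)
  dse <- serial_damping_coefficient(max(af * p$Fmax + fpee, 0), p)
  # residual g(v) = F_CE(v) + F_PEE - F_SEE - d_SE*(vMTU - v); g increasing
  g <- function(v) {
    fce <- if (v <= 0) .ce_force_con(v, af, hc$Arel, hc$Brel, p)
           else .ce_force_ecc(v, af, hc$Arel, hc$Brel, p)
    fce + fpee - fsee - dse * (kin$vmtu - v)
  }
  g0 <- g(0)
  tol <- 1e-9 * p$Fmax
  if (abs(g0) <= tol) return(0)
  if (g0 > 0) {
    # CE side too strong at v = 0: shortening, concentric branch
    v <- .solve_branch(af, hc$Arel, hc$Brel, fpee - fsee - dse * kin$vmtu,
                       dse, p, concentric = TRUE, g = g)
  } else {
    ec <- .ecc_coefficients(af, hc$Arel, hc$Brel, p)
    v <- .solve_branch(af, ec$Ae, ec$Be, fpee - fsee - dse * kin$vmtu,
                       dse, p, concentric = FALSE, g = g)
  }
  if (is.na(v) || abs(g(v)) > tol) {
    stop(sprintf(paste0("contraction_velocity: no consistent root ",
                        "(lmtu=%.6f, lce=%.6f, a=%.4f, g(0)=%.3e)"),
                 kin$lmtu, kin$lce, a, g0))
  }
  v
}

# Solve Fmax*((af+A)/(1 - v/(B*lopt)) - A) + R0 + dse*v = 0 for v on one
# branch, where R0 collects the v-independent terms. Multiplying by
# (1 - v/(B*lopt)) gives a quadratic; pick the root on the correct side of
# the branch pole with the correct sign, else bisect.
.solve_branch <- function(af, A, B, R0, dse, p, concentric, g) {
  lB <- B * p$lCEopt
  C <- af + A
  r0 <- R0 - A * p$Fmax
  a2 <- -dse / lB
  a1 <- dse - r0 / lB
  a0 <- p$Fmax * C + r0
  roots <- .quad_roots(a2, a1, a0)
  ok <- if (concentric) {
    # v in (pole, 0]; pole = lB > 0 so any v <= 0 is on-branch
    roots[roots <= 0 & is.finite(roots)]
  } else {
    # eccentric: B < 0 so pole lB < 0; branch is v >= 0
    roots[roots >= 0 & is.finite(roots)]
  }
  ok <- ok[abs(vapply(ok, g, numeric(1))) <= 1e-9 * p$Fmax]
  if (length(ok)) return(ok[which.min(abs(ok))])
  # bisection fallback on g (monotone increasing in v)
  if (concentric) {
    lo <- -p$lCEopt
    while (g(lo) > 0 && lo > -1e6) lo <- lo * 2
    if (g(lo) > 0) return(NA_real_)
    stats::uniroot(g, c(lo, 0), tol = 1e-14)$root
  } else {
    hi <- p$lCEopt
    while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (g(hi) < 0) return(NA_real_)
    stats::uniroot(g, c(0, hi), tol = 1e-14)$root
  }
}

.quad_roots <- function(a2, a1, a0) {
  if (abs(a2) < 1e-300) {
    if (abs(a1) < 1e-300) return(numeric(0))
    return(-a0 / a1)
  }
  disc <- a1 * a1 - 4 * a2 * a0
  if (disc < 0) return(numeric(0))
  s <- sqrt(disc)
  # numerically stable quadratic roots
  q <- -0.5 * (a1 + sign(a1 + (a1 == 0)) * s)
  r <- c(q / a2, if (abs(q) > 0) a0 / q else -a1 / a2 / 2)
  unique(r)
}

#' Active isometric equilibrium CE length
#'
#' CE length at which the SEE balances the active CE force plus the PEE
#' force for a held calcium level \code{gamma} with fresh metabolites
#' (relative chemical potential 1):
#' \code{F_SEE(lMTU - lCE) = q(gamma, lCE) * Fmax * Fisom(lCE) +
#' F_PEE(lCE)}. Used to start constant-stimulation runs at their activated
#' steady state.
#'
#' @param lmtu MTU length, m (must exceed \code{lSEE0}).
#' @param gamma held normalized calcium level in [0, 1].
#' @param p an [mtu_params()] object.
#' @param mu_rel relative chemical potential at the initial instant.
#' @return equilibrium CE length, m.
#' @export
active_equilibrium <- function(lmtu, gamma, p, mu_rel = 1) {
  if (lmtu <= p$lSEE0) stop("MTU shorter than tendon slack length")
  h <- function(lce) {
    a <- min(troponin_activity(gamma, lce / p$lCEopt, p) * mu_rel, 1)
    see_force(lmtu - lce, p) -
      a * p$Fmax * isometric_force_length(lce, p) - pee_force(lce, p)
  }
  lo <- 1e-6 * p$lCEopt
  hi <- lmtu - p$lSEE0
  if (h(lo) < 0 || h(hi) > 0) {
    stop("active_equilibrium: no root in bracket")
  }
  r <- stats::uniroot(h, c(lo, hi), tol = 1e-15)$root
  for (i in 1:60) {
    if (abs(h(r)) < 1e-10 * p$Fmax) break
    if (h(r) > 0) lo <- r else hi <- r
    r <- 0.5 * (lo + hi)
  }
  r
}

#' Passive (pre-stimulation) equilibrium CE length
#'
#' Finds the CE length at which the SEE force balances the resting CE force
#' plus the PEE force at fixed MTU length:
#' \code{F_SEE(lMTU - lCE) = a_rest * Fmax * Fisom(lCE) + F_PEE(lCE)}.
#' In the degenerate zero-force case (\code{a_rest = 0} and the MTU short
#' enough that both elastic elements can be slack simultaneously) the
#' infimum of the slack interval, \code{lMTU - lSEE0}, is returned as the
#' deterministic tie-break.
#'
#' @param lmtu MTU length, m (must exceed \code{lSEE0}).
#' @param a_rest resting activity (typically \code{q_min}).
#' @param p an [mtu_params()] object.
#' @return equilibrium CE length, m.
#' @export
passive_equilibrium <- function(lmtu, a_rest, p) {
  if (lmtu <= p$lSEE0) stop("MTU shorter than tendon slack length")
  if (a_rest == 0 && lmtu <= p$lSEE0 + p$L_PEE * p$lCEopt) {
    return(lmtu - p$lSEE0)
  }
  h <- function(lce) {
    see_force(lmtu - lce, p) -
      a_rest * p$Fmax * isometric_force_length(lce, p) - pee_force(lce, p)
  }
  lo <- 1e-6 * p$lCEopt
  hi <- lmtu - p$lSEE0
  if (h(lo) < 0 || h(hi) > 0) {
    stop("passive_equilibrium: no root in bracket (MTU too short/long)")
  }
  r <- stats::uniroot(h, c(lo, hi), tol = 1e-15)$root
  # polish by bisection to the force tolerance
  for (i in 1:60) {
    if (abs(h(r)) < 1e-10 * p$Fmax) break
    if (h(r) > 0) lo <- r else hi <- r
    r <- 0.5 * (lo + hi)
  }
  r
}
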