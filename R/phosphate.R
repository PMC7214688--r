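# Phosphate kinetics: the ATP-ADP-Pi hydrolysis/condensation ODE, the
# creatine-kinase / adenylate-kinase equilibrium projection under strict
# pool conservation, and the relative chemical potential of ATP.
#
# The dynamic state is the free inorganic phosphate concentration [Pi]; all
# other metabolite concentrations are algebraic functions of [Pi] on the
# equilibrium/conservation manifold (a differential-algebraic system solved
# by projection).

#' Effective ATP hydrolysis rate constant
#'
#' \code{k_hyd = khyd_hat * q / lce_rel}: hydrolysis scales linearly with
#' troponin activity (no active sites, no myosin ATPase turnover) and
#' inversely with relative CE length. \code{khyd_hat} is the rate at full
#' activity and optimal length.
#'
#' @param q troponin activity.
#' @param lce_rel CE length relative to optimal (> 0).
#' @param khyd_hat hydrolysis rate constant at (1, 1), 1/s.
#' @return rate constant, 1/s.
#' @export
hydrolysis_rate <- function(q, lce_rel, khyd_hat) {
  if (any(lce_rel <= 0)) stop("lce_rel must be strictly positive")
  khyd_hat * q / lce_rel
}

#' Net inorganic phosphate production rate
#'
#' The hydrolysis/condensation ODE,
#' \code{d[Pi]/dt = k_hyd * [ATP] - k_con * [ADP] * [Pi] / c0},
#' with concentrations in mM and the standard concentration \code{c0}
#' (1 M = 1000 mM) normalizing the second-order condensation term so that
#' both rate constants carry units 1/s. The rate vanishes exactly at the
#' hydrolysis/condensation equilibrium
#' \code{[ATP] c0 / ([ADP][Pi]) = k_con / k_hyd}.
#'
#' @param state a [metabolic_state()] (or any list with \code{ATP},
#'   \code{ADP}, \code{Pi} in mM).
#' @param k_hyd effective hydrolysis rate constant, 1/s.
#' @param mc a [metabolic_constants()] object.
#' @return rate, mM/s.
#' @export
pi_rate <- function(state, k_hyd, mc) {
  k_hyd * state$ATP - mc$k_con * state$ADP * state$Pi / mc$c0
}

#' Metabolic state container
#'
#' @param ATP,ADP,AMP,Pi,PCr,Cr concentrations, mM.
#' @param mu_rel relative chemical potential of ATP, dimensionless.
#' @param atp_clamped logical flag: TRUE when the [ATP] floor
#'   (\code{ATPmin}) binds.
#' @return a list with class \code{metabolic_state}.
#' @export
metabolic_state <- function(ATP, ADP, AMP, Pi, PCr, Cr, mu_rel = NA_real_,
                            atp_clamped = FALSE) {
  structure(list(ATP = ATP, ADP = ADP, AMP = AMP, Pi = Pi, PCr = PCr,
                 Cr = Cr, mu_rel = mu_rel, atp_clamped = atp_clamped),
            class = "metabolic_state")
}

#' @export
print.metabolic_state <- function(x, ...) {
  cat("Metabolic state [mM]:\n")
  print(signif(unlist(x[c("ATP", "ADP", "AMP", "Pi", "PCr", "Cr")]), 5))
  cat("mu_rel:", signif(x$mu_rel, 5),
      if (isTRUE(x$atp_clamped)) "(ATP floor active)" else "", "\n")
  invisible(x)
}

# phosphate bound per species under the chosen accounting
.phosphate_total <- function(ATP, ADP, AMP, Pi, PCr, mc) {
  if (mc$accounting == "nucleotide") {
    Pi + PCr + 3 * ATP + 2 * ADP + AMP
  } else {
    Pi + PCr
  }
}

# Given ADP = d, the adenine pool + AdK equilibrium fix ATP and AMP
# (ATP*AMP = K_adk d^2, ATP + AMP = c_ad - d; ATP is the larger root), and
# the creatine pool + CK equilibrium fix PCr and Cr.
.pools_from_adp <- function(d, mc) {
  s <- mc$c_ad - d
  disc <- s * s - 4 * mc$K_adk * d * d
  if (disc < 0) return(NULL)
  ATP <- 0.5 * (s + sqrt(disc))
  AMP <- mc$K_adk * d * d / ATP
  PCr <- mc$c_cr / (1 + mc$K_ck * d / ATP)
  Cr <- mc$c_cr - PCr
  list(ATP = ATP, ADP = d, AMP = AMP, PCr = PCr, Cr = Cr)
}

#' Project onto the CK/AdK equilibrium and conservation manifold
#'
#' Given the ODE-advanced free inorganic phosphate concentration, solves for
#' the unique metabolite state satisfying the creatine-kinase equilibrium
#' \code{K_ck = [ATP][Cr]/([ADP][PCr])}, the adenylate-kinase equilibrium
#' \code{K_adk = [ATP][AMP]/[ADP]^2}, and conservation of the adenine,
#' creatine and phosphate pools. The scalar unknown is [ADP]; the residual
#' of the phosphate balance is strictly decreasing in it, so Newton
#' iteration with a bisection safeguard converges to machine precision.
#'
#' When the solution would push [ATP] below \code{ATPmin}, the returned
#' state is the boundary state at \code{[ATP] = ATPmin} and
#' \code{atp_clamped} is set; callers zero the hydrolysis flux while the
#' clamp binds.
#'
#' @param Pi_target free inorganic phosphate, mM.
#' @param mc a [metabolic_constants()] object.
#' @param d_init optional warm-start value for the [ADP] root (used by the
#'   integrator, where consecutive calls are close).
#' @return a [metabolic_state()] with \code{mu_rel} filled in.
#' @export
equilibrate_pools <- function(Pi_target, mc, d_init = NULL) {
  if (Pi_target <= 0) stop("Pi_target must be positive")
  if (Pi_target >= mc$c_ph) {
    stop(sprintf("Pi_target = %g mM outside the feasible pool range",
                 Pi_target))
  }
  floor_st <- .atp_floor_state(mc)
  if (Pi_target >= floor_st$Pi) {
    st <- metabolic_state(floor_st$ATP, floor_st$ADP, floor_st$AMP,
                          Pi = floor_st$Pi, PCr = floor_st$PCr,
                          Cr = floor_st$Cr, atp_clamped = TRUE)
    st$mu_rel <- chemical_potential(st, mc)
    return(st)
  }
  resid <- function(d) {
    pools <- .pools_from_adp(d, mc)
    if (is.null(pools)) return(NA_real_)
    Pi_target +
      .phosphate_total(pools$ATP, d, pools$AMP, 0, pools$PCr, mc) - mc$c_ph
  }
  lo <- 1e-12
  hi <- floor_st$ADP
  flo <- resid(lo)
  if (flo < 0) {
    stop(sprintf("Pi_target = %g mM outside the feasible pool range",
                 Pi_target))
  }
  d <- .newton_bisect(resid, lo, hi, tol = 1e-13 * mc$c_ad,
                      init = d_init)
  pools <- .pools_from_adp(d, mc)
  st <- metabolic_state(pools$ATP, pools$ADP, pools$AMP, Pi = Pi_target,
                        PCr = pools$PCr, Cr = pools$Cr,
                        atp_clamped = FALSE)
  st$mu_rel <- chemical_potential(st, mc)
  st
}

# Boundary state where the [ATP] floor binds. On the physical branch of
# the adenylate-kinase equilibrium (ATP >= AMP) the smallest reachable
# ATP is c_ad*sqrt(K_adk)/(1+2*sqrt(K_adk)), where the adenine quadratic
# pinches; the binding floor is ATPmin or that branch minimum (slightly
# inset for conditioning), whichever is larger.
.atp_floor_state <- function(mc) {
  d_feas <- mc$c_ad / (1 + 2 * sqrt(mc$K_adk))
  atp_branch_min <- mc$c_ad * sqrt(mc$K_adk) / (1 + 2 * sqrt(mc$K_adk))
  atp_floor <- max(mc$ATPmin, atp_branch_min * (1 + 1e-3))
  f <- function(d) .pools_from_adp(d, mc)$ATP - atp_floor
  d <- stats::uniroot(f, c(1e-12, d_feas * (1 - 1e-9)),
                      tol = 1e-15)$root
  pools <- .pools_from_adp(d, mc)
  Pi <- mc$c_ph -
    .phosphate_total(pools$ATP, d, pools$AMP, 0, pools$PCr, mc)
  c(pools, list(Pi = Pi))
}

# safeguarded Newton (numeric derivative) on a strictly decreasing residual
.newton_bisect <- function(f, lo, hi, tol, init = NULL) {
  d <- if (!is.null(init) && init > lo && init < hi) init
       else 0.5 * (lo + hi)
  for (i in 1:100) {
    fd <- f(d)
    if (is.na(fd)) fd <- -Inf
    if (fd > 0) lo <- d else hi <- d
    h <- max(1e-9 * d, 1e-13)
    fp <- (f(d + h) - fd) / h
    step <- if (is.finite(fp) && fp != 0) -fd / fp else NA_real_
    dn <- d + step
    if (!is.finite(dn) || dn <= lo || dn >= hi) dn <- 0.5 * (lo + hi)
    if (abs(dn - d) < tol) return(dn)
    d <- dn
  }
  d
}

#' Relative chemical potential of ATP
#'
#' \deqn{\tilde\mu_{ATP} = \frac{-\Delta G^0_{ATP} +
#'   R T \ln([ATP] c_0 / ([ADP][Pi]))}{\mu_{ATP,max}}.}
#' With the calibrated \code{dG0_ATP} (default), the value is exactly 1 in
#' the resting equilibrated state; it falls as [Pi] and [ADP] accumulate and
#' [ATP] is consumed.
#'
#' @param state a [metabolic_state()] (fields \code{ATP}, \code{ADP},
#'   \code{Pi}, mM, all > 0).
#' @param mc a [metabolic_constants()] object.
#' @return dimensionless relative chemical potential.
#' @export
chemical_potential <- function(state, mc) {
  if (state$ATP <= 0 || state$ADP <= 0 || state$Pi <= 0) {
    stop("chemical_potential: concentrations must be positive")
  }
  X <- state$ATP * mc$c0 / (state$ADP * state$Pi)
  (-mc$dG0_ATP + mc$R_gas * mc$temperature * log(X)) / mc$mu_ATP_max
}

#' Muscle activity
#'
#' The relative number of force-producing cross-bridges at the available
#' active sites: the troponin activity discounted by the relative chemical
#' potential of ATP, \code{a = q * mu_rel}.
#'
#' @param q troponin activity.
#' @param mu_rel relative chemical potential of ATP (>= 0).
#' @return activity, dimensionless.
#' @export
muscle_activity <- function(q, mu_rel) {
  stopifnot(all(mu_rel >= 0))
  q * mu_rel
}

#' Resting metabolic state
#'
#' The initial (pre-stimulation) state: \code{[ADP] = ADP0}, ATP and AMP
#' from the adenine pool under the AdK equilibrium, PCr/Cr from the CK
#' equilibrium, and [Pi] from phosphate-pool conservation.
#'
#' @param mc a [metabolic_constants()] object.
#' @return a [metabolic_state()].
#' @export
resting_state <- function(mc) {
  pools <- .pools_from_adp(mc$ADP0, mc)
  Pi <- mc$c_ph - .phosphate_total(pools$ATP, pools$ADP, pools$AMP, 0,
                                   pools$PCr, mc)
  if (Pi <= 0) stop("phosphate pool too small for the resting state")
  st <- metabolic_state(pools$ATP, pools$ADP, pools$AMP, Pi, pools$PCr,
                        pools$Cr)
  st$mu_rel <- chemical_potential(st, mc)
  st
}

# dG0 such that mu_rel = 1 at the resting state
calibrate_dG0 <- function(mc) {
  mc$dG0_ATP <- 0
  st <- resting_state(mc)
  X <- st$ATP * mc$c0 / (st$ADP * st$Pi)
  mc$R_gas * mc$temperature * log(X) - mc$mu_ATP_max
}
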