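# Hatze-type calcium/troponin activation dynamics: stimulation u drives the
# normalized free-calcium concentration gamma, which sets the troponin
# activity q through a length-dependent sigmoid.

#' Calcium concentration rate
#'
#' First-order relaxation of the normalized free-calcium concentration
#' towards the stimulation level: \code{d(gamma)/dt = m_act * (u - gamma)}.
#'
#' @param gamma normalized free-calcium concentration in [0, 1].
#' @param u stimulation in [0, 1].
#' @param m_act activation rate constant, 1/s.
#' @return rate, 1/s.
#' @export
calcium_rate <- function(gamma, u, m_act) {
  stopifnot(all(gamma >= 0), all(gamma <= 1), all(u >= 0), all(u <= 1))
  m_act * (u - gamma)
}

#' Troponin activity
#'
#' Sigmoidal mapping from free calcium to the relative number of cleared
#' active sites on actin:
#' \deqn{q(\gamma, \ell) = \frac{q_{min} + (\rho(\ell)\gamma)^{\nu}}
#'                              {1 + (\rho(\ell)\gamma)^{\nu}},}
#' with length-dependent calcium sensitivity
#' \code{rho(lce_rel) = omega_opt * lce_rel^gamma_rho}. Bounded in
#' \code{[q_min, 1)}; equals \code{q_min} at rest and
#' \code{(q_min + 1)/2} at \code{rho * gamma = 1}.
#'
#' @param gamma normalized free-calcium concentration in [0, 1].
#' @param lce_rel CE length relative to optimal (> 0).
#' @param p an [mtu_params()] object (fields \code{q_min},
#'   \code{omega_opt}, \code{nu_act}, \code{gamma_rho}).
#' @return troponin activity, dimensionless.
#' @export
troponin_activity <- function(gamma, lce_rel, p) {
  stopifnot(all(gamma >= 0), all(gamma <= 1))
  if (any(lce_rel <= 0)) stop("lce_rel must be strictly positive")
  rho <- p$omega_opt * lce_rel^p$gamma_rho
  s <- (rho * gamma)^p$nu_act
  (p$q_min + s) / (1 + s)
}
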