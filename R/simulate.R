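# Forward simulation: couples calcium activation, contraction dynamics and
# phosphate kinetics into one isometric (or prescribed-length) experiment.
# ODE states: gamma (free calcium), lCE, Pi; the remaining metabolites are
# algebraic functions of Pi (equilibrium projection).

#' Piecewise-constant stimulation protocol
#'
#' @param breakpoints times at which the stimulation level changes, s
#'   (strictly increasing, starting at 0).
#' @param levels stimulation levels in [0, 1], one per breakpoint; level
#'   \code{levels[i]} holds on \code{[breakpoints[i], breakpoints[i+1])}.
#' @param duration total runtime, s.
#' @param sample_rate output sampling rate, Hz.
#' @return an object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(breakpoints, levels, duration, sample_rate = 1000) {
  stopifnot(length(breakpoints) == length(levels),
            all(diff(breakpoints) > 0), breakpoints[1] >= 0,
            all(levels >= 0), all(levels <= 1),
            duration > max(breakpoints), sample_rate > 0)
  structure(list(breakpoints = breakpoints, levels = levels,
                 duration = duration, sample_rate = sample_rate),
            class = "stim_protocol")
}

#' Default isometric stimulation protocol
#'
#' The protocol of the isometric experiments: no stimulation for the first
#' 0.1 s, full stimulation (\code{u = 1}) for \code{stim_duration} (0.7 s by
#' default), then zero stimulation for a further 0.4 s; output sampled at
#' 1 kHz.
#'
#' @param stim_duration length of the full-stimulation phase, s.
#' @param onset stimulation onset time, s.
#' @param tail post-stimulation relaxation time, s.
#' @param sample_rate output sampling rate, Hz.
#' @return a [stim_protocol()].
#' @export
default_protocol <- function(stim_duration = 0.7, onset = 0.1, tail = 0.4,
                             sample_rate = 1000) {
  stim_protocol(breakpoints = c(0, onset, onset + stim_duration),
                levels = c(0, 1, 0),
                duration = onset + stim_duration + tail,
                sample_rate = sample_rate)
}

#' Constant stimulation protocol
#'
#' Constant \code{u} from \code{t = 0} (no onset delay), as used for the
#' exhaustion maps.
#'
#' @param u stimulation level in [0, 1].
#' @param duration runtime, s.
#' @param sample_rate output sampling rate, Hz.
#' @return a [stim_protocol()].
#' @export
constant_protocol <- function(u, duration, sample_rate = 1000) {
  stim_protocol(breakpoints = 0, levels = u, duration = duration,
                sample_rate = sample_rate)
}

#' Stimulation level at time t
#'
#' @param protocol a [stim_protocol()].
#' @param t time, s (vectorized).
#' @return stimulation u(t) in [0, 1].
#' @export
protocol_u <- function(protocol, t) {
  idx <- findInterval(t, protocol$breakpoints)
  idx[idx < 1] <- 1
  protocol$levels[idx]
}

#' Simulate an isometric MTU experiment
#'
#' Integrates the coupled activation/contraction/phosphate dynamics at fixed
#' MTU length. The initial state is the passive equilibrium (\code{gamma =
#' 0}, resting troponin activity \code{q_min}) with metabolites at rest.
#' Within each protocol segment the stiff-capable \code{deSolve::lsoda}
#' integrator is used (relative tolerance \code{1e-8} by default) and the
#' solution is densely output on the protocol's sampling grid, so protocol
#' breakpoints are hit exactly by construction.
#'
#' With \code{metabolic = NULL} or \code{khyd_hat = NA} the phosphate
#' submodel is disabled (\code{mu_rel} held at 1): the classical model
#' without exhaustion. With \code{khyd_hat = 0} the phosphate state is
#' carried but the hydrolysis flux is zero, so the chemical potential can
#' only recover (condensation), never decay.
#'
#' @param p an [mtu_params()] object.
#' @param metabolic a [metabolic_constants()] object, or \code{NULL} to
#'   disable phosphate kinetics.
#' @param lmtu MTU length, m.
#' @param protocol a [stim_protocol()]; [default_protocol()] if missing.
#' @param rtol,atol solver tolerances. \code{atol} is scaled per state:
#'   dimensionless for gamma, meters for lCE, mM for Pi.
#' @return an object of class \code{mtu_simulation}: a data.frame with
#'   columns \code{time_s, force_N, lce_m, gamma, q, a, atp_mM, adp_mM,
#'   amp_mM, pi_mM, pcr_mM, cr_mM, mu_rel} plus attributes (parameters,
#'   protocol, lmtu).
#' @export
mtu_simulate <- function(p, metabolic = NULL, lmtu,
                         protocol = default_protocol(),
                         rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(p, "mtu_params"), inherits(protocol, "stim_protocol"))
  use_phos <- !is.null(metabolic) && !is.na(p$khyd_hat)
  if (!is.null(metabolic)) stopifnot(inherits(metabolic,
                                              "metabolic_constants"))
  lce0 <- passive_equilibrium(lmtu, a_rest = p$q_min, p)
  if (use_phos) {
    rest <- resting_state(metabolic)
    y0 <- c(gamma = 0, lce = lce0, Pi = rest$Pi)
    if (is.null(atol)) atol <- c(1e-10, 1e-12, 1e-8)
  } else {
    y0 <- c(gamma = 0, lce = lce0)
    if (is.null(atol)) atol <- c(1e-10, 1e-12)
  }

  fns <- .make_model_fns(p, metabolic, lmtu, use_phos)

  # integrate segment-wise so u is constant inside each lsoda call
  bp <- c(protocol$breakpoints, protocol$duration)
  grid <- seq(0, protocol$duration, by = 1 / protocol$sample_rate)
  rows <- vector("list", length(bp) - 1L)
  y <- y0
  for (k in seq_len(length(bp) - 1L)) {
    eps <- 1e-9
    tseg <- c(bp[k], grid[grid > bp[k] + eps & grid < bp[k + 1L] - eps],
              bp[k + 1L])
    sol <- deSolve::lsoda(y, tseg, fns$deriv, parms = NULL,
                          u = protocol$levels[k],
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failure in segment %d at t = %.4f s", k,
                   sol[nrow(sol), 1]))
    }
    y <- sol[nrow(sol), -1]
    rows[[k]] <- sol[if (k > 1L) -1L else TRUE, , drop = FALSE]
  }
  sol <- do.call(rbind, rows)
  # keep only the output grid (lsoda returned exactly tseg times)
  sol <- sol[!duplicated(sol[, 1]), , drop = FALSE]
  snapped <- round(sol[, 1] * protocol$sample_rate) / protocol$sample_rate
  on_grid <- abs(sol[, 1] - snapped) < 1e-9
  sol <- sol[on_grid, , drop = FALSE]
  sol[, 1] <- snapped[on_grid]

  .assemble_result(sol, fns, p, metabolic, use_phos, lmtu, protocol)
}

# reconstruct algebraic outputs (forces, activity, metabolites) on the grid
.assemble_result <- function(sol, fns, p, metabolic, use_phos, lmtu,
                             protocol) {
  n <- nrow(sol)
  obs <- vapply(seq_len(n), function(i) fns$evaluate(sol[i, -1]),
                numeric(12))
  out <- data.frame(time_s = sol[, 1], force_N = obs[1, ],
                    lce_m = obs[2, ], gamma = obs[3, ], q = obs[4, ],
                    a = obs[5, ], atp_mM = obs[6, ], adp_mM = obs[7, ],
                    amp_mM = obs[8, ], pi_mM = obs[9, ],
                    pcr_mM = obs[10, ], cr_mM = obs[11, ],
                    mu_rel = obs[12, ])
  structure(out, class = c("mtu_simulation", "data.frame"),
            params = p, metabolic = metabolic, lmtu = lmtu,
            protocol = protocol)
}

#' @export
print.mtu_simulation <- function(x, ...) {
  cat(sprintf("MTU simulation: %.3f s at %.0f mm, %d samples\n",
              max(x$time_s), attr(x, "lmtu") * 1000, nrow(x)))
  cat(sprintf("  peak force %.2f N, final force %.2f N, final mu_rel %.4f\n",
              max(x$force_N), x$force_N[nrow(x)], x$mu_rel[nrow(x)]))
  invisible(x)
}

#' @export
plot.mtu_simulation <- function(x, which = c("force", "metabolic"), ...) {
  which <- match.arg(which)
  if (which == "force") {
    graphics::plot(x$time_s, x$force_N, type = "l", xlab = "time [s]",
                   ylab = "MTU force [N]", ...)
  } else {
    graphics::matplot(x$time_s, cbind(x$atp_mM, x$pi_mM, x$pcr_mM),
                      type = "l", lty = 1,
                      col = c("blue", "red", "darkgreen"),
                      xlab = "time [s]", ylab = "concentration [mM]", ...)
    graphics::legend("topright", c("ATP", "Pi", "PCr"), lty = 1,
                     col = c("blue", "red", "darkgreen"), bty = "n")
  }
  invisible(x)
}

#' Simulate a batch of MTU lengths
#'
#' Element-wise [mtu_simulate()] over a vector of MTU lengths with a shared
#' protocol; order is preserved.
#'
#' @inheritParams mtu_simulate
#' @param lengths MTU lengths, m.
#' @return list of \code{mtu_simulation} objects.
#' @export
simulate_batch <- function(p, metabolic = NULL, lengths,
                           protocol = default_protocol(), ...) {
  lapply(lengths, function(l)
    mtu_simulate(p, metabolic, lmtu = l, protocol = protocol, ...))
}
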