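# Exhaustion analyses: steady-state force, empirical and theoretical force
# decay rates, the scalar kappa fit, exhaustion times and
# force-length-exhaustion maps under constant stimulation.

#' Exhaustion time of a force trace
#'
#' First time instant at which the force has decayed more than
#' \code{threshold} (default 5\%) below the reference force. For runs that
#' start from the passive equilibrium the reference is the running maximum
#' of the trace (default), which triggers once the force has peaked and
#' decayed; the literal convention \code{ref = "initial"} (reference =
#' force at t = 0) is also available.
#'
#' @param trace an \code{mtu_simulation}, or a data.frame/list with
#'   \code{time_s} and \code{force_N}.
#' @param threshold decay fraction.
#' @param horizon optional horizon, s; times beyond it are ignored.
#' @param ref reference convention, \code{"runmax"} or \code{"initial"}.
#' @return exhaustion time, s, or \code{Inf} if the force never decays
#'   below \code{(1 - threshold) * F_ref} within the horizon.
#' @export
exhaustion_time <- function(trace, threshold = 0.05, horizon = Inf,
                            ref = c("runmax", "initial")) {
  ref <- match.arg(ref)
  t <- trace$time_s
  F <- trace$force_N
  if (length(t) == 0) stop("empty trace")
  keep <- t <= horizon
  t <- t[keep]; F <- F[keep]
  fref <- if (ref == "runmax") cummax(F) else F[1]
  hit <- which(F < (1 - threshold) * fref)
  if (length(hit) == 0) Inf else t[hit[1]]
}

#' Empirical quasi-steady force decay rate
#'
#' Mean force rate over a window where near-steady-state conditions hold
#' (default 0.58-0.68 s, late in the full-stimulation phase), normalized to
#' the maximum isometric force: the least-squares slope of \code{F(t)} over
#' the window divided by \code{Fmax}, 1/s. Negative during exhaustion.
#'
#' @param result an \code{mtu_simulation} (or data.frame with
#'   \code{time_s}, \code{force_N}).
#' @param p an [mtu_params()] object (for \code{Fmax}); taken from the
#'   simulation attributes if missing.
#' @param window numeric length-2 window, s.
#' @return normalized force rate, 1/s.
#' @export
steady_decay_rate <- function(result, p = attr(result, "params"),
                              window = c(0.58, 0.68)) {
  t <- result$time_s
  if (window[1] < min(t) || window[2] > max(t)) {
    stop("window lies outside the trace")
  }
  inwin <- t >= window[1] & t <= window[2]
  tw <- t[inwin]; Fw <- result$force_N[inwin]
  slope <- sum((tw - mean(tw)) * (Fw - mean(Fw))) / sum((tw - mean(tw))^2)
  slope / p$Fmax
}

#' Theoretical force decay rate
#'
#' The model's prediction that the quasi-steady normalized force decay rate
#' scales with the isometric force-length value over CE length:
#' \code{rate(lCE) = -kappa * Fisom(lCE) * lCEopt / lCE}, 1/s.
#'
#' @param lce CE length, m (vectorized).
#' @param kappa decay-rate scale, 1/s (>= 0).
#' @param p an [mtu_params()] object.
#' @return decay rate, 1/s (non-positive).
#' @export
theoretical_decay_rate <- function(lce, kappa, p) {
  stopifnot(kappa >= 0)
  -kappa * isometric_force_length(lce, p) * p$lCEopt / lce
}

#' Fit the decay-rate scale kappa
#'
#' Scalar least squares of observed quasi-steady decay rates against the
#' theoretical shape: minimizes
#' \code{sum((rate_i + kappa * b_i)^2)} with
#' \code{b_i = Fisom(lCE_i) * lCEopt / lCE_i}, which has the closed-form
#' solution \code{kappa = -sum(rate_i b_i) / sum(b_i^2)}, clamped at 0.
#'
#' @param rates observed normalized decay rates, 1/s.
#' @param lces CE lengths, m (same length; at least 1 point, 2+ for a
#'   meaningful fit).
#' @param p an [mtu_params()] object.
#' @return an object of class \code{kappa_fit}: list with \code{kappa}
#'   (1/s), \code{residuals}, \code{basis}.
#' @export
fit_kappa <- function(rates, lces, p) {
  stopifnot(length(rates) == length(lces), length(rates) >= 1)
  b <- isometric_force_length(lces, p) * p$lCEopt / lces
  if (all(b == 0)) stop("degenerate basis: all predictor values zero")
  kappa <- max(0, -sum(rates * b) / sum(b * b))
  structure(list(kappa = kappa, residuals = rates + kappa * b, basis = b,
                 lces = lces),
            class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("kappa = %.4g 1/s (%d points, RMS residual %.3g 1/s)\n",
              x$kappa, length(x$residuals),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Isometric steady-state MTU force
#'
#' The closed-form MTU force when activation and contraction dynamics are
#' at rest (\code{dq/dt = 0}, \code{d lCE/dt = 0}):
#' \code{F = q * mu_rel * Fmax * Fisom(lCE) + F_PEE(lCE)}.
#'
#' @param q troponin activity.
#' @param mu_rel relative chemical potential of ATP.
#' @param lce CE length, m.
#' @param p an [mtu_params()] object.
#' @return force, N.
#' @export
steady_state_force <- function(q, mu_rel, lce, p) {
  q * mu_rel * p$Fmax * isometric_force_length(lce, p) + pee_force(lce, p)
}

#' Force-length-exhaustion map
#'
#' One constant-stimulation simulation per (MTU length, u) grid cell, each
#' run from the passive equilibrium with constant u from t = 0 until the
#' 5\% decay criterion triggers or the horizon is reached. Records the
#' exhaustion time (\code{Inf} where no decay within the horizon), the
#' quasi-steady force (mean over the 0.58-0.68 s near-steady window) and
#' the CE length at that window.
#'
#' @param p an [mtu_params()] object.
#' @param metabolic a [metabolic_constants()] object.
#' @param lmtu_grid MTU lengths, m.
#' @param u_grid stimulation levels in (0, 1].
#' @param horizon simulation horizon per cell, s.
#' @param threshold decay fraction of the exhaustion criterion.
#' @param ref reference convention passed to [exhaustion_time()].
#' @param sample_rate output rate of the per-cell runs, Hz.
#' @param rtol solver tolerance.
#' @return an object of class \code{exhaustion_map}: a long-format
#'   data.frame with columns \code{lmtu_m, u, t_exh_s, f_steady_N, lce_m,
#'   exhausted}; failed cells carry \code{NA} and the map is still
#'   returned.
#' @export
exhaustion_map <- function(p, metabolic, lmtu_grid, u_grid, horizon = 60,
                           threshold = 0.05, ref = "runmax",
                           sample_rate = 100, rtol = 1e-8,
                           init = "passive") {
  grid <- expand.grid(lmtu_m = lmtu_grid, u = u_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lmtu <- grid$lmtu_m[i]; u <- grid$u[i]
    out <- try({
      tr <- simulate_constant(p, metabolic, lmtu, u, horizon,
                              sample_rate = sample_rate, rtol = rtol,
                              stop_threshold = threshold, stop_ref = ref,
                              init = init)
      tex <- exhaustion_time(tr, threshold, horizon, ref)
      win <- tr$time_s >= 0.58 & tr$time_s <= 0.68
      if (!any(win)) win <- seq_len(nrow(tr)) == nrow(tr)
      data.frame(lmtu_m = lmtu, u = u, t_exh_s = tex,
                 f_steady_N = mean(tr$force_N[win]),
                 lce_m = mean(tr$lce_m[win]),
                 exhausted = is.finite(tex))
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      data.frame(lmtu_m = lmtu, u = u, t_exh_s = NA_real_,
                 f_steady_N = NA_real_, lce_m = NA_real_,
                 exhausted = NA)
    } else out
  })
  structure(do.call(rbind, rows),
            class = c("exhaustion_map", "data.frame"),
            params = p, metabolic = metabolic, horizon = horizon,
            threshold = threshold, ref = ref)
}

#' @export
print.exhaustion_map <- function(x, ...) {
  cat(sprintf(
    "Exhaustion map: %d lengths x %d stimulation levels (horizon %g s)\n",
    length(unique(x$lmtu_m)), length(unique(x$u)), attr(x, "horizon")))
  cat(sprintf("  exhausted cells: %d / %d\n", sum(x$exhausted %in% TRUE),
              nrow(x)))
  invisible(x)
}

#' @export
plot.exhaustion_map <- function(x, ...) {
  lm_mm <- sort(unique(x$lmtu_m)) * 1000
  us <- sort(unique(x$u))
  z <- matrix(x$t_exh_s[order(x$u, x$lmtu_m)], length(lm_mm), length(us))
  z[!is.finite(z)] <- attr(x, "horizon")
  graphics::image(lm_mm, us, log10(z), xlab = "MTU length [mm]",
                  ylab = "stimulation u",
                  main = "log10 exhaustion time [s]", ...)
  invisible(x)
}

#' Infinite-endurance stimulation boundary
#'
#' Bisects over the constant stimulation level for the largest \code{u}
#' whose force trace never decays more than \code{threshold} below its
#' reference within the horizon, and reports that boundary run's
#' quasi-steady force (mean over the 0.58-0.68 s near-steady window).
#' When even the smallest stimulation exhausts within the horizon, the
#' boundary collapses to \code{u = 0} and the passive run is reported.
#'
#' @inheritParams exhaustion_map
#' @param lmtu MTU length, m.
#' @param u_tol bisection tolerance on u.
#' @return list with \code{u_star}, \code{f_steady_N},
#'   \code{f_steady_frac} (fraction of Fmax), \code{t_exh_at_u_star}, and
#'   \code{n_runs}.
#' @export
endurance_boundary <- function(p, metabolic, lmtu, horizon = 60,
                               threshold = 0.05, ref = "runmax",
                               u_tol = 0.005, sample_rate = 50,
                               rtol = 1e-8, init = "passive") {
  qs_force <- function(tr) {
    win <- tr$time_s >= 0.58 & tr$time_s <= 0.68
    if (!any(win)) win <- seq_len(nrow(tr)) == nrow(tr)
    mean(tr$force_N[win])
  }
  probe <- function(u) {
    tr <- simulate_constant(p, metabolic, lmtu, u, horizon,
                            sample_rate = sample_rate, rtol = rtol,
                            stop_threshold = threshold, stop_ref = ref,
                            init = init)
    list(t_exh = exhaustion_time(tr, threshold, horizon, ref),
         f_qs = qs_force(tr))
  }
  n_runs <- 1L
  lo <- 0; run_lo <- probe(0)
  if (is.finite(run_lo$t_exh)) {
    # even the passive run exhausts within the horizon
    return(list(u_star = 0, f_steady_N = run_lo$f_qs,
                f_steady_frac = run_lo$f_qs / p$Fmax,
                t_exh_at_u_star = run_lo$t_exh, n_runs = n_runs))
  }
  hi <- 1
  run_hi <- probe(1); n_runs <- n_runs + 1L
  if (!is.finite(run_hi$t_exh)) {
    return(list(u_star = 1, f_steady_N = run_hi$f_qs,
                f_steady_frac = run_hi$f_qs / p$Fmax,
                t_exh_at_u_star = run_hi$t_exh, n_runs = n_runs))
  }
  while (hi - lo > u_tol) {
    mid <- 0.5 * (lo + hi)
    run_mid <- probe(mid); n_runs <- n_runs + 1L
    if (is.finite(run_mid$t_exh)) hi <- mid
    else { lo <- mid; run_lo <- run_mid }
  }
  list(u_star = lo, f_steady_N = run_lo$f_qs,
       f_steady_frac = run_lo$f_qs / p$Fmax,
       t_exh_at_u_star = run_lo$t_exh, n_runs = n_runs)
}

#' Constant-stimulation run with early stopping
#'
#' Integrates a constant-u isometric run in chunks, carrying the full state
#' between chunks, and stops as soon as the exhaustion criterion triggers
#' (or the horizon is reached). This is the workhorse behind
#' [exhaustion_map()] and endurance-boundary searches.
#'
#' @inheritParams exhaustion_map
#' @param lmtu MTU length, m.
#' @param u constant stimulation level.
#' @param stop_threshold decay fraction triggering the early stop;
#'   \code{NULL} disables early stopping.
#' @param stop_ref reference convention for the early stop.
#' @param chunk chunk length, s.
#' @return an \code{mtu_simulation} covering \code{[0, t_stop]}.
#' @export
simulate_constant <- function(p, metabolic, lmtu, u, horizon,
                              sample_rate = 100, rtol = 1e-8,
                              stop_threshold = 0.05, stop_ref = "runmax",
                              chunk = 2, init = c("passive", "active")) {
  init <- match.arg(init)
  use_phos <- !is.null(metabolic) && !is.na(p$khyd_hat)
  if (init == "active") {
    # activated steady state at fresh metabolites: gamma = u, CE length at
    # the active force balance, so t = 0 already carries the held force
    gamma0 <- u
    lce0 <- active_equilibrium(lmtu, gamma0, p)
    state <- c(gamma = gamma0, lce = lce0)
  } else {
    lce0 <- passive_equilibrium(lmtu, a_rest = p$q_min, p)
    state <- c(gamma = 0, lce = lce0)
  }
  if (use_phos) state <- c(state, Pi = resting_state(metabolic)$Pi)
  fns <- .make_model_fns(p, metabolic, lmtu, use_phos)
  pieces <- list()
  t0 <- 0
  runmax <- -Inf
  f_init <- NA_real_
  repeat {
    t1 <- min(t0 + chunk, horizon)
    sim <- .integrate_segment(p, metabolic, use_phos, lmtu, u, state,
                              t0, t1, sample_rate, rtol, fns = fns)
    if (is.na(f_init)) f_init <- sim$trace$force_N[1]
    pieces[[length(pieces) + 1L]] <- sim$trace
    state <- sim$state
    stopped <- FALSE
    if (!is.null(stop_threshold)) {
      # pointwise running maximum carried across chunks
      fref <- if (stop_ref == "runmax") {
        cummax(pmax(sim$trace$force_N, runmax))
      } else f_init
      stopped <- any(sim$trace$force_N < (1 - stop_threshold) * fref)
    }
    runmax <- max(runmax, max(sim$trace$force_N))
    if (stopped || t1 >= horizon) break
    t0 <- t1
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out$time_s), ]
  rownames(out) <- NULL
  structure(out, class = c("mtu_simulation", "data.frame"), params = p,
            metabolic = metabolic, lmtu = lmtu,
            protocol = constant_protocol(u, max(out$time_s), sample_rate))
}

# integrate one constant-u chunk from a given full state
.integrate_segment <- function(p, metabolic, use_phos, lmtu, u, y0,
                               t0, t1, sample_rate, rtol,
                               fns = .make_model_fns(p, metabolic, lmtu,
                                                     use_phos)) {
  atol <- if (use_phos) c(1e-10, 1e-12, 1e-8) else c(1e-10, 1e-12)
  tt <- unique(c(t0, seq(ceiling(t0 * sample_rate) / sample_rate, t1,
                         by = 1 / sample_rate), t1))
  sol <- deSolve::lsoda(y0, tt, fns$deriv, parms = NULL, u = u,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("solver failure at t = %.3f s (u = %.3f)",
                 sol[nrow(sol), 1], u))
  }
  trace <- .assemble_result(sol, fns, p, metabolic, use_phos, lmtu,
                            protocol = NULL)
  list(trace = as.data.frame(trace), state = sol[nrow(sol), -1])
}
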