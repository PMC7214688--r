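# Bounded least-squares parameter estimation against multi-length isometric
# force-time trace sets, residue metrics, and local sensitivity time courses.

#' Experiment record
#'
#' One measured (or synthetic) isometric force-time trace with its MTU
#' length and stimulation protocol.
#'
#' @param muscle muscle label (e.g. \code{"GAS"}).
#' @param lmtu MTU length, m.
#' @param t time grid, s (strictly increasing).
#' @param F force trace, N (finite, same length as \code{t}).
#' @param protocol the [stim_protocol()] under which the trace was recorded.
#' @return a list with class \code{experiment_record}.
#' @export
experiment_record <- function(muscle, lmtu, t, F,
                              protocol = default_protocol()) {
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (length(t) != length(F) || any(!is.finite(F))) {
    stop("force trace must be finite and match the time grid")
  }
  structure(list(muscle = muscle, lmtu = lmtu, t = t, F = F,
                 protocol = protocol),
            class = "experiment_record")
}

#' L2 residue scaled to 1000 data points
#'
#' \code{sqrt((1000 / N) * sum(r^2))} over all points of all experiments,
#' which makes least-squares residues comparable between datasets of
#' different size. Units N.
#'
#' @param model model force values, N (vector, or list of vectors).
#' @param data measured force values with the same layout.
#' @return scaled L2 residue, N.
#' @export
residue_L2_scaled <- function(model, data) {
  r <- .stack_residuals(model, data)
  sqrt(1000 / length(r) * sum(r^2))
}

#' Mean absolute (L1) residue per data point
#'
#' @inheritParams residue_L2_scaled
#' @return mean absolute deviation, N.
#' @export
residue_L1_per_point <- function(model, data) {
  r <- .stack_residuals(model, data)
  mean(abs(r))
}

.stack_residuals <- function(model, data) {
  if (is.list(model) != is.list(data)) stop("model/data layout mismatch")
  if (is.list(model)) {
    if (length(model) != length(data)) stop("model/data layout mismatch")
    model <- unlist(model)
    data <- unlist(data)
  }
  if (length(model) != length(data)) {
    stop("model and data grids are not aligned")
  }
  model - data
}

# model force traces for a parameter set, aligned to the experiments' grids
.model_forces <- function(p, metabolic, experiments, rtol = 1e-8) {
  lapply(experiments, function(e) {
    sim <- mtu_simulate(p, metabolic, lmtu = e$lmtu, protocol = e$protocol,
                        rtol = rtol)
    if (nrow(sim) == length(e$t) &&
        max(abs(sim$time_s - e$t)) < 1e-9) {
      sim$force_N
    } else {
      stats::approx(sim$time_s, sim$force_N, xout = e$t, rule = 2)$y
    }
  })
}

#' Fit MTU parameters to isometric experiments
#'
#' Bounded least-squares estimation of a subset of the MTU parameters
#' against one muscle's multi-length isometric force-time traces. All
#' experiments are fitted simultaneously with shared parameters; the
#' stacked force residuals are minimized by bounded Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) inside the per-parameter bound
#' hyperrectangle. Optional multi-start: the first start is \code{start}
#' itself, further starts are seeded Latin-hypercube points inside the
#' bounds of the free parameters; the best final objective wins, so the
#' reported optimum is never worse than any start.
#'
#' @param experiments list of [experiment_record()]s (one muscle).
#' @param start an [mtu_params()] object; fixed parameters keep these
#'   values, free parameters are initialized here (unless overridden by
#'   multi-start points).
#' @param free character vector of parameter names to estimate.
#' @param bounds data.frame as from [mtu_bounds()]; defaults to the bounds
#'   of the experiments' muscle label.
#' @param metabolic a [metabolic_constants()] object or \code{NULL}
#'   (classical model).
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed making the multi-start draw reproducible.
#' @param rtol forward-simulation tolerance used inside the objective.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @param epsfcn forward-difference Jacobian step control passed to
#'   \code{nls.lm}; the default gives relative steps of about 1e-3, well
#'   above the ODE-solver noise floor so Jacobian estimates stay clean.
#' @return an object of class \code{mtu_fit} with components
#'   \code{parameters} (full [mtu_params()] at the optimum),
#'   \code{residue_L2_1000}, \code{residue_L1_per_point}, \code{free},
#'   \code{bounds}, \code{converged}, \code{iterations}, \code{seed},
#'   \code{starts} (per-start summary) and the inputs.
#' @export
mtu_fit <- function(experiments, start, free = "khyd_hat", bounds = NULL,
                    metabolic = metabolic_constants(), n_starts = 1,
                    seed = 1, rtol = 1e-8, maxiter = 50, epsfcn = 1e-6) {
  stopifnot(length(experiments) >= 1, inherits(start, "mtu_params"))
  lapply(experiments, function(e)
    stopifnot(inherits(e, "experiment_record")))
  if (is.null(bounds)) {
    muscle <- experiments[[1]]$muscle
    bounds <- mtu_bounds(if (grepl("PLA", muscle)) "PLA" else "GAS")
  }
  bad <- setdiff(free, .mtu_param_names)
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  lb <- stats::setNames(bounds$lower, bounds$parameter)[free]
  ub <- stats::setNames(bounds$upper, bounds$parameter)[free]
  data_F <- lapply(experiments, `[[`, "F")

  obj <- function(theta) {
    p <- start
    p[free] <- as.list(theta)
    unlist(.model_forces(p, metabolic, experiments, rtol = rtol)) -
      unlist(data_F)
  }

  start0 <- unlist(start[free])
  starts <- matrix(start0, nrow = 1,
                   dimnames = list(NULL, free))
  if (n_starts > 1) {
    extra <- .latin_hypercube(n_starts - 1L, lb, ub, seed)
    starts <- rbind(starts, extra)
  }

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- minpack.lm::nls.lm(par = starts[i, ], lower = lb, upper = ub,
                              fn = obj,
                              control = minpack.lm::nls.lm.control(
                                maxiter = maxiter, ftol = 1e-12,
                                ptol = 1e-10, epsfcn = epsfcn))
    runs[[i]] <- fit
  }
  obj_vals <- vapply(runs, function(f) f$deviance, numeric(1))
  best <- runs[[which.min(obj_vals)]]

  p_hat <- start
  p_hat[free] <- as.list(unname(best$par))
  model_F <- .model_forces(p_hat, metabolic, experiments, rtol = rtol)
  res <- structure(list(
    parameters = p_hat,
    free = free,
    estimate = stats::setNames(as.numeric(best$par), free),
    residue_L2_1000 = residue_L2_scaled(model_F, data_F),
    residue_L1_per_point = residue_L1_per_point(model_F, data_F),
    bounds = bounds[bounds$parameter %in% free, ],
    converged = best$info %in% 1:4,
    iterations = best$niter,
    seed = seed,
    n_starts = nrow(starts),
    start_objectives = sqrt(1000 * obj_vals /
                              length(unlist(data_F))),
    experiments = experiments,
    metabolic = metabolic,
    rtol = rtol
  ), class = "mtu_fit")
  res
}

# small seeded Latin hypercube in the free-parameter box
.latin_hypercube <- function(n, lb, ub, seed) {
  k <- length(lb)
  old <- .Random.seed_safe()
  set.seed(seed)
  u <- matrix(stats::runif(n * k), n, k)
  perm <- apply(matrix(stats::runif(n * k), n, k), 2, order)
  .Random.seed_restore(old)
  strat <- (perm - 1 + u) / n
  out <- sweep(sweep(strat, 2, ub - lb, "*"), 2, lb, "+")
  colnames(out) <- names(lb)
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.mtu_fit <- function(x, ...) {
  cat("Bounded least-squares MTU fit\n")
  cat(sprintf("  %d experiment(s), %d free parameter(s): %s\n",
              length(x$experiments), length(x$free),
              paste(x$free, collapse = ", ")))
  cat("  estimates:\n")
  print(signif(x$estimate, 5))
  cat(sprintf("  residue L2 (1000 pts): %.4g N, L1 per point: %.4g N\n",
              x$residue_L2_1000, x$residue_L1_per_point))
  cat(sprintf("  converged: %s after %d iterations (%d start%s)\n",
              x$converged, x$iterations, x$n_starts,
              if (x$n_starts > 1) "s" else ""))
  invisible(x)
}

#' @export
coef.mtu_fit <- function(object, full = FALSE, ...) {
  if (full) unlist(object$parameters[.mtu_param_names]) else object$estimate
}

#' @export
summary.mtu_fit <- function(object, ...) {
  print(object)
  cat("  bounds:\n")
  print(object$bounds, row.names = FALSE)
  invisible(object)
}

#' @export
predict.mtu_fit <- function(object, lengths = NULL, protocol = NULL, ...) {
  if (is.null(lengths)) {
    lapply(object$experiments, function(e)
      mtu_simulate(object$parameters, object$metabolic, lmtu = e$lmtu,
                   protocol = e$protocol, rtol = object$rtol))
  } else {
    simulate_batch(object$parameters, object$metabolic, lengths,
                   protocol = if (is.null(protocol)) default_protocol()
                              else protocol,
                   rtol = object$rtol)
  }
}

#' @export
residuals.mtu_fit <- function(object, ...) {
  model_F <- .model_forces(object$parameters, object$metabolic,
                           object$experiments, rtol = object$rtol)
  data_F <- lapply(object$experiments, `[[`, "F")
  mapply(function(m, d) m - d, model_F, data_F, SIMPLIFY = FALSE)
}

#' @export
plot.mtu_fit <- function(x, ...) {
  sims <- predict(x)
  cols <- grDevices::hcl.colors(length(sims), "Zissou 1")
  rng <- range(unlist(lapply(x$experiments, `[[`, "F")))
  graphics::plot(NULL, xlim = c(0, max(x$experiments[[1]]$t)),
                 ylim = rng * c(0, 1.05), xlab = "time [s]",
                 ylab = "force [N]", ...)
  for (i in seq_along(sims)) {
    graphics::lines(x$experiments[[i]]$t, x$experiments[[i]]$F,
                    col = grDevices::adjustcolor(cols[i], 0.4))
    graphics::lines(sims[[i]]$time_s, sims[[i]]$force_N, col = cols[i])
  }
  invisible(x)
}

#' Local relative sensitivity time courses
#'
#' Central finite-difference sensitivities of the simulated force trace to
#' relative parameter perturbations,
#' \deqn{S_\theta(t) = \frac{\partial F(t)}{\partial \theta}
#'       \frac{\theta}{F(t)},}
#' so that e.g. a value of 1 means a 10\% parameter change moves the output
#' by 10\% at that instant. At instants where \code{F(t) = 0} the
#' unnormalized derivative is reported instead and the instant is flagged.
#'
#' @param p an [mtu_params()] object (the expansion point).
#' @param metabolic a [metabolic_constants()] object or \code{NULL}.
#' @param lmtu MTU length, m.
#' @param protocol a [stim_protocol()].
#' @param parameters which parameters to perturb (default: all that are
#'   finite at the expansion point).
#' @param rel_step relative perturbation size; either a scalar or a named
#'   vector with per-parameter overrides. A step of 0 yields a zero row
#'   (parameter frozen by construction).
#' @param truncate magnitude at which *exported* values are clipped (the
#'   internal matrix is kept unclipped); see [export_sensitivity()].
#' @param rtol forward-simulation tolerance.
#' @return an object of class \code{sensitivity_matrix}: a parameters-by-time
#'   matrix with attributes \code{time}, \code{truncate},
#'   \code{absolute_scale} (logical index of flagged instants).
#' @export
sensitivity_timecourse <- function(p, metabolic = NULL, lmtu,
                                   protocol = default_protocol(),
                                   parameters = NULL, rel_step = 1e-4,
                                   truncate = 1, rtol = 1e-8) {
  if (is.null(parameters)) {
    parameters <- .mtu_param_names[vapply(.mtu_param_names, function(nm)
      is.finite(p[[nm]]), logical(1))]
  }
  base <- mtu_simulate(p, metabolic, lmtu = lmtu, protocol = protocol,
                       rtol = rtol)
  F0 <- base$force_N
  zero_force <- F0 == 0
  steps <- if (length(rel_step) == 1L && is.null(names(rel_step))) {
    stats::setNames(rep(rel_step, length(parameters)), parameters)
  } else {
    out <- stats::setNames(rep(1e-4, length(parameters)), parameters)
    out[names(rel_step)] <- rel_step
    out
  }
  S <- matrix(0, length(parameters), length(F0),
              dimnames = list(parameters, NULL))
  for (nm in parameters) {
    h <- steps[[nm]]
    if (h == 0) next
    theta <- p[[nm]]
    pp <- p; pp[[nm]] <- theta * (1 + h)
    pm <- p; pm[[nm]] <- theta * (1 - h)
    Fp <- mtu_simulate(pp, metabolic, lmtu = lmtu, protocol = protocol,
                       rtol = rtol)$force_N
    Fm <- mtu_simulate(pm, metabolic, lmtu = lmtu, protocol = protocol,
                       rtol = rtol)$force_N
    dF_dtheta <- (Fp - Fm) / (2 * h * theta)
    S[nm, ] <- ifelse(zero_force, dF_dtheta, dF_dtheta * theta / F0)
  }
  structure(S, class = "sensitivity_matrix", time = base$time_s,
            truncate = truncate, absolute_scale = zero_force)
}

#' Export a sensitivity matrix with magnitude truncation
#'
#' Clips the sensitivities at the truncation level chosen in
#' [sensitivity_timecourse()] (for plotting/export only; internal values
#' are unclipped).
#'
#' @param S a \code{sensitivity_matrix}.
#' @return a plain matrix with \code{|S| <= truncate}.
#' @export
export_sensitivity <- function(S) {
  lim <- attr(S, "truncate")
  out <- pmin(pmax(unclass(S), -lim), lim)
  attributes(out) <- attributes(unclass(S))[c("dim", "dimnames")]
  out
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("Sensitivity time courses: %d parameters x %d instants\n",
              nrow(x), ncol(x)))
  rng <- apply(x, 1, function(r) max(abs(r)))
  print(signif(sort(rng, decreasing = TRUE), 3))
  invisible(x)
}
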