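# Parameter containers: 24 mechanical/activation/kinetic MTU parameters and
# the 9 metabolic constants of the phosphate-kinetics submodel.

.mtu_param_names <- c(
  "lSEE0", "dU_SEE_nll", "dF_SEE0", "dU_SEE_l",
  "F_PEE", "L_PEE", "nu_PEE",
  "dW_asc", "dW_des", "nu_asc", "nu_des",
  "Fmax", "lCEopt", "Arel0", "Brel0",
  "D_SDE", "R_SDE", "S_e", "F_e",
  "q_min", "omega_opt", "m_act", "nu_act",
  "khyd_hat"
)

#' MTU parameter set
#'
#' Bundles the 24 parameters of the muscle-tendon-unit model: serial elastic
#' element (SEE) slack length and toe/linear shape, parallel elastic element
#' (PEE) power law, contractile element (CE) force-length bell and Hill
#' force-velocity constants, serial damping element (SDE), eccentric branch,
#' Hatze-type activation constants, and the ATP hydrolysis rate constant
#' \code{khyd_hat} at full activity and optimal CE length.
#'
#' Lengths are in meters, forces in Newton, rates in 1/s; all other
#' parameters are dimensionless.
#'
#' @param ... named parameter values; every name in
#'   \code{hillphos:::.mtu_param_names} except \code{khyd_hat} is required.
#'   \code{khyd_hat} defaults to \code{NA} (no phosphate kinetics).
#' @param gamma_rho exponent of the length dependence of the calcium
#'   sensitivity \code{rho(lCE_rel) = omega_opt * lCE_rel^gamma_rho}
#'   (classical cubic scaling by default).
#' @param hill_activity_scaling logical; scale the Hill constants with
#'   activity via \code{Q_A(a) = (1+3a)/4}, \code{Q_B(a) = (3+4a)/7}. Set
#'   \code{FALSE} for activity-independent Hill constants.
#' @return an object of class \code{mtu_params} (a named list).
#' @seealso [mtu_preset()] for the fitted rabbit gastrocnemius (GAS) and
#'   plantaris (PLA) parameter sets, [mtu_bounds()] for the estimation
#'   bounds.
#' @export
mtu_params <- function(..., gamma_rho = 3, hill_activity_scaling = TRUE) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1L]])) {
    vals <- vals[[1L]]
  }
  unknown <- setdiff(names(vals), .mtu_param_names)
  if (length(unknown)) {
    stop("unknown MTU parameter(s): ", paste(unknown, collapse = ", "))
  }
  if (!"khyd_hat" %in% names(vals)) vals$khyd_hat <- NA_real_
  missing <- setdiff(.mtu_param_names, names(vals))
  if (length(missing)) {
    stop("missing MTU parameter(s): ", paste(missing, collapse = ", "))
  }
  p <- lapply(vals[.mtu_param_names], function(x) as.numeric(x)[1L])
  p$gamma_rho <- as.numeric(gamma_rho)
  p$hill_activity_scaling <- isTRUE(hill_activity_scaling)
  class(p) <- "mtu_params"
  validate_mtu_params(p)
  p
}

validate_mtu_params <- function(p) {
  pos <- setdiff(.mtu_param_names, "khyd_hat")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be strictly positive")
    }
  }
  if (!is.na(p$khyd_hat) && p$khyd_hat < 0) stop("khyd_hat must be >= 0")
  if (p$q_min <= 0 || p$q_min >= 1) stop("q_min must lie in (0,1)")
  if (p$R_SDE < 0 || p$R_SDE > 1) stop("R_SDE must lie in [0,1]")
  if (p$F_e <= 1) stop("F_e must exceed 1")
  invisible(p)
}

#' @export
print.mtu_params <- function(x, ...) {
  cat("MTU parameter set (24 parameters)\n")
  v <- unlist(x[.mtu_param_names])
  print(signif(v, 4))
  invisible(x)
}

#' @export
as.list.mtu_params <- function(x, ...) unclass(x)

# Fitted values (per-muscle columns of the estimation study) for rabbit
# gastrocnemius (GAS) and plantaris (PLA), with ("+") and without ("-")
# phosphate kinetics.
.mtu_preset_table <- list(
  GAS_minus = list(
    lSEE0 = 0.0996, dU_SEE_nll = 0.103, dF_SEE0 = 123, dU_SEE_l = 0.0524,
    F_PEE = 0.133, L_PEE = 1.19, nu_PEE = 5.00,
    dW_asc = 0.215, dW_des = 0.690, nu_asc = 4.10, nu_des = 4.46,
    Fmax = 120, lCEopt = 0.0160, Arel0 = 0.0786, Brel0 = 6.30,
    D_SDE = 1.65, R_SDE = 0.0233, S_e = 1.00, F_e = 1.10,
    q_min = 0.00576, omega_opt = 2.45, m_act = 12.8, nu_act = 4.99,
    khyd_hat = NA_real_
  ),
  GAS_plus = list(
    lSEE0 = 0.1017, dU_SEE_nll = 0.0785, dF_SEE0 = 109, dU_SEE_l = 0.0482,
    F_PEE = 0.135, L_PEE = 1.02, nu_PEE = 3.16,
    dW_asc = 0.404, dW_des = 0.330, nu_asc = 6.75, nu_des = 2.36,
    Fmax = 133, lCEopt = 0.0198, Arel0 = 0.0655, Brel0 = 2.91,
    D_SDE = 0.149, R_SDE = 0.0100, S_e = 2.85, F_e = 1.14,
    q_min = 0.00944, omega_opt = 3.47, m_act = 13.7, nu_act = 4.85,
    khyd_hat = 1.45
  ),
  PLA_minus = list(
    lSEE0 = 0.1045, dU_SEE_nll = 0.0620, dF_SEE0 = 69.4, dU_SEE_l = 0.0409,
    F_PEE = 0.118, L_PEE = 1.00, nu_PEE = 2.50,
    dW_asc = 0.237, dW_des = 0.429, nu_asc = 1.57, nu_des = 3.89,
    Fmax = 57.1, lCEopt = 0.0130, Arel0 = 0.244, Brel0 = 10.0,
    D_SDE = 10.0, R_SDE = 1.00, S_e = 4.50, F_e = 1.61,
    q_min = 0.0100, omega_opt = 1.82, m_act = 8.17, nu_act = 3.76,
    khyd_hat = NA_real_
  ),
  PLA_plus = list(
    lSEE0 = 0.1054, dU_SEE_nll = 0.0762, dF_SEE0 = 68.1, dU_SEE_l = 0.0414,
    F_PEE = 0.0908, L_PEE = 1.00, nu_PEE = 2.50,
    dW_asc = 0.268, dW_des = 0.570, nu_asc = 1.84, nu_des = 2.83,
    Fmax = 63.7, lCEopt = 0.0106, Arel0 = 0.240, Brel0 = 6.58,
    D_SDE = 3.88, R_SDE = 0.356, S_e = 3.40, F_e = 1.32,
    q_min = 0.0100, omega_opt = 2.03, m_act = 8.22, nu_act = 4.77,
    khyd_hat = 2.27
  )
)

#' Fitted parameter presets
#'
#' Returns one of the four fitted MTU parameter sets for the rabbit
#' gastrocnemius (GAS) and plantaris (PLA) preparations: \code{"GAS_plus"} /
#' \code{"PLA_plus"} include phosphate kinetics (\code{khyd_hat} fitted),
#' \code{"GAS_minus"} / \code{"PLA_minus"} are the classical model variants
#' without it (\code{khyd_hat = NA}).
#'
#' @param name preset name.
#' @return an [mtu_params()] object.
#' @export
mtu_preset <- function(name = c("GAS_plus", "GAS_minus",
                                "PLA_plus", "PLA_minus")) {
  name <- match.arg(name)
  mtu_params(.mtu_preset_table[[name]])
}

#' Estimation bounds per muscle
#'
#' The per-parameter search hyperrectangle used for bounded least-squares
#' estimation. Bounds were set from physiologically plausible ranges and are
#' mostly shared between GAS and PLA; they differ where the muscles differ in
#' size (forces, optimal length) and in a few shape exponents.
#'
#' @param muscle \code{"GAS"} or \code{"PLA"}.
#' @return a data.frame with columns \code{parameter}, \code{lower},
#'   \code{upper}.
#' @export
mtu_bounds <- function(muscle = c("GAS", "PLA")) {
  muscle <- match.arg(muscle)
  lower <- c(lSEE0 = 0.09, dU_SEE_nll = 0.04, dF_SEE0 = 80, dU_SEE_l = 0.01,
             F_PEE = 0, L_PEE = 0.9, nu_PEE = 2.5,
             dW_asc = 0.1, dW_des = 0.1, nu_asc = 1.5, nu_des = 1.5,
             Fmax = 80, lCEopt = 0.014, Arel0 = 0.03, Brel0 = 1,
             D_SDE = 0.1, R_SDE = 0.01, S_e = 1, F_e = 1.1,
             q_min = 0.001, omega_opt = 1.5, m_act = 5, nu_act = 2,
             khyd_hat = 1)
  upper <- c(lSEE0 = 0.11, dU_SEE_nll = 0.11, dF_SEE0 = 160, dU_SEE_l = 0.08,
             F_PEE = 1.2, L_PEE = 1.5, nu_PEE = 5,
             dW_asc = 1, dW_des = 1, nu_asc = 8, nu_des = 6,
             Fmax = 160, lCEopt = 0.025, Arel0 = 0.5, Brel0 = 10,
             D_SDE = 10, R_SDE = 1, S_e = 4.5, F_e = 2,
             q_min = 0.01, omega_opt = 10, m_act = 20, nu_act = 8,
             khyd_hat = 3)
  if (muscle == "PLA") {
    lower[c("dF_SEE0", "Fmax", "lCEopt", "L_PEE", "R_SDE")] <-
      c(50, 50, 0.005, 1, 0.1)
    upper[c("dF_SEE0", "Fmax", "lCEopt", "nu_asc", "nu_des")] <-
      c(70, 70, 0.02, 5, 5)
  }
  data.frame(parameter = .mtu_param_names,
             lower = unname(lower[.mtu_param_names]),
             upper = unname(upper[.mtu_param_names]),
             stringsAsFactors = FALSE)
}

#' Experimental MTU length series
#'
#' The isometric experiments sampled MTU lengths in 2 mm increments:
#' 114-120 and 128-132 mm for GAS (7 lengths) and 114-124 mm for PLA
#' (6 lengths).
#'
#' @param muscle \code{"GAS"} or \code{"PLA"}.
#' @return MTU lengths in meters.
#' @export
default_lengths <- function(muscle = c("GAS", "PLA")) {
  muscle <- match.arg(muscle)
  mm <- if (muscle == "GAS") c(seq(114, 120, 2), seq(128, 132, 2))
        else seq(114, 124, 2)
  mm / 1000
}

#' Metabolic constants of the phosphate submodel
#'
#' The concentration pools, equilibrium constants and rate constants that
#' drive the hydrolysis/condensation ODE and the creatine-kinase (CK) /
#' adenylate-kinase (AdK) equilibrium projection. Defaults are the literature
#' values used throughout: total adenine pool 7 mM, creatine pool 25 mM,
#' phosphate pool 46 mM, K_CK = 200, K_AdK = 1, condensation rate 0.1 1/s,
#' initial [ADP] 0.01 mM and an [ATP] floor of 1.2 mM.
#'
#' @param ADP0 initial ADP concentration, mM.
#' @param ATPmin hard minimum ATP concentration, mM; the hydrolysis flux is
#'   zeroed while the equilibrium projection would push ATP below it.
#' @param c_ad,c_cr,c_ph total adenine, creatine and phosphate pools, mM.
#' @param K_adk,K_ck adenylate-kinase and creatine-kinase equilibrium
#'   constants (dimensionless).
#' @param k_con condensation rate constant, 1/s.
#' @param c0 standard concentration expressed in mM (1 M).
#' @param R_gas universal gas constant, kJ/(mol K).
#' @param temperature absolute temperature, K (39 C preparation by default).
#' @param mu_ATP_max maximum chemical potential of ATP in a resting fiber,
#'   kJ/mol.
#' @param dG0_ATP either \code{"calibrated"} (default: the standard
#'   free-energy offset is chosen so that the relative chemical potential is
#'   exactly 1 in the resting equilibrated state) or a fixed numeric value in
#'   kJ/mol (e.g. -30.5).
#' @param accounting phosphate pool accounting: \code{"nucleotide"} counts
#'   phosphate bound in the nucleotides
#'   (\code{c_ph = Pi + PCr + 3 ATP + 2 ADP + AMP}), \code{"free"} counts
#'   only \code{Pi + PCr}.
#' @return an object of class \code{metabolic_constants}.
#' @export
metabolic_constants <- function(ADP0 = 0.01, ATPmin = 1.2,
                                c_ad = 7, c_cr = 25, c_ph = 46,
                                K_adk = 1, K_ck = 200, k_con = 0.1,
                                c0 = 1000, R_gas = 8.314e-3,
                                temperature = 312.15, mu_ATP_max = 60,
                                dG0_ATP = "calibrated",
                                accounting = c("nucleotide", "free")) {
  accounting <- match.arg(accounting)
  mc <- list(ADP0 = ADP0, ATPmin = ATPmin, c_ad = c_ad, c_cr = c_cr,
             c_ph = c_ph, K_adk = K_adk, K_ck = K_ck, k_con = k_con,
             c0 = c0, R_gas = R_gas, temperature = temperature,
             mu_ATP_max = mu_ATP_max, accounting = accounting)
  stopifnot(ADP0 > 0, ATPmin > 0, c_ad > 0, c_cr > 0, c_ph > 0,
            K_adk > 0, K_ck > 0, k_con > 0, ATPmin < c_ad)
  class(mc) <- "metabolic_constants"
  if (identical(dG0_ATP, "calibrated")) {
    mc$dG0_ATP <- calibrate_dG0(mc)
  } else {
    mc$dG0_ATP <- as.numeric(dG0_ATP)
  }
  mc
}

#' @export
print.metabolic_constants <- function(x, ...) {
  cat("Metabolic constants (phosphate kinetics)\n")
  num <- vapply(x, is.numeric, logical(1))
  print(signif(unlist(x[num]), 4))
  cat("phosphate accounting:", x$accounting, "\n")
  invisible(x)
}

#' Read a parameter configuration file
#'
#' Reads an MTU parameter block and optional metabolic block from a YAML or
#' JSON file. The MTU block is keyed by the ASCII parameter names (see
#' [mtu_params()]); a top-level \code{units: \{length: "mm"\}} entry converts
#' \code{lSEE0} and \code{lCEopt} from millimeters.
#'
#' @param path file path (extension .yaml/.yml or .json).
#' @return a list with elements \code{params} ([mtu_params()]) and, if a
#'   \code{metabolic} block is present, \code{metabolic}
#'   ([metabolic_constants()]).
#' @export
read_mtu_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
  block <- if (!is.null(cfg$params)) cfg$params else cfg
  block <- block[intersect(names(block), .mtu_param_names)]
  if (!is.null(cfg$units$length) && cfg$units$length == "mm") {
    for (nm in c("lSEE0", "lCEopt")) {
      if (!is.null(block[[nm]])) block[[nm]] <- block[[nm]] / 1000
    }
  }
  out <- list(params = mtu_params(block))
  if (!is.null(cfg$metabolic)) {
    out$metabolic <- do.call(metabolic_constants, cfg$metabolic)
  }
  out
}
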