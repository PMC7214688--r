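# Trace readers/writers, the seeded synthetic fixture generator emulating
# the rabbit isometric experiments, and a moving-average display filter.

#' Fixture specification
#'
#' Describes a synthetic multi-length isometric experiment set: which
#' preset, which MTU lengths, the force noise level and the seed.
#'
#' @param muscle preset name accepted by [mtu_preset()] (its \code{GAS}/
#'   \code{PLA} prefix selects the default length series).
#' @param lengths MTU lengths, m; defaults to the experimental series of
#'   the muscle ([default_lengths()]).
#' @param noise_sd standard deviation of i.i.d. Gaussian force noise, N.
#'   The default 0.5 N is of the order of the per-point L1 residues of the
#'   fits to the measured traces.
#' @param seed integer seed.
#' @param protocol a [stim_protocol()].
#' @return a list with class \code{fixture_spec}.
#' @export
fixture_spec <- function(muscle = "GAS_plus", lengths = NULL,
                         noise_sd = 0.5, seed = 1,
                         protocol = default_protocol()) {
  if (is.null(lengths)) {
    lengths <- default_lengths(if (grepl("^PLA", muscle)) "PLA" else "GAS")
  }
  stopifnot(noise_sd >= 0, all(lengths > 0))
  structure(list(muscle = muscle, lengths = lengths, noise_sd = noise_sd,
                 seed = seed, protocol = protocol),
            class = "fixture_spec")
}

#' Generate synthetic isometric experiment records
#'
#' Simulates the model at each MTU length of the spec and adds i.i.d.
#' Gaussian noise to the force channel, reproducing the layout of the
#' rabbit isometric experiment sets (the measured traces themselves are
#' not deposited in machine-readable form; these records are synthetic
#' stand-ins). Deterministic per seed; with \code{noise_sd = 0} the records
#' equal the [simulate_batch()] output.
#'
#' @param spec a [fixture_spec()].
#' @param p an [mtu_params()] object; defaults to the spec's preset.
#' @param metabolic a [metabolic_constants()] object (or \code{NULL}).
#' @return list of [experiment_record()]s.
#' @export
generate_fixtures <- function(spec, p = NULL,
                              metabolic = metabolic_constants()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(p)) p <- mtu_preset(spec$muscle)
  sims <- simulate_batch(p, metabolic, spec$lengths,
                         protocol = spec$protocol)
  old <- .Random.seed_safe()
  set.seed(spec$seed)
  out <- lapply(seq_along(sims), function(i) {
    F <- sims[[i]]$force_N
    if (spec$noise_sd > 0) {
      F <- F + stats::rnorm(length(F), 0, spec$noise_sd)
    }
    experiment_record(muscle = spec$muscle, lmtu = spec$lengths[i],
                      t = sims[[i]]$time_s, F = F,
                      protocol = spec$protocol)
  })
  .Random.seed_restore(old)
  out
}

#' Write an experiment record as CSV
#'
#' Comma-separated with a mandatory header \code{time_s,force_N} and
#' \code{#}-prefixed metadata comments carrying the muscle label and the
#' MTU length in mm.
#'
#' @param record an [experiment_record()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(record, path) {
  stopifnot(inherits(record, "experiment_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# muscle=%s", record$muscle),
               sprintf("# lmtu_mm=%.17g", record$lmtu * 1000),
               "time_s,force_N"), con)
  utils::write.table(
    data.frame(time_s = sprintf("%.17g", record$t),
               force_N = sprintf("%.17g", record$F)),
    con, sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an experiment record from CSV
#'
#' Inverse of [write_trace()]: expects the \code{time_s,force_N} header and
#' the \code{# muscle=}, \code{# lmtu_mm=} metadata comments. A round trip
#' \code{read_trace(write_trace(x))} reproduces \code{x} to 1e-12.
#'
#' @param path input file path.
#' @param protocol protocol to attach (not stored in the CSV).
#' @return an [experiment_record()].
#' @export
read_trace <- function(path, protocol = default_protocol()) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  kv <- regmatches(meta, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", meta))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  if (!"lmtu_mm" %in% keys) {
    stop("missing required metadata field 'lmtu_mm' in ", path)
  }
  muscle <- if ("muscle" %in% keys) vals[keys == "muscle"][1] else "unknown"
  lmtu <- as.numeric(vals[keys == "lmtu_mm"][1]) / 1000
  body <- lines[-meta_idx]
  header <- strsplit(body[1], ",")[[1]]
  if (!identical(header[1:2], c("time_s", "force_N"))) {
    stop("malformed header at line ", meta_idx[length(meta_idx)] + 1,
         ": expected 'time_s,force_N'")
  }
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  if (any(diff(dat$time_s) <= 0)) {
    bad <- which(diff(dat$time_s) <= 0)[1]
    stop("non-monotone time column at data line ", bad + 1)
  }
  experiment_record(muscle = muscle, lmtu = lmtu, t = dat$time_s,
                    F = dat$force_N, protocol = protocol)
}

#' Moving-average filter
#'
#' Centered moving average of the force channel with a given window width
#' (40 ms by default), for display and export only - never fed into the
#' estimation. Edges use the truncated window mean.
#'
#' @param trace a data.frame with \code{time_s} and \code{force_N} (an
#'   \code{mtu_simulation} or [experiment_record()] coerced via
#'   \code{as.data.frame}), or a numeric force vector with \code{dt} given.
#' @param width window width, s (must be at least one sample interval).
#' @param dt sample interval, s; inferred from \code{time_s} if absent.
#' @return the input with the force channel smoothed.
#' @export
moving_average <- function(trace, width = 0.040, dt = NULL) {
  if (is.numeric(trace)) {
    F <- trace
    if (is.null(dt)) stop("dt required for a bare numeric trace")
  } else if (inherits(trace, "experiment_record")) {
    F <- trace$F
    dt <- stats::median(diff(trace$t))
  } else {
    F <- trace$force_N
    dt <- stats::median(diff(trace$time_s))
  }
  if (width < dt) stop("width must be at least one sample interval")
  half <- floor(width / dt / 2)
  n <- length(F)
  sm <- vapply(seq_len(n), function(i) {
    mean(F[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  if (is.numeric(trace)) return(sm)
  if (inherits(trace, "experiment_record")) {
    trace$F <- sm
  } else {
    trace$force_N <- sm
  }
  trace
}
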