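# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

gas_plus <- function() mtu_preset("GAS_plus")
pla_plus <- function() mtu_preset("PLA_plus")
gas_minus <- function() mtu_preset("GAS_minus")
met_const <- function() cached("mc", function() metabolic_constants())

# one default-protocol GAS+ run at 126 mm, reused by several tests
gas_sim_126 <- function() {
  cached("gas_sim_126", function() {
    mtu_simulate(gas_plus(), met_const(), lmtu = 0.126)
  })
}

# a short cheap protocol for estimation tests: 0.05 s rest, 0.45 s
# stimulation, 0.2 s tail at 250 Hz
short_protocol <- function() {
  default_protocol(stim_duration = 0.45, onset = 0.05, tail = 0.2,
                   sample_rate = 250)
}

# brute-force dense-grid oracle for the pool projection: two-stage grid
# search over the feasible [ADP] interval minimizing the absolute
# phosphate-balance residual
brute_force_adp <- function(Pi_target, mc, n = 4000) {
  resid <- function(d) {
    s <- mc$c_ad - d
    disc <- s * s - 4 * mc$K_adk * d * d
    ATP <- 0.5 * (s + sqrt(pmax(disc, 0)))
    AMP <- mc$K_adk * d * d / ATP
    PCr <- mc$c_cr / (1 + mc$K_ck * d / ATP)
    bound <- if (mc$accounting == "nucleotide") 3 * ATP + 2 * d + AMP
             else 0
    abs(Pi_target + PCr + bound - mc$c_ph)
  }
  lo <- 1e-9
  hi <- mc$c_ad / (1 + 2 * sqrt(mc$K_adk)) * (1 - 1e-9)
  for (stage in 1:3) {
    grid <- seq(lo, hi, length.out = n)
    i <- which.min(resid(grid))
    step <- grid[2] - grid[1]
    lo <- max(1e-9, grid[i] - step)
    hi <- min(mc$c_ad / (1 + 2 * sqrt(mc$K_adk)), grid[i] + step)
  }
  grid[i]
}
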