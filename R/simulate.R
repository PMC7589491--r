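#' Simulation configuration
#'
#' Ground truth and design of a synthetic Franz-cell permeation run. The
#' defaults reproduce the packaged study conditions: 1.77 cm2 / 1 mL / 7 mL
#' cell with 1 mL sample replacement, the 10-point 12-hour schedule, a
#' 10 mg/mL donor load, triplicate cells and 5% multiplicative analytic
#' noise.
#'
#' @param true_peff ground-truth permeability coefficient, cm/s.
#' @param geometry a [cell_geometry()].
#' @param schedule a [sampling_schedule()].
#' @param donor_concentration_0 initial donor concentration, ug/mL.
#' @param n_replicates number of replicate cells (>= 1).
#' @param noise_cv relative standard deviation of the multiplicative
#'   measurement noise applied to recorded concentrations (0 = noise-free).
#' @param seed integer random seed; identical seeds give identical
#'   experiments.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(true_peff,
                              geometry = cell_geometry(sample_volume = 1),
                              schedule = sampling_schedule(),
                              donor_concentration_0 = 10000,
                              n_replicates = 3,
                              noise_cv = 0.05,
                              seed = 1L) {
  stopifnot(
    is.numeric(true_peff), length(true_peff) == 1L, true_peff > 0,
    inherits(geometry, "cell_geometry"),
    inherits(schedule, "sampling_schedule"),
    is.numeric(donor_concentration_0), donor_concentration_0 > 0,
    n_replicates >= 1,
    is.numeric(noise_cv), noise_cv >= 0
  )
  structure(
    list(true_peff = true_peff, geometry = geometry, schedule = schedule,
         donor_concentration_0 = donor_concentration_0,
         n_replicates = as.integer(n_replicates),
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Closed-form receiver concentration after one interval
#'
#' Propagates the receiver concentration of a two-compartment diffusion cell
#' across a time interval during which no sampling occurs. Both compartments
#' exchange drug through the membrane; the donor concentration is implied by
#' mass balance, `C_donor = (q_total - C_receiver * V_receiver) / V_donor`.
#' The receiver concentration relaxes exponentially towards the well-mixed
#' equilibrium `q_total / (V_receiver + V_donor)` with rate constant
#' `peff * S * (1/V_receiver + 1/V_donor)` (1/s, since 1 mL = 1 cm3):
#'
#' `C_end = C_eq + (C_start - C_eq) * exp(-peff * S * (1/Vr + 1/Vd) * dt)`
#'
#' This is the exact solution of the linear two-compartment ODE, so interval
#' subdivision changes nothing.
#'
#' @param c_receiver_start receiver concentration at interval start, ug/mL.
#' @param q_total total drug mass in both chambers, ug.
#' @param peff permeability coefficient, cm/s (>= 0).
#' @param geometry a [cell_geometry()].
#' @param delta_t interval length, seconds (>= 0).
#' @return Receiver concentration at interval end, ug/mL.
#' @examples
#' geo <- cell_geometry(sample_volume = 1)
#' propagate_interval(0, q_total = 8000, peff = 1e-5, geo, delta_t = 3600)
#' @export
propagate_interval <- function(c_receiver_start, q_total, peff, geometry,
                               delta_t) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (!is.numeric(delta_t) || delta_t < 0) {
    stop("`delta_t` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(peff) || peff < 0) {
    stop("`peff` must be non-negative", call. = FALSE)
  }
  stopifnot(c_receiver_start >= 0, q_total >= 0)
  v_r <- geometry$receiver_volume
  v_d <- geometry$donor_volume
  c_eq <- q_total / (v_r + v_d)
  k <- peff * geometry$area * (1 / v_r + 1 / v_d)  # 1/s
  c_eq + (c_receiver_start - c_eq) * exp(-k * delta_t)
}

#' Simulate a Franz-cell permeation experiment
#'
#' Generates replicate receiver concentration-time series with known true
#' permeability. For each replicate the simulator iterates the schedule:
#' it propagates the two-compartment state across each interval with
#' [propagate_interval()], records the receiver concentration (perturbed by
#' multiplicative Gaussian noise, mean 1, sd `noise_cv`, truncated at zero),
#' then applies the sampling event — the receiver concentration is diluted by
#' `f = (V_receiver - sample_volume) / V_receiver` and the total mass in the
#' cell is reduced by the withdrawn mass `C * sample_volume`.
#'
#' Bookkeeping is always mass-conserving: at every step donor mass +
#' receiver mass + cumulative withdrawn mass equals the loaded dose
#' `V_donor * C0`. Noise affects only the recorded values, never the
#' propagated state, mirroring an analytic (HPLC) error that does not feed
#' back into the physics.
#'
#' @param config a [simulation_config()].
#' @return A [permeation_experiment()] whose `replicates` are the recorded
#'   (pre-replacement) receiver concentrations; the ground truth is attached
#'   as attribute `"true_peff"`.
#' @examples
#' exp <- simulate_permeation(simulation_config(true_peff = 1e-5, seed = 42))
#' replicate_mean(exp)
#' @export
simulate_permeation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geo <- config$geometry
  times_s <- config$schedule$times * 3600
  dts <- diff(c(0, times_s))
  f <- (geo$receiver_volume - geo$sample_volume) / geo$receiver_volume

  set.seed(config$seed)
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    c_r <- 0
    q_total <- geo$donor_volume * config$donor_concentration_0
    recorded <- numeric(length(dts))
    for (i in seq_along(dts)) {
      c_r <- propagate_interval(c_r, q_total, config$true_peff, geo, dts[i])
      noise <- if (config$noise_cv > 0) {
        max(0, stats::rnorm(1, mean = 1, sd = config$noise_cv))
      } else 1
      recorded[i] <- c_r * noise
      # sampling event: withdraw sample_volume, replace with fresh buffer
      q_total <- q_total - c_r * geo$sample_volume
      c_r <- c_r * f
    }
    reps[[r]] <- recorded
  }

  exp <- permeation_experiment(
    drug_name = sprintf("simulated_peff_%g", config$true_peff),
    geometry = geo, schedule = config$schedule,
    donor_concentration_0 = config$donor_concentration_0,
    replicates = reps)
  attr(exp, "true_peff") <- config$true_peff
  exp
}
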