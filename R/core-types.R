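#' Franz-cell geometry
#'
#' Physical constants of a single Franz vertical diffusion cell: the membrane
#' diffusion area, the donor and receiver chamber volumes, and the volume
#' withdrawn (and replaced with fresh buffer) at each sampling event.
#'
#' Defaults correspond to the MicroettePlus-type cell used throughout the
#' packaged examples: 1.77 cm2 diffusion area, 1 mL donor, 7 mL receiver.
#' `sample_volume` has no default: the replacement volume is an operational
#' setting of the autosampler and must be supplied explicitly.
#'
#' @param area membrane diffusion area, cm2.
#' @param donor_volume donor chamber volume, mL.
#' @param receiver_volume receiver chamber volume, mL.
#' @param sample_volume volume withdrawn and replaced per sampling event, mL.
#'   Must be strictly smaller than `receiver_volume`; may be 0 (no
#'   withdrawal, e.g. in-line probes).
#'
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry(sample_volume = 1)
#' @export
cell_geometry <- function(area = 1.77, donor_volume = 1, receiver_volume = 7,
                          sample_volume) {
  stopifnot(
    is.numeric(area), length(area) == 1L, is.finite(area), area > 0,
    is.numeric(donor_volume), length(donor_volume) == 1L, donor_volume > 0,
    is.numeric(receiver_volume), length(receiver_volume) == 1L,
    receiver_volume > 0,
    is.numeric(sample_volume), length(sample_volume) == 1L,
    sample_volume >= 0
  )
  if (sample_volume >= receiver_volume) {
    stop("`sample_volume` must be smaller than `receiver_volume`",
         call. = FALSE)
  }
  structure(
    list(area = as.numeric(area),
         donor_volume = as.numeric(donor_volume),
         receiver_volume = as.numeric(receiver_volume),
         sample_volume = as.numeric(sample_volume)),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "Franz cell: A = %g cm2, donor %g mL, receiver %g mL, sample %g mL\n",
    x$area, x$donor_volume, x$receiver_volume, x$sample_volume))
  invisible(x)
}

#' Sampling schedule
#'
#' A strictly increasing sequence of sampling times in hours. The default is
#' the 10-point, 12-hour autosampler schedule used in the packaged examples.
#'
#' @param times numeric vector of sampling times, hours; strictly increasing,
#'   all positive.
#' @return An object of class `sampling_schedule`.
#' @examples
#' sampling_schedule()
#' sampling_schedule(c(0.5, 1, 2, 4))
#' @export
sampling_schedule <- function(times = c(0.25, 0.5, 1, 2, 3, 4, 5, 6, 10, 12)) {
  stopifnot(is.numeric(times), length(times) >= 1L, all(is.finite(times)))
  if (any(times <= 0)) {
    stop("sampling times must all be positive", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times)), class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat("Sampling schedule (h):", paste(x$times, collapse = ", "), "\n")
  invisible(x)
}

#' Permeation experiment
#'
#' One drug's Franz-cell permeation run: the cell geometry, the sampling
#' schedule, the initial donor concentration and one or more replicate series
#' of receiver-compartment concentrations aligned to the schedule.
#'
#' Receiver concentrations are the values measured at each sampling time,
#' *before* the withdrawn volume is replaced with fresh buffer (the usual
#' autosampler convention); the replacement dilution is corrected downstream
#' by [cumulative_amount()] and by the non-sink model's dilution factor.
#'
#' @param drug_name character scalar.
#' @param geometry a [cell_geometry()].
#' @param schedule a [sampling_schedule()].
#' @param donor_concentration_0 initial donor concentration C0, ug/mL.
#' @param replicates list of numeric vectors (or a single vector), one
#'   receiver-concentration series per replicate, ug/mL, each the same length
#'   as the schedule.
#'
#' @return An object of class `permeation_experiment`.
#' @seealso [validate_experiment()] for non-throwing validation,
#'   [simulate_permeation()] to generate synthetic experiments.
#' @export
permeation_experiment <- function(drug_name, geometry, schedule,
                                  donor_concentration_0, replicates) {
  if (is.numeric(replicates)) replicates <- list(replicates)
  exp <- structure(
    list(drug_name = as.character(drug_name),
         geometry = geometry,
         schedule = schedule,
         donor_concentration_0 = as.numeric(donor_concentration_0),
         replicates = lapply(replicates, as.numeric)),
    class = "permeation_experiment"
  )
  findings <- validate_experiment(exp)
  if (length(findings) > 0L) {
    stop("invalid permeation experiment:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  }
  exp
}

#' Validate a permeation experiment
#'
#' Checks every structural invariant of a [permeation_experiment()] and
#' returns findings rather than throwing, so malformed inputs read from disk
#' can be reported in full.
#'
#' @param exp an object shaped like a `permeation_experiment` (it need not be
#'   valid — that is the point).
#' @return A character vector of findings, one per violated invariant, each
#'   naming the offending field; `character(0)` when the experiment is
#'   well-formed.
#' @examples
#' geo <- cell_geometry(sample_volume = 1)
#' sch <- sampling_schedule(c(1, 2, 3))
#' exp <- simulate_permeation(simulation_config(
#'   true_peff = 1e-6, geometry = geo, schedule = sch,
#'   donor_concentration_0 = 1000, n_replicates = 2, noise_cv = 0, seed = 1))
#' validate_experiment(exp)
#' @export
validate_experiment <- function(exp) {
  findings <- character(0)
  note <- function(msg) findings <<- c(findings, msg)

  geo <- exp$geometry
  if (!inherits(geo, "cell_geometry")) {
    note("geometry: not a cell_geometry object")
  } else {
    for (fld in c("area", "donor_volume", "receiver_volume")) {
      v <- geo[[fld]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        note(sprintf("geometry$%s: must be a positive number", fld))
    }
    sv <- geo$sample_volume
    if (!is.numeric(sv) || length(sv) != 1L || !is.finite(sv) || sv < 0) {
      note("geometry$sample_volume: must be a non-negative number")
    } else if (is.numeric(geo$receiver_volume) &&
               length(geo$receiver_volume) == 1L &&
               is.finite(geo$receiver_volume) &&
               sv >= geo$receiver_volume) {
      note("geometry$sample_volume: must be smaller than receiver_volume")
    }
  }

  sch <- exp$schedule
  n_times <- NA_integer_
  if (!inherits(sch, "sampling_schedule") || !is.numeric(sch$times)) {
    note("schedule: not a sampling_schedule object")
  } else {
    n_times <- length(sch$times)
    if (n_times < 1L) note("schedule$times: empty")
    if (any(!is.finite(sch$times)) || any(sch$times <= 0))
      note("schedule$times: all times must be positive and finite")
    if (n_times > 1L && any(diff(sch$times) <= 0))
      note("schedule$times: must be strictly increasing")
  }

  c0 <- exp$donor_concentration_0
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    note("donor_concentration_0: must be a positive number")

  reps <- exp$replicates
  if (!is.list(reps) || length(reps) < 1L) {
    note("replicates: must be a non-empty list of concentration series")
  } else {
    for (i in seq_along(reps)) {
      r <- reps[[i]]
      if (!is.numeric(r)) {
        note(sprintf("replicates[[%d]]: not numeric", i))
        next
      }
      if (!is.na(n_times) && length(r) != n_times)
        note(sprintf(
          "replicates[[%d]]: length mismatch (%d concentrations for %d schedule times)",
          i, length(r), n_times))
      bad <- which(!is.finite(r) | r < 0)
      if (length(bad) > 0L)
        note(sprintf(
          "replicates[[%d]]: negative or non-finite concentration at index %s",
          i, paste(bad, collapse = ", ")))
    }
  }

  findings
}

#' @export
print.permeation_experiment <- function(x, ...) {
  cat(sprintf(
    "Permeation experiment: %s\n  C0 = %g ug/mL, %d replicate(s), %d sampling times (%g-%g h)\n",
    x$drug_name, x$donor_concentration_0, length(x$replicates),
    length(x$schedule$times), min(x$schedule$times), max(x$schedule$times)))
  invisible(x)
}

#' Replicate-mean receiver concentration series
#'
#' @param exp a [permeation_experiment()].
#' @return Numeric vector, elementwise mean across replicates, ug/mL.
#' @export
replicate_mean <- function(exp) {
  rowMeans(do.call(cbind, exp$replicates))
}
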