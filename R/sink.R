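#' Cumulative transported mass, corrected for sample replacement
#'
#' Converts a receiver concentration series into the cumulative mass of drug
#' that has crossed the membrane. Because each sampling event removes
#' `sample_volume` of receiver medium (replaced with fresh buffer), the mass
#' currently in the receiver understates transport; the withdrawn mass is
#' added back:
#'
#' `Q(t_k) = C_k * V_receiver + sum_{i<k} C_i * sample_volume`
#'
#' @param concentrations receiver concentrations at the schedule times,
#'   ug/mL (pre-replacement values).
#' @param geometry a [cell_geometry()].
#' @return Cumulative transported mass at each schedule time, ug.
#' @examples
#' geo <- cell_geometry(receiver_volume = 7, sample_volume = 1)
#' cumulative_amount(c(1, 2, 3), geo)  # 7, 15, 24
#' @export
cumulative_amount <- function(concentrations, geometry) {
  stopifnot(inherits(geometry, "cell_geometry"), is.numeric(concentrations))
  if (length(concentrations) < 1L) {
    stop("empty concentration series", call. = FALSE)
  }
  withdrawn <- c(0, cumsum(concentrations * geometry$sample_volume))
  concentrations * geometry$receiver_volume +
    withdrawn[seq_along(concentrations)]
}

#' Best-fitting linear window of a cumulative transport curve
#'
#' Steady-state flux is read from the linear portion of the cumulative
#' transport curve. This selects, among all contiguous windows of at least
#' `min_window` points, the one whose ordinary least-squares fit has the
#' highest R-squared. Ties (within 1e-9) are broken in favour of the longer
#' window, then the later start — closer to steady state.
#'
#' Windows in which the response is constant have undefined R-squared; they
#' are skipped unless every window is degenerate, in which case the full
#' series is returned with `r_squared = NA` and slope 0.
#'
#' @param times sampling times, hours.
#' @param values cumulative mass (or any response linear in time), same
#'   length.
#' @param min_window minimum number of points in the window (default 4, so a
#'   straight-line fit keeps at least 2 residual degrees of freedom on the
#'   10-point schedule).
#' @return A list with `start`, `end` (1-based indices into the series),
#'   `slope`, `intercept` and `r_squared`.
#' @export
find_linear_portion <- function(times, values, min_window = 4) {
  n <- length(times)
  stopifnot(length(values) == n, min_window >= 2)
  if (n < min_window) {
    stop(sprintf("series has %d points; need at least min_window = %d",
                 n, min_window), call. = FALSE)
  }

  best <- NULL
  for (start in seq_len(n - min_window + 1L)) {
    for (end in seq(start + min_window - 1L, n)) {
      w <- window_ols(times[start:end], values[start:end])
      if (is.na(w$r_squared)) next
      if (is.null(best) ||
          w$r_squared > best$r_squared + 1e-9 ||
          (abs(w$r_squared - best$r_squared) <= 1e-9 &&
           better_tie(start, end, best))) {
        best <- list(start = start, end = end, slope = w$slope,
                     intercept = w$intercept, r_squared = w$r_squared)
      }
    }
  }
  if (is.null(best)) {
    # flat everywhere: no informative window
    best <- list(start = 1L, end = n, slope = 0, intercept = values[1],
                 r_squared = NA_real_)
  }
  best
}

# longer window wins; equal length -> later start wins
better_tie <- function(start, end, best) {
  len <- end - start + 1L
  best_len <- best$end - best$start + 1L
  len > best_len || (len == best_len && start > best$start)
}

window_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (syy <= .Machine$double.eps * max(1, mean(y)^2)) {
    return(list(slope = 0, intercept = mean(y), r_squared = NA_real_))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * syy))
}

#' Steady-state flux from a permeation experiment
#'
#' For each replicate, builds the replacement-corrected cumulative transport
#' curve ([cumulative_amount()]), selects its best linear window
#' ([find_linear_portion()]) and takes the slope (ug/h). The flux is the
#' across-replicate mean slope divided by the membrane area, converted to
#' seconds:
#'
#' `J = mean(slope) / (A * 3600)`  (ug cm-2 s-1)
#'
#' The reported window and R-squared come from the fit to the replicate-mean
#' cumulative curve; the coefficient of variation is computed on the
#' per-replicate fluxes (0 for a single replicate).
#'
#' @param exp a [permeation_experiment()].
#' @param min_window minimum linear-window size, passed to
#'   [find_linear_portion()].
#' @return An object of class `flux_estimate`: a list with `slope` (ug/h,
#'   replicate mean), `window_start_index`, `window_end_index`, `r_squared`,
#'   `flux_J` (ug cm-2 s-1), `cv_percent` and `per_replicate_J`.
#' @export
estimate_flux <- function(exp, min_window = 4) {
  stopifnot(inherits(exp, "permeation_experiment"))
  geo <- exp$geometry
  times <- exp$schedule$times

  per_slope <- vapply(exp$replicates, function(conc) {
    find_linear_portion(times, cumulative_amount(conc, geo), min_window)$slope
  }, numeric(1))
  per_J <- per_slope / (geo$area * 3600)

  mean_fit <- find_linear_portion(
    times, cumulative_amount(replicate_mean(exp), geo), min_window)

  j <- mean(per_J)
  cv <- if (length(per_J) > 1L && abs(mean(per_J)) > 0) {
    100 * stats::sd(per_J) / mean(per_J)
  } else 0

  structure(
    list(slope = mean(per_slope),
         window_start_index = mean_fit$start,
         window_end_index = mean_fit$end,
         r_squared = mean_fit$r_squared,
         flux_J = j,
         cv_percent = cv,
         per_replicate_J = per_J),
    class = "flux_estimate"
  )
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(
    "Flux: J = %.4g ug/cm2/s (CV %.1f%%), window [%d, %d], R2 = %s\n",
    x$flux_J, x$cv_percent, x$window_start_index, x$window_end_index,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Sink-condition apparent permeability
#'
#' Normalises the steady-state flux by the initial donor concentration:
#' `Papp = J / C0`, with J in ug cm-2 s-1 and C0 in ug/mL = ug/cm3, giving
#' cm/s. Valid when the receiver stays far from the donor concentration
#' (sink conditions) and donor depletion is negligible; otherwise it
#' underestimates the true permeability (see [fit_peff()]).
#'
#' @param flux_J steady-state flux, ug cm-2 s-1 (see [estimate_flux()]).
#' @param c0 initial donor concentration, ug/mL.
#' @return Apparent permeability, cm/s.
#' @examples
#' papp_sink(1e-2, 1000)  # 1e-5 cm/s
#' @export
papp_sink <- function(flux_J, c0) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0) {
    stop("`c0` must be a positive number", call. = FALSE)
  }
  stopifnot(is.numeric(flux_J))
  flux_J / c0
}
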