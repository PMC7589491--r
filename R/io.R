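#' Read a concentration-time CSV into a permeation experiment
#'
#' The dialect is long-format, UTF-8, "." decimal, with a required header
#' `drug,replicate,time_h,conc_ug_ml`: one row per (replicate, sampling
#' time). All replicates of one drug per file. The cell geometry and donor
#' concentration are not part of the table; supply them via a config (see
#' [read_config()]) or directly.
#'
#' @param path CSV file path.
#' @param geometry a [cell_geometry()].
#' @param donor_concentration_0 initial donor concentration, ug/mL.
#' @return A validated [permeation_experiment()].
#' @seealso [write_concentration_csv()] for the inverse.
#' @export
read_concentration_csv <- function(path, geometry, donor_concentration_0) {
  stopifnot(file.exists(path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  required <- c("drug", "replicate", "time_h", "conc_ug_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("time_h", "conc_ug_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at data line %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  drug <- unique(df$drug)
  if (length(drug) != 1L) {
    stop("file must contain exactly one drug; found: ",
         paste(drug, collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(df$time_h))
  rep_ids <- unique(df$replicate)
  reps <- lapply(rep_ids, function(rid) {
    sub <- df[df$replicate == rid, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    if (!identical(sub$time_h, times)) {
      stop(sprintf("replicate '%s' does not cover the common schedule", rid),
           call. = FALSE)
    }
    sub$conc_ug_ml
  })
  exp <- structure(
    list(drug_name = drug, geometry = geometry,
         schedule = sampling_schedule(times),
         donor_concentration_0 = as.numeric(donor_concentration_0),
         replicates = reps),
    class = "permeation_experiment")
  findings <- validate_experiment(exp)
  if (length(findings) > 0L) {
    stop("validation failed for '", path, "':\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  }
  exp
}

#' Write a permeation experiment to the concentration-time CSV dialect
#'
#' @param exp a [permeation_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(exp, path) {
  stopifnot(inherits(exp, "permeation_experiment"))
  times <- exp$schedule$times
  rows <- do.call(rbind, lapply(seq_along(exp$replicates), function(r) {
    data.frame(drug = exp$drug_name, replicate = r, time_h = times,
               conc_ug_ml = exp$replicates[[r]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table to CSV or JSON
#'
#' Column order is preserved, floating-point values are rendered with 6
#' significant digits, and output bytes are deterministic for identical
#' inputs.
#'
#' @param results a data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with top-level keys `geometry` (`area`, `donor_volume`,
#' `receiver_volume`, `sample_volume`), `schedule` (`times`, hours),
#' `simulation` (`true_peff`, `donor_concentration_0`, `n_replicates`,
#' `noise_cv`, `seed`), `fitting` (`method`, `qtotal_mode`, `min_window`)
#' and `correlation` (`papp_column`, `form`, `exclude`). Only `geometry` is
#' mandatory; the other sections default sensibly. See
#' `system.file("extdata", "demo_config.yaml", package = "franzpampa")`.
#'
#' @param path YAML file path.
#' @return A list with a `cell_geometry` under `$geometry`, a
#'   `sampling_schedule` under `$schedule` (when given), and the remaining
#'   sections as lists.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry)) {
    stop("config must contain a `geometry` section", call. = FALSE)
  }
  cfg$geometry <- do.call(cell_geometry, cfg$geometry)
  if (!is.null(cfg$schedule)) {
    cfg$schedule <- sampling_schedule(as.numeric(cfg$schedule$times))
  }
  cfg
}
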