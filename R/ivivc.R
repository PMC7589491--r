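#' Reference table of BCS model drugs
#'
#' Loads the packaged reference dataset: one row per drug with its BCS
#' class, human fraction absorbed (Fa%), apparent permeability measured in
#' the Franz-cell PAMPA system (sink-condition "best linear fit" and
#' non-sink fitted values) and literature permeabilities in Caco-2
#' monolayers, the Corti artificial membrane, conventional PAMPA at pH 7.4
#' and Permeapad, plus physicochemical descriptors.
#'
#' All permeabilities are in 1e-6 cm/s. Missing cells in the published
#' table are `NA`, never zero. `actively_transported` carries the table's
#' "(AT)" flag (ketoprofen, verapamil, ranitidine, trimethoprim);
#' `excluded_at_text` flags the trio (ranitidine, trimethoprim, verapamil)
#' that the accompanying correlation analysis removes as actively
#' transported — the two flags disagree on ketoprofen and both are kept.
#' `hp_literature` is the "(HP)" high-permeability literature flag. `pka`
#' is a semicolon-separated string for polyprotic drugs.
#'
#' @return A data frame with 20 rows and columns `name`, `bcs_class`,
#'   `fa_percent`, `papp_franz`, `papp_nonsink`, `papp_caco2`,
#'   `papp_corti`, `papp_pampa74`, `papp_permeapad`, `log_p`, `log_d`,
#'   `pka`, `intrinsic_solubility`, `actively_transported`,
#'   `hp_literature`, `excluded_at_text`.
#' @export
drug_reference_table <- function() {
  path <- system.file("extdata", "bcs_drug_table.csv",
                      package = "franzpampa", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$bcs_class <- factor(df$bcs_class, levels = c("I", "II", "III", "IV"))
  df
}

# drugs removed as actively transported in the IVIVC analysis
at_excluded_drugs <- function() c("ranitidine", "trimethoprim", "verapamil")

#' Correlate fraction absorbed with apparent permeability
#'
#' Ordinary least squares of human fraction absorbed (Fa%) on apparent
#' permeability, either on the log10 scale (`"log-linear"`, the usual choice
#' since permeabilities span several orders of magnitude) or on the raw
#' scale (`"linear"`). Rows with a missing Fa% or permeability are dropped;
#' under the log-linear form, rows with non-positive permeability are
#' additionally dropped with a warning.
#'
#' @param records a data frame like [drug_reference_table()].
#' @param papp_column name of the permeability column to use.
#' @param form `"log-linear"` or `"linear"`.
#' @param exclude character vector of drug names to leave out.
#' @return An object of class `correlation_result`: list with `model_form`,
#'   `x_column`, `included_drugs`, `n`, `slope`, `intercept`, `r`,
#'   `r_squared`.
#' @examples
#' tab <- drug_reference_table()
#' fit_fa_correlation(tab, "papp_franz", "log-linear")
#' fit_fa_correlation(tab, "papp_corti", "linear")
#' @export
fit_fa_correlation <- function(records, papp_column,
                               form = c("log-linear", "linear"),
                               exclude = character(0)) {
  form <- match.arg(form)
  stopifnot(is.data.frame(records), papp_column %in% names(records),
            "fa_percent" %in% names(records), "name" %in% names(records))
  keep <- !(records$name %in% exclude) &
    is.finite(records$fa_percent) & is.finite(records[[papp_column]])
  df <- records[keep, , drop = FALSE]
  if (form == "log-linear") {
    nonpos <- df[[papp_column]] <= 0
    if (any(nonpos)) {
      warning(sprintf(
        "dropping %d record(s) with non-positive %s under log-linear form: %s",
        sum(nonpos), papp_column,
        paste(df$name[nonpos], collapse = ", ")), call. = FALSE)
      df <- df[!nonpos, , drop = FALSE]
    }
  }
  if (nrow(df) < 3L) {
    stop("fewer than 3 usable records after exclusions", call. = FALSE)
  }
  x <- if (form == "log-linear") log10(df[[papp_column]]) else
    df[[papp_column]]
  y <- df$fa_percent
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(
    list(model_form = form, x_column = papp_column,
         included_drugs = df$name, n = nrow(df),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, r_squared = r^2),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Fa%% ~ %s [%s], n = %d\n  Fa%% = %.3f %+.3f * x,  r = %.4f,  R2 = %.4f\n",
    x$x_column, x$model_form, x$n, x$intercept, x$slope, x$r, x$r_squared))
  invisible(x)
}

#' Pearson correlation between two permeability columns
#'
#' @param records a data frame like [drug_reference_table()].
#' @param column_a,column_b permeability column names.
#' @param log_scale correlate log10 values (default) or raw values. Under
#'   the log scale, pairs with a non-positive value in either column are
#'   dropped.
#' @param exclude drug names to leave out.
#' @return List with `r`, `r_squared`, `n`, `included_drugs`, `log_scale`.
#' @export
cross_column_correlation <- function(records, column_a, column_b,
                                     log_scale = TRUE,
                                     exclude = character(0)) {
  stopifnot(is.data.frame(records),
            column_a %in% names(records), column_b %in% names(records))
  a <- records[[column_a]]
  b <- records[[column_b]]
  keep <- !(records$name %in% exclude) & is.finite(a) & is.finite(b)
  if (log_scale) keep <- keep & a > 0 & b > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 complete pairs", call. = FALSE)
  }
  a <- a[keep]; b <- b[keep]
  if (log_scale) { a <- log10(a); b <- log10(b) }
  r <- stats::cor(a, b)
  list(r = r, r_squared = r^2, n = sum(keep),
       included_drugs = records$name[keep], log_scale = log_scale)
}

#' Recompute the published correlation battery
#'
#' Recomputes, from the packaged reference table, every correlation
#' statistic reported with the Franz-cell PAMPA validation dataset and sets
#' each against its published value. Because the published analysis does not
#' enumerate the exact drug subset (or axis scale) behind every statistic,
#' each row states the statistic, the scale, the number of drugs and the
#' drug set actually used, so any discrepancy is diagnosable rather than
#' silent. Cross-membrane comparisons are emitted on both log10 and raw
#' scales.
#'
#' @param records a data frame like [drug_reference_table()] (the default).
#' @return A data frame with columns `comparison`, `statistic`, `scale`,
#'   `n`, `value`, `reference_value`, `abs_difference`, `drugs`. Rows whose
#'   inputs are unavailable are reported with `NA` values rather than
#'   dropped.
#' @export
ivivc_report <- function(records = drug_reference_table()) {
  at <- at_excluded_drugs()
  rows <- list(
    list("Fa% vs Franz-PAMPA Papp", "R2", "log10", 0.664,
         function() fit_fa_correlation(records, "papp_franz", "log-linear")),
    list("Fa% vs Franz-PAMPA Papp, passive only", "R2", "log10", 0.6982,
         function() fit_fa_correlation(records, "papp_franz", "log-linear",
                                       exclude = at)),
    list("Fa% vs Caco-2 Papp", "R2", "log10", 0.805,
         function() fit_fa_correlation(records, "papp_caco2", "log-linear")),
    list("Fa% vs Corti Papp", "R2", "linear", 0.904,
         function() fit_fa_correlation(records, "papp_corti", "linear")),
    list("Fa% vs Corti Papp, passive only", "R2", "linear", 0.890,
         function() fit_fa_correlation(records, "papp_corti", "linear",
                                       exclude = at)),
    list("Franz-PAMPA vs Caco-2", "R2", "log10", 0.826,
         function() cross_column_correlation(records, "papp_franz",
                                             "papp_caco2", TRUE)),
    list("Franz-PAMPA vs Caco-2", "R2", "linear", 0.826,
         function() cross_column_correlation(records, "papp_franz",
                                             "papp_caco2", FALSE)),
    list("Franz-PAMPA vs non-sink Papp", "r", "log10", NA_real_,
         function() cross_column_correlation(records, "papp_franz",
                                             "papp_nonsink", TRUE)),
    list("Franz-PAMPA vs non-sink Papp", "r", "linear", 0.8984,
         function() cross_column_correlation(records, "papp_franz",
                                             "papp_nonsink", FALSE)),
    list("Franz-PAMPA vs PAMPA pH 7.4", "r", "linear", 0.7355,
         function() cross_column_correlation(records, "papp_franz",
                                             "papp_pampa74", FALSE))
  )

  out <- lapply(rows, function(row) {
    res <- tryCatch(suppressWarnings(row[[5]]()), error = function(e) NULL)
    if (is.null(res)) {
      value <- NA_real_; n <- NA_integer_; drugs <- "not computable"
    } else {
      value <- if (row[[2]] == "R2") res$r_squared else res$r
      n <- res$n
      drugs <- paste(res$included_drugs, collapse = ";")
    }
    data.frame(comparison = row[[1]], statistic = row[[2]],
               scale = row[[3]], n = n, value = value,
               reference_value = row[[4]],
               abs_difference = abs(value - row[[4]]),
               drugs = drugs, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
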