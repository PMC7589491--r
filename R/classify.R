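#' BCS permeability class against an internal reference
#'
#' Metoprolol sits on the low/high permeability boundary of the BCS, so a
#' drug is called highly permeable when its apparent permeability exceeds
#' 80% of the metoprolol value measured *by the same method in the same
#' system*. The inequality is strict: a drug at exactly 0.8 x reference is
#' classified low.
#'
#' @param papp apparent permeability of the drug, cm/s (or any unit shared
#'   with the reference — the rule is scale-invariant).
#' @param papp_reference apparent permeability of the reference drug, same
#'   units.
#' @return `"high"` or `"low"`.
#' @examples
#' classify_permeability(36.2e-6, 15.8e-6)  # "high"
#' classify_permeability(0.40e-6, 15.8e-6)  # "low"
#' @export
classify_permeability <- function(papp, papp_reference) {
  if (!is.numeric(papp) || !is.numeric(papp_reference) ||
      any(!is.finite(papp)) || any(!is.finite(papp_reference)) ||
      any(papp <= 0) || any(papp_reference <= 0)) {
    stop("`papp` and `papp_reference` must be positive", call. = FALSE)
  }
  ifelse(papp > 0.8 * papp_reference, "high", "low")
}

#' Classify a table of drugs against a reference drug
#'
#' Applies [classify_permeability()] to every non-reference drug with a
#' non-missing permeability.
#'
#' @param records data frame with columns `drug` (character) and `papp`
#'   (numeric, `NA` allowed).
#' @param reference_drug name of the internal reference; must be present in
#'   `records` with a positive `papp`.
#' @return A list with `labels` — a data frame `drug`, `papp`,
#'   `classification` (`"high"`, `"low"` or `"missing"`) over the
#'   non-reference rows — and `counts`, a named vector with entries `high`,
#'   `low`, `missing`.
#' @export
classify_table <- function(records, reference_drug = "metoprolol") {
  stopifnot(is.data.frame(records),
            all(c("drug", "papp") %in% names(records)))
  ref_row <- records[records$drug == reference_drug, , drop = FALSE]
  if (nrow(ref_row) != 1L || is.na(ref_row$papp) || ref_row$papp <= 0) {
    stop(sprintf(
      "reference drug '%s' absent or without a positive permeability",
      reference_drug), call. = FALSE)
  }
  ref <- ref_row$papp
  others <- records[records$drug != reference_drug, , drop = FALSE]
  cls <- vapply(others$papp, function(p) {
    if (is.na(p)) "missing" else classify_permeability(p, ref)
  }, character(1))
  labels <- data.frame(drug = others$drug, papp = others$papp,
                       classification = cls, stringsAsFactors = FALSE)
  counts <- c(high = sum(cls == "high"), low = sum(cls == "low"),
              missing = sum(cls == "missing"))
  list(labels = labels, counts = counts, reference = ref)
}

#' Dose number
#'
#' The BCS dose number `D0 = (dose / V_ref) / solubility` compares the
#' concentration of the full dose dissolved in a reference gastric volume
#' (250 mL by convention) to the drug's solubility; `D0 <= 1` means
#' solubility does not limit absorption, and `D0 <= 0.01` is effectively
#' dilute.
#'
#' @param dose_mass administered dose, mg.
#' @param solubility aqueous solubility, mg/mL.
#' @param reference_volume reference gastric volume, mL (default 250).
#' @return Dimensionless dose number.
#' @examples
#' dose_number(250, 1)          # 1
#' dose_number(10, 1000)        # 4e-5
#' @export
dose_number <- function(dose_mass, solubility, reference_volume = 250) {
  if (!is.numeric(solubility) || any(!is.finite(solubility)) ||
      any(solubility <= 0)) {
    stop("`solubility` must be positive", call. = FALSE)
  }
  if (!is.numeric(dose_mass) || any(dose_mass <= 0) ||
      !is.numeric(reference_volume) || any(reference_volume <= 0)) {
    stop("`dose_mass` and `reference_volume` must be positive", call. = FALSE)
  }
  (dose_mass / reference_volume) / solubility
}
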