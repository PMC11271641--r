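# Multiple-testing correction across exposure-outcome hypothesis families.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' `p_(i)` by `m/i`, enforce monotonicity from the largest down, cap at 1,
#' return in input order. Delegates to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' `min(1, m * p)` elementwise, `m` the family size.
#'
#' @inheritParams bh_fdr
#' @return Adjusted p-values in input order.
#' @export
bonferroni <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "bonferroni")
}

#' Build a correction table across exposure-outcome hypotheses
#'
#' Applies BH-FDR and Bonferroni corrections to the primary (IVW)
#' p-values of a set of exposure-outcome results. Adjustment is computed
#' from unrounded raw p-values within each family; the default family is
#' all exposures tested against one outcome (so `m` = number of
#' exposures), the layout of a per-outcome correction table.
#'
#' @param results Data frame with columns `exposure`, `outcome`,
#'   `pvalue` (raw p-values of the primary method, one row per pair).
#' @param family `"outcome"` (default: adjust across exposures within
#'   each outcome), `"exposure"` (across outcomes within each exposure),
#'   or `"all"` (one family of all pairs).
#' @return `results` with columns `fdr` and `bonferroni` appended.
#' @export
correction_table <- function(results, family = c("outcome", "exposure",
                                                 "all")) {
  family <- match.arg(family)
  stopifnot(all(c("exposure", "outcome", "pvalue") %in% names(results)))
  key <- switch(family,
                outcome = results$outcome,
                exposure = results$exposure,
                all = rep("all", nrow(results)))
  results$fdr <- NA_real_
  results$bonferroni <- NA_real_
  for (g in unique(key)) {
    idx <- which(key == g)
    results$fdr[idx] <- bh_fdr(results$pvalue[idx])
    results$bonferroni[idx] <- bonferroni(results$pvalue[idx])
  }
  results
}

#' Render a correction table in wide publication shape
#'
#' Rows are exposures; for each outcome a pair of columns holds the FDR-
#' and Bonferroni-adjusted p-values (rounded to `digits`).
#'
#' @param corrections Output of [correction_table()].
#' @param digits Rounding for display; default 2.
#' @return Wide data frame, one row per exposure.
#' @export
correction_table_wide <- function(corrections, digits = 2) {
  exposures <- unique(corrections$exposure)
  outcomes <- unique(corrections$outcome)
  out <- data.frame(exposure = exposures, stringsAsFactors = FALSE)
  for (oc in outcomes) {
    sub <- corrections[corrections$outcome == oc, ]
    i <- match(exposures, sub$exposure)
    out[[paste0(oc, "_fdr")]] <- round(sub$fdr[i], digits)
    out[[paste0(oc, "_bonferroni")]] <- round(sub$bonferroni[i], digits)
  }
  out
}
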