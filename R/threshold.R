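# Significance threshold calibration from non-phosphopeptide ratios, and
# selection of kinase-dependent phosphopeptides.

#' Calibrate the treated/control significance threshold
#'
#' The threshold is anchored on the contaminant non-phosphopeptides, whose
#' true ratio is 1: their observed log2 ratio distribution shows how far pure
#' quantification noise reaches. In `fixed` mode the threshold is the
#' conventional ratio 2 (log2 ratio 1, which the non-phosphopeptide
#' distribution is observed not to exceed); in `empirical` mode it is
#' `2 ^ max(observed non-phosphopeptide log2 ratio)`, reproducing that
#' inspection programmatically.
#'
#' @param quants Peptide-quantification `data.frame` (see
#'   [quantify_peptides()]); rows with `is_phospho == FALSE` calibrate, rows
#'   with `is_phospho == TRUE` are summarized against the threshold when
#'   present.
#' @param mode `"fixed"` (default) or `"empirical"`.
#' @param fixed_ratio Threshold used in fixed mode (default 2).
#' @return An object of class `threshold_report`: `mode`, `threshold` (ratio
#'   scale), `max_nonphospho_log2`, `n_nonphospho`, counts of phosphopeptides
#'   above/below the threshold, and log2-ratio histograms (`hist()` objects,
#'   `plot = FALSE`) for both sets.
#' @export
calibrate_threshold <- function(quants, mode = c("fixed", "empirical"),
                                fixed_ratio = 2) {
  mode <- match.arg(mode)
  stopifnot(fixed_ratio > 0)
  nonphospho_log2 <- pooled_log2(quants[!quants$is_phospho, , drop = FALSE])
  if (mode == "empirical" && length(nonphospho_log2) == 0L) {
    stop("empirical calibration requires at least one non-phosphopeptide")
  }
  max_log2 <- if (length(nonphospho_log2)) max(nonphospho_log2) else NA_real_
  threshold <- switch(mode, fixed = fixed_ratio, empirical = 2^max_log2)
  phospho <- quants[quants$is_phospho, , drop = FALSE]
  phospho_log2 <- pooled_log2(phospho)
  best <- peptide_best_ratio(phospho)
  hist_or_null <- function(x) {
    if (length(x)) graphics::hist(x, breaks = "FD", plot = FALSE) else NULL
  }
  structure(list(mode = mode,
                 threshold = threshold,
                 max_nonphospho_log2 = max_log2,
                 n_nonphospho = sum(!quants$is_phospho),
                 n_phospho = nrow(phospho),
                 n_phospho_above = sum(best > threshold, na.rm = TRUE),
                 n_phospho_below = sum(best <= threshold, na.rm = TRUE),
                 phospho_log2_hist = hist_or_null(phospho_log2),
                 nonphospho_log2_hist = hist_or_null(nonphospho_log2)),
            class = "threshold_report")
}

# pooled per-experiment mean log2 ratios, NAs dropped
pooled_log2 <- function(quants) {
  if (nrow(quants) == 0L) return(numeric(0))
  x <- log2(c(quants$ratio_forward, quants$ratio_reverse))
  x[!is.na(x)]
}

# the larger available per-experiment mean ratio of each peptide
peptide_best_ratio <- function(quants) {
  if (nrow(quants) == 0L) return(numeric(0))
  pmax(quants$ratio_forward, quants$ratio_reverse, na.rm = TRUE)
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Threshold report (%s mode)\n", x$mode))
  cat(sprintf("  ratio threshold: %.4g (log2 %.4g)\n",
              x$threshold, log2(x$threshold)))
  cat(sprintf("  max non-phosphopeptide log2 ratio: %.4g (n = %d)\n",
              x$max_nonphospho_log2, x$n_nonphospho))
  cat(sprintf("  phosphopeptides above/below threshold: %d / %d\n",
              x$n_phospho_above, x$n_phospho_below))
  invisible(x)
}

#' Select kinase-dependent phosphopeptides
#'
#' Keeps phosphopeptides whose per-experiment mean treated/control ratio
#' exceeds the threshold (strict `>`). Class 2 peptides are judged on their
#' single experiment; class 1 peptides per `rule`: `"both"` requires both
#' experiment means above the threshold, `"any"` at least one.
#'
#' @param quants Peptide-quantification `data.frame`.
#' @param threshold Ratio threshold (> 0), e.g. from [calibrate_threshold()].
#' @param rule Class-1 rule, `"both"` (default, conservative) or `"any"`.
#' @return The selected subset of phospho rows of `quants`.
#' @export
select_dependent <- function(quants, threshold, rule = c("both", "any")) {
  rule <- match.arg(rule)
  if (inherits(threshold, "threshold_report")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), threshold > 0)
  phospho <- quants[quants$is_phospho, , drop = FALSE]
  if (nrow(phospho) == 0L) return(phospho)
  fwd_ok <- !is.na(phospho$ratio_forward) & phospho$ratio_forward > threshold
  rev_ok <- !is.na(phospho$ratio_reverse) & phospho$ratio_reverse > threshold
  keep <- ifelse(phospho$class == 1L,
                 if (rule == "both") fwd_ok & rev_ok else fwd_ok | rev_ok,
                 fwd_ok | rev_ok)  # class 2: its single experiment mean
  out <- phospho[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
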