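# PSM table parsing, confidence filtering, ratio orientation/capping,
# replicate aggregation, and class 1/2 peptide classification.

PSM_COLUMNS <- c("peptide", "phospho_positions_in_peptide", "accession",
                 "raw_ratio_light_over_medium", "q_value", "experiment",
                 "replicate")

#' Read a PSM table
#'
#' Tab-separated, one row per quantified peptide-spectrum match, with columns
#' `peptide`, `phospho_positions_in_peptide` (';'-joined 1-based positions
#' within the peptide; empty for a non-phosphopeptide), `accession`
#' (';'-joined group allowed), `raw_ratio_light_over_medium`, `q_value`,
#' `experiment` (`forward`/`reverse`) and `replicate`. Extra columns are kept.
#'
#' @param path One or more TSV paths; multiple files are row-bound.
#' @return Validated PSM `data.frame`.
#' @export
read_psm_table <- function(path) {
  tabs <- lapply(path, function(p) {
    tab <- utils::read.delim(p, stringsAsFactors = FALSE, na.strings = NULL)
    if ("phospho_positions_in_peptide" %in% names(tab)) {
      tab$phospho_positions_in_peptide <-
        as.character(tab$phospho_positions_in_peptide)
    }
    tab
  })
  check_psm_table(do.call(rbind, tabs))
}

#' Write a PSM table
#'
#' @param psms PSM `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  check_psm_table(psms)
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_psm_table <- function(psms) {
  miss <- setdiff(PSM_COLUMNS, names(psms))
  if (length(miss)) stop("PSM table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(psms) == 0L) return(psms)
  psms$phospho_positions_in_peptide[is.na(psms$phospho_positions_in_peptide)] <- ""
  if (any(!psms$experiment %in% c("forward", "reverse"))) {
    stop("experiment must be 'forward' or 'reverse'")
  }
  if (any(!is.finite(psms$raw_ratio_light_over_medium)) ||
      any(psms$raw_ratio_light_over_medium <= 0)) {
    stop("raw ratios must be positive")
  }
  if (any(psms$q_value < 0 | psms$q_value > 1)) stop("q_value must be in [0, 1]")
  phos <- parse_positions(psms$phospho_positions_in_peptide)
  bad <- mapply(function(pp, pep) {
    length(pp) > 0L && (any(pp < 1L | pp > nchar(pep)) ||
      any(!substring(pep, pp, pp) %in% c("S", "T", "Y")))
  }, phos, psms$peptide)
  if (any(bad)) {
    stop("phospho positions outside the peptide or not on S/T/Y in ",
         sum(bad), " row(s)")
  }
  psms
}

# ';'-joined position strings -> list of sorted integer vectors
parse_positions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) sort(as.integer(v[nzchar(v)])))
}

# canonical analyte key: sequence + sorted phospho positions
analyte_key <- function(peptide, positions_chr) {
  canon <- vapply(parse_positions(positions_chr), paste,
                  character(1), collapse = ";")
  paste(peptide, canon, sep = "|")
}

#' Filter PSMs by identification confidence
#'
#' Strictly keeps records with `q_value` below the threshold (a record at
#' exactly the threshold is removed).
#'
#' @param psms PSM `data.frame`.
#' @param q_threshold Confidence threshold in (0, 1]; default 0.05.
#' @return Filtered PSM `data.frame`.
#' @export
filter_psms <- function(psms, q_threshold = 0.05) {
  stopifnot(q_threshold > 0, q_threshold <= 1)
  psms[psms$q_value < q_threshold, , drop = FALSE]
}

#' Orient a raw channel ratio as treated/control and cap it
#'
#' In the forward experiment the treated sample carries the light label, so
#' the reported light/medium ratio is already treated/control; in the reverse
#' experiment the labels are swapped and the ratio is inverted. Values are
#' then capped at `cap` (the quantification software's maximum reported
#' ratio).
#'
#' @param raw_ratio Positive numeric vector of light/medium ratios.
#' @param experiment Character vector, `"forward"` or `"reverse"`.
#' @param cap Maximum reported treated/control ratio (default 100).
#' @return Numeric vector of capped treated/control ratios.
#' @export
orient_ratio <- function(raw_ratio, experiment, cap = 100) {
  stopifnot(cap > 0)
  if (any(!is.finite(raw_ratio)) || any(raw_ratio <= 0)) {
    stop("raw_ratio must be positive")
  }
  if (any(!experiment %in% c("forward", "reverse"))) {
    stop("experiment must be 'forward' or 'reverse'")
  }
  oriented <- ifelse(experiment == "reverse", 1 / raw_ratio, raw_ratio)
  pmin(oriented, cap)
}

#' Average oriented ratios over technical replicates
#'
#' @param ratios Oriented (treated/control, capped) ratios of one analyte in
#'   one experiment, one per replicate.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return List with `ratio` (the mean) and `n` (replicate count).
#' @export
aggregate_replicates <- function(ratios, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (length(ratios) == 0L) stop("no replicate ratios to aggregate")
  m <- switch(mean_type,
              arithmetic = mean(ratios),
              geometric = exp(mean(log(ratios))))
  list(ratio = m, n = length(ratios))
}

#' Classify per-experiment aggregates into class 1/2 peptides
#'
#' Class 1 peptides are quantified in both the forward and the reverse
#' experiment; class 2 in only one. Non-phosphopeptides get `NA` class and
#' are carried separately for threshold calibration.
#'
#' @param aggregates `data.frame` with one row per (analyte, experiment):
#'   columns `peptide`, `phospho_positions_in_peptide`, `accession`,
#'   `experiment`, `ratio`, `n`.
#' @return Peptide-quantification `data.frame`: one row per analyte with
#'   `ratio_forward`/`n_forward`/`ratio_reverse`/`n_reverse`,
#'   `log2_forward`/`log2_reverse`, `is_phospho` and `class` (1, 2, or `NA`
#'   for non-phosphopeptides).
#' @export
classify_peptides <- function(aggregates) {
  if (nrow(aggregates) == 0L) {
    return(data.frame(peptide = character(0),
                      phospho_positions_in_peptide = character(0),
                      accession = character(0), is_phospho = logical(0),
                      ratio_forward = numeric(0), n_forward = integer(0),
                      ratio_reverse = numeric(0), n_reverse = integer(0),
                      log2_forward = numeric(0), log2_reverse = numeric(0),
                      class = integer(0)))
  }
  key <- analyte_key(aggregates$peptide, aggregates$phospho_positions_in_peptide)
  first <- !duplicated(key)
  out <- aggregates[first, c("peptide", "phospho_positions_in_peptide",
                             "accession"), drop = FALSE]
  ukey <- key[first]
  pick <- function(exp_name, col) {
    sel <- aggregates$experiment == exp_name
    idx <- match(ukey, key[sel])
    aggregates[[col]][sel][idx]
  }
  out$is_phospho <- nzchar(out$phospho_positions_in_peptide)
  out$ratio_forward <- pick("forward", "ratio")
  out$n_forward <- pick("forward", "n")
  out$ratio_reverse <- pick("reverse", "ratio")
  out$n_reverse <- pick("reverse", "n")
  out$log2_forward <- log2(out$ratio_forward)
  out$log2_reverse <- log2(out$ratio_reverse)
  both <- !is.na(out$ratio_forward) & !is.na(out$ratio_reverse)
  out$class <- ifelse(out$is_phospho, ifelse(both, 1L, 2L), NA_integer_)
  rownames(out) <- NULL
  out
}

#' Quantify peptides from PSM tables
#'
#' Full quantification stage: q-value filtering, per-replicate orientation
#' and capping, replicate averaging per experiment, and class 1/2
#' classification.
#'
#' @param psms PSM `data.frame` containing both experiments (or one).
#' @param q_threshold Confidence threshold (strict `<`; default 0.05).
#' @param ratio_cap Maximum treated/control ratio (default 100).
#' @param cap_before_average Cap each replicate's oriented ratio before
#'   averaging (default `TRUE`); if `FALSE`, the cap is applied to the
#'   per-experiment mean instead.
#' @param mean_type Passed to [aggregate_replicates()].
#' @return See [classify_peptides()].
#' @export
quantify_peptides <- function(psms, q_threshold = 0.05, ratio_cap = 100,
                              cap_before_average = TRUE,
                              mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  psms <- check_psm_table(psms)
  psms <- filter_psms(psms, q_threshold)
  if (nrow(psms) == 0L) {
    return(classify_peptides(data.frame(
      peptide = character(0), phospho_positions_in_peptide = character(0),
      accession = character(0), experiment = character(0),
      ratio = numeric(0), n = integer(0))))
  }
  oriented <- orient_ratio(psms$raw_ratio_light_over_medium, psms$experiment,
                           cap = if (cap_before_average) ratio_cap else Inf)
  key <- paste(analyte_key(psms$peptide, psms$phospho_positions_in_peptide),
               psms$experiment, sep = "\r")
  first <- !duplicated(key)
  agg <- psms[first, c("peptide", "phospho_positions_in_peptide",
                       "accession", "experiment"), drop = FALSE]
  grp <- match(key, key[first])
  means <- if (mean_type == "arithmetic") {
    as.numeric(tapply(oriented, grp, mean))
  } else {
    exp(as.numeric(tapply(log(oriented), grp, mean)))
  }
  agg$ratio <- means
  agg$n <- as.integer(tapply(oriented, grp, length))
  if (!cap_before_average) agg$ratio <- pmin(agg$ratio, ratio_cap)
  classify_peptides(agg)
}
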