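# Position-specific kinase preference model driving the simulator.

POSITIONS_14 <- c(-7:-1, 1:7)

#' Construct a kinase preference model
#'
#' The model assigns each candidate phosphoacceptor a probability of being a
#' substrate through an additive log-odds (logistic) model over its sequence
#' context: `P = logistic(baseline_logit + sum_p propensity[window[p], p])`
#' for positions -7..+7 excluding the center. Gap positions (windows at a
#' protein terminus) contribute zero.
#'
#' @param propensity Numeric matrix of log-odds weights, 20 rows named by
#'   [AA_ALPHABET_20] and 14 columns named `-7..-1, 1..7`. Defaults to all
#'   zeros.
#' @param baseline_logit Scalar intercept on the logit scale.
#' @param target_residues Residues the kinase can phosphorylate; non-empty
#'   subset of S, T, Y.
#' @return An object of class `kinase_model`.
#' @export
kinase_model <- function(propensity = NULL, baseline_logit = 0,
                         target_residues = c("S", "T")) {
  if (is.null(propensity)) {
    propensity <- matrix(0, nrow = 20L, ncol = 14L,
                         dimnames = list(AA_ALPHABET_20,
                                         as.character(POSITIONS_14)))
  }
  stopifnot(is.matrix(propensity),
            identical(rownames(propensity), AA_ALPHABET_20),
            identical(colnames(propensity), as.character(POSITIONS_14)),
            all(is.finite(propensity)),
            is.numeric(baseline_logit), length(baseline_logit) == 1L)
  target_residues <- match.arg(target_residues, c("S", "T", "Y"),
                               several.ok = TRUE)
  structure(list(propensity = propensity,
                 baseline_logit = baseline_logit,
                 target_residues = target_residues),
            class = "kinase_model")
}

#' Substrate probability of a sequence window
#'
#' Evaluates the logistic preference model on one or more 15-residue windows.
#' The window center must be one of the model's target residues.
#'
#' @param window Character vector of windows (length `2 * 7 + 1 = 15`, gap
#'   character allowed away from the center).
#' @param model A [kinase_model()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
phospho_probability <- function(window, model) {
  stopifnot(inherits(model, "kinase_model"))
  if (length(window) == 0L) return(numeric(0))
  if (any(nchar(window) != 15L)) stop("windows must have length 15")
  centers <- substr(window, 8L, 8L)
  if (!all(centers %in% model$target_residues)) {
    stop("window center must be one of: ",
         paste(model$target_residues, collapse = ", "))
  }
  mat <- matrix(unlist(strsplit(window, "", fixed = TRUE), use.names = FALSE),
                ncol = 15L, byrow = TRUE)
  score <- rep(model$baseline_logit, length(window))
  cols <- c(1:7, 9:15)
  for (j in seq_along(cols)) {
    ridx <- match(mat[, cols[j]], AA_ALPHABET_20)  # gap/'X' -> NA -> 0
    w <- model$propensity[, j][ridx]
    w[is.na(w)] <- 0
    score <- score + w
  }
  unname(stats::plogis(score))
}

#' Calibrate a kinase model to target motif frequencies
#'
#' Solves for the log-odds weights of a small set of positional determinants
#' so that, among substrates selected by the model from windows with i.i.d.
#' residues, each determinant residue occurs at its target marginal
#' frequency. With one determinant per position the indicator variables are
#' independent Bernoullis, so the selected-set marginals can be computed
#' exactly by enumerating the `2^k` indicator combinations; the weights are
#' found by quasi-Newton minimization of the squared frequency error.
#'
#' @param determinants `data.frame` with columns `position` (in -7..+7, not
#'   0, at most one determinant per position), `residue`, and `freq`
#'   (target frequency among selected substrates, in (0, 1)).
#' @param residue_frequencies Background residue distribution (named over
#'   [AA_ALPHABET_20], summing to 1); default [aa_frequencies()].
#' @param baseline_logit Intercept controlling the overall substrate rate
#'   (default -11; strong marginal targets over a proteome-like residue
#'   distribution are only exactly attainable at low baselines, and the
#'   calibration fails with an error when no exact solution exists at the
#'   requested baseline). The marginal system can have several exact
#'   solutions; the calibrator returns the one with the largest overall
#'   substrate rate.
#' @inheritParams kinase_model
#' @return A calibrated [kinase_model()].
#' @export
calibrate_kinase_model <- function(determinants,
                                   residue_frequencies = aa_frequencies(),
                                   baseline_logit = -11,
                                   target_residues = c("S", "T")) {
  stopifnot(is.data.frame(determinants),
            all(c("position", "residue", "freq") %in% names(determinants)),
            all(determinants$position %in% POSITIONS_14),
            !anyDuplicated(determinants$position),
            all(determinants$residue %in% AA_ALPHABET_20),
            all(determinants$freq > 0 & determinants$freq < 1))
  k <- nrow(determinants)
  q <- residue_frequencies[determinants$residue]
  target <- determinants$freq
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  prior <- apply(combos, 1L, function(x) prod(ifelse(x == 1, q, 1 - q)))

  marginals <- function(w) {
    p_sel <- stats::plogis(baseline_logit + drop(combos %*% w))
    joint <- prior * p_sel
    vapply(seq_len(k), function(i) {
      sum(joint[combos[, i] == 1]) / sum(joint)
    }, numeric(1))
  }
  obj <- function(w) sum((marginals(w) - target)^2)
  p_sel <- function(w) {
    sum(prior * stats::plogis(baseline_logit + drop(combos %*% w)))
  }
  # rare-selection (exponential) approximation, plus progressively scaled
  # starts: the marginal system can have several roots and we keep the one
  # with the largest overall substrate rate
  w0 <- log(target / (1 - target) * (1 - q) / q)
  starts <- lapply(c(1, 1.2, 1.4, 1.6, 1.8), function(s) w0 * s)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(suppressWarnings({
      f <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16))
      stats::optim(f$par, obj, control = list(maxit = 5000, reltol = 1e-16))
    }), error = function(e) NULL)
    if (is.null(fit) || fit$value > 1e-12) next
    if (is.null(best) || p_sel(fit$par) > p_sel(best$par)) best <- fit
  }
  if (is.null(best)) {
    stop("kinase model calibration did not converge to the target ",
         "frequencies; try a lower baseline_logit")
  }
  prop <- matrix(0, nrow = 20L, ncol = 14L,
                 dimnames = list(AA_ALPHABET_20, as.character(POSITIONS_14)))
  for (i in seq_len(k)) {
    prop[determinants$residue[i], as.character(determinants$position[i])] <-
      best$par[i]
  }
  kinase_model(prop, baseline_logit, target_residues)
}

#' Default kinase model used by the simulator
#'
#' A serine/threonine kinase with the acidophilic, N-terminally determined
#' specificity characteristic of polo-like kinase 2: glutamate at -3 in 75%
#' of substrates, leucine at -2 in 62.5%, and aspartate at -1 in 59%.
#'
#' @inheritParams calibrate_kinase_model
#' @return A calibrated [kinase_model()].
#' @export
default_kinase_model <- function(residue_frequencies = aa_frequencies(),
                                 baseline_logit = -11) {
  calibrate_kinase_model(
    data.frame(position = c(-3L, -2L, -1L),
               residue = c("E", "L", "D"),
               freq = c(0.75, 0.625, 0.59)),
    residue_frequencies = residue_frequencies,
    baseline_logit = baseline_logit)
}
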