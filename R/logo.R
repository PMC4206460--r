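# Two-sample logo statistics: per-position, per-residue enrichment of
# foreground phosphosite windows against proteome background windows.

# windows -> character matrix (n x width); validates equal width
window_matrix <- function(windows, width = 15L) {
  if (length(windows) == 0L) stop("no windows supplied")
  if (any(nchar(windows) != width)) {
    stop("all windows must have length ", width)
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

# per-position residue counts; returns list(K = positions x 20 counts,
# N = defined (non-gap, standard-residue) count per position)
logo_counts <- function(windows, positions = c(-7:-1, 1:7), half_width = 7L) {
  mat <- window_matrix(windows, 2L * half_width + 1L)
  cols <- positions + half_width + 1L
  K <- t(vapply(cols, function(j) {
    tabulate(match(mat[, j], AA_ALPHABET_20), nbins = 20L)
  }, integer(20L)))
  dimnames(K) <- list(as.character(positions), AA_ALPHABET_20)
  list(K = K, N = rowSums(K))
}

#' Residue frequency at a window position
#'
#' Fraction of windows carrying `residue` at `position`, among windows with a
#' defined (non-gap) residue there.
#'
#' @param windows Character vector of equal-length windows.
#' @param position Offset from the center (negative = N-terminal side); 0 is
#'   the phosphosite itself and is not a valid query.
#' @param residue One-letter residue code.
#' @return Fraction in `[0, 1]`; `NA` with a warning when no window has a
#'   defined residue at that position.
#' @export
residue_frequency <- function(windows, position, residue) {
  half_width <- (nchar(windows[1]) - 1L) %/% 2L
  stopifnot(position %in% c(-half_width:-1, 1:half_width),
            residue %in% AA_ALPHABET_20)
  cnt <- logo_counts(windows, positions = position, half_width = half_width)
  if (cnt$N == 0L) {
    warning("no defined residue at position ", position)
    return(NA_real_)
  }
  unname(cnt$K[1, residue] / cnt$N)
}

# Welch two-sample t-test on binary indicator vectors, from their sufficient
# statistics (match counts k and defined counts n). Zero variance in both
# samples carries no information: t = 0, p = 1.
welch_indicator_test <- function(k1, n1, k2, n2) {
  f1 <- k1 / n1
  f2 <- k2 / n2
  v1 <- f1 * (1 - f1) * n1 / (n1 - 1)  # sample variance of a 0/1 vector
  v2 <- f2 * (1 - f2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (f1 - f2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
  list(t = t, p = p, df = df, fg_freq = f1, bg_freq = f2)
}

#' Two-sample test of one (position, residue) pair
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on the binary
#' indicator vectors "window has `residue` at `position`" of the foreground
#' and background samples; gap positions are excluded from both samples. The
#' t statistic is positive when the foreground frequency exceeds the
#' background frequency.
#'
#' @param fg,bg Character vectors of foreground/background windows.
#' @inheritParams residue_frequency
#' @return List with `t`, `p`, `df`, `fg_freq`, `bg_freq`.
#' @export
position_residue_test <- function(fg, bg, position, residue) {
  half_width <- (nchar(fg[1]) - 1L) %/% 2L
  stopifnot(position %in% c(-half_width:-1, 1:half_width),
            residue %in% AA_ALPHABET_20)
  cf <- logo_counts(fg, positions = position, half_width = half_width)
  cb <- logo_counts(bg, positions = position, half_width = half_width)
  if (cf$N < 2L || cb$N < 2L) {
    stop("need at least 2 defined entries per sample at position ", position)
  }
  welch_indicator_test(unname(cf$K[1, residue]), unname(cf$N),
                       unname(cb$K[1, residue]), unname(cb$N))
}

#' Two-sample logo over all positions and residues
#'
#' Runs [position_residue_test()] for every position in -7..+7 (center
#' excluded: it is constrained to S/T in the foreground by construction) and
#' every standard residue, and flags significantly over- and
#' under-represented pairs.
#'
#' @param fg Foreground windows (S/T-centered phosphosite contexts).
#' @param bg Background windows (random S/T proteome contexts; see
#'   [extract_st_background()]).
#' @param alpha Significance level for flagging (default 0.05).
#' @param adjust Multiple-testing adjustment across the 14 x 20 tests:
#'   `"none"` (default, the classical two-sample-logo behavior) or
#'   `"bonferroni"`.
#' @param half_width Window half-width (default 7).
#' @return An object of class `two_sample_logo`: a `data.frame` with one row
#'   per (position, residue) — `position`, `residue`, `fg_freq`, `bg_freq`,
#'   `t`, `p`, `direction` (`"over"`, `"under"`, `"none"`) — with attributes
#'   `alpha`, `adjust`, `n_fg`/`n_bg` (defined counts per position).
#' @export
compute_logo <- function(fg, bg, alpha = 0.05, adjust = c("none", "bonferroni"),
                         half_width = 7L) {
  adjust <- match.arg(adjust)
  stopifnot(alpha >= 0, alpha <= 1)
  positions <- c(-half_width:-1, 1:half_width)
  cf <- logo_counts(fg, positions, half_width)
  cb <- logo_counts(bg, positions, half_width)
  res <- welch_indicator_test(cf$K, cf$N, cb$K, cb$N)
  out <- data.frame(
    position = rep(positions, times = 20L),
    residue = rep(AA_ALPHABET_20, each = length(positions)),
    fg_freq = as.vector(res$fg_freq),
    bg_freq = as.vector(res$bg_freq),
    t = as.vector(res$t),
    p = as.vector(res$p),
    stringsAsFactors = FALSE)
  p_crit <- if (adjust == "bonferroni") out$p * nrow(out) else out$p
  out$direction <- ifelse(p_crit < alpha & out$t > 0, "over",
                          ifelse(p_crit < alpha & out$t < 0, "under", "none"))
  out <- out[order(out$position, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, adjust = adjust,
            n_fg = cf$N, n_bg = cb$N, class = c("two_sample_logo", "data.frame"))
}

#' Text rendering of a two-sample logo
#'
#' Deterministic plain-text table of the over-represented (upper section) and
#' under-represented (lower section) residues per position, ordered by
#' decreasing absolute frequency difference.
#'
#' @param result A [compute_logo()] result.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_logo <- function(result) {
  stopifnot(inherits(result, "two_sample_logo"))
  section <- function(dir, label) {
    rows <- result[result$direction == dir, , drop = FALSE]
    rows <- rows[order(-abs(rows$fg_freq - rows$bg_freq),
                       rows$position, rows$residue), , drop = FALSE]
    lines <- sprintf("  %+d %s  fg %5.1f%%  bg %5.1f%%  t %7.2f  p %.3g",
                     rows$position, rows$residue, 100 * rows$fg_freq,
                     100 * rows$bg_freq, rows$t, rows$p)
    c(label, if (length(lines)) lines else "  (none)")
  }
  out <- c(section("over", "Over-represented:"),
           section("under", "Under-represented:"))
  cat(out, sep = "\n")
  invisible(out)
}

#' Plot a two-sample logo
#'
#' Upper panel: residues over-represented in the foreground; lower panel
#' (negative axis): under-represented residues. Letter height is the absolute
#' foreground-background frequency difference, letters stacked per position
#' by decreasing height.
#'
#' @param result A [compute_logo()] result.
#' @return A `ggplot` object.
#' @export
plot_logo <- function(result) {
  stopifnot(inherits(result, "two_sample_logo"))
  d <- result[result$direction != "none", , drop = FALSE]
  if (nrow(d) > 0L) {
    d$height <- abs(d$fg_freq - d$bg_freq)
    d$sign <- ifelse(d$direction == "over", 1, -1)
    d <- d[order(d$position, -d$height), , drop = FALSE]
    ymid <- unlist(lapply(split(seq_len(nrow(d)), paste(d$position, d$sign)),
                          function(idx) {
                            h <- d$height[idx]
                            (cumsum(h) - h / 2) * d$sign[idx]
                          }))
    d$y <- NA_real_
    d$y[unlist(split(seq_len(nrow(d)), paste(d$position, d$sign)))] <- ymid
    acidic <- c("D", "E")
    basic <- c("K", "R", "H")
    d$class <- ifelse(d$residue %in% acidic, "acidic",
                      ifelse(d$residue %in% basic, "basic", "other"))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = c(-7:-1, 1:7)) +
    ggplot2::labs(x = "position relative to phosphosite",
                  y = "frequency difference (fg - bg)",
                  title = "Two-sample logo") +
    ggplot2::theme_minimal()
  if (nrow(d) > 0L) {
    p <- p + ggplot2::geom_text(
      data = d,
      ggplot2::aes(x = .data$position, y = .data$y, label = .data$residue,
                   size = .data$height, colour = .data$class),
      fontface = "bold", show.legend = c(size = FALSE, colour = TRUE)) +
      ggplot2::scale_colour_manual(
        values = c(acidic = "#c0392b", basic = "#2980b9", other = "#2c3e50")) +
      ggplot2::scale_size_continuous(range = c(2, 8))
  }
  p
}
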