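# Shared constants and small helpers.

#' Amino-acid alphabet and gap character
#'
#' The 20 standard residues in alphabetical one-letter order, and the gap/pad
#' character used for sequence windows that run past a protein terminus. The
#' gap character never collides with an amino-acid letter.
#'
#' @format `AA_ALPHABET_20` is a character vector of length 20; `GAP_CHAR` is a
#'   single character, `"-"`.
#' @export
AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET_20
#' @export
GAP_CHAR <- "-"

#' Average human proteome residue frequencies
#'
#' Approximate amino-acid composition of the human proteome (SwissProt
#' averages, normalized to sum to one), used as the default residue
#' distribution of the synthetic proteome generator.
#'
#' @return Named numeric vector over [AA_ALPHABET_20], summing to 1.
#' @export
aa_frequencies <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.6, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 9.9, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  f <- f[AA_ALPHABET_20]
  f / sum(f)
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Merge groups (character vectors) that share any element; returns a list of
# disjoint components. Small-n iterative union; used for protein-group
# counting and phosphosite collapsing.
merge_groups <- function(groups) {
  groups <- lapply(groups, unique)
  out <- list()
  for (g in groups) {
    hit <- which(vapply(out, function(x) any(g %in% x), logical(1)))
    if (length(hit) == 0L) {
      out[[length(out) + 1L]] <- g
    } else {
      merged <- sort(unique(c(g, unlist(out[hit]))))
      out <- out[-hit]
      out[[length(out) + 1L]] <- merged
    }
  }
  out
}

# Locally set the RNG seed when non-NULL (functions stay deterministic under
# a caller-supplied seed but do not disturb an unseeded workflow otherwise).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  expr
}
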