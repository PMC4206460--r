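# Kinase consensus pattern parsing and matching.

#' Parse a compact consensus pattern
#'
#' The grammar mirrors the field's usual notation, e.g. `"s/t[DE]x[DE]"` for
#' the strict CK2 consensus: lowercase `s`/`t`/`y` (slash-separated for
#' alternatives) mark the phosphoacceptor center; each following token
#' constrains the next C-terminal offset (+1, +2, ...) and each preceding
#' token the N-terminal offsets; `[...]` is a residue set, an uppercase
#' letter a single required residue, and `x` a wildcard.
#'
#' @param pattern Pattern string.
#' @param name Pattern name (defaults to the pattern string).
#' @return An object of class `consensus_pattern`: `name`, `center_residues`,
#'   and `constraints` (named list, offset -> allowed residue set).
#' @export
parse_consensus <- function(pattern, name = pattern) {
  rx <- "\\[[A-Z]+\\]|[sty](?:/[sty])*|x|[A-Z]"
  tokens <- regmatches(pattern, gregexpr(rx, pattern, perl = TRUE))[[1]]
  if (paste(tokens, collapse = "") != pattern) {
    stop("cannot parse consensus pattern: ", pattern)
  }
  is_center <- grepl("^[sty](/[sty])*$", tokens)
  if (sum(is_center) != 1L) {
    stop("pattern must contain exactly one lowercase s/t/y center: ", pattern)
  }
  center_idx <- which(is_center)
  center <- toupper(strsplit(tokens[center_idx], "/", fixed = TRUE)[[1]])
  offsets <- seq_along(tokens) - center_idx
  constraints <- list()
  for (i in seq_along(tokens)) {
    if (i == center_idx || tokens[i] == "x") next
    set <- if (startsWith(tokens[i], "[")) {
      str_chars(substr(tokens[i], 2L, nchar(tokens[i]) - 1L))
    } else {
      tokens[i]
    }
    if (abs(offsets[i]) > 7L) stop("constraint offset outside -7..+7: ", pattern)
    constraints[[as.character(offsets[i])]] <- set
  }
  structure(list(name = name, center_residues = center,
                 constraints = constraints),
            class = "consensus_pattern")
}

#' The strict CK2 consensus pattern
#'
#' `s/t[DE]x[DE]`: an S/T phosphoacceptor followed by an acidic residue at +1
#' and +3.
#'
#' @return A [parse_consensus()] pattern named `"CK2"`.
#' @export
ck2_consensus <- function() parse_consensus("s/t[DE]x[DE]", name = "CK2")

#' Match a window against a consensus pattern
#'
#' `TRUE` iff the window center is one of the pattern's acceptor residues and
#' every constrained offset carries an allowed residue. A gap at a
#' constrained offset fails the (strict) match.
#'
#' @param window Character vector of 15-residue windows.
#' @param pattern A `consensus_pattern` (see [parse_consensus()]) or a
#'   pattern string.
#' @return Logical vector.
#' @export
match_motif <- function(window, pattern) {
  if (is.character(pattern)) pattern <- parse_consensus(pattern)
  stopifnot(inherits(pattern, "consensus_pattern"))
  if (length(window) == 0L) return(logical(0))
  if (any(nchar(window) != 15L)) stop("windows must have length 15")
  ok <- substr(window, 8L, 8L) %in% pattern$center_residues
  for (off in names(pattern$constraints)) {
    j <- 8L + as.integer(off)
    ok <- ok & substr(window, j, j) %in% pattern$constraints[[off]]
  }
  ok
}

#' Fraction of phosphosites matching a consensus
#'
#' @param sites Site `data.frame` (with a `window` column) or a character
#'   vector of windows.
#' @param pattern A `consensus_pattern` or pattern string.
#' @return List with `fraction`, `n_matched`, `n_total`, and `matched` (the
#'   matching subset of the input).
#' @export
fraction_matching <- function(sites, pattern) {
  windows <- if (is.data.frame(sites)) sites$window else sites
  if (length(windows) == 0L) stop("no sites to match")
  hit <- match_motif(windows, pattern)
  matched <- if (is.data.frame(sites)) sites[hit, , drop = FALSE] else windows[hit]
  list(fraction = mean(hit), n_matched = sum(hit), n_total = length(hit),
       matched = matched)
}
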