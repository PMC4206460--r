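# In-silico tryptic digestion and background window extraction.

#' Tryptic digestion of a single protein
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the following
#' residue is proline (P), the standard trypsin rule. Peptides with up to
#' `max_missed` uncut internal cleavage sites are enumerated. Termini are not
#' cleavage sites and the initiator methionine is kept as given.
#'
#' @param sequence Protein sequence (single uppercase string).
#' @param max_missed Maximum number of missed cleavages (default 2, the usual
#'   database-search setting).
#' @param accession Optional accession carried into the output.
#' @return `data.frame` with columns `accession` (if given), `start` (1-based
#'   position in the parent), `peptide`, `missed_cleavages`, sorted by
#'   (`start`, peptide length).
#' @export
digest_protein <- function(sequence, max_missed = 2L, accession = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) stop("empty protein sequence")
  if (max_missed < 0) stop("max_missed must be >= 0")
  chars <- str_chars(sequence)
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  sites <- sites[chars[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  starts <- integer(0); ends <- integer(0); mcs <- integer(0)
  for (k in 0:max_missed) {
    last <- nb - 1L - k
    if (last < 1L) break
    i <- seq_len(last)
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + 1L + k])
    mcs <- c(mcs, rep.int(k, last))
  }
  pep <- substring(sequence, starts, ends)
  out <- data.frame(start = starts, peptide = pep,
                    missed_cleavages = mcs, stringsAsFactors = FALSE)
  if (!is.null(accession)) out <- cbind(accession = accession, out)
  out[order(out$start, nchar(out$peptide)), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Tryptic digestion of a whole database
#'
#' @param database `data.frame` with columns `accession`, `sequence` (see
#'   [read_fasta()]).
#' @inheritParams digest_protein
#' @return Row-bound [digest_protein()] results with an `accession` column.
#' @export
digest_proteome <- function(database, max_missed = 2L) {
  check_database(database)
  res <- mapply(function(s, a) digest_protein(s, max_missed, accession = a),
                database$sequence, database$accession,
                SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract a sequence window around a position
#'
#' Returns the `2 * half_width + 1` residue context centered on `position`,
#' padded with the gap character where the window runs past a terminus.
#'
#' @param sequence Protein sequence.
#' @param position 1-based center position.
#' @param half_width Number of residues on each side (default 7).
#' @return Window string of length `2 * half_width + 1`.
#' @export
extract_window <- function(sequence, position, half_width = 7L) {
  n <- nchar(sequence)
  if (any(position < 1L | position > n)) {
    stop("position out of range 1..", n)
  }
  vapply(position, function(p) {
    idx <- (p - half_width):(p + half_width)
    ch <- rep(GAP_CHAR, length(idx))
    ok <- idx >= 1L & idx <= n
    ch[ok] <- substring(sequence, idx[ok], idx[ok])
    paste(ch, collapse = "")
  }, character(1))
}

#' Random S/T-centered background windows from a proteome
#'
#' Samples positions of the given center residues uniformly (with replacement)
#' across the pooled eligible positions of the database and returns their
#' sequence windows. Used as the background sample of the two-sample logo.
#'
#' @param database Protein database `data.frame`.
#' @param n_windows Number of windows to draw.
#' @param half_width Window half-width (default 7).
#' @param seed Optional RNG seed; sampling is bit-reproducible for a fixed
#'   seed.
#' @param residues Eligible center residues (default S and T).
#' @param dedupe If `TRUE`, identical windows are collapsed to one after
#'   sampling (default `FALSE`).
#' @return Character vector of windows (length `n_windows`, or fewer when
#'   `dedupe = TRUE`).
#' @export
extract_st_background <- function(database, n_windows, half_width = 7L,
                                  seed = NULL, residues = c("S", "T"),
                                  dedupe = FALSE) {
  check_database(database)
  stopifnot(half_width >= 1L, n_windows >= 0L)
  pos_list <- lapply(seq_len(nrow(database)), function(i) {
    ch <- str_chars(database$sequence[i])
    which(ch %in% residues)
  })
  n_per <- lengths(pos_list)
  total <- sum(n_per)
  if (total == 0L) {
    stop("database contains no ", paste(residues, collapse = "/"), " residues")
  }
  if (n_windows == 0L) return(character(0))
  prot_idx <- rep.int(seq_len(nrow(database)), n_per)
  site_pos <- unlist(pos_list, use.names = FALSE)
  pick <- with_seed(seed, sample.int(total, n_windows, replace = TRUE))
  win <- vapply(pick, function(k) {
    extract_window(database$sequence[prot_idx[k]], site_pos[k], half_width)
  }, character(1))
  if (dedupe) win <- unique(win)
  win
}
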