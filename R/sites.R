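# Mapping selected phosphopeptides to protein coordinates, collapsing to
# unique phosphosites, and counting sites/protein groups.

#' Locate a peptide in a protein database
#'
#' All exact substring matches of each peptide across the database (multiple
#' matches within one protein are all reported).
#'
#' @param peptide Character vector of peptide sequences.
#' @param database Protein database `data.frame`.
#' @return `data.frame` with columns `peptide`, `accession`, `start`
#'   (1-based); zero rows for peptides absent from the database.
#' @export
locate_peptide <- function(peptide, database) {
  check_database(database)
  res <- lapply(unique(peptide), function(pep) {
    hits <- lapply(seq_len(nrow(database)), function(i) {
      m <- gregexpr(pep, database$sequence[i], fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      data.frame(peptide = pep, accession = database$accession[i],
                 start = as.integer(m), stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), accession = character(0),
                      start = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Collapse selected phosphopeptides to unique phosphosites
#'
#' Maps each selected phosphopeptide to protein coordinates and merges all
#' peptides supporting the same protein position — in particular
#' missed-cleavage variants of the same site — into one phosphosite record.
#' A peptide carrying k phospho positions contributes k sites. Peptides
#' matching several proteins yield one site with a grouped accession; records
#' sharing any (accession, position) pair are merged. Sites whose windows
#' disagree across group members (non-homologous multi-matches) are flagged
#' `ambiguous`.
#'
#' Peptides with no database match are excluded with a warning and reported
#' in the `"excluded"` attribute of the result.
#'
#' @param selected Selected peptide-quantification rows (see
#'   [select_dependent()]).
#' @param database Protein database `data.frame`.
#' @param half_width Window half-width (default 7).
#' @return `data.frame`, one row per unique phosphosite: `accession`
#'   (';'-joined sorted group), `position` (position in the first group
#'   member), `loci` (all `accession:position` pairs, ';'-joined), `residue`,
#'   `window`, `peptides` (';'-joined supporting peptide sequences),
#'   `n_peptides`, `class` (1 if any supporting peptide is class 1),
#'   `max_ratio` (largest per-experiment mean over supporting peptides), and
#'   `ambiguous`. Attributes: `excluded` (unlocatable peptide sequences).
#' @export
collapse_sites <- function(selected, database, half_width = 7L) {
  check_database(database)
  cols <- c("peptide", "phospho_positions_in_peptide", "class")
  stopifnot(all(cols %in% names(selected)))
  if (nrow(selected) == 0L) {
    out <- empty_site_table()
    attr(out, "excluded") <- character(0)
    return(out)
  }
  seq_of <- stats::setNames(database$sequence, database$accession)
  loc <- locate_peptide(unique(selected$peptide), database)
  excluded <- setdiff(unique(selected$peptide), unique(loc$peptide))
  if (length(excluded)) {
    warning(length(excluded), " selected peptide(s) not found in the database",
            " and excluded from site mapping")
  }

  # one "instance" per (selected analyte, phospho position): the set of
  # protein loci that peptide places the site at
  inst <- list()
  for (i in seq_len(nrow(selected))) {
    pep <- selected$peptide[i]
    hits <- loc[loc$peptide == pep, , drop = FALSE]
    if (nrow(hits) == 0L) next
    for (ppos in parse_positions(selected$phospho_positions_in_peptide[i])[[1]]) {
      prot_pos <- hits$start + ppos - 1L
      inst[[length(inst) + 1L]] <- data.frame(
        accession = hits$accession, position = prot_pos,
        residue = substr(pep, ppos, ppos),
        window = vapply(seq_len(nrow(hits)), function(h) {
          extract_window(seq_of[[hits$accession[h]]], prot_pos[h], half_width)
        }, character(1)),
        peptide = pep,
        class = selected$class[i],
        ratio = if (all(c("ratio_forward", "ratio_reverse") %in% names(selected))) {
          max(c(selected$ratio_forward[i], selected$ratio_reverse[i]), na.rm = TRUE)
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(inst) == 0L) {
    out <- empty_site_table()
    attr(out, "excluded") <- excluded
    return(out)
  }

  # merge instances sharing any accession:position atom
  atom_groups <- lapply(inst, function(d) paste(d$accession, d$position, sep = ":"))
  comps <- merge_groups(atom_groups)
  comp_of <- integer(length(inst))
  for (ci in seq_along(comps)) {
    member <- vapply(atom_groups, function(a) any(a %in% comps[[ci]]), logical(1))
    comp_of[member] <- ci
  }
  sites <- do.call(rbind, lapply(seq_along(comps), function(ci) {
    d <- do.call(rbind, inst[comp_of == ci])
    atoms <- unique(d[, c("accession", "position", "residue", "window")])
    atoms <- atoms[order(atoms$accession, atoms$position), , drop = FALSE]
    peps <- sort(unique(d$peptide))
    data.frame(
      accession = paste(atoms$accession, collapse = ";"),
      position = atoms$position[1],
      loci = paste(paste(atoms$accession, atoms$position, sep = ":"),
                   collapse = ";"),
      residue = atoms$residue[1],
      window = atoms$window[1],
      peptides = paste(peps, collapse = ";"),
      n_peptides = length(peps),
      class = min(d$class),
      max_ratio = max(d$ratio),
      ambiguous = length(unique(atoms$window)) > 1L,
      stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "excluded") <- excluded
  sites
}

empty_site_table <- function() {
  data.frame(accession = character(0), position = integer(0),
             loci = character(0), residue = character(0), window = character(0),
             peptides = character(0), n_peptides = integer(0),
             class = integer(0), max_ratio = numeric(0), ambiguous = logical(0))
}

#' Count unique phosphosites and protein groups
#'
#' Protein groups are counted after merging accession groups that share any
#' member, so a protein listed in several grouped rows is counted once.
#'
#' @param sites Site `data.frame` from [collapse_sites()].
#' @return List with `n_unique_sites`, `n_protein_groups` (shared-accession
#'   merge) and `n_accessions` (distinct individual accessions).
#' @export
summarize_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(n_unique_sites = 0L, n_protein_groups = 0L, n_accessions = 0L))
  }
  groups <- strsplit(sites$accession, ";", fixed = TRUE)
  list(n_unique_sites = nrow(sites),
       n_protein_groups = length(merge_groups(groups)),
       n_accessions = length(unique(unlist(groups))))
}

#' Write the phosphosite table
#'
#' @param sites Site `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Windows eligible for motif statistics
#'
#' Filters a phosphosite table down to the sequence windows used by the
#' two-sample logo and consensus statistics: unambiguous sites centered on
#' the given residues, with no undefined ('X') residues in the window.
#'
#' @param sites Site `data.frame` from [collapse_sites()].
#' @param include_ambiguous Keep multi-locus sites with discordant windows
#'   (default `FALSE`).
#' @param centers Allowed center residues (default S and T).
#' @return Character vector of windows.
#' @export
motif_windows <- function(sites, include_ambiguous = FALSE,
                          centers = c("S", "T")) {
  keep <- sites$residue %in% centers & !grepl("X", sites$window, fixed = TRUE)
  if (!include_ambiguous) keep <- keep & !sites$ambiguous
  sites$window[keep]
}
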