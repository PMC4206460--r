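# Cross-reference identified phosphosites against a curated phosphosite
# annotation table (PhosphositePlus-style export).

#' Load a phosphosite annotation table
#'
#' Tab-separated with header; required columns `accession`, `residue`,
#' `position`, `kinases`. One row is one annotation record. Grouped records
#' are allowed: `accession` may be a ';'-joined group with matching
#' '/'-joined `position`s (a single position applies to every member).
#' `kinases` lists '/'-separated upstream kinases; `"No"` or an empty field
#' means none are known (an "orphan" site).
#'
#' @param path Annotation TSV path.
#' @return `data.frame`, one row per record, with list-columns `accessions`
#'   and `positions` (the expanded group members) and `kinase_list` (possibly
#'   empty character vector) alongside the raw columns.
#' @export
load_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("accession", "residue", "position", "kinases")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  }
  accs <- strsplit(tab$accession, ";", fixed = TRUE)
  pos_chr <- strsplit(tab$position, "/", fixed = TRUE)
  pos <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- suppressWarnings(as.integer(pos_chr[[i]]))
    if (any(is.na(p)) || any(p < 1L)) {
      stop("malformed position '", tab$position[i], "' on line ", i + 1L)
    }
    if (length(p) == 1L) p <- rep.int(p, length(accs[[i]]))
    if (length(p) != length(accs[[i]])) {
      stop("accession/position count mismatch on line ", i + 1L)
    }
    pos[[i]] <- p
  }
  pairs <- data.frame(accession = as.character(unlist(accs)),
                      position = as.integer(unlist(pos)),
                      record = rep.int(seq_len(nrow(tab)), lengths(accs)),
                      stringsAsFactors = FALSE)
  dup <- duplicated(pairs[, c("accession", "position")]) |
    duplicated(pairs[, c("accession", "position")], fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate (accession, position) annotations: ",
         paste(unique(paste0(pairs$accession[dup], ":", pairs$position[dup])),
               collapse = ", "))
  }
  if (any(!tab$residue %in% c("S", "T", "Y"))) {
    stop("annotation residues must be S, T or Y")
  }
  tab$accessions <- I(accs)
  tab$positions <- I(pos)
  tab$kinase_list <- I(lapply(tab$kinases, function(k) {
    if (!nzchar(k) || identical(k, "No")) character(0)
    else strsplit(k, "/", fixed = TRUE)[[1]]
  }))
  tab
}

#' Cross-reference phosphosites against annotations
#'
#' A site is annotated iff any of its (accession, position) loci appears in
#' the annotation table with a matching residue letter; a coordinate match
#' with a different residue is treated as unannotated with a warning.
#' Annotated sites with no known upstream kinase are "orphan".
#'
#' @param sites Site `data.frame` from [collapse_sites()], or any
#'   `data.frame` with columns `accession` (';'-joined group allowed),
#'   `position` (aligned, ';'- or '/'-joined allowed; a single position
#'   applies to all group members) and `residue`. A `loci` column
#'   (`"acc:pos;acc:pos"`) takes precedence when present.
#' @param annotations Annotation table from [load_annotations()].
#' @return An object of class `xref_report`: `sites` (input plus `annotated`,
#'   `orphan`, `kinases` columns), `n_total`, `n_annotated`, `n_unannotated`,
#'   `n_orphan`, `fraction_annotated`, `fraction_orphan_of_annotated`.
#' @export
crossref <- function(sites, annotations) {
  stopifnot(is.data.frame(sites), is.data.frame(annotations))
  ann_pairs <- data.frame(
    accession = unlist(annotations$accessions),
    position = unlist(annotations$positions),
    residue = rep.int(annotations$residue, lengths(annotations$accessions)),
    record = rep.int(seq_len(nrow(annotations)),
                     lengths(annotations$accessions)),
    stringsAsFactors = FALSE)
  loci <- site_loci(sites)
  n <- nrow(sites)
  annotated <- logical(n)
  kin <- character(n)
  for (i in seq_len(n)) {
    li <- loci[[i]]
    hit <- match(paste(li$accession, li$position),
                 paste(ann_pairs$accession, ann_pairs$position))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) next
    res_ok <- ann_pairs$residue[hit] == sites$residue[i]
    if (any(!res_ok)) {
      warning("residue mismatch at ", ann_pairs$accession[hit[!res_ok]][1],
              ":", ann_pairs$position[hit[!res_ok]][1],
              " (site ", sites$residue[i], ", annotation ",
              ann_pairs$residue[hit[!res_ok]][1], ")")
    }
    hit <- hit[res_ok]
    if (length(hit) == 0L) next
    annotated[i] <- TRUE
    kl <- unique(unlist(annotations$kinase_list[ann_pairs$record[hit]]))
    kin[i] <- paste(kl, collapse = ";")
  }
  out <- sites
  out$annotated <- annotated
  out$orphan <- annotated & !nzchar(kin)
  out$kinases <- kin
  n_ann <- sum(annotated)
  structure(list(sites = out,
                 n_total = n,
                 n_annotated = n_ann,
                 n_unannotated = n - n_ann,
                 n_orphan = sum(out$orphan),
                 fraction_annotated = if (n > 0) n_ann / n else NA_real_,
                 fraction_orphan_of_annotated =
                   if (n_ann > 0) sum(out$orphan) / n_ann else NA_real_),
            class = "xref_report")
}

# per-site list of data.frame(accession, position)
site_loci <- function(sites) {
  if ("loci" %in% names(sites)) {
    return(lapply(strsplit(sites$loci, ";", fixed = TRUE), function(v) {
      parts <- strsplit(v, ":", fixed = TRUE)
      data.frame(accession = vapply(parts, `[`, character(1), 1L),
                 position = as.integer(vapply(parts, `[`, character(1), 2L)),
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("accession", "position") %in% names(sites)))
  lapply(seq_len(nrow(sites)), function(i) {
    a <- strsplit(as.character(sites$accession[i]), ";", fixed = TRUE)[[1]]
    p <- as.integer(strsplit(gsub("/", ";", as.character(sites$position[i]),
                                  fixed = TRUE), ";", fixed = TRUE)[[1]])
    if (length(p) == 1L) p <- rep.int(p, length(a))
    stopifnot(length(a) == length(p))
    data.frame(accession = a, position = p, stringsAsFactors = FALSE)
  })
}

#' @export
print.xref_report <- function(x, ...) {
  cat("Phosphosite annotation cross-reference\n")
  cat(sprintf("  sites: %d, annotated: %d (%.1f%%), orphan among annotated: %d (%.1f%%)\n",
              x$n_total, x$n_annotated, 100 * x$fraction_annotated,
              x$n_orphan, 100 * x$fraction_orphan_of_annotated))
  invisible(x)
}
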