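# End-to-end orchestration: simulation bundles and the full analysis run.

#' Pipeline configuration
#'
#' Defaults hold the analysis constants: q-value threshold 0.05 (strict),
#' treated/control ratio cap 100, significance threshold ratio 2 (fixed
#' mode), +/-7 sequence windows.
#'
#' @param psm_paths One or more PSM TSV paths.
#' @param fasta_path Protein database FASTA path.
#' @param annotation_path Optional phosphosite annotation TSV.
#' @param truth_path Optional ground-truth TSV (synthetic runs); enables the
#'   precision/recall evaluation block of the summary.
#' @param q_threshold,ratio_cap,cap_before_average,mean_type See
#'   [quantify_peptides()].
#' @param threshold_mode,fixed_ratio See [calibrate_threshold()].
#' @param class1_rule See [select_dependent()].
#' @param half_width Window half-width (default 7).
#' @param background_n Background window sample size for the logo (default
#'   10000).
#' @param alpha Logo significance level.
#' @param adjust Logo multiple-testing adjustment (`"none"`/`"bonferroni"`).
#' @param consensus_patterns Named character vector of consensus pattern
#'   strings (default the strict CK2 consensus).
#' @param seed RNG seed (background sampling).
#' @param out_dir Output directory; created if needed. `NULL` = no files
#'   written.
#' @param write_figure Also write the logo figure as SVG (default `FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_paths, fasta_path, annotation_path = NULL,
                            truth_path = NULL,
                            q_threshold = 0.05, ratio_cap = 100,
                            cap_before_average = TRUE,
                            mean_type = "arithmetic",
                            threshold_mode = "fixed", fixed_ratio = 2,
                            class1_rule = "both",
                            half_width = 7L, background_n = 10000L,
                            alpha = 0.05, adjust = "none",
                            consensus_patterns = c(CK2 = "s/t[DE]x[DE]"),
                            seed = 1L, out_dir = NULL, write_figure = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

# stable md5 hash of the configuration (written into every output)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Quantification (q-filter, orientation, capping, replicate averaging,
#' class 1/2) -> threshold calibration and selection -> site mapping and
#' collapsing -> two-sample logo vs a random S/T proteome background ->
#' consensus matching -> annotation cross-reference (when an annotation table
#' is configured) -> evaluation against ground truth (when available).
#' Fully deterministic for a fixed config; any stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @return List with the stage objects (`quants`, `threshold`, `selected`,
#'   `sites`, `site_summary`, `logo`, `consensus`, `xref`, `evaluation`) and
#'   `summary` (the JSON-ready run summary). When `config$out_dir` is set,
#'   writes `sites.tsv`, `logo.tsv`, `threshold.json`, `xref.json`,
#'   `summary.json` (and `logo.svg` if requested) there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)

  psms <- run_stage("load", read_psm_table(config$psm_paths))
  database <- run_stage("load", read_fasta(config$fasta_path))
  annotations <- if (!is.null(config$annotation_path)) {
    run_stage("load", load_annotations(config$annotation_path))
  }

  quants <- run_stage("quant", quantify_peptides(
    psms, q_threshold = config$q_threshold, ratio_cap = config$ratio_cap,
    cap_before_average = config$cap_before_average,
    mean_type = config$mean_type))
  threshold <- run_stage("threshold", calibrate_threshold(
    quants, mode = config$threshold_mode, fixed_ratio = config$fixed_ratio))
  selected <- run_stage("threshold", select_dependent(
    quants, threshold, rule = config$class1_rule))
  sites <- run_stage("sites", collapse_sites(selected, database,
                                             half_width = config$half_width))
  site_summary <- summarize_sites(sites)

  logo <- NULL
  consensus <- NULL
  fg <- motif_windows(sites)
  if (length(fg) >= 2L) {
    bg <- run_stage("background", extract_st_background(
      database, config$background_n, half_width = config$half_width,
      seed = config$seed))
    logo <- run_stage("logo", compute_logo(fg, bg, alpha = config$alpha,
                                           adjust = config$adjust,
                                           half_width = config$half_width))
    consensus <- run_stage("consensus", lapply(
      stats::setNames(nm = names(config$consensus_patterns)), function(nm) {
        fm <- fraction_matching(sites, parse_consensus(
          config$consensus_patterns[[nm]], name = nm))
        fm$matched <- NULL
        fm
      }))
  }

  xref <- if (!is.null(annotations) && nrow(sites) > 0L) {
    run_stage("xref", crossref(sites, annotations))
  }
  evaluation <- if (!is.null(config$truth_path) && file.exists(config$truth_path)) {
    truth <- utils::read.delim(config$truth_path, stringsAsFactors = FALSE)
    run_stage("evaluate", evaluate_selection(sites, truth))
  }

  over <- NULL
  if (!is.null(logo)) {
    over <- logo[logo$direction == "over", c("position", "residue", "fg_freq",
                                             "bg_freq", "p")]
    over <- over[order(-abs(over$fg_freq - over$bg_freq)), , drop = FALSE]
    rownames(over) <- NULL
  }
  summary <- list(
    config_hash = hash,
    n_psms = nrow(psms),
    n_peptides_quantified = nrow(quants),
    n_phosphopeptides = sum(quants$is_phospho),
    n_selected_peptides = nrow(selected),
    threshold_ratio = threshold$threshold,
    max_nonphospho_log2 = threshold$max_nonphospho_log2,
    n_sites = site_summary$n_unique_sites,
    n_protein_groups = site_summary$n_protein_groups,
    n_accessions = site_summary$n_accessions,
    over_represented = over,
    consensus = lapply(consensus, function(x) {
      x[c("fraction", "n_matched", "n_total")]
    }),
    xref = if (!is.null(xref)) {
      xref[c("n_total", "n_annotated", "n_orphan", "fraction_annotated",
             "fraction_orphan_of_annotated")]
    },
    evaluation = evaluation)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_site_table(sites, out("sites.tsv"))
    if (!is.null(logo)) {
      utils::write.table(cbind(as.data.frame(logo), config_hash = hash),
                         out("logo.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (isTRUE(config$write_figure)) {
        grDevices::svg(out("logo.svg"), width = 8, height = 5)
        print(plot_logo(logo))
        grDevices::dev.off()
      }
    }
    jsonlite::write_json(
      c(list(config_hash = hash),
        threshold[c("mode", "threshold", "max_nonphospho_log2",
                    "n_nonphospho", "n_phospho_above", "n_phospho_below")]),
      out("threshold.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(xref)) {
      jsonlite::write_json(
        c(list(config_hash = hash),
          xref[c("n_total", "n_annotated", "n_orphan", "fraction_annotated",
                 "fraction_orphan_of_annotated")]),
        out("xref.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null",
                         dataframe = "rows")
  }

  invisible(list(quants = quants, threshold = threshold, selected = selected,
                 sites = sites, site_summary = site_summary, logo = logo,
                 consensus = consensus, xref = xref, evaluation = evaluation,
                 summary = summary))
}

#' Generate and write a synthetic experiment bundle
#'
#' Wraps [generate_random_proteome()] and [simulate_experiment()] and writes
#' the generated FASTA, the combined forward/reverse PSM table, and the
#' ground-truth site table.
#'
#' @param config A [simulation_config()].
#' @param model A [kinase_model()]; default [default_kinase_model()].
#' @param out_dir Output directory (created if needed).
#' @param database Optional pre-built protein database; generated from
#'   `config` when `NULL`.
#' @return List with the simulation objects plus `paths` (named: `fasta`,
#'   `psms`, `truth`).
#' @export
run_simulation <- function(config, model = default_kinase_model(),
                           out_dir = NULL, database = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(database)) database <- generate_random_proteome(config)
  sim <- simulate_experiment(database, model, config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(out_dir, "database.fasta"),
               psms = file.path(out_dir, "psms.tsv"),
               truth = file.path(out_dir, "ground_truth.tsv"))
    write_fasta(database, paths[["fasta"]])
    write_psm_table(rbind(sim$forward, sim$reverse), paths[["psms"]])
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  c(sim, list(database = database, paths = paths))
}

#' Evaluate selected sites against simulation ground truth
#'
#' A selected site is a true positive when any of its (accession, position)
#' loci is a kinase-dependent ground-truth site.
#'
#' @param sites Site `data.frame` from [collapse_sites()].
#' @param truth Ground-truth `data.frame` (columns `accession`, `position`,
#'   `kinase_dependent`).
#' @return List with `n_selected`, `n_dependent_truth`, `n_true_positive`,
#'   `precision`, `recall`.
#' @export
evaluate_selection <- function(sites, truth) {
  dep <- truth[truth$kinase_dependent, , drop = FALSE]
  dep_keys <- paste(dep$accession, dep$position)
  site_keys <- lapply(site_loci(sites),
                      function(l) paste(l$accession, l$position))
  tp <- vapply(site_keys, function(k) any(k %in% dep_keys), logical(1))
  matched_truth <- unique(unlist(site_keys[tp]))
  matched_truth <- matched_truth[matched_truth %in% dep_keys]
  list(n_selected = nrow(sites),
       n_dependent_truth = nrow(dep),
       n_true_positive = sum(tp),
       precision = if (nrow(sites) > 0) sum(tp) / nrow(sites) else NA_real_,
       recall = if (nrow(dep) > 0) length(matched_truth) / nrow(dep)
                else NA_real_)
}
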