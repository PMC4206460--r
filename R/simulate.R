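# Synthetic forward/reverse label-swap experiments with ground truth.

# Dimethyl label mass shifts (Da), carried as metadata only.
LIGHT_LABEL_DA <- 28.0313
MEDIUM_LABEL_DA <- 32.0564

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment generator. Defaults
#' describe a mid-sized in-vitro kinase assay on a dephosphorylated tryptic
#' peptide library: 3 technical replicates per label-swap experiment, a small
#' residual (incomplete-dephosphorylation) background phosphorylation rate,
#' non-phosphopeptide contaminants surviving enrichment with true ratio 1,
#' multiplicative log-normal ratio noise, and per-replicate dropout.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length_range Integer pair, inclusive range of protein
#'   lengths.
#' @param residue_frequencies Residue distribution (named 20-vector summing
#'   to 1).
#' @param background_phospho_rate Probability that a non-substrate S/T site
#'   carries residual phosphorylation (true ratio 1).
#' @param nonphospho_contaminant_count Number of contaminant
#'   non-phosphopeptides.
#' @param ratio_noise_sigma SD of the per-replicate multiplicative noise on
#'   the log2 ratio scale.
#' @param replicate_dropout Probability that an analyte is missing from a
#'   given replicate.
#' @param n_replicates Technical replicates per experiment (default 3).
#' @param q_value_range Interval q-values are drawn from.
#' @param q_above_fraction Fraction of PSMs drawn with q-value above 0.05, to
#'   exercise confidence filtering.
#' @param max_missed Missed cleavages in the in-silico digest (default 2).
#' @param min_peptide_length Shortest observable peptide (default 6).
#' @param missed_cleavage_detect_rate Probability that each missed-cleavage
#'   variant of a phosphopeptide is observed in addition to its fully cleaved
#'   form.
#' @param dependent_log2_mean,dependent_log2_sd,dependent_log2_min True
#'   treated/control log2 ratios of kinase-dependent peptides are drawn from
#'   Normal(mean, sd) truncated below at `dependent_log2_min`, so that
#'   observed capped ratios concentrate at the reporting cap.
#' @param seed RNG seed for the whole simulation.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_proteins = 200L,
                              protein_length_range = c(300L, 1200L),
                              residue_frequencies = aa_frequencies(),
                              background_phospho_rate = 0.01,
                              nonphospho_contaminant_count = 300L,
                              ratio_noise_sigma = 0.3,
                              replicate_dropout = 0.2,
                              n_replicates = 3L,
                              q_value_range = c(0, 0.2),
                              q_above_fraction = 0.05,
                              max_missed = 2L,
                              min_peptide_length = 6L,
                              missed_cleavage_detect_rate = 0.3,
                              dependent_log2_mean = 6.6,
                              dependent_log2_sd = 1,
                              dependent_log2_min = 2,
                              seed = NULL) {
  stopifnot(length(protein_length_range) == 2L,
            protein_length_range[1] >= 15L,
            protein_length_range[1] <= protein_length_range[2],
            length(residue_frequencies) == 20L,
            background_phospho_rate >= 0, background_phospho_rate <= 1,
            nonphospho_contaminant_count >= 0L,
            ratio_noise_sigma >= 0,
            replicate_dropout >= 0, replicate_dropout < 1,
            n_replicates >= 1L,
            length(q_value_range) == 2L, q_value_range[1] >= 0,
            q_value_range[2] <= 1, q_value_range[1] <= q_value_range[2],
            q_above_fraction >= 0, q_above_fraction <= 1,
            min_peptide_length >= 1L,
            missed_cleavage_detect_rate >= 0, missed_cleavage_detect_rate <= 1,
            dependent_log2_sd >= 0)
  if (!is.null(names(residue_frequencies))) {
    residue_frequencies <- residue_frequencies[AA_ALPHABET_20]
  } else {
    names(residue_frequencies) <- AA_ALPHABET_20
  }
  if (abs(sum(residue_frequencies) - 1) > 1e-9) {
    stop("residue_frequencies must sum to 1")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a random protein database
#'
#' Sequences are i.i.d. draws from the configured residue distribution;
#' lengths are uniform over `protein_length_range`. Deterministic under the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return Protein database `data.frame` (columns `accession`, `sequence`),
#'   accessions `SYN0001`...
#' @export
generate_random_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_proteins < 1L) stop("n_proteins must be >= 1")
  with_seed(config$seed, {
    lens <- sample(seq(config$protein_length_range[1],
                       config$protein_length_range[2]),
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(AA_ALPHABET_20, n, replace = TRUE,
                   prob = config$residue_frequencies), collapse = "")
    }, character(1))
  })
  data.frame(accession = sprintf("SYN%04d", seq_len(config$n_proteins)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# Truncated-normal draw (lower truncation) via inverse-CDF.
rnorm_trunc_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# Draw q-values: a configurable fraction falls above the 0.05 confidence
# threshold, the rest below it, both uniform within the allowed range.
draw_q_values <- function(n, config) {
  lo <- config$q_value_range[1]
  hi <- config$q_value_range[2]
  above <- stats::runif(n) < config$q_above_fraction
  q <- numeric(n)
  q[!above] <- stats::runif(sum(!above), lo, min(hi, 0.05))
  q[above] <- stats::runif(sum(above), min(max(lo, 0.05), hi), hi)
  q
}

#' Simulate a forward/reverse kinase assay experiment
#'
#' Digests the database, draws kinase-dependent phosphosites from the
#' preference model and residual background phosphosites at the configured
#' rate, assigns true treated/control ratios (large, cap-concentrated for
#' kinase-dependent peptides; 1 for background sites and contaminants), and
#' emits per-replicate PSM rows for a forward experiment (treated sample
#' light-labeled, so the reported light/medium ratio equals treated/control)
#' and a reverse experiment (labels swapped, reported ratio is its
#' reciprocal). Noise is multiplicative log-normal per replicate; analytes
#' drop out of individual replicates at the configured rate.
#'
#' @param database Protein database `data.frame`; see
#'   [generate_random_proteome()].
#' @param model A [kinase_model()].
#' @param config A [simulation_config()].
#' @return List with elements `forward` and `reverse` (PSM `data.frame`s in
#'   the dialect read by [read_psm_table()]), `truth` (one row per emitted
#'   phosphosite: `accession`, `position`, `residue`, `window`,
#'   `kinase_dependent`, `true_log2_ratio`), and `analytes` (peptide-level
#'   ground truth).
#' @export
simulate_experiment <- function(database, model, config) {
  check_database(database)
  stopifnot(inherits(model, "kinase_model"),
            inherits(config, "simulation_config"))
  with_seed(config$seed, {
    peptides <- digest_proteome(database, config$max_missed)
    peptides <- peptides[nchar(peptides$peptide) >= config$min_peptide_length, ]

    # candidate phosphoacceptor sites
    sites <- do.call(rbind, lapply(seq_len(nrow(database)), function(i) {
      ch <- str_chars(database$sequence[i])
      pos <- which(ch %in% model$target_residues)
      if (length(pos) == 0L) return(NULL)
      data.frame(accession = database$accession[i], position = pos,
                 residue = ch[pos],
                 window = extract_window(database$sequence[i], pos, 7L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sites)) stop("database contains no phosphoacceptor residues")
    p_dep <- phospho_probability(sites$window, model)
    dep <- stats::runif(nrow(sites)) < p_dep
    bg <- !dep & stats::runif(nrow(sites)) < config$background_phospho_rate

    truth <- sites[dep | bg, , drop = FALSE]
    truth$kinase_dependent <- dep[dep | bg]
    truth$true_log2_ratio <- ifelse(
      truth$kinase_dependent,
      rnorm_trunc_lower(nrow(truth), config$dependent_log2_mean,
                        config$dependent_log2_sd, config$dependent_log2_min),
      0)
    rownames(truth) <- NULL

    # map phosphosites onto covering peptides -> singly-phosphorylated analytes
    analytes <- NULL
    if (nrow(truth) > 0L) {
      analytes <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
        cov <- peptides[peptides$accession == truth$accession[i] &
                          peptides$start <= truth$position[i] &
                          peptides$start + nchar(peptides$peptide) - 1L >=
                            truth$position[i], , drop = FALSE]
        if (nrow(cov) == 0L) return(NULL)
        keep <- cov$missed_cleavages == 0L |
          stats::runif(nrow(cov)) < config$missed_cleavage_detect_rate
        cov <- cov[keep, , drop = FALSE]
        if (nrow(cov) == 0L) return(NULL)
        data.frame(peptide = cov$peptide,
                   phospho_positions_in_peptide =
                     as.character(truth$position[i] - cov$start + 1L),
                   accession = truth$accession[i],
                   true_log2_ratio = truth$true_log2_ratio[i],
                   kinase_dependent = truth$kinase_dependent[i],
                   stringsAsFactors = FALSE)
      }))
    }
    if (is.null(analytes)) {
      analytes <- data.frame(peptide = character(0),
                             phospho_positions_in_peptide = character(0),
                             accession = character(0),
                             true_log2_ratio = numeric(0),
                             kinase_dependent = logical(0))
    } else {
      analytes <- analytes[!duplicated(analytes[, c("peptide",
                                                    "phospho_positions_in_peptide")]),
                           , drop = FALSE]
    }

    # contaminant non-phosphopeptides with true ratio 1
    n_cont <- min(config$nonphospho_contaminant_count, nrow(peptides))
    if (n_cont > 0L) {
      cont <- peptides[sample.int(nrow(peptides), n_cont), , drop = FALSE]
      cont <- data.frame(peptide = cont$peptide,
                         phospho_positions_in_peptide = "",
                         accession = cont$accession,
                         true_log2_ratio = 0,
                         kinase_dependent = FALSE,
                         stringsAsFactors = FALSE)
      cont <- cont[!duplicated(cont$peptide), , drop = FALSE]
      cont <- cont[!cont$peptide %in% analytes$peptide, , drop = FALSE]
      analytes <- rbind(analytes, cont)
    }
    rownames(analytes) <- NULL

    emit <- function(experiment) {
      n <- nrow(analytes)
      rows <- vector("list", config$n_replicates)
      for (r in seq_len(config$n_replicates)) {
        present <- stats::runif(n) >= config$replicate_dropout
        if (!any(present)) next
        obs_log2 <- analytes$true_log2_ratio[present] +
          stats::rnorm(sum(present), 0, config$ratio_noise_sigma)
        tc <- 2^obs_log2                      # treated/control
        raw <- if (experiment == "forward") tc else 1 / tc
        rows[[r]] <- data.frame(
          peptide = analytes$peptide[present],
          phospho_positions_in_peptide =
            analytes$phospho_positions_in_peptide[present],
          accession = analytes$accession[present],
          raw_ratio_light_over_medium = raw,
          q_value = draw_q_values(sum(present), config),
          experiment = experiment,
          replicate = r,
          light_label_da = LIGHT_LABEL_DA,
          medium_label_da = MEDIUM_LABEL_DA,
          stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      if (is.null(out)) out <- empty_psm_table()
      rownames(out) <- NULL
      out
    }
    forward <- emit("forward")
    reverse <- emit("reverse")
  })
  list(forward = forward, reverse = reverse, truth = truth,
       analytes = analytes)
}

empty_psm_table <- function() {
  data.frame(peptide = character(0), phospho_positions_in_peptide = character(0),
             accession = character(0), raw_ratio_light_over_medium = numeric(0),
             q_value = numeric(0), experiment = character(0),
             replicate = integer(0), light_label_da = numeric(0),
             medium_label_da = numeric(0))
}
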