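# Independent oracles and small fixture builders used across the suite.

# Brute-force tryptic digestion oracle: enumerate ALL substrings whose ends
# are cleavage boundaries and whose internal boundary count is <= max_missed.
# Deliberately O(n^2) and structured differently from the implementation.
brute_force_digest <- function(sequence, max_missed) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  is_boundary <- function(i) {          # boundary after residue i (0 = N-term)
    if (i == 0L || i == n) return(TRUE)
    ch[i] %in% c("K", "R") && ch[i + 1L] != "P"
  }
  out <- data.frame(start = integer(0), peptide = character(0),
                    missed_cleavages = integer(0))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!is_boundary(i - 1L) || !is_boundary(j)) next
      internal <- if (j > i) sum(vapply(i:(j - 1L), is_boundary, logical(1)))
                  else 0L
      if (internal <= max_missed) {
        out <- rbind(out, data.frame(
          start = i, peptide = substr(sequence, i, j),
          missed_cleavages = internal))
      }
    }
  }
  out[order(out$start, nchar(out$peptide)), , drop = FALSE]
}

random_protein <- function(n, residues = phosphoswap::AA_ALPHABET_20) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# random 15-mer windows centered on S/T, i.i.d. residues elsewhere
random_windows <- function(n, prob = NULL) {
  m <- matrix(sample(phosphoswap::AA_ALPHABET_20, n * 14L, replace = TRUE,
                     prob = prob), nrow = n)
  centers <- sample(c("S", "T"), n, replace = TRUE)
  do.call(paste0, c(as.data.frame(m[, 1:7, drop = FALSE],
                                  stringsAsFactors = FALSE),
                    list(centers),
                    as.data.frame(m[, 8:14, drop = FALSE],
                                  stringsAsFactors = FALSE)))
}

# minimal PSM row builder
psm_row <- function(peptide, positions = "", accession = "P1", raw = 1,
                    q = 0.01, experiment = "forward", replicate = 1L) {
  data.frame(peptide = peptide, phospho_positions_in_peptide = positions,
             accession = accession, raw_ratio_light_over_medium = raw,
             q_value = q, experiment = experiment, replicate = replicate,
             stringsAsFactors = FALSE)
}

fixture_annotation_path <- function() {
  system.file("extdata", "plk2_sites_phosphositeplus.tsv",
              package = "phosphoswap", mustWork = TRUE)
}

# small deterministic recovery run shared by tests
small_recovery_run <- function(seed = 7L, n_proteins = 60L) {
  cfg <- simulation_config(n_proteins = n_proteins,
                           protein_length_range = c(300L, 800L),
                           seed = seed)
  db <- generate_random_proteome(cfg)
  sim <- simulate_experiment(db, default_kinase_model(), cfg)
  list(cfg = cfg, db = db, sim = sim)
}
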