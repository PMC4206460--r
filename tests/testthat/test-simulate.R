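test_that("random proteomes are seed-deterministic with the configured composition", {
  cfg <- simulation_config(n_proteins = 2L, protein_length_range = c(30L, 30L),
                           seed = 5L)
  expect_identical(generate_random_proteome(cfg),
                   generate_random_proteome(cfg))

  cfg_u <- simulation_config(n_proteins = 100L,
                             protein_length_range = c(200L, 400L),
                             residue_frequencies = rep(0.05, 20L), seed = 6L)
  db <- generate_random_proteome(cfg_u)
  pooled <- table(strsplit(paste(db$sequence, collapse = ""), "")[[1]])
  freqs <- as.numeric(pooled) / sum(pooled)
  expect_true(all(abs(freqs - 0.05) < 0.005))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(residue_frequencies = rep(0.04, 20L)),
               "sum to 1")
  expect_error(simulation_config(background_phospho_rate = 2))
  expect_error(simulation_config(n_replicates = 0L))
  cfg <- simulation_config(seed = 1L)
  cfg$n_proteins <- 0L
  expect_error(generate_random_proteome(cfg), "n_proteins")
})

test_that("a silenced kinase with no background yields zero phosphopeptides", {
  cfg <- simulation_config(n_proteins = 20L, protein_length_range = c(300L, 400L),
                           background_phospho_rate = 0, seed = 8L)
  sim <- simulate_experiment(generate_random_proteome(cfg),
                             kinase_model(baseline_logit = -1e9), cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(!nzchar(sim$forward$phospho_positions_in_peptide)))
  expect_true(all(!nzchar(sim$reverse$phospho_positions_in_peptide)))
  expect_gt(nrow(sim$forward), 0L)  # contaminants remain
})

test_that("label swap is an exact reciprocal without noise or dropout", {
  cfg <- simulation_config(n_proteins = 15L, protein_length_range = c(300L, 500L),
                           ratio_noise_sigma = 0, replicate_dropout = 0,
                           background_phospho_rate = 0,
                           dependent_log2_mean = 3, dependent_log2_sd = 0,
                           dependent_log2_min = 0, seed = 9L)
  sim <- simulate_experiment(generate_random_proteome(cfg),
                             default_kinase_model(), cfg)
  phos_f <- sim$forward[nzchar(sim$forward$phospho_positions_in_peptide), ]
  expect_true(all(abs(phos_f$raw_ratio_light_over_medium - 8) < 1e-12))
  phos_r <- sim$reverse[nzchar(sim$reverse$phospho_positions_in_peptide), ]
  expect_true(all(abs(phos_r$raw_ratio_light_over_medium - 0.125) < 1e-12))
  # orienting both reproduces the true treated/control ratio exactly
  both <- rbind(phos_f, phos_r)
  oriented <- orient_ratio(both$raw_ratio_light_over_medium, both$experiment)
  expect_true(all(abs(oriented - 8) < 1e-12))
})

test_that("emitted kinase-dependent fraction matches the model's analytic mean", {
  cfg <- simulation_config(n_proteins = 200L, seed = 10L)
  db <- generate_random_proteome(cfg)
  model <- default_kinase_model()
  sim <- simulate_experiment(db, model, cfg)
  # analytic expectation: mean phospho_probability over all eligible windows
  ch_sites <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    ch <- strsplit(db$sequence[i], "")[[1]]
    pos <- which(ch %in% c("S", "T"))
    data.frame(window = extract_window(db$sequence[i], pos, 7L))
  }))
  p <- phospho_probability(ch_sites$window, model)
  n_dep <- sum(sim$truth$kinase_dependent)
  expect_lt(abs(n_dep - sum(p)), 4 * sqrt(sum(p * (1 - p))))
})

test_that("q-values exercise the confidence filter at the configured rate", {
  cfg <- simulation_config(n_proteins = 50L, seed = 11L,
                           q_above_fraction = 0.2)
  sim <- simulate_experiment(generate_random_proteome(cfg),
                             default_kinase_model(), cfg)
  q <- c(sim$forward$q_value, sim$reverse$q_value)
  frac_above <- mean(q >= 0.05)
  expect_lt(abs(frac_above - 0.2), 4 * sqrt(0.2 * 0.8 / length(q)))
  expect_true(all(q >= 0 & q <= 0.2))
})

test_that("simulation bundles are reproducible and written to disk", {
  cfg <- simulation_config(n_proteins = 10L, protein_length_range = c(300L, 400L),
                           seed = 12L)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  b1 <- run_simulation(cfg, out_dir = d1)
  b2 <- run_simulation(cfg, out_dir = d2)
  for (f in c("database.fasta", "psms.tsv", "ground_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_fasta(file.path(d1, "database.fasta"))
  expect_equal(back$sequence, b1$database$sequence)
  psms <- read_psm_table(file.path(d1, "psms.tsv"))
  expect_setequal(unique(psms$experiment), c("forward", "reverse"))
  unlink(c(d1, d2), recursive = TRUE)
})
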