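test_that("q-value filtering is strict", {
  psms <- rbind(psm_row("AAASK", q = 0.05), psm_row("AAATK", q = 0.0),
                psm_row("AAAYK", q = 0.049999))
  kept <- filter_psms(psms, 0.05)
  expect_setequal(kept$peptide, c("AAATK", "AAAYK"))

  set.seed(401)
  many <- do.call(rbind, lapply(1:400, function(i) {
    psm_row(sprintf("PEP%dK", i), q = runif(1))
  }))
  n_kept <- nrow(filter_psms(many, 0.05))
  expect_lt(abs(n_kept - 400 * 0.05), 3 * sqrt(400 * 0.05 * 0.95) + 1)
})

test_that("ratio orientation inverts reverse experiments and caps at the maximum", {
  expect_equal(orient_ratio(8.0, "forward", 100), 8.0)
  expect_equal(orient_ratio(0.125, "reverse", 100), 8.0)
  expect_equal(orient_ratio(500, "forward", 100), 100)
  expect_equal(orient_ratio(0.001, "reverse", 100), 100)
  expect_error(orient_ratio(-1, "forward"), "positive")
  expect_error(orient_ratio(1, "sideways"), "experiment")
  # monotone in treated share, never exceeding the cap
  raw <- sort(runif(50, 0.001, 1000))
  o <- orient_ratio(raw, rep("forward", 50), 100)
  expect_true(all(diff(o) >= 0))
  expect_true(all(o <= 100))
})

test_that("replicate aggregation averages and counts", {
  expect_equal(aggregate_replicates(c(100, 100, 100)),
               list(ratio = 100, n = 3L))
  expect_equal(aggregate_replicates(c(2, 4))$ratio, 3.0)
  expect_equal(aggregate_replicates(7), list(ratio = 7, n = 1L))
  expect_equal(aggregate_replicates(c(2, 8), mean_type = "geometric")$ratio, 4)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
  # permutation invariance
  set.seed(402)
  x <- runif(6, 0.1, 90)
  expect_equal(aggregate_replicates(x)$ratio,
               aggregate_replicates(sample(x))$ratio)
})

test_that("class 1 means both experiments, class 2 one", {
  psms <- rbind(
    psm_row("AAASK", "4", raw = 8, experiment = "forward", replicate = 1),
    psm_row("AAASK", "4", raw = 0.125, experiment = "reverse", replicate = 1),
    psm_row("CCCTK", "4", raw = 10, experiment = "forward", replicate = 1),
    psm_row("GGGGK", "", raw = 1.1, experiment = "reverse", replicate = 2))
  q <- quantify_peptides(psms)
  expect_equal(q$class[q$peptide == "AAASK"], 1L)
  expect_equal(q$class[q$peptide == "CCCTK"], 2L)
  expect_true(is.na(q$class[q$peptide == "GGGGK"]))
  expect_false(q$is_phospho[q$peptide == "GGGGK"])
  expect_equal(q$ratio_forward[q$peptide == "AAASK"], 8)
  expect_equal(q$ratio_reverse[q$peptide == "AAASK"], 8)
  expect_equal(nrow(classify_peptides(
    data.frame(peptide = character(0), phospho_positions_in_peptide = character(0),
               accession = character(0), experiment = character(0),
               ratio = numeric(0), n = integer(0)))), 0L)
})

test_that("capping is applied per replicate before averaging by default", {
  psms <- rbind(
    psm_row("AAASK", "4", raw = 500, experiment = "forward", replicate = 1),
    psm_row("AAASK", "4", raw = 50, experiment = "forward", replicate = 2))
  q <- quantify_peptides(psms)
  expect_equal(q$ratio_forward, (100 + 50) / 2)
  q2 <- quantify_peptides(psms, cap_before_average = FALSE)
  expect_equal(q2$ratio_forward, 100)  # mean 275 capped afterwards
  expect_equal(q$n_forward, 2L)
})

test_that("same sequence with different site sets is a different analyte", {
  psms <- rbind(psm_row("ASATK", "2", raw = 8),
                psm_row("ASATK", "4", raw = 2),
                psm_row("ASATK", "2;4", raw = 4))
  q <- quantify_peptides(psms)
  expect_equal(nrow(q), 3L)
})

test_that("PSM tables round-trip through TSV", {
  psms <- rbind(psm_row("AAASK", "4", raw = 8),
                psm_row("GGGGK", "", raw = 1, experiment = "reverse"))
  tf <- tempfile(fileext = ".tsv")
  write_psm_table(psms, tf)
  back <- read_psm_table(tf)
  expect_equal(back$peptide, psms$peptide)
  expect_equal(back$phospho_positions_in_peptide,
               psms$phospho_positions_in_peptide)
  expect_equal(back$raw_ratio_light_over_medium,
               psms$raw_ratio_light_over_medium)
  expect_error(read_psm_table(fixture_annotation_path()), "lacks columns")
})

test_that("PSM validation rejects malformed phospho positions", {
  expect_error(check_psm_table <- quantify_peptides(psm_row("AAAGK", "4")),
               "S/T/Y")
  expect_error(quantify_peptides(psm_row("AAASK", "9")), "outside|S/T/Y")
})
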