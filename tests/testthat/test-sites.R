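homolog_db <- function() {
  # two homologous proteins sharing a peptide, plus one unrelated
  # H1/H2 share the peptide AND its full +/-7 context, so the grouped site is
  # unambiguous; U1 is unrelated
  shared <- "ELDTLNEESYK"
  data.frame(
    accession = c("H1", "H2", "U1"),
    sequence = c(paste0("MAAAR", shared, "GGGWWK"),
                 paste0("MCCCAAAR", shared, "PPPPFFK"),
                 "MKNNNNSDDDEEEAAKLLLK"),
    stringsAsFactors = FALSE)
}

sel_row <- function(peptide, positions, class = 2L) {
  data.frame(peptide = peptide, phospho_positions_in_peptide = positions,
             accession = "x", is_phospho = TRUE, ratio_forward = 50,
             n_forward = 3L, ratio_reverse = NA_real_, n_reverse = NA_integer_,
             class = class, stringsAsFactors = FALSE)
}

test_that("locate_peptide reports all exact matches", {
  db <- homolog_db()
  hits <- locate_peptide("ELDTLNEESYK", db)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$accession, c("H1", "H2"))
  expect_equal(hits$start[hits$accession == "H1"], 6L)
  expect_equal(hits$start[hits$accession == "H2"], 9L)
  one <- locate_peptide("NNNNSDDDEEEAAK", db)
  expect_equal(nrow(one), 1L)
  expect_equal(locate_peptide("WWWWWW", db)$accession, character(0))
})

test_that("missed-cleavage variants of a site collapse to one phosphosite", {
  db <- data.frame(accession = "P1",
                   sequence = "MAAAKELDTLNEESYKGGGGK")
  sel <- rbind(sel_row("ELDTLNEESYK", "4"),       # T at protein position 9
               sel_row("MAAAKELDTLNEESYK", "9"),  # same site, 1 missed cleavage
               sel_row("GGGGK", ""))              # no phospho -> no site
  sites <- collapse_sites(sel, db)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 9L)
  expect_equal(sites$residue, "T")
  expect_equal(sites$n_peptides, 2L)
  expect_equal(sites$window, extract_window(db$sequence, 9L, 7L))
})

test_that("one peptide with two phospho positions contributes two sites", {
  db <- data.frame(accession = "P1", sequence = "MAAASGGGTDDDKLLLL")
  sites <- collapse_sites(sel_row("MAAASGGGTDDDK", "5;9"), db)
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$position, c(5L, 9L))
  expect_setequal(sites$residue, c("S", "T"))
})

test_that("homolog-shared peptides make one grouped, unambiguous site", {
  db <- homolog_db()
  sites <- collapse_sites(sel_row("ELDTLNEESYK", "4"), db)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$accession, "H1;H2")
  expect_equal(sites$loci, "H1:9;H2:12")
  expect_false(sites$ambiguous)  # identical windows in both homologs
  expect_equal(summarize_sites(sites)$n_protein_groups, 1L)
})

test_that("unlocatable peptides are excluded with a warning and accounted for", {
  db <- homolog_db()
  sel <- rbind(sel_row("ELDTLNEESYK", "4"), sel_row("WWWWSWWWW", "5"))
  expect_warning(sites <- collapse_sites(sel, db), "not found")
  expect_equal(nrow(sites), 1L)
  expect_equal(attr(sites, "excluded"), "WWWWSWWWW")
  expect_equal(sites$n_peptides + length(attr(sites, "excluded")), nrow(sel))
})

test_that("collapsing is idempotent and order-independent", {
  db <- homolog_db()
  sel <- rbind(sel_row("ELDTLNEESYK", "4"),
               sel_row("ELDTLNEESYK", "9"),
               sel_row("NNNNSDDDEEEAAK", "5"))
  a <- collapse_sites(sel, db)
  b <- collapse_sites(sel[c(3, 1, 2), ], db)
  attr(a, "excluded") <- NULL
  attr(b, "excluded") <- NULL
  expect_equal(a, b)
  # feeding supporting peptides back in changes nothing
  sel2 <- rbind(sel, sel)
  c2 <- collapse_sites(sel2, db)
  expect_equal(nrow(c2), nrow(a))
  expect_equal(c2$loci, a$loci)
})

test_that("site positions are consistent with peptide-local coordinates", {
  set.seed(601)
  cfg <- simulation_config(n_proteins = 10L, protein_length_range = c(300L, 400L),
                           seed = 13L)
  db <- generate_random_proteome(cfg)
  sim <- simulate_experiment(db, default_kinase_model(), cfg)
  q <- quantify_peptides(rbind(sim$forward, sim$reverse))
  sel <- select_dependent(q, 2)
  sites <- collapse_sites(sel, db)
  if (nrow(sites) > 0) {
    seq_of <- setNames(db$sequence, db$accession)
    for (i in seq_len(nrow(sites))) {
      acc1 <- strsplit(sites$accession[i], ";")[[1]][1]
      expect_equal(substr(seq_of[[acc1]], sites$position[i], sites$position[i]),
                   sites$residue[i])
      expect_equal(substr(sites$window[i], 8, 8), sites$residue[i])
    }
  }
})

test_that("summaries count sites and merged protein groups", {
  expect_equal(summarize_sites(empty_sites <- collapse_sites(
    sel_row("ZZZZ", "")[0, ], homolog_db())),
    list(n_unique_sites = 0L, n_protein_groups = 0L, n_accessions = 0L))
  sites <- data.frame(accession = c("A;B", "B;C", "D"),
                      position = c(5L, 9L, 2L),
                      loci = c("A:5;B:5", "B:9;C:9", "D:2"),
                      residue = "S",
                      window = paste0(strrep("A", 7), "S", strrep("A", 7)),
                      peptides = "p", n_peptides = 1L, class = 2L,
                      max_ratio = 10, ambiguous = FALSE)
  s <- summarize_sites(sites)
  expect_equal(s$n_unique_sites, 3L)
  expect_equal(s$n_protein_groups, 2L)  # {A,B,C} merged via shared B, plus {D}
  expect_equal(s$n_accessions, 4L)
})
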