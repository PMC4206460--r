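test_that("residue frequencies count only defined positions", {
  w <- c("AAAAEAASAAAAAAA",  # E at -3
         "AAAAEAATAAAAAAA",
         "AAAAEAASAAAAAAA",
         "AAAAGAASAAAAAAA")
  expect_equal(residue_frequency(w, -3, "E"), 0.75)
  expect_equal(residue_frequency(w, -3, "W"), 0.0)
  gappy <- c("-AAAAAASAAAAAAA", "-AAAAAATAAAAAAA")
  expect_warning(f <- residue_frequency(gappy, -7, "A"), "no defined")
  expect_true(is.na(f))
  # gaps leave the denominator: 1 defined window of 2
  half <- c("-AAAAAASAAAAAAA", "EAAAAAATAAAAAAA")
  expect_equal(residue_frequency(half, -7, "E"), 1.0)
})

test_that("position tests agree with R's Welch t.test on indicator vectors", {
  # frozen example: fg 8/10 vs bg 2/10
  r <- welch_indicator_test(8, 10, 2, 10)
  expect_equal(round(r$t, 3), 3.182)
  ref <- t.test(c(rep(1, 8), rep(0, 2)), c(rep(1, 2), rep(0, 8)))
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  set.seed(701)
  for (rep in 1:20) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    x <- c(rep(1, k1), rep(0, n1 - k1))
    y <- c(rep(1, k2), rep(0, n2 - k2))
    got <- welch_indicator_test(k1, n1, k2, n2)
    ref <- t.test(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("identical samples and zero-variance cases are uninformative", {
  w <- random_windows(10)
  r <- position_residue_test(w, w, -3, "E")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  z <- welch_indicator_test(0, 10, 0, 12)  # zero variance in both
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
})

test_that("swapping foreground and background negates t and flips directions", {
  set.seed(702)
  fg <- random_windows(60)
  bg <- random_windows(80)
  a <- position_residue_test(fg, bg, 2, "L")
  b <- position_residue_test(bg, fg, 2, "L")
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  la <- compute_logo(fg, bg, alpha = 0.1)
  lb <- compute_logo(bg, fg, alpha = 0.1)
  flagged <- la$direction != "none"
  expect_true(any(flagged))
  expect_equal(la$direction[flagged] == "over", lb$direction[flagged] == "under")
  # consistency: flagged pairs have a real frequency difference
  expect_true(all(abs(la$fg_freq[flagged] - la$bg_freq[flagged]) > 0))
})

test_that("compute_logo covers all pairs, and alpha = 0 flags nothing", {
  set.seed(703)
  fg <- random_windows(40)
  bg <- random_windows(40)
  logo <- compute_logo(fg, bg)
  expect_equal(nrow(logo), 14 * 20)
  expect_true(all(logo$fg_freq >= 0 & logo$fg_freq <= 1))
  # per position, defined fg frequencies sum to 1
  for (p in c(-7, -1, 3)) {
    expect_equal(sum(logo$fg_freq[logo$position == p]), 1)
  }
  expect_true(all(compute_logo(fg, bg, alpha = 0)$direction == "none"))
})

test_that("planted enrichment is flagged as over-represented", {
  set.seed(704)
  bg <- random_windows(2000)
  fg <- random_windows(150)
  substr(fg[1:110], 5, 5) <- "E"  # plant E at -3 in ~73% of foreground
  logo <- compute_logo(fg, bg)
  expect_equal(logo$direction[logo$position == -3 & logo$residue == "E"], "over")
})

test_that("null resampling keeps the flag rate near the nominal level", {
  # 250 null resamples at n = 100 per sample; indicator t-tests are discrete,
  # so the average per-pair flag rate is checked within 0.05 +/- 0.02
  set.seed(705)
  pool <- random_windows(4000)
  rates <- vapply(1:250, function(i) {
    idx <- sample.int(4000, 200)
    fg <- pool[idx[1:100]]
    bg <- pool[idx[101:200]]
    logo <- compute_logo(fg, bg, alpha = 0.05)
    mean(logo$direction != "none")
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("logo rendering is deterministic and structured", {
  set.seed(706)
  fg <- random_windows(100)
  substr(fg[1:80], 5, 5) <- "E"
  bg <- random_windows(1000)
  logo <- compute_logo(fg, bg)
  txt1 <- capture.output(r1 <- render_logo(logo))
  txt2 <- capture.output(r2 <- render_logo(logo))
  expect_identical(txt1, txt2)
  expect_true(any(grepl("^Over-represented", txt1)))
  expect_true(any(grepl("-3 E", txt1)))
  empty <- compute_logo(fg, bg, alpha = 0)
  txt <- capture.output(render_logo(empty))
  expect_true(sum(grepl("\\(none\\)", txt)) == 2L)
  p <- plot_logo(logo)
  expect_s3_class(p, "ggplot")
})
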