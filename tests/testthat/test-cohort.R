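test_that("summarize_group reproduces the reference Mean +/- SD cells", {
  s1 <- summarize_group(table3_phase1_manual)
  expect_equal(round(s1$mean_mm, 1), 15.8)
  expect_equal(round(s1$sd_mm, 1), 7.2)    # sample SD, n-1 denominator
  s2 <- summarize_group(table3_phase2_manual)
  expect_equal(round(s2$mean_mm, 1), 10.9)
  expect_equal(round(s2$sd_mm, 1), 4.2)
  s3 <- summarize_group(table3_phase2_semiauto)
  expect_equal(round(s3$mean_mm, 1), 13.9)
  expect_equal(round(s3$sd_mm, 1), 4.4)
  expect_equal(summarize_group(rep(5, 4))$sd_mm, 0)
  expect_error(summarize_group(c(1)), class = "liverreg_insufficient_data")
})

test_that("shapiro_wilk matches the reference implementation", {
  # independent oracle: stats::shapiro.test (Royston AS R94)
  cases <- list(table3_phase1_manual, table3_phase2_manual,
                table3_phase2_semiauto)
  set.seed(50)
  for (n in c(4, 5, 7, 12, 20, 35, 50)) {
    cases[[length(cases) + 1]] <- rnorm(n)
    cases[[length(cases) + 1]] <- rexp(n)
  }
  for (x in cases) {
    got <- shapiro_wilk(x)
    ref <- stats::shapiro.test(x)
    expect_equal(got$W, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("shapiro_wilk invariances and edge cases", {
  x <- table3_phase2_manual
  a <- shapiro_wilk(x)
  b <- shapiro_wilk(3.2 * x + 17)   # affine transform leaves W unchanged
  expect_equal(a$W, b$W, tolerance = 1e-12)
  # three equally spaced values are perfectly linear in the Q-Q sense
  expect_equal(shapiro_wilk(c(1, 2, 3))$W, 1, tolerance = 1e-9)
  expect_error(shapiro_wilk(c(1, 2)), class = "liverreg_unsupported_n")
  expect_error(shapiro_wilk(rnorm(51)), class = "liverreg_unsupported_n")
  expect_error(shapiro_wilk(rep(1, 5)),
               class = "liverreg_insufficient_data")
})

test_that("two_sample_t_pooled reproduces the phase contrast", {
  t1 <- two_sample_t_pooled(table3_phase1_manual, table3_phase2_manual)
  expect_equal(round(t1$estimate_mm, 1), 4.9)
  expect_equal(round(t1$ci95_mm, 1), c(-1.1, 10.9))
  expect_equal(round(t1$p_two_sided, 3), 0.104)
  expect_equal(t1$df, 14)
  # oracle: stats::t.test with var.equal = TRUE
  set.seed(51)
  a <- rnorm(8, 5, 2); b <- rnorm(13, 4, 2)
  got <- two_sample_t_pooled(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  expect_equal(got$ci95_mm, as.numeric(ref$conf.int), tolerance = 1e-12)
  # identical samples: no difference
  same <- two_sample_t_pooled(a, a)
  expect_equal(same$estimate_mm, 0)
  expect_equal(same$p_two_sided, 1)
})

test_that("two_sample_t_pooled hand-computed textbook fixture", {
  a <- c(2, 4, 6, 8); b <- c(1, 3, 5)
  # pooled variance: ((4-1)*var(a) + (3-1)*var(b)) / 5
  sp2 <- (3 * var(a) + 2 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  got <- two_sample_t_pooled(a, b)
  expect_equal(got$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 5)
  # degenerate: zero variance, unequal means -> infinite-t flag
  z <- two_sample_t_pooled(c(1, 1), c(2, 2))
  expect_true(z$infinite_t)
  expect_equal(z$p_two_sided, 0)
})

test_that("paired_t reproduces the phase-2 contrast and the hand check", {
  p <- paired_t(table3_phase2_manual, table3_phase2_semiauto)
  expect_equal(round(p$estimate_mm, 1), -3.0)
  expect_equal(p$df, 9)
  ref <- t.test(table3_phase2_manual, table3_phase2_semiauto, paired = TRUE)
  expect_equal(p$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(p$p_two_sided, ref$p.value, tolerance = 1e-12)
  # constructed differences
  d <- c(1, 2, 3, 4)
  ph <- paired_t(d, rep(0, 4))
  expect_equal(ph$t_stat, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  ident <- paired_t(d, d)
  expect_equal(ident$estimate_mm, 0)
  expect_equal(ident$p_two_sided, 1)
  expect_error(paired_t(1:3, 1:4), class = "liverreg_schema")
})

test_that("pooled and Welch t coincide for equal-n samples", {
  set.seed(52)
  a <- rnorm(10); b <- rnorm(10)
  got <- two_sample_t_pooled(a, b)
  welch <- t.test(a, b, var.equal = FALSE)
  expect_equal(got$t_stat, unname(welch$statistic), tolerance = 1e-12)
})

test_that("cohort_table validates the two-phase schema", {
  tab <- reference_cohort()
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$phase == 1), 6)
  bad <- as.data.frame(tab)
  bad$tre_semiauto[bad$phase == 1][1] <- 9
  expect_error(cohort_table(bad), class = "liverreg_schema")
  bad2 <- as.data.frame(tab)
  bad2$patient_id[2] <- bad2$patient_id[1]
  expect_error(cohort_table(bad2), class = "liverreg_schema")
  bad3 <- as.data.frame(tab)
  bad3$tre_manual[bad3$phase == 2][1] <- NA
  expect_error(cohort_table(bad3), class = "liverreg_schema")
})

test_that("analyze_cohort mirrors the published analysis structure", {
  rep <- analyze_cohort(reference_cohort())
  expect_equal(round(rep$groups$phase1_manual$mean_mm, 1), 15.8)
  expect_equal(round(rep$groups$phase2_manual$sd_mm, 1), 4.2)
  expect_equal(round(rep$groups$phase2_semiauto$mean_mm, 1), 13.9)
  expect_equal(round(rep$phase1_vs_phase2_manual$estimate_mm, 1), 4.9)
  expect_equal(round(rep$phase2_manual_vs_semiauto$paired$estimate_mm, 1), -3.0)
  # both variants reported for the phase-2 contrast
  expect_equal(rep$phase2_manual_vs_semiauto$pooled$test_kind,
               "pooled-independent")
  # phases swapped: the independent contrast flips sign
  sw <- as.data.frame(reference_cohort())
  sw$phase <- ifelse(sw$phase == 1L, 2L, 1L)
  sw$tre_semiauto[sw$phase == 1L] <- NA
  sw$tre_semiauto[sw$phase == 2L] <- 1  # dummy to satisfy schema
  rep_sw <- analyze_cohort(sw)
  expect_equal(rep_sw$phase1_vs_phase2_manual$estimate_mm,
               -rep$phase1_vs_phase2_manual$estimate_mm, tolerance = 1e-12)
  # jackknife bookkeeping: dropping one phase-2 patient drops n in both
  jk <- as.data.frame(reference_cohort())
  jk <- jk[jk$patient_id != "LR08", ]
  rep_jk <- analyze_cohort(jk)
  expect_equal(rep_jk$groups$phase2_manual$n, 9)
  expect_equal(rep_jk$groups$phase2_semiauto$n, 9)
  expect_equal(rep_jk$phase2_manual_vs_semiauto$paired$df, 8)
})

test_that("analyze_cohort degrades gracefully on partial input", {
  one_phase <- data.frame(patient_id = paste0("P", 1:4), phase = 2L,
                          tre_manual = c(10, 11, 12, 13),
                          tre_semiauto = c(9, 12, 14, 11))
  rep <- analyze_cohort(one_phase)
  expect_null(rep$phase1_vs_phase2_manual)
  expect_true(any(grepl("skipped", rep$notices)))
  expect_false(is.null(rep$phase2_manual_vs_semiauto))
})

test_that("cohort CSV and report JSON round trip", {
  tab <- reference_cohort()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  write_cohort(tab, f)
  tab2 <- read_cohort(f)
  expect_equal(as.data.frame(tab2), as.data.frame(tab), ignore_attr = TRUE)
  emptyf <- tempfile(fileext = ".csv")
  on.exit(unlink(emptyf), add = TRUE)
  writeLines("patient_id,phase,tre_manual,tre_semiauto", emptyf)
  expect_error(read_cohort(emptyf), class = "liverreg_insufficient_data")
  rep <- analyze_cohort(tab)
  j <- tempfile(fileext = ".json")
  on.exit(unlink(j), add = TRUE)
  cohort_report_to_json(rep, j)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$groups$phase1_manual$display, "15.8 ± 7.2")
  expect_equal(parsed$groups$phase2_semiauto$display, "13.9 ± 4.4")
})
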