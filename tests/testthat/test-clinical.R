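fixture <- system.file("extdata", "table1_clinical.tsv", package = "fcdlong")

test_that("the packaged patient table parses with missing sessions intact", {
  co <- read_clinical_table(fixture)
  expect_s3_class(co, "stroke_cohort")
  counts <- scan_counts(co)
  expect_equal(nrow(counts), 8)
  expect_equal(counts$n_scans[counts$patient_id %in% c("6", "7")], c(4L, 4L))
  expect_equal(sum(counts$n_scans), 38L)
  # missing cells stay missing
  expect_true(is.na(co$day[co$patient_id == "6" & co$session == 1]))
  expect_true(is.na(co$mi[co$patient_id == "7" & co$session == 5]))
})

test_that("degenerate and malformed tables are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("patient_id\tage", empty)
  expect_error(read_clinical_table(empty), "empty|columns")
  headers <- paste(c("patient_id", "age", paste0("day_", 1:5),
                     paste0("mi_", 1:5), paste0("nihss_", 1:5)),
                   collapse = "\t")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(headers, paste(c("1", "50", "10", "5", "30", "40", "50",
                                rep("0", 10)), collapse = "\t")), bad)
  expect_error(read_clinical_table(bad), "increasing")
  oops <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(headers, paste(c("1", "fifty", rep("1", 15)), collapse = "\t")),
             oops)
  expect_error(read_clinical_table(oops), "malformed")
})

test_that("a single-patient file reads back identically", {
  headers <- paste(c("patient_id", "age", paste0("day_", 1:5),
                     paste0("mi_", 1:5), paste0("nihss_", 1:5)),
                   collapse = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(headers,
               paste(c("p1", "50", "1", "10", "30", "-", "-",
                       "10", "20", "30", "-", "-", "5", "4", "3", "-", "-"),
                     collapse = "\t")), f)
  co <- read_clinical_table(f)
  expect_equal(scan_counts(co)$n_scans, 3L)
  expect_equal(co$day[co$session <= 3], c(1, 10, 30))
})

test_that("session interval statistics reproduce the printed timing table", {
  co <- read_clinical_table(fixture)
  st <- session_interval_stats(co)
  expect_equal(round(st$mean_day, 1), c(3.0, 13.0, 31.4, 97.6, 370.3))
  expect_equal(round(st$sd_day, 1), c(2.1, 1.5, 2.7, 24.5, 42.8))
  expect_equal(st$n, c(7L, 8L, 8L, 8L, 7L))
  one <- session_interval_stats(co, session = 1)
  expect_equal(one$mean_day, 3.0)
  expect_error(session_interval_stats(co, session = 9), "out of range")
})

test_that("zero-variance session timing gives sd 0", {
  tbl <- tibble::tibble(patient_id = c("a", "b"), age = c(50, 51),
                        session = 1L, day = 10, mi = 100, nihss = 2)
  co <- as_stroke_cohort(tbl, n_sessions = 1)
  st <- session_interval_stats(co, session = 1)
  expect_equal(st$mean_day, 10)
  expect_equal(st$sd_day, 0)
})

test_that("demographics match the study cohort", {
  co <- read_clinical_table(fixture)
  dg <- cohort_demographics(co)
  expect_equal(dg$mean_age, 49.0)
  expect_equal(c(dg$age_min, dg$age_max), c(41, 55))
  expect_equal(dg$n_complete, 6L)
  expect_equal(dg$n_patients, 8L)
})

test_that("score centring is exact, keeps missing, and is idempotent", {
  mi1 <- c(33, 88, 130, 190, 190)
  expect_equal(center_scores(mi1), c(-93.2, -38.2, 3.8, 63.8, 63.8))
  expect_equal(center_scores(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(center_scores(c(10, NA, 20)), c(-5, NA, 5))
  expect_error(center_scores(c(NA, NA)), "missing")
  expect_equal(center_scores(center_scores(mi1)), center_scores(mi1))
  co <- read_clinical_table(fixture)
  nm <- normalize_scores(co, "mi")
  sums <- tapply(nm$score_centered, nm$patient_id,
                 function(x) sum(x, na.rm = TRUE))
  expect_true(all(abs(sums) < 1e-9))
})

test_that("recovery is significant in the right direction for MI and NIHSS", {
  co <- read_clinical_table(fixture)
  for (which in c("mi", "nihss")) {
    rt <- recovery_test(co, which)
    expect_equal(rt$direction, c(1, 1))
    expect_lt(rt$p_value[rt$method == "paired_t"], 0.001)
    expect_lt(rt$p_value[rt$method == "wilcoxon_signed_rank"], 0.05)
  }
})

test_that("recovery test handles degenerate and synthetic monotone scores", {
  flat <- tibble::tibble(patient_id = rep(letters[1:4], each = 2),
                         age = 50, session = rep(1:2, 4),
                         day = rep(c(1, 100), 4), mi = 50, nihss = 3)
  rt <- recovery_test(as_stroke_cohort(flat, 2), "mi")
  expect_equal(rt$p_value, c(1, 1))
  expect_equal(rt$direction, c(0, 0))
  mono <- tibble::tibble(patient_id = rep(letters[1:8], each = 2),
                         age = 50, session = rep(1:2, 8),
                         day = rep(c(1, 100), 8),
                         mi = rep(c(20, 150), 8) + rep(1:8, each = 2) *
                           rep(c(1, 3), 8),
                         nihss = 3)
  rt2 <- recovery_test(as_stroke_cohort(mono, 2), "mi")
  expect_equal(rt2$direction, c(1, 1))
  few <- flat[1:4, ]
  expect_error(recovery_test(as_stroke_cohort(few, 2), "mi"), "3 patients")
})
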