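make_cohort_file <- function(path, sep = "\t", drop = NULL) {
  tab <- data.frame(subject_id = c("s1", "s2", "s3"),
                    group = c("ET", "HC", "ET"),
                    age = c(60, 65, 70), sex = c(0, 1, 1),
                    icv = c(1.4e6, 1.5e6, 1.45e6),
                    roi_a = c(100, 110, 120), roi_b = c(200, 210, 220),
                    note = c("x", "y", "z"), check.names = FALSE)
  if (!is.null(drop)) tab <- tab[, setdiff(names(tab), drop)]
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("read_cohort loads a well-formed table and keeps extras", {
  f <- withr::local_tempfile(fileext = ".tsv")
  make_cohort_file(f)
  msgs <- capture_messages(co <- read_cohort(f))
  expect_s3_class(co, "cohort_table")
  expect_identical(nrow(co), 3L)
  expect_identical(volume_cols(co), c("roi_a", "roi_b"))
  expect_true(any(grepl("ET = 2", msgs)))
  expect_true(any(grepl("extra column.*note", msgs)))
})

test_that("read_cohort errors name the offending field", {
  f <- withr::local_tempfile(fileext = ".tsv")
  make_cohort_file(f, drop = "icv")
  expect_error(suppressMessages(read_cohort(f)), "icv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  tab <- utils::read.delim(make_cohort_file(withr::local_tempfile()),
                           check.names = FALSE)
  tab$subject_id <- "dup"
  utils::write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_cohort(f2)), "duplicate subject_id")
})

test_that("text sex is coded 0/1 by sorted label order", {
  tab <- data.frame(subject_id = c("a", "b"), group = "G",
                    age = c(1, 2), sex = c("M", "F"), icv = c(1, 2),
                    v = c(3, 4))
  co <- cohort_table(tab)
  expect_identical(co$sex, c(1, 0))  # F sorts first -> 0
  expect_identical(attr(co, "sex_levels"), c(F = 0L, M = 1L))
})

test_that("freesurfer-style volume listings parse and normalize", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "Left-LGN 223.0", "Left-MGN, 109", ""), f)
  v <- read_freesurfer_volumes(f)
  expect_equal(v, c("left lgn" = 223, "left mgn" = 109))
  f2 <- withr::local_tempfile()
  writeLines(character(), f2)
  expect_error(read_freesurfer_volumes(f2), "no volumes")
  f3 <- withr::local_tempfile()
  writeLines(c("Left-LGN 1", "left lgn 2"), f3)
  expect_error(read_freesurfer_volumes(f3), "duplicated label")
  f4 <- withr::local_tempfile()
  writeLines(c("Left-LGN abc"), f4)
  expect_error(read_freesurfer_volumes(f4), "line 1")
})

test_that("IQR fences flag exactly the points beyond 1.5 IQR", {
  expect_true(all(iqr_outliers(rep(10, 5)) == "none"))
  fl <- iqr_outliers(c(1, 2, 3, 4, 100))
  expect_identical(as.character(fl),
                   c("none", "none", "none", "none", "high"))
  # type-7 quartiles of 1..5: Q1 = 2, Q3 = 4 -> fences (-1, 7)
  fl2 <- iqr_outliers(1:5)
  expect_true(all(fl2 == "none"))
  expect_equal(attr(fl2, "fences"), c(lower = -1, upper = 7))
  expect_error(iqr_outliers(c(1, 2, 3)), "at least 4")
})

test_that("outlier flags are shift-invariant and scale-equivariant", {
  set.seed(21)
  for (rep in 1:20) {
    v <- rnorm(30, 1000, 50)
    v[sample(30, 2)] <- v[sample(30, 2)] + sample(c(-400, 400), 2,
                                                  replace = TRUE)
    base <- as.character(iqr_outliers(v))
    expect_identical(as.character(iqr_outliers(v + 123.4)), base)
    expect_identical(as.character(iqr_outliers(v * 7.7)), base)
  }
})

test_that("thalamus consistency ratio follows |whole - sum| / whole", {
  expect_equal(thalamus_consistency(6000, 6000),
               data.frame(ratio = 0, flagged = FALSE))
  r <- thalamus_consistency(6000, 3000)
  expect_equal(r$ratio, 0.5)
  expect_true(r$flagged)
  r2 <- thalamus_consistency(6229, 6229 * 0.95)
  expect_equal(r2$ratio, 0.05)
  expect_false(r2$flagged)
  expect_error(thalamus_consistency(-1, 10), "positive")
})

test_that("QC reports without mutating; exclusion is separate and logged", {
  set.seed(5)
  n <- 40L
  tab <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    group = rep(c("ET", "HC"), each = n / 2),
                    age = rnorm(n, 64, 10), sex = rbinom(n, 1, 0.5),
                    icv = rnorm(n, 1.4e6, 1e5),
                    `left ventral` = rnorm(n, 2571, 100),
                    `left whole thalamus` = rnorm(n, 2700, 100),
                    check.names = FALSE)
  tab[["left ventral"]][1] <- 6000  # gross outlier
  co <- cohort_table(tab, volume_cols = c("left ventral",
                                          "left whole thalamus"))
  before <- as.data.frame(co)
  rep <- qc_report(co, rois = "left ventral",
                   whole_thalamus = list(left = "left whole thalamus"))
  expect_identical(as.data.frame(co), before)
  expect_true("s01" %in% rep$outliers$subject_id)
  expect_identical(rep$quartile_method, "linear interpolation (type 7)")
  # s01's ventral is more than double its whole-thalamus proxy
  flagged <- rep$consistency$subject_id[rep$consistency$flagged]
  expect_true("s01" %in% flagged)
  # default: report only, never auto-drop
  res0 <- apply_qc_exclusions(co, rep)
  expect_identical(nrow(res0$cohort), n)
  res1 <- suppressMessages(
    apply_qc_exclusions(co, rep, max_outlier_rois = 0))
  expect_identical(res1$dropped, "s01")
  expect_identical(nrow(res1$cohort), n - 1L)
  d <- withr::local_tempdir()
  paths <- write_qc_report(rep, d)
  expect_true(all(file.exists(paths)))
  expect_match(readLines(paths[1], n = 1), "type 7")
})
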