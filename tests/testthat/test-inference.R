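test_that("BH step-up matches hand-computed decisions", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05),
                   rep(TRUE, 5))
  expect_identical(bh_fdr(c(0.5, 0.9), q = 0.05), c(FALSE, FALSE))
  expect_identical(bh_fdr(0.04, q = 0.05), TRUE)
  expect_identical(bh_fdr(numeric(0)), logical(0))
  # non-monotone case: p_(2) fails but p_(3) passes -> reject 1..3
  expect_identical(bh_fdr(c(0.012, 0.025, 0.03, 0.8), q = 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
})

test_that("BH flags agree with p.adjust on random inputs", {
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q),
                     unname(stats::p.adjust(p, "BH") <= q))
  }
})

perm_cohort <- function(n_per = 10, seed = 71, p = 6) {
  null_cohort(n_per, p = p, seed = seed)
}

test_that("identical groups yield zero differences and p = 1", {
  co1 <- perm_cohort(12)
  tab <- as.data.frame(co1)
  half <- tab[tab$group == "A", ]
  dup <- half
  dup$group <- "B"
  dup$subject_id <- paste0(dup$subject_id, "_copy")
  co <- cohort_table(rbind(half, dup), volume_cols = volume_cols(co1),
                     adjusted = TRUE)
  res <- permutation_test(co, R = 120, seed = 3, reference = "A",
                          measures_global = c("Average strength",
                                              "Clustering"),
                          measures_nodal = character(0))
  expect_equal(res$global$difference, c(0, 0))
  expect_equal(res$global$p, c(1, 1))
})

test_that("the permutation engine is exactly reproducible", {
  co <- perm_cohort(10, seed = 72)
  run <- function() permutation_test(
    co, R = 60, seed = 11,
    measures_global = c("Average strength",
                        "Characteristic path length"),
    measures_nodal = c("Strength"), sw_n_rand_obs = 0)
  r1 <- suppressWarnings(run())
  r2 <- suppressWarnings(run())
  expect_identical(r1, r2)
})

test_that("label swap negates differences and mirrors the null", {
  co <- perm_cohort(10, seed = 73)
  swapped <- as.data.frame(co)
  swapped$group <- ifelse(swapped$group == "A", "B", "A")
  co_sw <- cohort_table(swapped, volume_cols = volume_cols(co),
                        adjusted = TRUE)
  args <- list(R = 80, seed = 19, reference = "A",
               measures_global = c("Average strength", "Clustering"),
               measures_nodal = character(0), sw_n_rand_obs = 0)
  r1 <- suppressWarnings(do.call(permutation_test, c(list(co), args)))
  r2 <- suppressWarnings(do.call(permutation_test, c(list(co_sw), args)))
  expect_equal(r2$global$difference, -r1$global$difference)
  expect_equal(r2$global$p, r1$global$p)
  expect_equal(r2$global$ci_low, -r1$global$ci_high)
  expect_equal(r2$global$ci_high, -r1$global$ci_low)
})

test_that("one-sided and small-sample p-value rules are available", {
  co <- perm_cohort(10, seed = 74)
  r_two <- suppressWarnings(permutation_test(
    co, R = 50, seed = 5, measures_global = "Average strength",
    measures_nodal = character(0)))
  r_corr <- suppressWarnings(permutation_test(
    co, R = 50, seed = 5, measures_global = "Average strength",
    measures_nodal = character(0), small_sample = TRUE))
  k <- r_two$global$p * 50
  expect_equal(r_corr$global$p, (k + 1) / 51)
  r_one <- suppressWarnings(permutation_test(
    co, R = 50, seed = 5, measures_global = "Average strength",
    measures_nodal = character(0), tail = "one"))
  expect_true(r_one$global$p >= 0 && r_one$global$p <= 1)
})

test_that("report tables use the published layout and consistent signs", {
  co <- preset_et_hc(contrast = 0.4, n1 = 20, n2 = 20, seed = 81)
  m <- suppressMessages(fit_adjustment(co))
  adj <- residualize(co, m)
  res <- suppressWarnings(
    permutation_test(adj, R = 100, seed = 7,
                     measures_nodal = c("Strength"),
                     sw_n_rand_obs = 10, sw_n_rand = 5))
  tabs <- report_tables(res, all_nodal = TRUE)
  expect_identical(names(tabs$global),
                   c("Global graph measure", "ET", "HC", "CI lower",
                     "CI upper", "Difference", "p value", "Comparison"))
  expect_identical(names(tabs$nodal)[1:2],
                   c("Brain region", "Local graph measure"))
  gl <- tabs$global
  for (i in seq_len(nrow(gl))) {
    if (is.na(gl$Difference[i]) || gl$Difference[i] == 0) next
    expected <- if (gl$Difference[i] > 0) "ET < HC" else "ET > HC"
    expect_identical(gl$Comparison[i], expected)
  }
  # difference = HC - ET (reference minus other)
  expect_equal(gl$Difference, gl$HC - gl$ET)
  # deterministic bytes on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  report_tables(res, all_nodal = TRUE, dir = d1)
  report_tables(res, all_nodal = TRUE, dir = d2)
  expect_identical(readLines(file.path(d1, "global_measures.tsv")),
                   readLines(file.path(d2, "global_measures.tsv")))
})

test_that("nodal FDR defaults to one pooled family", {
  co <- preset_et_hc(contrast = 1, n1 = 15, n2 = 15, seed = 83)
  adj <- residualize(co, suppressMessages(fit_adjustment(co)))
  res <- permutation_test(adj, R = 100, seed = 13,
                          measures_global = "Average strength",
                          measures_nodal = c("Strength", "Degree"),
                          sw_n_rand_obs = 0, small_sample = TRUE)
  expect_identical(nrow(res$nodal), 44L)
  expect_true(all(c("node", "measure", "p", "fdr_significant") %in%
                    names(res$nodal)))
  # exchangeable groups: expect no significant nodal rows
  tabs <- report_tables(res)
  expect_true(is.null(tabs$nodal) || nrow(tabs$nodal) == 0)
})
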