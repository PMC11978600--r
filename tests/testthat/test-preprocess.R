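make_table <- function(...) dplyr::bind_rows(...)

obs_row <- function(id, visit, var, value, age = 60) {
  tibble::tibble(participant_id = id, visit_index = as.integer(visit),
                 age = age, variable = var, value = value)
}

test_that("coverage filter keeps tests with >= min_n participants per administered visit", {
  tab <- make_table(
    obs_row(sprintf("A%03d", 1:80), 1, "good", rnorm(80)),
    obs_row(sprintf("A%03d", 1:80), 2, "good", rnorm(80)),
    obs_row(sprintf("A%03d", 1:76), 3, "good", rnorm(76)),
    obs_row(sprintf("A%03d", 1:80), 1, "thin", rnorm(80)),
    obs_row(sprintf("A%03d", 1:74), 2, "thin", rnorm(74)))
  out <- filter_low_coverage_tests(tab, min_n = 75)
  expect_setequal(unique(out$table$variable), "good")
  expect_equal(out$qc$removed_variables, "thin")
  # min_n = 0 leaves the table unchanged
  expect_identical(filter_low_coverage_tests(tab, min_n = 0)$table, tab)
  expect_error(filter_low_coverage_tests(tab[0, ]), "empty")
})

test_that("constancy filter removes variables constant in the central percentile band", {
  near_const <- c(rep(0, 96), rep(1, 4))
  tab <- make_table(
    obs_row(sprintf("B%03d", 1:100), 1, "nearly_constant", near_const),
    obs_row(sprintf("B%03d", 1:100), 1, "increasing", seq_len(100)),
    obs_row(sprintf("B%03d", 1:100), 1, "flat", rep(3, 100)))
  # oracle: type-7 quantiles of the 96%-zeros variable give a [0, 0] band
  q <- quantile(near_const, c(0.05, 0.95), type = 7, names = FALSE)
  expect_equal(q, c(0, 0))
  out <- filter_constant_tests(tab)
  expect_setequal(out$qc$removed_variables, c("nearly_constant", "flat"))
  expect_setequal(unique(out$table$variable), "increasing")
})

test_that("IQR mask flags exactly the points beyond the 5x fences", {
  expect_equal(iqr_outlier_mask(1:9), rep(FALSE, 9))
  expect_equal(iqr_outlier_mask(rep(2, 10)), rep(FALSE, 10))   # IQR = 0
  vals <- c(1:20, 1000)
  mask <- iqr_outlier_mask(vals, multiplier = 5)
  # oracle (type-7 quantiles over all 21 values): Q1 = 6, Q3 = 16,
  # fences [-44, 66] -> only 1000 is outside
  q <- quantile(vals, c(.25, .75), type = 7, names = FALSE)
  expect_equal(q, c(6, 16))
  expect_equal(which(mask), 21L)
  expect_warning(iqr_outlier_mask(c(1, 2, 3)), "fewer than 4")
})

test_that("IQR filtering is idempotent and respects the mask", {
  tab <- make_table(
    obs_row(sprintf("C%03d", 1:30), 1, "x", c(rnorm(29), 50)))
  once <- filter_iqr_outliers(tab)$table
  twice <- filter_iqr_outliers(once)$table
  expect_identical(once, twice)
  expect_false(50 %in% once$value)
})

test_that("participants with no usable cognitive data are dropped", {
  tab <- make_table(
    obs_row("P1", 1, "x", 1.5),
    obs_row("P2", 1, "x", NA_real_))
  out <- drop_empty_participants(tab, roster = c("P1", "P2", "P3"))
  expect_equal(unique(out$table$participant_id), "P1")
  expect_setequal(out$qc$removed_participants, c("P2", "P3"))
  # empty removal set leaves the table unchanged
  full <- make_table(obs_row(c("P1", "P2"), 1, "x", c(1, 2)))
  expect_identical(drop_empty_participants(full)$table, full)
})

test_that("ICV normalization is exact, scale-invariant, and reversible", {
  vols <- make_table(obs_row(c("P1", "P2"), 1, "hippocampus",
                             c(1500, 3000)))
  icv <- tibble::tibble(participant_id = c("P1", "P2"),
                        icv = c(1.5e6, 3e6))
  out <- icv_normalize(vols, icv)$table
  expect_equal(out$value, c(1e-3, 1e-3))
  # round trip
  back <- out$value * icv$icv[match(out$participant_id,
                                    icv$participant_id)]
  expect_equal(back, vols$value, tolerance = 1e-12)
  # non-positive ICV excludes the participant with a warning
  icv_bad <- tibble::tibble(participant_id = c("P1", "P2"),
                            icv = c(-1, 3e6))
  expect_warning(res <- icv_normalize(vols, icv_bad), "ICV")
  expect_equal(unique(res$table$participant_id), "P2")
})

test_that("modality matching restricts to the cognitive participant set", {
  cog <- make_table(obs_row(c("P1", "P2"), 1, "x", c(1, 2)))
  mri <- make_table(obs_row(c("P1", "P3"), 1, "vol", c(5, 6)))
  out <- match_modalities(cog, mri = mri)
  expect_equal(unique(out$mri$participant_id), "P1")
  expect_identical(match_modalities(cog, mri = cog)$mri, cog)
  lone <- make_table(obs_row("Q9", 1, "vol", 1))
  expect_error(match_modalities(cog, mri = lone), "no participants")
})

test_that("matched EEG participant count tracks the availability rate", {
  cfg <- cohort_config(n_participants = 582L, eeg_rate = 0.7, seed = 77L)
  co <- generate_cohort(cfg)
  pp <- preprocess_cognitive(co$cognitive,
                             roster = co$participants$participant_id)
  n_cog <- length(unique(pp$table$participant_id))
  n_eeg <- length(unique(
    co$eeg_truth$participant_id[co$eeg_truth$participant_id %in%
                                  unique(pp$table$participant_id)]))
  se <- sqrt(0.7 * 0.3 / n_cog)
  expect_lt(abs(n_eeg / n_cog - 0.7), 3 * se + 0.01)
})

test_that("the preprocessing pipeline applies its rules in order and never imputes", {
  co <- generate_cohort(small_config(seed = 6))
  pp <- preprocess_cognitive(co$cognitive, min_n = 10,
                             roster = co$participants$participant_id)
  expect_named(pp$qc, c("coverage", "constancy", "iqr", "participants"))
  # applying the pipeline twice changes nothing (idempotence)
  again <- preprocess_cognitive(pp$table,
                                min_n = 0)  # coverage already guaranteed
  expect_equal(nrow(again$table), nrow(pp$table))
  # row count never increases at any stage (nothing was filled in)
  expect_lte(nrow(pp$table), nrow(co$cognitive))
})
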