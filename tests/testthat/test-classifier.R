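test_that("high/low merge follows the archetype map and is idempotent", {
  labels <- setNames(c(1L, 2L, 3L, 4L, 2L), sprintf("P%d", 1:5))
  map <- c("1" = "low_stable", "2" = "high_upper", "3" = "low_declining",
           "4" = "high_lower")
  out <- merge_high_low(labels, map)
  expect_equal(out$class, c("low", "high", "low", "high", "high"))
  out2 <- merge_high_low(labels[c(3, 1, 5, 2, 4)], map)
  expect_setequal(paste(out$participant_id, out$class),
                  paste(out2$participant_id, out2$class))
  expect_error(merge_high_low(labels, c(map[-1], "1" = "mystery")),
               "unknown archetype")
})

test_that("default cohort class sizes track the 392/134 high/low split", {
  co <- generate_cohort(cohort_config(seed = 41L))
  cls <- ifelse(grepl("^high", co$truth$archetype), "high", "low")
  p_high <- mean(cls == "high")
  expect_lt(abs(p_high - (256 + 136) / 526), 3 * sqrt(0.745 * 0.255 / 582))
})

test_that("first-visit features pick the earliest visit and mean-impute gaps", {
  tab <- tibble::tibble(
    participant_id = c("A", "A", "B", "B", "C"),
    visit_index = c(2L, 3L, 1L, 1L, 3L),
    age = c(62, 67, 58, 58, 67),
    variable = c("v1", "v1", "v1", "v2", "v1"),
    value = c(10, 11, 1, 2, 5))
  X <- first_visit_features(tab)
  expect_equal(X["A", "v1"], 10)          # visit 2 selected over visit 3
  expect_equal(X["C", "v1"], 5)           # single visit
  expect_equal(attr(X, "visit_used")[["A"]], 2L)
  # v2 missing for A and C at their first visits -> imputed to B's value
  expect_equal(X["A", "v2"], 2)
  expect_equal(attr(X, "n_imputed"), 2)
  expect_error(first_visit_features(tab[0, ]), "no participants")
})

test_that("ridge logistic respects monotonicity, symmetry, and guards", {
  # separable 1-d data: probabilities ordered with the feature
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c("low", "low", "low", "high", "high", "high")
  fit <- suppressWarnings(fit_logistic(x, factor(y, c("low", "high"))))
  p <- predict_logistic(fit, x)
  expect_true(all(diff(p) > 0))
  # duplicated standardized feature splits weight symmetrically
  set.seed(401)
  z <- rnorm(200)
  yy <- rbinom(200, 1, 1 / (1 + exp(-2 * z)))
  X2 <- cbind(a = z, b = z)
  f2 <- fit_logistic(X2, yy, l2 = 0.05)
  expect_equal(f2$coefficients[["a"]], f2$coefficients[["b"]],
               tolerance = 1e-4)
  # zero-variance feature gets coefficient 0 through the guard
  X3 <- cbind(a = z, flat = 1)
  f3 <- fit_logistic(X3, yy)
  expect_equal(f3$coefficients[["flat"]], 0)
  expect_error(fit_logistic(x, rep("low", 6)), "two classes")
})

test_that("AUC equals the trapezoidal ROC area and handles ties", {
  # all-tied scores: AUC exactly 0.5
  r <- roc_auc(rep(1, 40), rep(c("low", "high"), 20))
  expect_equal(r$auc, 0.5)
  # perfect separation
  r2 <- roc_auc(c(1:10, 21:30), rep(c("low", "high"), each = 10),
                positive = "high")
  expect_equal(r2$auc, 1)
  # oracle equivalence on random data, including ties
  set.seed(402)
  for (i in 1:20) {
    s <- sample(round(rnorm(100), 1))   # rounding induces ties
    y <- sample(c("low", "high"), 100, replace = TRUE, prob = c(.6, .4))
    rr <- roc_auc(s, factor(y, c("low", "high")))
    expect_equal(rr$auc, roc_trapezoid_area(rr), tolerance = 1e-12)
    expect_true(all(diff(rr$tpr) >= 0), all(diff(rr$fpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep("low", 5)), "two classes")
})

test_that("AUC agrees with an independent implementation and monotone invariance", {
  skip_if_not_installed("pROC")
  set.seed(403)
  s <- rnorm(300)
  y <- rbinom(300, 1, 1 / (1 + exp(-s)))
  mine <- roc_auc(s, factor(y, c(0, 1)))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(roc_auc(exp(s), factor(y, c(0, 1)))$auc, mine,
               tolerance = 1e-12)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(404)
  s <- rnorm(500)
  y <- rep(c("low", "high"), 250)
  aucs <- replicate(200, roc_auc(s, sample(y))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("univariate scan ranks scores by effect size and is direction-corrected", {
  set.seed(405)
  n <- 500
  ids <- sprintf("P%03d", 1:n)
  y <- rep(c("low", "high"), length.out = n)
  eff <- c(strong = 2, medium = 1, weak = 0.4, null = 0)
  tab <- dplyr::bind_rows(lapply(names(eff), function(v) {
    sgn <- if (v == "medium") -1 else 1   # a higher-is-worse style score
    tibble::tibble(participant_id = ids, visit_index = 1L, age = 60,
                   variable = v,
                   value = sgn * (eff[[v]] * (y == "high") + rnorm(n)))
  }))
  lab <- tibble::tibble(participant_id = ids, class = y)
  scan <- univariate_auc_scan(tab, lab)
  expect_equal(scan$variable, c("strong", "medium", "weak", "null"))
  expect_true(all(scan$auc >= 0.5))
  expect_lt(abs(scan$auc[scan$variable == "null"] - 0.5), 0.06)
  # a score equal to the label separates perfectly
  perfect <- tibble::tibble(participant_id = ids, visit_index = 1L,
                            age = 60, variable = "oracle",
                            value = as.numeric(y == "high"))
  expect_equal(univariate_auc_scan(perfect, lab)$auc, 1)
})

test_that("modality comparison ranks per-modality models and supports CV", {
  set.seed(406)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  y <- rep(c("low", "high"), length.out = n)
  mk <- function(name, effect, p) {
    dplyr::bind_rows(lapply(seq_len(p), function(j) {
      tibble::tibble(participant_id = ids, visit_index = 1L, age = 60,
                     variable = sprintf("%s_%02d", name, j),
                     value = effect * (y == "high") + rnorm(n))
    }))
  }
  tabs <- list(strong = mk("s", 1.5, 3), weak = mk("w", 0.3, 3))
  lab <- tibble::tibble(participant_id = ids, class = y)
  res <- modality_auc_comparison(tabs, lab)
  expect_equal(names(res), c("strong", "weak"))
  expect_gt(res$strong$auc, res$weak$auc)
  cvres <- modality_auc_comparison(tabs, lab, cv_folds = 5)
  expect_lt(cvres$strong$auc, res$strong$auc + 1e-9)  # CV not optimistic
})
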