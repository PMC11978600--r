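test_that("default wave arithmetic yields 582 unique participants", {
  cfg <- cohort_config()
  expect_equal(cfg$n_participants, 582L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$participants), 582L)
  expect_equal(length(unique(co$visits$participant_id)), 582L)
  # per-wave visit counts match the configured wave sizes
  expect_equal(unname(table(co$visits$wave)), c(211L, 503L, 113L),
               ignore_attr = TRUE)
  # truth labels cover all participants exactly once
  expect_equal(sort(co$truth$participant_id),
               sort(co$participants$participant_id))
})

test_that("inconsistent wave arithmetic is rejected with the offending numbers", {
  expect_error(cohort_config(n_participants = 500L),
               "wave arithmetic inconsistent.*582")
  expect_error(cohort_config(wave_overlaps = c(300L, 99L, 10L)),
               "overlap")
})

test_that("participant visit structure satisfies its invariants", {
  co <- generate_cohort(small_config(seed = 3))
  by_p <- split(co$visits, co$visits$participant_id)
  lens <- vapply(by_p, nrow, integer(1))
  expect_true(all(lens >= 1 & lens <= 3))
  for (d in by_p) {
    expect_true(all(diff(d$age) > 0))
    expect_true(all(d$age >= 57 & d$age <= 68))
    expect_true(all(diff(d$visit_index) > 0))
  }
})

test_that("same seed reproduces the cohort byte-identically; seeds differ", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(small_config(seed = 7))
  expect_identical(a$cognitive, b$cognitive)
  expect_identical(a$participants, b$participants)
  expect_identical(a$risk_factors, b$risk_factors)
  c8 <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$participants$archetype,
                         c8$participants$archetype))
})

test_that("a minimal one-wave cohort is generated", {
  cfg <- cohort_config(n_participants = 1L, wave_sizes = c(1L, 0L, 0L),
                       wave_overlaps = c(0L, 0L, 0L),
                       cognitive_dropout_rate = 0, missing_rate = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$participants), 1L)
  expect_gte(nrow(co$visits), 1L)
})

test_that("noiseless scores reproduce latent trajectories through the loadings", {
  cfg <- small_config(seed = 2)
  co <- generate_cohort(cfg)
  loading <- default_loading(cfg$n_cognitive_scores,
                             cfg$loading_matrix_rank, cfg$seed)
  tab <- generate_cognitive_scores(co, loading = loading, noise_sd = 0)
  catalog <- cognitive_score_catalog()[seq_len(cfg$n_cognitive_scores), ]
  v <- catalog$variable[1]
  dir <- if (catalog$higher_is_worse[1]) -1 else 1
  got <- tab$value[tab$variable == v]
  keys <- paste(tab$participant_id[tab$variable == v],
                tab$visit_index[tab$variable == v])
  Z <- as.matrix(co$latent[match(keys, paste(co$latent$participant_id,
                                             co$latent$visit_index)),
                           c("z1", "z2")])
  expect_equal(got, dir * as.numeric(Z %*% loading[1, ]), tolerance = 1e-12)
})

test_that("a flagged latency test increases over visits for a declining participant", {
  cfg <- small_config(seed = 4)
  co <- generate_cohort(cfg)
  tab <- generate_cognitive_scores(co, noise_sd = 0)
  catalog <- cognitive_score_catalog()
  flagged <- catalog$variable[catalog$higher_is_worse][1]   # a latency score
  decl <- co$participants$participant_id[
    co$participants$archetype == "low_declining" &
      co$participants$n_visits >= 2]
  skip_if(length(decl) == 0, "no multi-visit declining participant drawn")
  d <- tab[tab$participant_id == decl[1] & tab$variable == flagged, ]
  d <- d[order(d$visit_index), ]
  expect_true(all(diff(d$value) > 0))
})

test_that("empirical between-test covariance approaches the loading-implied analytic form", {
  # large single-archetype cohort: covariance of scores for fixed archetype
  # is L V L' + noise^2 I with V the within-archetype latent covariance
  arch <- default_archetypes()
  one <- arch[arch$name == "high_upper", ]
  one$mixing_weight <- 1
  cfg <- cohort_config(n_participants = 5000L,
                       wave_sizes = c(5000L, 0L, 0L),
                       wave_overlaps = c(0L, 0L, 0L),
                       n_cognitive_scores = 6L,
                       cognitive_dropout_rate = 0, missing_rate = 0,
                       noise_sd = 0.5, archetypes = one, seed = 31L)
  co <- generate_cohort(cfg)
  tab <- co$cognitive
  fm <- feature_matrix(tab)
  emp <- stats::cov(fm$X)
  L <- default_loading(6L, 2L, cfg$seed)
  catalog <- cognitive_score_catalog()[1:6, ]
  dirs <- ifelse(catalog$higher_is_worse, -1, 1)
  Ld <- L * dirs
  V <- diag(c(0.25^2 + 0.10^2, 0.25^2 + 0.10^2))  # intercept + visit noise
  ana <- Ld %*% V %*% t(Ld) + 0.5^2 * diag(6)
  expect_lt(max(abs(emp - ana)), 6 * max(ana) / sqrt(5000) * 3)
})

test_that("ventricles expand and neocortex atrophies as designed", {
  cfg <- small_config(seed = 9)
  co <- generate_cohort(cfg)
  # noiseless, to read the slopes directly
  mri <- generate_mri(co, noise_sd_log = 0)
  vent <- mri$volumes[mri$volumes$variable == "lateral_ventricle", ]
  for (d in split(vent, vent$participant_id)) {
    if (nrow(d) >= 2) expect_true(all(diff(d$value[order(d$age)]) > 0))
  }
  # zero atrophy, zero noise -> constant volumes across visits
  frozen <- generate_mri(co, atrophy_scale = 0, noise_sd_log = 0,
                         decline_slope_boost = 0)
  cor_vol <- frozen$volumes[frozen$volumes$variable == "hippocampus", ]
  for (d in split(cor_vol, cor_vol$participant_id)) {
    if (nrow(d) >= 2) expect_equal(diff(d$value), rep(0, nrow(d) - 1),
                                   tolerance = 1e-12)
  }
  # ICV constant across visits by construction (one value per participant)
  expect_equal(nrow(mri$icv), nrow(co$participants))
})

test_that("neocortical atrophy slope is steeper for low_declining than high_upper", {
  cfg <- cohort_config(n_participants = 2000L,
                       wave_sizes = c(2000L, 2000L, 0L),
                       wave_overlaps = c(2000L, 0L, 0L),
                       cognitive_dropout_rate = 0, missing_rate = 0,
                       seed = 17L)
  co <- generate_cohort(cfg)
  mri <- generate_mri(co, noise_sd_log = 0.01)
  reg <- mri$volumes[mri$volumes$variable == "frontal_cortex", ]
  slope_of <- vapply(split(reg, reg$participant_id), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    unname(coef(stats::lm(log(value) ~ age, d))[2])
  }, numeric(1))
  arch <- co$participants$archetype[match(names(slope_of),
                                          co$participants$participant_id)]
  s_decl <- slope_of[arch == "low_declining"]
  s_high <- slope_of[arch == "high_upper"]
  tt <- stats::t.test(s_decl, s_high)
  expect_lt(tt$p.value, 1e-6)
  expect_lt(mean(s_decl, na.rm = TRUE), mean(s_high, na.rm = TRUE))
})

test_that("risk factors follow their configured prevalences", {
  # prevalence 1 -> everyone "yes"
  prev <- default_risk_prevalences()
  prev$binary$prevalence[prev$binary$variable == "alcohol_use"] <- 1
  co <- generate_cohort(small_config(seed = 5))
  rf <- generate_risk_factors(co, prev)
  expect_true(all(rf$alcohol_use == "yes"))
  # out-of-range prevalence is rejected
  prev$binary$prevalence[1] <- 1.2
  expect_error(generate_risk_factors(co, prev), "\\[0, 1\\]")
})

test_that("large-sample risk-factor moments match the printed group statistics", {
  cfg <- cohort_config(n_participants = 5000L,
                       wave_sizes = c(5000L, 0L, 0L),
                       wave_overlaps = c(0L, 0L, 0L),
                       n_cognitive_scores = 5L,
                       cognitive_dropout_rate = 0, missing_rate = 0,
                       seed = 23L)
  co <- generate_cohort(cfg)
  rf <- co$risk_factors
  hl <- rf[rf$archetype == "high_lower", ]
  # alcohol yes-fraction in high_lower ~ 128/136
  expect_lt(abs(mean(hl$alcohol_use == "yes") - 128 / 136), 0.03)
  # IQ means ordered high_upper > high_lower > low groups
  iq <- tapply(rf$iq, rf$archetype, mean)
  expect_gt(iq[["high_upper"]], iq[["high_lower"]])
  expect_gt(iq[["high_lower"]], max(iq[["low_stable"]],
                                    iq[["low_declining"]]))
})

test_that("missingness removal is MCAR at the requested rate and seeded", {
  tab <- long_from_matrix(matrix(rnorm(10000), nrow = 100))
  expect_identical(apply_missingness(tab, 0, seed = 1), tab)
  out <- apply_missingness(tab, 0.3, seed = 42)
  expect_lt(abs(1 - nrow(out) / nrow(tab) - 0.3), 0.02)
  expect_identical(out, apply_missingness(tab, 0.3, seed = 42))
  expect_false(identical(out, apply_missingness(tab, 0.3, seed = 43)))
  # visit-level removal drops whole participant-visit blocks
  outv <- apply_missingness(tab, 0.4, seed = 1, level = "visit")
  kept <- table(outv$participant_id)
  expect_true(all(kept == 100))
})
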