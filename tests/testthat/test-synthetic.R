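test_that("generation is a pure function of config and seed", {
  cfg <- population_config(n_subjects = 20, seed = 42)
  a <- sample_population(cfg, build_landmarks = FALSE)
  b <- sample_population(cfg, build_landmarks = FALSE)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$subjects_df, b$subjects_df)
  fa <- sample_flexext(cfg); fb <- sample_flexext(cfg)
  expect_identical(fa$metrics, fb$metrics)
})

test_that("config validation names the offending fields", {
  expect_error(population_config(n_subjects = 0), "n_subjects")
  expect_error(population_config(degeneration = list(prevalence = 1.5,
                                                     height_shift_sd = -3,
                                                     flag_sensitivity = .8,
                                                     flag_fp = .05)),
               "prevalence")
  expect_error(population_config(flexext = list(da_flexion = c(5, -8),
                                                da_extension = c(5, 18))),
               "ranges")
})

test_that("degeneration prevalence and flags behave as configured", {
  cfg1 <- population_config(n_subjects = 400, seed = 1,
                            degeneration = list(prevalence = 1))
  p1 <- sample_population(cfg1, build_landmarks = FALSE)
  expect_true(all(p1$metrics$is_degenerated))
  # severity-coupled flags: marginal sensitivity E[min(1, 0.8 s)], s~U(0.5,1.5)
  expect_lt(abs(mean(p1$metrics$osteo_flag) - 0.775), 0.03)

  cfg0 <- population_config(n_subjects = 2000, seed = 2,
                            degeneration = list(prevalence = 0),
                            age_effect = list(enabled = FALSE, b0 = 0, b1 = 0))
  p0 <- sample_population(cfg0, build_landmarks = FALSE)
  expect_false(any(p0$metrics$is_degenerated))
  expect_lt(abs(mean(p0$metrics$osteo_flag) - 0.05), 0.01)
  # prevalence 0 + age effect off: avg_dh is Gaussian per level
  x <- p0$metrics$avg_dh[p0$metrics$level_name == "L3L4"]
  expect_lt(abs(descriptive_stats(x)$skewness), 0.1)
  expect_lt(abs(mean(x) - 30), 0.3)
})

test_that("the age effect lowers disc height in the old per the exponential model", {
  cfg <- population_config(n_subjects = 4000, seed = 3,
                           degeneration = list(prevalence = 0))
  p <- sample_population(cfg, build_landmarks = FALSE)
  m <- p$metrics
  old <- m$avg_dh[m$age > 70]; young <- m$avg_dh[m$age < 40]
  # expected shift at the oldest ages approaches b0*exp(b1*74) ~ -1.19 z units
  expect_lt(mean(old) - mean(young), -1.5)
})

test_that("metric targets round-trip exactly through landmark construction", {
  set.seed(53)
  worst <- 0
  for (i in 1:200) {
    tg <- random_targets()
    lv <- metrics_to_landmarks(tg)
    m <- level_metrics(lv)
    worst <- max(worst,
                 abs(m$adh - tg$adh), abs(m$pdh - tg$pdh),
                 abs(m$aspo - tg$aspo), abs(m$pspo - tg$pspo),
                 abs(m$hw_ratio - tg$hw_ratio),
                 abs(m$epwr - implied_epwr(tg$adh, tg$pdh, tg$aspo, tg$pspo)))
  }
  expect_lt(worst, 1e-9)
})

test_that("infeasible targets are rejected with explanatory errors", {
  tg <- random_targets()
  tg$adh <- -5
  expect_error(metrics_to_landmarks(tg), "heights")
  tg2 <- list(adh = 20, pdh = 20, aspo = -60, pspo = -60, epwr = 1, hw_ratio = 0.6)
  expect_error(metrics_to_landmarks(tg2), "collapses")
  tg3 <- list(adh = 20, pdh = 20, aspo = 0, pspo = 0, epwr = 3, hw_ratio = 0.3)
  expect_error(metrics_to_landmarks(tg3), "wall length")
})

test_that("full loop: sampled method-1 metrics are recovered from landmarks", {
  cfg <- population_config(n_subjects = 60, seed = 63)
  pop <- sample_population(cfg)
  tab <- metrics_table(pop$subjects)
  truth <- pop$metrics
  key_t <- paste(truth$subject_id, truth$level_name)
  key_m <- paste(tab$subject_id, tab$level_name)
  idx <- match(key_m, key_t)
  for (col in c("adh", "pdh", "avg_dh", "da", "aspo", "pspo", "hw_ratio"))
    expect_lt(max(abs(tab[[col]] - truth[[col]][idx])), 1e-9)
  expect_identical(tab$osteo_flag, truth$osteo_flag[idx])
})

test_that("injected slips carry their labels and configured magnitude", {
  cfg <- population_config(n_subjects = 2000, seed = 73,
                           injection = list(antero_frac = 0.05,
                                            retro_frac = 0.05, shift = 3),
                           degeneration = list(prevalence = 0),
                           age_effect = list(enabled = FALSE, b0 = 0, b1 = 0))
  p <- sample_population(cfg, build_landmarks = FALSE)
  m <- p$metrics
  expect_lt(abs(mean(m$injected == "antero") - 0.05), 0.01)
  # injected residual replaced by shift*sigma: true ASPO exceeds the normal
  # prediction by exactly 3 * 1.5 on every injected level
  for (ln in unique(m$level_name)) {
    inj <- m$aspo[m$injected == "antero" & m$level_name == ln]
    nrm <- m$aspo[m$injected == "none" & m$level_name == ln]
    expect_gt(mean(inj) - mean(nrm), 3.5)
  }
})

test_that("paired flexion-extension exams share discs but differ in angle range", {
  cfg <- population_config(n_subjects = 161, seed = 83)
  fx <- sample_flexext(cfg)
  m <- fx$metrics
  expect_equal(nrow(m), 161 * 5 * 2)
  expect_equal(sum(m$position == "flexion"), 805)
  fl <- m[m$position == "flexion", ]; ex <- m[m$position == "extension", ]
  expect_identical(fl$subject_id, ex$subject_id)
  expect_equal(fl$avg_dh, ex$avg_dh, tolerance = 1e-12)  # disc-intrinsic, shared
  expect_true(all(ex$da >= fl$da - 26))
  # normal discs only: flex/ext spans a far wider angle range than side-lying
  side <- sample_population(population_config(n_subjects = 161, seed = 83),
                            build_landmarks = FALSE)$metrics
  nrm <- m[!m$is_degenerated, ]
  expect_gt(var(c(nrm$da[nrm$position == "flexion"],
                  nrm$da[nrm$position == "extension"])),
            var(side$da[!side$is_degenerated]))
})
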