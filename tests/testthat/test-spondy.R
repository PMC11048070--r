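# SpondyIndex training, scoring and the position-dependence failure mode.

flexext_fixture <- function(n = 800, seed = 11, ...) {
  cfg <- population_config(n_subjects = n, seed = seed,
                           degeneration = list(prevalence = 0), ...)
  sample_flexext(cfg)$metrics
}

true_spondy_coefficients <- function(cfg = population_config(), target = "aspo") {
  s <- cfg$spo
  if (target == "aspo") c(disc_area = s$a_area, adh = s$a_adh, pdh = s$a_pdh,
                          epwr = 0)
  else c(disc_area = s$p_area, adh = s$p_adh, pdh = s$p_pdh, epwr = 0)
}

test_that("training recovers the generative coefficients within their 95% CIs", {
  m <- flexext_fixture(n = 200, seed = 11)   # 2000 levels
  for (target in c("aspo", "pspo")) {
    model <- train_spondy_index(m, target)
    fit <- attr(model, "fit")
    ci <- confint(fit)
    truth <- true_spondy_coefficients(target = target)
    for (nm in names(truth)) {
      expect_gt(truth[[nm]], ci[nm, 1])
      expect_lt(truth[[nm]], ci[nm, 2])
    }
  }
})

test_that("a degenerate target (identical to a predictor) is flagged", {
  m <- flexext_fixture(n = 30, seed = 13)
  m$aspo <- m$adh   # target identical to one predictor
  expect_error(train_spondy_index(m, "aspo"), "degenerate residual scale")
})

test_that("too few rows for the design is an error", {
  m <- flexext_fixture(n = 1, seed = 17)[1:8, ]
  expect_error(train_spondy_index(m, "aspo"), "too few rows")
})

test_that("the index is centred and unit-scaled on its own training set", {
  m <- flexext_fixture(n = 400, seed = 19)
  model <- train_spondy_index(m, "aspo")
  si <- spondy_index(m, model)
  for (ln in unique(m$level_name)) {
    expect_lt(abs(mean(si[m$level_name == ln])), 0.05)
    expect_lt(abs(sd(si[m$level_name == ln]) - 1), 0.06)
  }
})

test_that("held-out normal levels have the Gaussian one-sided tail at SI > 2", {
  model <- train_spondy_index(flexext_fixture(n = 200, seed = 23), "aspo")
  held <- flexext_fixture(n = 1000, seed = 29)
  si <- spondy_index(held, model)
  expect_lt(abs(mean(si > 2) * 100 - 2.5), 1)
})

test_that("injected anterolisthesis of +3 residual SD is detected at SI > 2", {
  model <- train_spondy_index(flexext_fixture(n = 200, seed = 31), "aspo")
  cfg <- population_config(n_subjects = 400, seed = 37,
                           injection = list(antero_frac = 0.2, retro_frac = 0,
                                            shift = 3),
                           degeneration = list(prevalence = 0))
  m <- sample_flexext(cfg)$metrics
  si <- spondy_index(m, model)
  det <- mean(si[m$injected == "antero"] > 2)
  expect_gte(det, 0.9)
  expect_lt(mean(si[m$injected == "none"] > 2), 0.05)
})

test_that("scoring a level unseen in training errors", {
  m <- flexext_fixture(n = 50, seed = 41)
  model <- train_spondy_index(m[m$level_name != "L5S1", ], "aspo")
  expect_error(spondy_index(m, model), "unseen")
})

test_that("neutral z-scored SPO breaks on flexed spines while the index holds", {
  # reference built from the side-lying population (narrow disc angles)
  cfg_ref <- population_config(n_subjects = 1500, seed = 43,
                               degeneration = list(prevalence = 0),
                               age_effect = list(enabled = FALSE, b0 = 0, b1 = 0))
  neutral <- sample_population(cfg_ref, build_landmarks = FALSE)$metrics
  tr <- trim_population(neutral)
  ref <- build_reference(tr$kept, metric_names = c("aspo", "pspo"))

  flexed <- flexext_fixture(n = 300, seed = 47)
  flexed <- flexed[flexed$position == "flexion", ]
  z <- score_metrics(flexed, ref)
  naive_abnormal <- abs(z$z_aspo) > 2 | abs(z$z_pspo) > 2
  expect_gt(mean(naive_abnormal), 0.20)

  model_a <- train_spondy_index(flexext_fixture(n = 200, seed = 53), "aspo")
  model_p <- train_spondy_index(flexext_fixture(n = 200, seed = 53), "pspo")
  expect_lte(mean(abs(spondy_index(neutral, model_a)) > 2), 0.07)
  expect_lte(mean(abs(spondy_index(neutral, model_p)) > 2), 0.07)
})
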