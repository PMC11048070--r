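test_that("zero pose projects to a uniformly magnified, metric-exact silhouette", {
  lv <- rectangle_level()
  ph <- make_phantom(lv, half_width = 10, pose = c(axial = 0, coronal = 0))
  geo <- projection_geometry(sdd = 1016, odd = 150)
  pr <- project_phantom(ph, geo)
  meas <- collapse_landmarks(pr, "L3L4")
  m0 <- unlist(level_metrics(lv))
  m1 <- unlist(level_metrics(meas))
  expect_lt(max(abs(m1 - m0)), 1e-9)
})

test_that("a planar object parallel to the detector magnifies by sdd/(sdd-odd)", {
  lv <- rectangle_level()
  ph <- make_phantom(lv, half_width = 0)
  geo <- projection_geometry(sdd = 1000, odd = 200)
  pr <- project_phantom(ph, geo)
  # all inter-point distances scale by 1000/800
  w <- sqrt(diff(pr$u[c(1, 3)])^2 + diff(pr$v[c(1, 3)])^2)
  expect_equal(w, 20 * 1000 / 800, tolerance = 1e-9)
  # doubling the source distance pulls magnification toward 1
  geo2 <- projection_geometry(sdd = 2000, odd = 200)
  pr2 <- project_phantom(ph, geo2)
  w2 <- sqrt(diff(pr2$u[c(1, 3)])^2 + diff(pr2$v[c(1, 3)])^2)
  expect_lt(abs(w2 / 20 - 1), abs(w / 20 - 1))
  # orthographic limit: parallel projection, no magnification
  pr3 <- project_phantom(ph, projection_geometry(sdd = Inf, odd = 200))
  w3 <- sqrt(diff(pr3$u[c(1, 3)])^2 + diff(pr3$v[c(1, 3)])^2)
  expect_equal(w3, 20, tolerance = 1e-12)
})

test_that("points at or behind the source are rejected", {
  lv <- rectangle_level()
  ph <- make_phantom(lv, half_width = 300)
  expect_error(project_phantom(ph, projection_geometry(sdd = 400, odd = 200)),
               "behind the source")
})

test_that("axial rotation separates lateral corner pairs symmetrically in sign", {
  lv <- rectangle_level()
  geo <- projection_geometry()
  err_of <- function(ax) {
    ph <- make_phantom(lv, 10, pose = c(axial = ax, coronal = 0))
    meas <- collapse_landmarks(project_phantom(ph, geo), "L3L4")
    unlist(level_metrics(meas)) - unlist(level_metrics(lv))
  }
  e0 <- err_of(0); e10 <- err_of(10); em10 <- err_of(-10)
  expect_lt(max(abs(e0)), 1e-9)
  expect_gt(max(abs(e10)), 1e-6)        # out-of-plane pose does err
  # flipping the rotation sign views the segment from the other side, which
  # swaps the anterior/posterior roles: symmetric metrics have even errors,
  # corner metrics swap, the disc-angle error is odd
  expect_equal(e10[["avg_dh"]], em10[["avg_dh"]], tolerance = 1e-9)
  expect_equal(e10[["adh"]], em10[["pdh"]], tolerance = 1e-9)
  expect_equal(e10[["aspo"]], em10[["pspo"]], tolerance = 1e-9)
  expect_equal(e10[["da"]], -em10[["da"]], tolerance = 1e-9)
  expect_equal(max(abs(e10)), max(abs(em10)), tolerance = 1e-9)
})

test_that("coronal tilt shifts collapsed landmarks vertically off truth", {
  lv <- rectangle_level()
  ph <- make_phantom(lv, 10, pose = c(axial = 0, coronal = 15))
  meas <- collapse_landmarks(project_phantom(ph, projection_geometry()), "L3L4")
  m <- level_metrics(meas)
  expect_gt(abs(m$avg_dh - 30), 1e-4)
})

test_that("the error study is exact at zero pose and grows along the pose grid", {
  cfg <- population_config(n_subjects = 300, seed = 61,
                           degeneration = list(prevalence = 0),
                           age_effect = list(enabled = FALSE, b0 = 0, b1 = 0))
  pop <- sample_population(cfg, build_landmarks = FALSE)
  ref <- build_reference(pop$metrics,
                         metric_names = c("adh", "pdh", "avg_dh", "da",
                                          "aspo", "pspo"))
  study <- projection_error_study(ref, config = cfg,
                                  poses = data.frame(axial = c(0, 10, 20),
                                                     coronal = c(0, 10, 20)),
                                  n_phantoms = 25, seed = 71)
  z0 <- study[study$axial == 0, ]
  expect_lt(max(z0$max_err), 1e-6)
  for (mc in unique(study$metric)) {
    med <- study$median_err[study$metric == mc]
    expect_true(all(diff(med) >= -1e-12))
  }
  expect_gt(max(study$p95_err[study$axial == 20]), 0.5)
})
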