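test_that("rectangle fixture yields the exact analytic metric values", {
  m <- level_metrics(rectangle_level())
  expect_equal(m$adh, 30); expect_equal(m$pdh, 30)
  expect_equal(m$vdh, 30); expect_equal(m$ddh, 30)
  expect_equal(m$avg_dh, 30)
  expect_equal(m$da, 0);  expect_equal(m$mpa, 0)
  expect_equal(m$aspo, 0); expect_equal(m$pspo, 0); expect_equal(m$cspo, 0)
  expect_equal(m$disc_area, 0.30)
  expect_equal(m$epwr, 1.0)
  expect_equal(m$hw_ratio, 0.6)
})

test_that("endplate widths are Euclidean corner distances and reject degeneracy", {
  v <- vertebra_landmarks("L3", c(10, 1), c(-10, 0), c(10, -12), c(-10, -12))
  expect_equal(endplate_width(v, "superior"), sqrt(401))
  expect_equal(endplate_width(v, "inferior"), 20)
  degen <- vertebra_landmarks("L3", c(0, 1), c(0, 1), c(1, -1), c(-1, -1),
                              check_frame = FALSE)
  expect_error(endplate_width(degen, "superior"), "degenerate")
})

test_that("anterior translation of the superior vertebra moves offsets, not heights", {
  lv <- rectangle_level()
  for (nm in c("as_pt", "ps_pt", "ai_pt", "pi_pt"))
    lv$sup[[nm]] <- lv$sup[[nm]] + c(2, 0)
  m <- level_metrics(lv)
  expect_equal(m$aspo, 10)
  expect_equal(m$pspo, -10)   # posterior corner moved anteriorly
  expect_equal(m$cspo, 10)
  expect_equal(m$adh, 30); expect_equal(m$pdh, 30)
  expect_equal(m$vdh, 30); expect_equal(m$ddh, 30)
})

test_that("rotating the superior vertebra opens the disc angle with positive sign", {
  lv <- rectangle_level()
  th <- 5 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ctr <- c(0, 6)  # midpoint of the superior vertebra's inferior endplate
  for (nm in c("as_pt", "ps_pt", "ai_pt", "pi_pt"))
    lv$sup[[nm]] <- drop(R %*% (lv$sup[[nm]] - ctr)) + ctr
  m <- level_metrics(lv)
  expect_equal(m$da, 5, tolerance = 1e-9)
  expect_equal(m$mpa, 5, tolerance = 1e-9)
  expect_gt(m$adh, m$pdh)   # anterior opens
})

test_that("rotation about the superior centroid tilts the bisectrix and offsets the feet", {
  # the centroids stay put but the bisectrix rotates by theta/2, so the feet
  # of the centroid perpendiculars separate by |c_sup - c_inf| sin(theta/2)
  lv <- rectangle_level()
  th <- 5 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ctr <- c(0, 12)
  for (nm in c("as_pt", "ps_pt", "ai_pt", "pi_pt"))
    lv$sup[[nm]] <- drop(R %*% (lv$sup[[nm]] - ctr)) + ctr
  m <- level_metrics(lv)
  expect_equal(m$mpa, 5, tolerance = 1e-9)
  expect_equal(m$cspo, 18 * sin(2.5 * pi / 180) / 20 * 100, tolerance = 1e-9)
})

test_that("midplane passes through both wall midpoints; bisectrix handles all cases", {
  v <- vertebra_landmarks("L3", c(10, 18), c(-10, 18), c(10, 6), c(-10, 6))
  mp <- vertebral_midplane(v)
  expect_equal(abs(sum((c(0, 12) - mp$point) * c(-mp$dir[2], mp$dir[1]))), 0)
  expect_equal(mp$dir, c(1, 0))

  # parallel case: lines y = 12 and y = -6 -> y = 3
  b <- bisectrix(list(point = c(0, 12), dir = c(1, 0)),
                 list(point = c(5, -6), dir = c(1, 0)))
  expect_equal(b$point[2], 3)
  expect_equal(b$dir, c(1, 0))

  # symmetric +/- 10 degrees through the origin -> x axis
  th <- 10 * pi / 180
  b2 <- bisectrix(list(point = c(0, 0), dir = c(cos(th), sin(th))),
                  list(point = c(0, 0), dir = c(cos(th), -sin(th))))
  expect_equal(b2$dir, c(1, 0))
  expect_equal(abs(b2$point[2]), 0)

  # y = 0 and y = x -> line through origin at 22.5 degrees
  b3 <- bisectrix(list(point = c(0, 0), dir = c(1, 0)),
                  list(point = c(0, 0), dir = c(1, 1) / sqrt(2)))
  expect_equal(atan2(b3$dir[2], b3$dir[1]) * 180 / pi, 22.5)
})

test_that("cspo equals the brute-force distance between projected centroid feet", {
  set.seed(11)
  for (i in 1:200) {
    lv <- random_level()
    m_sup <- vertebral_midplane(lv$sup); m_inf <- vertebral_midplane(lv$inf)
    bis <- bisectrix(m_sup, m_inf)
    cen <- function(v) (v$as_pt + v$ps_pt + v$ai_pt + v$pi_pt) / 4
    foot <- function(p) bis$point + sum((p - bis$point) * bis$dir) * bis$dir
    f1 <- foot(cen(lv$sup)); f2 <- foot(cen(lv$inf))
    d <- sqrt(sum((f1 - f2)^2)) / endplate_width(lv$inf, "superior") * 100
    expect_equal(abs(method2_metrics(lv)$cspo), d, tolerance = 1e-9)
  }
})

test_that("all metrics are invariant under rigid motion plus uniform scaling", {
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    lv <- random_level()
    m0 <- unlist(level_metrics(lv))
    lv2 <- transform_level(lv, theta = runif(1, -pi, pi),
                           shift = runif(2, -100, 100),
                           scale = runif(1, 0.2, 5))
    worst <- max(worst, abs(unlist(level_metrics(lv2)) - m0))
  }
  expect_lt(worst, 1e-9)
})

test_that("mirror reflection swaps anterior/posterior roles and negates angles", {
  set.seed(31)
  for (i in 1:50) {
    lv <- random_level()
    m <- unlist(level_metrics(lv))
    mm <- unlist(level_metrics(mirror_level(lv)))
    expect_equal(mm[["aspo"]], m[["pspo"]], tolerance = 1e-9)
    expect_equal(mm[["pspo"]], m[["aspo"]], tolerance = 1e-9)
    expect_equal(mm[["adh"]], m[["pdh"]], tolerance = 1e-9)
    expect_equal(mm[["pdh"]], m[["adh"]], tolerance = 1e-9)
    expect_equal(mm[["vdh"]], m[["ddh"]], tolerance = 1e-9)
    expect_equal(mm[["da"]], -m[["da"]], tolerance = 1e-9)
    expect_equal(mm[["mpa"]], -m[["mpa"]], tolerance = 1e-9)
    expect_equal(mm[["cspo"]], -m[["cspo"]], tolerance = 1e-9)
    expect_equal(mm[["avg_dh"]], m[["avg_dh"]], tolerance = 1e-9)
    expect_equal(mm[["disc_area"]], m[["disc_area"]], tolerance = 1e-9)
    expect_equal(mm[["epwr"]], m[["epwr"]], tolerance = 1e-9)
  }
})

test_that("avg_dh is exactly the mean of adh/pdh; parallel stacks equate methods", {
  set.seed(41)
  for (i in 1:50) {
    lv <- random_level()
    m <- level_metrics(lv)
    expect_identical(m$avg_dh, (m$adh + m$pdh) / 2)
  }
  # rectangles stacked with parallel endplates: adh == vdh, pdh == ddh
  m <- level_metrics(rectangle_level())
  expect_equal(m$adh, m$vdh); expect_equal(m$pdh, m$ddh)
})

test_that("metrics_table reports one row per level and logs missing levels", {
  cfg <- population_config(n_subjects = 3, seed = 5)
  pop <- sample_population(cfg)
  subs <- pop$subjects
  subs[[2]]$levels <- subs[[2]]$levels[-1]   # drop L1L2
  tab <- metrics_table(subs)
  expect_equal(nrow(tab), 14)
  sk <- attr(tab, "skipped")
  expect_equal(nrow(sk), 1)
  expect_equal(sk$level_name, "L1L2")
  empty <- metrics_table(list())
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "summary")["analyzed"]), 0)
})
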