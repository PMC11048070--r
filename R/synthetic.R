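#' Configuration of the synthetic landmark population
#'
#' Defines every distributional assumption of the generator: level-specific
#' Gaussian metric distributions for normal discs, a contaminating degenerated
#' subpopulation, an exponential age trend on standardized disc height, a
#' structural model coupling sagittal plane offset to disc geometry, and
#' optional labeled listhesis injection.  Generation is a pure function of
#' (config, seed).
#'
#' The SPO structural model is shared by the side-lying and the
#' flexion-extension generators (the point of the SpondyIndex is that one
#' model of normal SPO holds across positions):
#' `aspo = a0(level) + a_area*disc_area + a_adh*adh + a_pdh*pdh + eps`,
#' `eps ~ N(0, sigma)`, and analogously for `pspo` with mirrored height
#' coefficients.  The level intercepts are centred so normal SPO means are
#' near zero at each level's typical disc angle, plus a small explicit level
#' effect.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed used by the sampling functions.
#' @param W inferior-vertebra endplate width in landmark units (arbitrary).
#' @param levels data.frame of per-level normal-metric parameters (columns
#'   `level_name`, `avg_dh_mean`, `avg_dh_sd`, `da_mean`, `da_sd`,
#'   `epwr_mean`, `epwr_sd`, `hw_mean`, `hw_sd`).  Defaults: average disc
#'   height 30 (SD 4) %EPW at every level; disc angle graded -2..+12 degrees
#'   (SD 3) from L1L2 to L5S1; endplate width ratio 1.00 (SD 0.03);
#'   height/width ratio 0.60 (SD 0.05).
#' @param degeneration list: `prevalence` (0.3); `height_shift_sd` (-3, mean
#'   height shift in multiples of the level's avg_dh SD); `severity_range`
#'   (c(0.5, 1.5): each degenerated level draws a uniform severity `s`, its
#'   height shift scales with `s` and the osteophyte/sclerosis flag fires
#'   with probability `min(1, flag_sensitivity * s)`, so mild narrowings are
#'   the ones the grader misses -- mean sensitivity stays at
#'   `flag_sensitivity`); `flag_sensitivity` (0.8); `flag_fp` (0.05);
#'   `dispersion` (5: degenerated levels draw their SPO residuals, disc
#'   angle, EPWR and height/width deviations with this SD multiplier --
#'   osteophytes and irregular endplates make every landmark-derived metric
#'   noisier, which is what gives the pre-trim population its heavy tails);
#'   `height_dispersion` (3.5, SD multiplier of the degenerated height
#'   draw: narrowing severity varies on the scale of the shift itself).
#' @param age list: `min`, `max`, `shape1`, `shape2` of a beta draw mapped to
#'   [min, max]; the default beta(2, 1) skews toward older ages.
#' @param age_effect list: `enabled`, `b0`, `b1` of the exponential trend
#'   `zAvgDH = b0 * exp(b1 * age)` applied as a shift to the avg_dh z draw.
#' @param spo list: structural-model constants `a_area`, `a_adh`, `a_pdh`,
#'   `p_area`, `p_adh`, `p_pdh`, `sigma` (residual SD, %EPW),
#'   `level_effect_a`, `level_effect_p` (length-5 intercept offsets), and
#'   `area_noise` (SD of the independent disc-area measurement component).
#' @param injection list: `antero_frac`, `retro_frac` (fractions of levels
#'   with a labeled slip) and `shift` (slip size in multiples of `spo$sigma`;
#'   the injected level's SPO residual is *replaced* by the shift, so its true
#'   offset exceeds the normal prediction by exactly `shift * sigma`).
#' @param flexext list: `da_flexion`, `da_extension` uniform disc-angle
#'   ranges (degrees) of the paired-exam generator.
#' @param back_pain_rate marginal probability of the back-pain flag.
#' @return validated list of class `population_config`.
#' @export
population_config <- function(
    n_subjects = 400L, seed = 1L, W = 20,
    levels = data.frame(level_name = LEVEL_NAMES,
                        avg_dh_mean = 30, avg_dh_sd = 4,
                        da_mean = seq(-2, 12, length.out = 5), da_sd = 3,
                        epwr_mean = 1, epwr_sd = 0.03,
                        hw_mean = 0.6, hw_sd = 0.05),
    degeneration = list(),
    age = list(),
    age_effect = list(),
    spo = list(),
    injection = list(),
    flexext = list(),
    back_pain_rate = 0.18) {
  defaults <- list(
    degeneration = list(prevalence = 0.3, height_shift_sd = -3,
                        flag_sensitivity = 0.8, flag_fp = 0.05,
                        severity_range = c(0.5, 1.5), dispersion = 5,
                        height_dispersion = 3.5),
    age = list(min = 25, max = 74, shape1 = 2, shape2 = 1),
    age_effect = list(enabled = TRUE, b0 = -0.0037, b1 = 0.078),
    spo = list(a_area = 5, a_adh = 0.25, a_pdh = -0.25,
               p_area = 5, p_adh = -0.25, p_pdh = 0.25,
               sigma = 1.5, area_noise = 0.008,
               level_effect_a = c(0.5, 0.25, 0, -0.25, -0.5),
               level_effect_p = c(-0.5, -0.25, 0, 0.25, 0.5)),
    injection = list(antero_frac = 0, retro_frac = 0, shift = 3),
    flexext = list(da_flexion = c(-8, 5), da_extension = c(5, 18)))
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              W = W, levels = levels,
              degeneration = utils::modifyList(defaults$degeneration, degeneration),
              age = utils::modifyList(defaults$age, age),
              age_effect = utils::modifyList(defaults$age_effect, age_effect),
              spo = utils::modifyList(defaults$spo, spo),
              injection = utils::modifyList(defaults$injection, injection),
              flexext = utils::modifyList(defaults$flexext, flexext),
              back_pain_rate = back_pain_rate)
  bad <- validate_population_config(cfg)
  if (length(bad))
    stop("invalid population config: ", paste(bad, collapse = "; "))
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(cfg$n_subjects >= 1, "n_subjects >= 1")
  chk(cfg$W > 0, "W > 0")
  chk(identical(cfg$levels$level_name, LEVEL_NAMES), "levels rows must be L1L2..L5S1")
  chk(all(c(cfg$levels$avg_dh_sd, cfg$levels$da_sd, cfg$levels$epwr_sd,
            cfg$levels$hw_sd) >= 0), "level sds >= 0")
  for (p in c("prevalence", "flag_sensitivity", "flag_fp"))
    chk(cfg$degeneration[[p]] >= 0 && cfg$degeneration[[p]] <= 1,
        paste0("degeneration$", p, " in [0,1]"))
  chk(all(cfg$degeneration$severity_range > 0) &&
        diff(cfg$degeneration$severity_range) >= 0,
      "degeneration$severity_range positive and increasing")
  chk(cfg$degeneration$dispersion > 0 && cfg$degeneration$height_dispersion > 0,
      "degeneration dispersion multipliers > 0")
  chk(cfg$age$min >= 0 && cfg$age$max > cfg$age$min, "age range valid")
  chk(cfg$spo$sigma > 0, "spo$sigma > 0")
  chk(cfg$injection$antero_frac >= 0 && cfg$injection$retro_frac >= 0 &&
        cfg$injection$antero_frac + cfg$injection$retro_frac <= 1,
      "injection fractions in [0,1] and sum <= 1")
  chk(cfg$flexext$da_flexion[1] < cfg$flexext$da_flexion[2] &&
        cfg$flexext$da_extension[1] < cfg$flexext$da_extension[2],
      "flexext disc-angle ranges increasing")
  chk(diff(range(cfg$flexext$da_flexion)) > 0 &&
        cfg$flexext$da_extension[2] > cfg$flexext$da_flexion[1],
      "flexext ranges non-degenerate")
  chk(cfg$back_pain_rate >= 0 && cfg$back_pain_rate <= 1, "back_pain_rate in [0,1]")
  bad
}

# split avg_dh/da into adh/pdh with positive heights; returns list(adh, pdh, da)
heights_from_angle <- function(avg_dh, da_deg, along = 100) {
  delta <- along * tan(da_deg * pi / 180)
  lim <- 2 * (avg_dh - 0.5)
  clamp <- abs(delta) > lim
  delta[clamp] <- sign(delta[clamp]) * pmax(lim[clamp], 0)
  list(adh = avg_dh + delta / 2, pdh = avg_dh - delta / 2,
       da = atan2(delta, along) * 180 / pi)
}

# Minimum constructible height/width ratio of the superior vertebra: its wall
# length must exceed half the mismatch between its two endplate widths
# (superior endplate = epwr target, inferior endplate = value implied by the
# method-1 targets).  A 10% margin keeps the walls clear of collapse.
hw_feasibility_floor <- function(g, epwr) {
  wi <- implied_epwr(g$adh, g$pdh, g$aspo, g$pspo)
  1.1 * abs(epwr - wi) / (epwr + wi)
}

# Degeneration state of N levels: indicator, graded severity, the height
# shift in z units, and the dispersion multipliers for the other metrics.
# Mild narrowings are the ones the osteophyte grader tends to miss (flag
# probability scales with severity), and degenerated levels draw every
# landmark-derived metric with inflated spread -- together these reproduce the
# heavy-tailed pre-trim distributions that make trimming worthwhile.
draw_degeneration <- function(cfg, N) {
  d <- cfg$degeneration
  is_deg <- stats::runif(N) < d$prevalence
  severity <- stats::runif(N, d$severity_range[1], d$severity_range[2])
  severity[!is_deg] <- 0
  list(is_deg = is_deg,
       severity = severity,
       shift = ifelse(is_deg, d$height_shift_sd * severity, 0),
       hdisp = ifelse(is_deg, d$height_dispersion, 1),
       disp = ifelse(is_deg, d$dispersion, 1))
}

# Jointly realize heights and SPO so that the landmark-measured disc angle
# equals the drawn target exactly: the height split uses the along-endplate
# extent 100 + aspo + pspo, which itself depends on the heights through the
# structural model.  The sum aspo + pspo is along-independent (the height
# coefficients of the two models cancel), so the fixed point is reached after
# a couple of passes.
realize_level_geometry <- function(cfg, li, avg_dh, da_target, eps_a, eps_p,
                                   area_eta) {
  along <- rep(100, length(avg_dh))
  for (it in 1:8) {
    h <- heights_from_angle(avg_dh, da_target, along)
    disc_area <- (h$adh + h$pdh) / 200 + area_eta
    aspo <- spo_predict_truth(cfg, li, disc_area, h$adh, h$pdh, "aspo") + eps_a
    pspo <- spo_predict_truth(cfg, li, disc_area, h$adh, h$pdh, "pspo") + eps_p
    along_new <- 100 + aspo + pspo
    conv <- max(abs(along_new - along))
    along <- along_new
    if (conv < 1e-11) break
  }
  list(adh = h$adh, pdh = h$pdh, da = h$da, aspo = aspo, pspo = pspo,
       disc_area = disc_area)
}

# structural SPO model evaluated on a metrics frame (truth, no residual)
spo_predict_truth <- function(cfg, level_idx, disc_area, adh, pdh, target) {
  s <- cfg$spo
  lev <- cfg$levels
  if (target == "aspo") {
    base <- s$level_effect_a[level_idx] + s$a_area * disc_area +
      s$a_adh * adh + s$a_pdh * pdh
    # centre so the level mean is ~0 at the level-typical geometry
    h0 <- heights_from_angle(lev$avg_dh_mean[level_idx], lev$da_mean[level_idx])
    ctr <- s$a_area * (h0$adh + h0$pdh) / 200 + s$a_adh * h0$adh + s$a_pdh * h0$pdh
  } else {
    base <- s$level_effect_p[level_idx] + s$p_area * disc_area +
      s$p_adh * adh + s$p_pdh * pdh
    h0 <- heights_from_angle(lev$avg_dh_mean[level_idx], lev$da_mean[level_idx])
    ctr <- s$p_area * (h0$adh + h0$pdh) / 200 + s$p_adh * h0$adh + s$p_pdh * h0$pdh
  }
  base - ctr
}

#' Sample a synthetic landmark population
#'
#' Draws a side-lying reference population: per level, normal metrics from
#' level-specific Gaussians; an exponential age shift on the standardized
#' average disc height; with the configured prevalence a level becomes
#' degenerated (heights shifted down, osteophyte/sclerosis flag set with the
#' configured sensitivity, false positives among normals); optional labeled
#' anterolisthesis/retrolisthesis injection.  Ground-truth labels are emitted
#' for every level.
#'
#' @param config a [population_config()].
#' @param build_landmarks also construct `spondy_subject` records with
#'   landmark geometry via [metrics_to_landmarks()] (set `FALSE` for large
#'   purely tabular simulations).
#' @return list with `subjects_df` (demographics), `levels_df` (per-level
#'   flags), `metrics` (the ground-truth metrics table with label columns
#'   `is_degenerated`, `injected`, `osteo_flag`), and `subjects` (list of
#'   `spondy_subject`, or `NULL`).
#' @export
sample_population <- function(config, build_landmarks = TRUE) {
  stopifnot(inherits(config, "population_config"))
  with_local_seed(config$seed, sample_population_impl(config, build_landmarks))
}

sample_population_impl <- function(cfg, build_landmarks) {
  n <- cfg$n_subjects
  lev <- cfg$levels
  nl <- nrow(lev)
  N <- n * nl
  sid <- sprintf("S%05d", rep(seq_len(n), each = nl))
  li <- rep(seq_len(nl), n)

  ages <- cfg$age$min + (cfg$age$max - cfg$age$min) *
    stats::rbeta(n, cfg$age$shape1, cfg$age$shape2)
  subjects_df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)), age = ages,
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = stats::rnorm(n, 26, 4),
    back_pain = stats::runif(n) < cfg$back_pain_rate,
    position = "side-lying")

  deg <- draw_degeneration(cfg, N)
  is_deg <- deg$is_deg

  z_dh <- stats::rnorm(N) * deg$hdisp + deg$shift
  if (isTRUE(cfg$age_effect$enabled))
    z_dh <- z_dh + cfg$age_effect$b0 * exp(cfg$age_effect$b1 * rep(ages, each = nl))
  avg_dh <- lev$avg_dh_mean[li] + lev$avg_dh_sd[li] * z_dh
  avg_dh <- pmax(avg_dh, 1)   # geometric feasibility floor

  osteo <- ifelse(is_deg,
                  stats::runif(N) < pmin(1, cfg$degeneration$flag_sensitivity *
                                           deg$severity),
                  stats::runif(N) < cfg$degeneration$flag_fp)

  da_t <- lev$da_mean[li] + lev$da_sd[li] * stats::rnorm(N) * deg$disp
  area_eta <- stats::rnorm(N, 0, cfg$spo$area_noise) * deg$disp
  # clamp shape draws to the geometrically constructible range
  epwr <- pmin(pmax(lev$epwr_mean[li] + lev$epwr_sd[li] * stats::rnorm(N) * deg$disp,
                    0.7), 1.3)
  hw <- pmin(pmax(lev$hw_mean[li] + lev$hw_sd[li] * stats::rnorm(N) * deg$disp,
                  0.3), 1.2)

  eps_a <- stats::rnorm(N, 0, cfg$spo$sigma) * deg$disp
  eps_p <- stats::rnorm(N, 0, cfg$spo$sigma) * deg$disp
  injected <- rep("none", N)
  u <- stats::runif(N)
  injected[u < cfg$injection$antero_frac] <- "antero"
  injected[u >= cfg$injection$antero_frac &
             u < cfg$injection$antero_frac + cfg$injection$retro_frac] <- "retro"
  shift <- cfg$injection$shift * cfg$spo$sigma
  eps_a[injected == "antero"] <- shift
  eps_p[injected == "retro"] <- shift

  g <- realize_level_geometry(cfg, li, avg_dh, da_t, eps_a, eps_p, area_eta)
  hw <- pmax(hw, hw_feasibility_floor(g, epwr))

  metrics <- data.frame(
    subject_id = sid, level_name = lev$level_name[li],
    adh = g$adh, pdh = g$pdh, avg_dh = (g$adh + g$pdh) / 2, da = g$da,
    aspo = g$aspo, pspo = g$pspo, disc_area = g$disc_area, epwr = epwr,
    hw_ratio = hw, osteo_flag = osteo, is_degenerated = is_deg,
    injected = injected, age = rep(ages, each = nl))

  levels_df <- metrics[, c("subject_id", "level_name", "osteo_flag")]
  subjects <- NULL
  if (build_landmarks) {
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- ((i - 1L) * nl + 1L):(i * nl)   # rows are ordered by subject
      tg <- lapply(rows, function(r)
        list(adh = metrics$adh[r], pdh = metrics$pdh[r],
             aspo = metrics$aspo[r], pspo = metrics$pspo[r],
             epwr = metrics$epwr[r], hw_ratio = metrics$hw_ratio[r],
             osteo_flag = metrics$osteo_flag[r]))
      names(tg) <- metrics$level_name[rows]
      lvls <- spine_from_metrics(tg, W = cfg$W)
      subjects[[i]] <- spondy_subject(
        subjects_df$subject_id[i], age = subjects_df$age[i],
        sex = subjects_df$sex[i], bmi = subjects_df$bmi[i],
        back_pain = subjects_df$back_pain[i], position = "side-lying",
        levels = lvls)
    }
  }
  list(subjects_df = subjects_df, levels_df = levels_df, metrics = metrics,
       subjects = subjects)
}

#' Build an exact landmark realization of target metrics
#'
#' Inverse of the method-1 measurement construction: the inferior vertebra is
#' a rectangle whose superior endplate has width `W`; the superior vertebra's
#' inferior corners are placed so that `adh`, `pdh`, `aspo` and `pspo` are
#' reproduced exactly; its superior endplate is completed parallel to its
#' inferior endplate with width `epwr * W`, at the wall length that makes the
#' measured height/width ratio equal `hw_ratio` exactly.
#'
#' Because both inferior corners of the superior vertebra are pinned by the
#' four method-1 targets, the measured endplate width ratio is the implied
#' value `sqrt((1+(aspo+pspo)/100)^2 + ((adh-pdh)/100)^2)` (the `epwr` target
#' governs the superior endplate of the superior vertebra); see
#' [implied_epwr()].
#'
#' @param targets named list/vector with `adh`, `pdh` (> 0, %EPW), `aspo`,
#'   `pspo` (%EPW), `epwr`, `hw_ratio`.
#' @param W inferior endplate width in landmark units.
#' @param sup_label label of the superior vertebra.
#' @param inf_hw height/width ratio of the (rectangular) inferior vertebra.
#' @param osteo_flag level flag to attach.
#' @return a `spine_level` whose [method1_metrics()] reproduce the targets.
#' @examples
#' lv <- metrics_to_landmarks(list(adh = 40, pdh = 20, aspo = 10, pspo = -10,
#'                                 epwr = 1, hw_ratio = 0.6))
#' method1_metrics(lv)
#' @export
metrics_to_landmarks <- function(targets, W = 20, sup_label = "L3",
                                 inf_hw = 0.6, osteo_flag = FALSE) {
  if (W <= 0) stop("W must be > 0")
  i <- match(sup_label, VERTEBRA_LABELS)
  inf <- vertebra_landmarks(VERTEBRA_LABELS[i + 1L],
                            as_pt = c(W / 2, 0), ps_pt = c(-W / 2, 0),
                            ai_pt = c(W / 2, -inf_hw * W),
                            pi_pt = c(-W / 2, -inf_hw * W), check_frame = FALSE)
  sup <- build_superior_on(inf, targets, sup_label)
  spine_level(sup, inf, osteo_flag = osteo_flag)
}

# Construct the superior vertebra of a level on an existing inferior vertebra,
# working in the frame of the inferior vertebra's superior endplate so the
# method-1 targets are reproduced exactly whatever the global pose.
build_superior_on <- function(inf, targets, sup_label) {
  t <- as.list(targets)
  need <- c("adh", "pdh", "aspo", "pspo", "epwr", "hw_ratio")
  if (!all(need %in% names(t))) stop("targets must name ", paste(need, collapse = ", "))
  if (t$adh <= 0 || t$pdh <= 0)
    stop("infeasible targets: disc heights must be > 0")
  W <- endplate_width(inf, "superior")
  u <- vunit(inf$as_pt - inf$ps_pt)
  nrm <- c(-u[2], u[1])
  inf_cen <- (inf$as_pt + inf$ps_pt + inf$ai_pt + inf$pi_pt) / 4
  mid <- (inf$as_pt + inf$ps_pt) / 2
  if (sum(nrm * (mid - inf_cen)) < 0) nrm <- -nrm   # point away from the body
  A <- mid + (W / 2 + t$aspo * W / 100) * u + (t$adh * W / 100) * nrm
  P <- mid - (W / 2 + t$pspo * W / 100) * u + (t$pdh * W / 100) * nrm
  if (sum((A - P) * u) <= 0)
    stop("infeasible targets: superior vertebra's inferior endplate collapses")
  wi <- vnorm(A - P)
  ws <- t$epwr * W
  if (ws <= 0) stop("infeasible targets: epwr must be > 0")
  mw <- (wi + ws) / 2
  L <- t$hw_ratio * mw
  half_dw <- (ws - wi) / 2
  if (L^2 <= half_dw^2)
    stop("infeasible targets: wall length below endplate-width mismatch")
  hgt <- sqrt(L^2 - half_dw^2)
  e <- (A - P) / wi
  n2 <- c(-e[2], e[1])
  if (sum(n2 * nrm) < 0) n2 <- -n2
  M <- (A + P) / 2
  vertebra_landmarks(sup_label,
                     as_pt = M + (ws / 2) * e + hgt * n2,
                     ps_pt = M - (ws / 2) * e + hgt * n2,
                     ai_pt = A, pi_pt = P, check_frame = FALSE)
}

#' Assemble a coherent spine from per-level metric targets
#'
#' Stacks the five lumbar levels bottom-up in one global frame: S1 is the
#' rectangular base, and each superior vertebra is constructed on the actual
#' superior endplate of the vertebra below it via [build_superior_on()]'s
#' frame-local construction, so every level reproduces its method-1 targets
#' exactly while adjacent levels share their common vertebra.
#'
#' @param targets_by_level named list: for each available level name, a target
#'   list as in [metrics_to_landmarks()] plus optional `osteo_flag`.
#'   Contiguous runs are required from the bottom up (the construction chains
#'   upward from S1).
#' @param W base endplate width of S1.
#' @param inf_hw height/width ratio of the S1 base.
#' @return list of `spine_level` in cranio-caudal order.
#' @export
spine_from_metrics <- function(targets_by_level, W = 20, inf_hw = 0.6) {
  verts <- list()
  verts[["S1"]] <- vertebra_landmarks("S1",
                                      as_pt = c(W / 2, 0), ps_pt = c(-W / 2, 0),
                                      ai_pt = c(W / 2, -inf_hw * W),
                                      pi_pt = c(-W / 2, -inf_hw * W),
                                      check_frame = FALSE)
  levels <- list()
  for (j in rev(seq_len(length(VERTEBRA_LABELS) - 1L))) {
    sup_lab <- VERTEBRA_LABELS[j]
    inf_lab <- VERTEBRA_LABELS[j + 1L]
    ln <- paste0(sup_lab, inf_lab)
    tg <- targets_by_level[[ln]]
    if (is.null(tg)) break   # chain upward only through contiguous levels
    inf <- verts[[inf_lab]]
    sup <- build_superior_on(inf, tg, sup_lab)
    verts[[sup_lab]] <- sup
    levels[[ln]] <- spine_level(sup, inf, osteo_flag = isTRUE(tg$osteo_flag))
  }
  rev(levels)
}

#' Endplate width ratio implied by method-1 targets
#'
#' The measured EPWR of a level built by [metrics_to_landmarks()] is fully
#' determined by the four method-1 targets:
#' `sqrt((1 + (aspo+pspo)/100)^2 + ((adh-pdh)/100)^2)`.
#'
#' @param adh,pdh,aspo,pspo method-1 targets in %EPW.
#' @export
implied_epwr <- function(adh, pdh, aspo, pspo) {
  sqrt((1 + (aspo + pspo) / 100)^2 + ((adh - pdh) / 100)^2)
}

#' Sample paired flexion-extension exams
#'
#' Each synthetic subject receives a flexion and an extension exam of all five
#' levels.  Disc-intrinsic quantities (average height, endplate width ratio,
#' height/width ratio, the disc-area measurement component, degeneration
#' state) are shared between the two exams; the disc angle is drawn uniformly
#' from the position-specific range, and SPO follows the shared structural
#' model with an independent residual per exam (neutral-zone repositioning).
#' Injected slips persist across both exams.
#'
#' @param config a [population_config()] (fields `n_subjects`, `flexext`,
#'   `spo`, `levels`, `injection`, `degeneration$prevalence` are used; the
#'   degeneration height shift applies as in [sample_population()] but flags
#'   and age effects are omitted: the source flexion-extension exams are
#'   asymptomatic volunteers).
#' @param build_landmarks also construct one landmark level per row via
#'   [metrics_to_landmarks()].
#' @return list with `metrics` (rows = level x exam, column `position` in
#'   `flexion`/`extension`, truth labels as in [sample_population()]) and
#'   `subjects` (landmark records, one per exam position).
#' @export
sample_flexext <- function(config, build_landmarks = FALSE) {
  stopifnot(inherits(config, "population_config"))
  with_local_seed(config$seed + 1L, sample_flexext_impl(config, build_landmarks))
}

sample_flexext_impl <- function(cfg, build_landmarks) {
  n <- cfg$n_subjects
  lev <- cfg$levels
  nl <- nrow(lev)
  N <- n * nl
  sid <- sprintf("F%05d", rep(seq_len(n), each = nl))
  li <- rep(seq_len(nl), n)

  deg <- draw_degeneration(cfg, N)
  is_deg <- deg$is_deg
  avg_dh <- lev$avg_dh_mean[li] +
    lev$avg_dh_sd[li] * (stats::rnorm(N) * deg$hdisp + deg$shift)
  avg_dh <- pmax(avg_dh, 1)
  epwr <- pmin(pmax(lev$epwr_mean[li] + lev$epwr_sd[li] * stats::rnorm(N) * deg$disp,
                    0.7), 1.3)
  hw <- pmin(pmax(lev$hw_mean[li] + lev$hw_sd[li] * stats::rnorm(N) * deg$disp,
                  0.3), 1.2)
  area_eta <- stats::rnorm(N, 0, cfg$spo$area_noise) * deg$disp

  injected <- rep("none", N)
  u <- stats::runif(N)
  injected[u < cfg$injection$antero_frac] <- "antero"
  injected[u >= cfg$injection$antero_frac &
             u < cfg$injection$antero_frac + cfg$injection$retro_frac] <- "retro"
  shift <- cfg$injection$shift * cfg$spo$sigma

  one_exam <- function(position, da_range) {
    da_t <- stats::runif(N, da_range[1], da_range[2])
    eps_a <- stats::rnorm(N, 0, cfg$spo$sigma) * deg$disp
    eps_p <- stats::rnorm(N, 0, cfg$spo$sigma) * deg$disp
    eps_a[injected == "antero"] <- shift
    eps_p[injected == "retro"] <- shift
    g <- realize_level_geometry(cfg, li, avg_dh, da_t, eps_a, eps_p, area_eta)
    hw_exam <- pmax(hw, hw_feasibility_floor(g, epwr))
    data.frame(
      subject_id = sid, level_name = lev$level_name[li], position = position,
      adh = g$adh, pdh = g$pdh, avg_dh = (g$adh + g$pdh) / 2, da = g$da,
      aspo = g$aspo, pspo = g$pspo,
      disc_area = g$disc_area, epwr = epwr, hw_ratio = hw_exam,
      osteo_flag = FALSE, is_degenerated = is_deg, injected = injected)
  }
  metrics <- rbind(one_exam("flexion", cfg$flexext$da_flexion),
                   one_exam("extension", cfg$flexext$da_extension))

  subjects <- NULL
  if (build_landmarks) {
    subjects <- lapply(seq_len(nrow(metrics)), function(r)
      metrics_to_landmarks(
        list(adh = metrics$adh[r], pdh = metrics$pdh[r],
             aspo = metrics$aspo[r], pspo = metrics$pspo[r],
             epwr = metrics$epwr[r], hw_ratio = metrics$hw_ratio[r]),
        W = cfg$W, sup_label = substr(metrics$level_name[r], 1, 2)))
  }
  list(metrics = metrics, subjects = subjects)
}
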