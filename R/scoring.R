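#' Standardized Z score
#'
#' `(value - ref_mean) / ref_sd`: how many reference standard deviations a
#' measurement lies from the average for normal discs at that level.
#'
#' @param value measurement(s).
#' @param ref_mean,ref_sd reference mean and SD; `ref_sd > 0`.
#' @return z score(s).
#' @export
z_score <- function(value, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) stop("ref_sd must be > 0")
  (value - ref_mean) / ref_sd
}

#' Robust normalized score
#'
#' `(value - hl_location) / qn_scale`: the robust analogue of the Z score,
#' using the Hodges-Lehmann location and the Qn scale of the reference data.
#' On clean Gaussian reference data it is nearly identical to the Z score.
#'
#' @param value measurement(s).
#' @param hl_location,qn_scale robust reference location and scale;
#'   `qn_scale > 0`.
#' @return normalized score(s).
#' @export
robust_score <- function(value, hl_location, qn_scale) {
  if (any(qn_scale <= 0)) stop("qn_scale must be > 0")
  (value - hl_location) / qn_scale
}

#' Score a metrics table against a reference table
#'
#' Standardizes every metric of every level against its level-specific
#' reference row, with either classical (Z) or robust scoring.
#'
#' @param metrics data.frame from [metrics_table()].
#' @param reference a `reference_table` from [build_reference()].
#' @param robust use [robust_score()] instead of [z_score()].
#' @param metric_names metrics to score (default: all reference metrics
#'   present in `metrics`).
#' @return data.frame with `subject_id`, `level_name`, and one column
#'   `z_<metric>` per scored metric.
#' @export
score_metrics <- function(metrics, reference, robust = FALSE,
                          metric_names = intersect(unique(reference$metric), names(metrics))) {
  out <- metrics[, intersect(c("subject_id", "level_name"), names(metrics)), drop = FALSE]
  for (mn in metric_names) {
    col <- rep(NA_real_, nrow(metrics))
    for (ln in unique(metrics$level_name)) {
      r <- reference_row(reference, ln, mn)
      i <- metrics$level_name == ln
      col[i] <- if (robust)
        robust_score(metrics[[mn]][i], r$hl_location, r$qn_scale)
      else
        z_score(metrics[[mn]][i], r$mean, r$sd)
    }
    out[[paste0("z_", mn)]] <- col
  }
  out
}

#' Prevalence of abnormal standardized scores
#'
#' For each metric and level, the fraction of levels whose score exceeds each
#' threshold: two-sided (`|z| > t`, the default report) and one-sided
#' (`z > t`, `z < -t`) separately.
#'
#' @param scores data.frame from [score_metrics()] (columns `z_*`).
#' @param thresholds numeric thresholds (default `c(2, 3)`: a score of 2 is
#'   just outside the 95% reference interval, 3 is definitively abnormal).
#' @return data.frame with `level_name`, `metric`, `threshold`, `prev_abs`,
#'   `prev_above`, `prev_below` (fractions in [0, 1]).
#' @export
classify_prevalence <- function(scores, thresholds = c(2, 3)) {
  zcols <- grep("^z_", names(scores), value = TRUE)
  rows <- list()
  for (ln in unique(scores$level_name)) {
    d <- scores[scores$level_name == ln, , drop = FALSE]
    for (zc in zcols) {
      for (t in thresholds) {
        z <- d[[zc]]
        rows[[length(rows) + 1L]] <- data.frame(
          level_name = ln, metric = sub("^z_", "", zc), threshold = t,
          prev_abs = mean(abs(z) > t),
          prev_above = mean(z > t), prev_below = mean(z < -t))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exponential age model for standardized average disc height
#'
#' The expected standardized average disc height declines exponentially with
#' age: `zAvgDH = b0 * exp(b1 * age)`.  The reference fit on the source
#' population reported `b0 = -0.0037`, `b1 = 0.078`.
#'
#' @param age age(s) in years, `>= 0`.
#' @param model an `age_model` (list with `b0`, `b1`).
#' @return expected zAvgDH.
#' @export
age_model_eval <- function(age, model = age_model()) {
  if (any(age < 0)) stop("age must be >= 0")
  model$b0 * exp(model$b1 * age)
}

#' @rdname age_model_eval
#' @param b0,b1 model coefficients.
#' @export
age_model <- function(b0 = -0.0037, b1 = 0.078) {
  stopifnot(is.finite(b0), is.finite(b1))
  structure(list(b0 = b0, b1 = b1), class = "age_model")
}

#' Fit the exponential age model by nonlinear least squares
#'
#' @param ages,z paired observations (`n >= 10`).
#' @return an `age_model` with the fit object in attribute `"fit"`.
#' @export
fit_age_model <- function(ages, z) {
  stopifnot(length(ages) == length(z), length(ages) >= 10)
  start <- list(b0 = sign(mean(z)) * 0.001, b1 = 0.05)
  if (start$b0 == 0) start$b0 <- 0.001
  fit <- minpack.lm::nlsLM(z ~ b0 * exp(b1 * ages), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  m <- age_model(co[["b0"]], co[["b1"]])
  attr(m, "fit") <- fit
  m
}

#' Train a SpondyIndex model
#'
#' Ordinary least squares of the target SPO metric (ASPO or PSPO) on disc
#' area, endplate width ratio, anterior and posterior disc heights, and level
#' indicators, fit on radiographically normal levels spanning a wide range of
#' disc angles (flexion-extension exams).  Disc angle itself is excluded: the
#' two disc heights carry the angle information.  One pass of outlier
#' exclusion at |studentized residual| > 3 precedes the final fit.  Per-level
#' residual SDs provide the index scale.
#'
#' @param metrics training metrics table (columns `aspo`/`pspo`, `disc_area`,
#'   `epwr`, `adh`, `pdh`, `level_name`).
#' @param target `"aspo"` or `"pspo"`.
#' @param outlier_t studentized-residual cutoff for the single trimming pass.
#' @return object of class `spondy_model`: `target`, `coefficients`,
#'   `residual_sd` (named by level), `provenance` (n used, n trimmed), and the
#'   `lm` fit in attribute `"fit"`.
#' @export
train_spondy_index <- function(metrics, target = c("aspo", "pspo"), outlier_t = 3) {
  target <- match.arg(target)
  need <- c(target, "disc_area", "epwr", "adh", "pdh", "level_name")
  stopifnot(all(need %in% names(metrics)))
  d <- metrics[, need]
  names(d)[1] <- "y"
  d$level_name <- factor(d$level_name)
  if (nrow(d) <= 4 + nlevels(d$level_name)) stop("too few rows to fit the model")
  form <- y ~ disc_area + epwr + adh + pdh + level_name
  fit0 <- stats::lm(form, data = d)
  if (fit0$rank < length(stats::coef(fit0)))
    stop("rank-deficient design; collinear predictors: ",
         paste(names(which(is.na(stats::coef(fit0)))), collapse = ", "))
  keep <- abs(stats::rstudent(fit0)) <= outlier_t
  fit <- stats::lm(form, data = d[keep, , drop = FALSE])
  res <- stats::residuals(fit)
  lev <- d$level_name[keep]
  rsd <- tapply(res, lev, stats::sd)
  floor_sd <- 1e-8 * max(stats::sd(d$y), .Machine$double.eps)
  if (any(rsd <= floor_sd | is.na(rsd)))
    stop("degenerate residual scale for some level (target collinear with ",
         "the predictors?)")
  structure(list(target = target,
                 coefficients = stats::coef(fit),
                 residual_sd = rsd[levels(lev)],
                 provenance = list(n_train = sum(keep), n_trimmed = sum(!keep),
                                   levels = levels(lev))),
            class = "spondy_model", fit = fit)
}

#' @export
print.spondy_model <- function(x, ...) {
  cat("<spondy_model> target:", toupper(x$target),
      "| n =", x$provenance$n_train, "(", x$provenance$n_trimmed, "trimmed )\n")
  print(round(x$coefficients, 4))
  cat("residual sd per level:\n"); print(round(x$residual_sd, 3))
  invisible(x)
}

# design-matrix prediction without relying on the stored lm object, so that a
# deserialized model predicts identically
spondy_predict <- function(model, metrics) {
  lev <- model$provenance$levels
  if (!all(metrics$level_name %in% lev))
    stop("level(s) unseen in training: ",
         paste(setdiff(unique(metrics$level_name), lev), collapse = ", "))
  d <- data.frame(disc_area = metrics$disc_area, epwr = metrics$epwr,
                  adh = metrics$adh, pdh = metrics$pdh,
                  level_name = factor(metrics$level_name, levels = lev))
  X <- stats::model.matrix(~ disc_area + epwr + adh + pdh + level_name, d)
  drop(X %*% model$coefficients)
}

#' SpondyIndex of measured levels
#'
#' `(observed SPO - predicted normal SPO) / per-level residual SD`, in units
#' of deviation from average normal.  The anterior index (AntSI) comes from an
#' ASPO model, the posterior index (PstSI) from a PSPO model.  An index > 2
#' lies above the 95% reference interval for normal SPO; a posterior index
#' > +2 suggests retrolisthesis.
#'
#' @param metrics metrics table of the levels to score.
#' @param model a `spondy_model`.
#' @return numeric vector of index values aligned with `metrics` rows.
#' @export
spondy_index <- function(metrics, model) {
  stopifnot(inherits(model, "spondy_model"))
  pred <- spondy_predict(model, metrics)
  obs <- metrics[[model$target]]
  (obs - pred) / as.numeric(model$residual_sd[metrics$level_name])
}

#' Serialize / deserialize a SpondyIndex model
#'
#' Versioned JSON with the target, coefficients, per-level residual SDs and
#' training provenance; a read-back model predicts identically to the
#' original.
#'
#' @param model a `spondy_model`.
#' @param path file path.
#' @export
write_spondy_model <- function(model, path) {
  obj <- list(schema = "spondy_model/1",
              target = model$target,
              coefficients = as.list(model$coefficients),
              residual_sd = as.list(model$residual_sd),
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spondy_model
#' @export
read_spondy_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "spondy_model/1"))
    stop("unrecognized model schema: ", obj$schema)
  structure(list(target = obj$target,
                 coefficients = unlist(obj$coefficients),
                 residual_sd = unlist(obj$residual_sd),
                 provenance = obj$provenance),
            class = "spondy_model")
}

#' Per-spine summary scores
#'
#' Collapses per-level scores to the per-subject extrema used for outcome
#' analysis: the maximum anterior and posterior SpondyIndex and the minimum
#' standardized average disc height across available levels.
#'
#' @param scores data.frame with `subject_id` and columns `ant_si`, `pst_si`,
#'   `z_avg_dh` (any subset); missing levels are simply absent rows.
#' @return data.frame with one row per subject: `max_ant_si`, `max_pst_si`,
#'   `min_z_avg_dh` (NA when the source column is absent).
#' @export
spine_summary <- function(scores) {
  stopifnot("subject_id" %in% names(scores), nrow(scores) >= 1)
  agg <- function(col, f) {
    if (!col %in% names(scores)) return(NULL)
    tapply(scores[[col]], scores$subject_id, f)
  }
  ids <- sort(unique(scores$subject_id))
  out <- data.frame(subject_id = ids)
  for (spec in list(c("ant_si", "max_ant_si", "max"),
                    c("pst_si", "max_pst_si", "max"),
                    c("z_avg_dh", "min_z_avg_dh", "min"))) {
    v <- agg(spec[1], match.fun(spec[3]))
    out[[spec[2]]] <- if (is.null(v)) NA_real_ else as.numeric(v[ids])
  }
  out
}

#' Association of per-spine summaries with a binary outcome
#'
#' Univariable logistic regression of the outcome on each summary metric.
#'
#' @param summaries data.frame from [spine_summary()].
#' @param outcome logical/0-1 vector aligned with `summaries` rows (e.g. the
#'   back-pain flag); both classes must be present, `n >= 50`.
#' @param predictors columns of `summaries` to test.
#' @return data.frame with `predictor`, `odds_ratio` (per unit), `p`, and
#'   McFadden `pseudo_r2`.
#' @export
outcome_association <- function(summaries, outcome,
                                predictors = c("max_ant_si", "max_pst_si", "min_z_avg_dh")) {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == nrow(summaries))
  if (length(outcome) < 50) stop("need n >= 50")
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  rows <- list()
  for (p in predictors) {
    x <- summaries[[p]]
    if (all(is.na(x))) next
    fit <- stats::glm(outcome ~ x, family = stats::binomial())
    if (!fit$converged || any(abs(stats::coef(fit)) > 15))
      stop("apparent separation for predictor ", p,
           "; a penalized fit would be required (out of scope)")
    null_dev <- fit$null.deviance
    co <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = p,
      odds_ratio = exp(co["x", "Estimate"]),
      p = co["x", "Pr(>|z|)"],
      pseudo_r2 = 1 - fit$deviance / null_dev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
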