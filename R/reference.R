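#' Classical descriptive statistics for one metric sample
#'
#' @param x numeric sample with `n >= 2` finite values.
#' @return named list: `n`, `mean`, `sd` (sample, n-1 denominator), `median`,
#'   `cv` (sd/|mean|, `NA` when the mean is 0), moment `skewness`
#'   (m3/m2^1.5) and moment `kurtosis` (m4/m2^2, non-excess: a normal
#'   distribution gives ~3).
#' @examples
#' descriptive_stats(c(1, 2, 3))
#' @export
descriptive_stats <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop("need n >= 2 finite values")
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  list(n = n, mean = m, sd = stats::sd(x), median = stats::median(x),
       cv = if (m == 0) NA_real_ else stats::sd(x) / abs(m),
       skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_)
}

#' 95% reference-interval limits
#'
#' The interval mean +/- 1.96 sd used both to trim outlying levels and, after
#' trimming, to delimit "normal" for each metric.  This is an interval for
#' individual observations under normality, not a confidence interval for the
#' mean.
#'
#' @param mean,sd centre and spread; `sd >= 0`.
#' @return numeric `c(lo, hi)`.
#' @export
ci_limits <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be >= 0")
  c(lo = mean - 1.96 * sd, hi = mean + 1.96 * sd)
}

#' Metrics gating the outlier-trimming pass
#'
#' The seven metrics whose joint 95% reference intervals define pass 2 of
#' [trim_population()].
#'
#' @export
TRIM_GATES <- c("da", "aspo", "pspo", "avg_dh", "disc_area", "epwr", "hw_ratio")

#' Two-pass exclusion of degenerated and outlying levels
#'
#' Pass 1 drops every level flagged for definite osteophytes/sclerosis.  On
#' the remainder, level-specific means and SDs of the seven gating metrics
#' (`TRIM_GATES`) are computed, and pass 2 keeps only levels whose gating
#' metrics all lie within their level-specific `mean +/- 1.96 sd` limits.
#' The surviving levels define "normal" for [build_reference()].
#'
#' @param metrics data.frame as produced by [metrics_table()] (needs
#'   `level_name`, `osteo_flag` and the gating metric columns).
#' @param iterate repeat pass 2 to a fixed point (exploration only; the
#'   default single re-computation is the reference procedure).
#' @param min_stratum warn when a level stratum has fewer rows than this
#'   after pass 1.
#' @return list with `kept` (the trimmed data.frame), and `audit`: per-level
#'   counts of input/kept rows, removals attributed to the first triggering
#'   rule (osteophyte flag first, then the gates in `TRIM_GATES` order), and a
#'   long table of every violated rule per removed row.
#' @export
trim_population <- function(metrics, iterate = FALSE, min_stratum = 30L) {
  stopifnot(all(c("level_name", "osteo_flag", TRIM_GATES) %in% names(metrics)))
  n_in <- nrow(metrics)
  osteo <- metrics$osteo_flag %in% TRUE
  pass1 <- metrics[!osteo, , drop = FALSE]

  small <- names(which(table(pass1$level_name) < min_stratum))
  if (length(small))
    warning("level strata with n < ", min_stratum, " after pass 1: ",
            paste(small, collapse = ", "))

  rule_first <- rep(NA_character_, n_in)
  rule_first[osteo] <- "osteo_sclerosis"
  violations <- list()
  keep_idx <- which(!osteo)

  repeat {
    cur <- metrics[keep_idx, , drop = FALSE]
    lev <- factor(cur$level_name)
    # per-level, per-gate violation matrix (vectorized over rows)
    viol <- matrix(FALSE, nrow(cur), length(TRIM_GATES),
                   dimnames = list(NULL, TRIM_GATES))
    for (g in TRIM_GATES) {
      v <- cur[[g]]
      mu <- tapply(v, lev, mean)[lev]
      sg <- tapply(v, lev, stats::sd)[lev]
      viol[, g] <- v < mu - 1.96 * sg | v > mu + 1.96 * sg
    }
    ok <- rowSums(viol) == 0L
    bad_rows <- which(!ok)
    if (length(bad_rows)) {
      new <- bad_rows[is.na(rule_first[keep_idx[bad_rows]])]
      first_gate <- TRIM_GATES[max.col(viol[new, , drop = FALSE], "first")]
      rule_first[keep_idx[new]] <- paste0(first_gate, "_ci")
      hits <- which(viol[new, , drop = FALSE], arr.ind = TRUE)
      violations[[length(violations) + 1L]] <- data.frame(
        row = keep_idx[new][hits[, 1L]],
        level_name = cur$level_name[new][hits[, 1L]],
        rule = paste0(TRIM_GATES[hits[, 2L]], "_ci"))
    }
    keep_idx2 <- keep_idx[ok]
    if (!iterate || length(keep_idx2) == length(keep_idx)) { keep_idx <- keep_idx2; break }
    keep_idx <- keep_idx2
  }

  kept <- metrics[keep_idx, , drop = FALSE]
  removed <- setdiff(seq_len(n_in), keep_idx)
  audit <- list(
    n_input = n_in, n_kept = nrow(kept), n_removed = length(removed),
    removed_by_rule = table(rule_first[removed]),
    per_level = do.call(rbind, lapply(unique(metrics$level_name), function(ln) {
      data.frame(level_name = ln,
                 n_input = sum(metrics$level_name == ln),
                 n_kept = sum(kept$level_name == ln))
    })),
    violations = if (length(violations)) do.call(rbind, violations) else
      data.frame(row = integer(0), level_name = character(0), rule = character(0)))
  list(kept = kept, audit = audit)
}

#' Build the level-specific reference table
#'
#' Per (level, metric) descriptive statistics over a (typically trimmed)
#' metrics table: classical moments, the robust Hodges-Lehmann location and
#' Qn scale, and the 95% reference-interval limits.  These rows define
#' "normal" for the scoring stage.
#'
#' @param metrics data.frame with `level_name` and metric columns.
#' @param metric_names metrics to summarize (default all of `METRIC_NAMES`
#'   present in the input).
#' @param ... passed to [hodges_lehmann()] and [qn_scale()] (subsampling
#'   controls for very large strata).
#' @return data.frame of class `reference_table`: one row per level x metric
#'   with columns `level_name`, `metric`, `n`, `mean`, `sd`, `median`, `cv`,
#'   `skewness`, `kurtosis`, `hl_location`, `qn_scale`, `ci_lo`, `ci_hi`.
#' @export
build_reference <- function(metrics, metric_names = intersect(METRIC_NAMES, names(metrics)),
                            ...) {
  rows <- list()
  for (ln in unique(metrics$level_name)) {
    d <- metrics[metrics$level_name == ln, , drop = FALSE]
    if (nrow(d) < 2L) {
      warning("stratum ", ln, " has fewer than 2 rows; omitted")
      next
    }
    for (mn in metric_names) {
      st <- descriptive_stats(d[[mn]])
      ci <- ci_limits(st$mean, st$sd)
      rows[[length(rows) + 1L]] <- data.frame(
        level_name = ln, metric = mn, n = st$n, mean = st$mean, sd = st$sd,
        median = st$median, cv = st$cv, skewness = st$skewness,
        kurtosis = st$kurtosis,
        hl_location = hodges_lehmann(d[[mn]], ...),
        qn_scale = qn_scale(d[[mn]], ...),
        ci_lo = ci["lo"], ci_hi = ci["hi"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reference_table", "data.frame")
  out
}

# fetch one reference row (errors if absent)
reference_row <- function(reference, level_name, metric) {
  r <- reference[reference$level_name == level_name & reference$metric == metric, ]
  if (nrow(r) != 1L)
    stop("no reference entry for ", metric, " at ", level_name)
  r
}
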