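# 2D vector helpers.  Points are numeric length-2 (x, y); +x anterior,
# +y cephalad in the canonical frame, but nothing below depends on the frame.

vnorm <- function(p) sqrt(sum(p * p))

vunit <- function(p) {
  n <- vnorm(p)
  if (n < .Machine$double.eps) stop("degenerate geometry: zero-length direction")
  p / n
}

# z-component of the 2D cross product a x b
vcross <- function(a, b) a[1] * b[2] - a[2] * b[1]

# signed angle (degrees) rotating `from` onto `to`, positive anticlockwise
signed_angle_deg <- function(from, to) {
  atan2(vcross(from, to), sum(from * to)) * 180 / pi
}

#' Width of a vertebral endplate
#'
#' Euclidean distance between the anterior and posterior corners of the named
#' endplate.  The superior endplate of the inferior vertebra of a level is the
#' normalizing width W for all SPO and disc-height metrics.
#'
#' @param v a `vertebra_landmarks`.
#' @param which `"superior"` (as-ps corners) or `"inferior"` (ai-pi corners).
#' @return positive length in landmark units.
#' @export
endplate_width <- function(v, which = c("superior", "inferior")) {
  which <- match.arg(which)
  w <- if (which == "superior") vnorm(v$as_pt - v$ps_pt) else vnorm(v$ai_pt - v$pi_pt)
  if (w < .Machine$double.eps)
    stop("degenerate geometry: coincident ", which, " endplate corners of ", v$label)
  w
}

#' Method-1 disc metrics for one level
#'
#' Disc heights and corner sagittal plane offsets measured against the
#' superior endplate of the inferior vertebra (the reference line of the
#' level).  All heights/offsets are in percent of that endplate's width W.
#'
#' * `adh` / `pdh`: perpendicular distance from the antero-/postero-inferior
#'   corner of the superior vertebra to the reference line, signed positive
#'   toward the superior vertebra.
#' * `da`: disc angle between the inferior endplate of the superior vertebra
#'   and the reference line; negative when ADH < PDH.
#' * `aspo`: offset of the superior vertebra's antero-inferior corner relative
#'   to the inferior vertebra's antero-superior corner, measured along the
#'   reference line; positive when the superior corner lies anterior.
#' * `pspo`: analogous at the posterior corners; positive when the superior
#'   vertebra's postero-inferior corner lies posterior.
#'
#' @param level a `spine_level`.
#' @return named list with `adh`, `pdh`, `da`, `aspo`, `pspo`.
#' @examples
#' method1_metrics(rectangle_level())
#' @export
method1_metrics <- function(level) {
  sup <- level$sup; inf <- level$inf
  W <- endplate_width(inf, "superior")
  u <- vunit(inf$as_pt - inf$ps_pt)            # along endplate, posterior -> anterior
  # normal oriented toward the superior vertebra (cephalad for a valid level)
  n <- c(-u[2], u[1])
  sup_centroid <- (sup$as_pt + sup$ps_pt + sup$ai_pt + sup$pi_pt) / 4
  if (sum(n * (sup_centroid - inf$as_pt)) < 0) n <- -n

  adh <- sum((sup$ai_pt - inf$as_pt) * n) / W * 100
  pdh <- sum((sup$pi_pt - inf$ps_pt) * n) / W * 100
  aspo <- sum((sup$ai_pt - inf$as_pt) * u) / W * 100
  pspo <- -sum((sup$pi_pt - inf$ps_pt) * u) / W * 100

  d_sup <- vunit(sup$ai_pt - sup$pi_pt)        # sup inferior endplate, post -> ant
  da <- signed_angle_deg(u, d_sup)
  # orient the sign so that opening anteriorly (ADH > PDH) is positive even if
  # the normal had to be flipped (handles reflected/rotated inputs uniformly)
  if (vcross(u, n) < 0) da <- -da
  list(adh = adh, pdh = pdh, da = da, aspo = aspo, pspo = pspo)
}

#' Vertebral midplane
#'
#' The line through the midpoints of the anterior wall (as-ai) and posterior
#' wall (ps-pi) of a vertebral body, oriented posterior to anterior.  The
#' midplanes of the two vertebrae of a level define the disc bisectrix used by
#' the method-2 (Frobin-style) metrics.
#'
#' @param v a `vertebra_landmarks`.
#' @return list with `point` (posterior wall midpoint is on the line) and unit
#'   `dir`.
#' @export
vertebral_midplane <- function(v) {
  ant <- (v$as_pt + v$ai_pt) / 2
  post <- (v$ps_pt + v$pi_pt) / 2
  if (vnorm(ant - post) < .Machine$double.eps)
    stop("degenerate geometry: coincident wall midpoints of ", v$label)
  list(point = post, dir = vunit(ant - post))
}

#' Bisectrix of two vertebral midplanes
#'
#' The line bisecting the angle between the two midplanes, through their
#' intersection; among the two bisectors, the one whose direction is the
#' normalized mean of the two consistently oriented midplane directions.  For
#' midplanes parallel within `tol` radians the intersection is numerically
#' unstable, so the parallel line midway between them is returned instead.
#'
#' @param m_sup,m_inf midplane lines as returned by [vertebral_midplane()].
#' @param tol parallelism tolerance in radians.
#' @return list with `point` and unit `dir`.
#' @export
bisectrix <- function(m_sup, m_inf, tol = 1e-6) {
  d1 <- m_sup$dir; d2 <- m_inf$dir
  if (sum(d1 * d2) < 0) d2 <- -d2            # orient consistently
  ang <- abs(atan2(vcross(d1, d2), sum(d1 * d2)))
  dir <- vunit(d1 + d2)
  if (ang < tol) {
    return(list(point = (m_sup$point + m_inf$point) / 2, dir = dir))
  }
  # intersection of p1 + t d1 and p2 + s d2
  dp <- m_inf$point - m_sup$point
  t <- vcross(dp, d2) / vcross(d1, d2)
  list(point = m_sup$point + t * d1, dir = dir)
}

# unsigned perpendicular distance from point p to line (point, dir)
perp_distance <- function(p, line) {
  d <- p - line$point
  abs(vcross(line$dir, d))
}

#' Method-2 (Frobin-style) disc metrics for one level
#'
#' Metrics measured against the disc bisectrix, designed to be less sensitive
#' to radiographic distortion than corner-based measurements.
#'
#' * `vdh` / `ddh`: ventral/dorsal disc height, the sum of the perpendicular
#'   distances of the two adjacent anterior (posterior) corners to the
#'   bisectrix, in percent endplate width W.
#' * `mpa`: midplane angle between the two vertebral midplanes; negative when
#'   VDH < DDH (same sign convention as the method-1 disc angle).
#' * `cspo`: centroid sagittal plane offset, the signed distance along the
#'   bisectrix between the perpendicular projections of the two vertebral
#'   centroids; positive when the superior centroid projects anterior to the
#'   inferior one.
#'
#' @param level a `spine_level`.
#' @return named list with `vdh`, `ddh`, `mpa`, `cspo`.
#' @export
method2_metrics <- function(level) {
  sup <- level$sup; inf <- level$inf
  W <- endplate_width(inf, "superior")
  m_sup <- vertebral_midplane(sup)
  m_inf <- vertebral_midplane(inf)
  bis <- bisectrix(m_sup, m_inf)

  vdh <- (perp_distance(sup$ai_pt, bis) + perp_distance(inf$as_pt, bis)) / W * 100
  ddh <- (perp_distance(sup$pi_pt, bis) + perp_distance(inf$ps_pt, bis)) / W * 100

  d2 <- m_inf$dir
  if (sum(m_sup$dir * d2) < 0) d2 <- -d2
  mpa <- signed_angle_deg(d2, m_sup$dir)
  # anchor the sign to the anatomical frame the same way method-1 does: an
  # anteriorly opening disc (VDH > DDH) is positive
  u <- vunit(inf$as_pt - inf$ps_pt)
  n <- c(-u[2], u[1])
  sup_centroid <- (sup$as_pt + sup$ps_pt + sup$ai_pt + sup$pi_pt) / 4
  if (sum(n * (sup_centroid - inf$as_pt)) < 0) n <- -n
  if (vcross(u, n) < 0) mpa <- -mpa

  c_sup <- sup_centroid
  c_inf <- (inf$as_pt + inf$ps_pt + inf$ai_pt + inf$pi_pt) / 4
  cspo <- sum((c_sup - c_inf) * bis$dir) / W * 100
  list(vdh = vdh, ddh = ddh, mpa = mpa, cspo = cspo)
}

# shoelace area of a polygon given as a list of points (absolute value)
shoelace_area <- function(pts) {
  n <- length(pts)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + vcross(pts[[i]], pts[[j]])
  }
  abs(s) / 2
}

#' Composite disc metrics for one level
#'
#' * `avg_dh`: mean of ADH and PDH.
#' * `disc_area`: shoelace area of the disc quadrilateral (superior vertebra's
#'   inferior corners, inferior vertebra's superior corners), in units of
#'   endplate width squared.  The absolute signed area is used so digitization
#'   order cannot flip the sign; self-intersecting quadrilaterals are flagged.
#' * `epwr`: endplate width ratio, the superior vertebra's inferior endplate
#'   width over the inferior vertebra's superior endplate width.
#' * `hw_ratio`: the superior vertebra's height (mean of anterior and
#'   posterior wall lengths) over its mean endplate width.
#'
#' @param level a `spine_level`.
#' @return named list with `avg_dh`, `disc_area`, `epwr`, `hw_ratio`, and
#'   logical `self_intersecting`.
#' @export
composite_metrics <- function(level) {
  sup <- level$sup; inf <- level$inf
  W <- endplate_width(inf, "superior")
  m1 <- method1_metrics(level)
  quad <- list(sup$ai_pt, sup$pi_pt, inf$ps_pt, inf$as_pt)
  disc_area <- shoelace_area(quad) / W^2
  self_int <- segments_intersect(sup$ai_pt, sup$pi_pt, inf$ps_pt, inf$as_pt) ||
    segments_intersect(sup$pi_pt, inf$ps_pt, inf$as_pt, sup$ai_pt)
  if (self_int)
    warning("self-intersecting disc quadrilateral at ", level$level_name,
            "; |signed area| reported")
  epwr <- endplate_width(sup, "inferior") / W
  height <- (vnorm(sup$as_pt - sup$ai_pt) + vnorm(sup$ps_pt - sup$pi_pt)) / 2
  mean_width <- (endplate_width(sup, "superior") + endplate_width(sup, "inferior")) / 2
  list(avg_dh = (m1$adh + m1$pdh) / 2, disc_area = disc_area, epwr = epwr,
       hw_ratio = height / mean_width, self_intersecting = self_int)
}

# proper intersection test for segments ab and cd (shared endpoints excluded)
segments_intersect <- function(a, b, c, d) {
  o1 <- vcross(b - a, c - a); o2 <- vcross(b - a, d - a)
  o3 <- vcross(d - c, a - c); o4 <- vcross(d - c, b - c)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' All thirteen metrics for one level
#'
#' Convenience wrapper combining [method1_metrics()], [method2_metrics()] and
#' [composite_metrics()] into one named list ordered as `METRIC_NAMES`.
#'
#' @param level a `spine_level`.
#' @return named list of the 13 metric values.
#' @export
level_metrics <- function(level) {
  m1 <- method1_metrics(level)
  m2 <- method2_metrics(level)
  cm <- composite_metrics(level)
  out <- c(m1, m2, cm[c("avg_dh", "disc_area", "epwr", "hw_ratio")])
  out[METRIC_NAMES]
}

#' Per-level metrics table for a collection of subjects
#'
#' One row per available level; missing levels are counted, never fabricated.
#'
#' @param subjects list of `spondy_subject`.
#' @return data.frame with columns `subject_id`, `level_name`, the 13 metrics,
#'   and `osteo_flag`; attribute `"skipped"` holds a data.frame of
#'   subject/level pairs absent from the input, and attribute `"summary"` the
#'   analyzed/skipped counts.
#' @export
metrics_table <- function(subjects) {
  per <- lapply(subjects, function(s) {
    have <- vapply(s$levels, function(l) l$level_name, character(1))
    list(sid = s$subject_id,
         vals = lapply(s$levels, function(lv) unlist(level_metrics(lv))),
         ids = rep(s$subject_id, length(s$levels)),
         lns = have,
         flags = vapply(s$levels, function(lv) lv$osteo_flag, logical(1)),
         miss = setdiff(LEVEL_NAMES, have))
  })
  vals <- unlist(lapply(per, `[[`, "vals"), recursive = FALSE)
  sk_ln <- as.character(unlist(lapply(per, `[[`, "miss")))
  sk_id <- as.character(unlist(lapply(per, function(p) rep(p$sid, length(p$miss)))))
  if (length(vals)) {
    m <- do.call(rbind, vals)
    out <- data.frame(subject_id = unlist(lapply(per, `[[`, "ids")),
                      level_name = unlist(lapply(per, `[[`, "lns")),
                      as.data.frame(m),
                      osteo_flag = unlist(lapply(per, `[[`, "flags")))
  } else out <- empty_metrics_frame()
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(subject_id = sk_id, level_name = sk_ln)
  attr(out, "summary") <- c(analyzed = nrow(out), skipped = length(sk_id))
  out
}

empty_metrics_frame <- function() {
  cols <- c(list(subject_id = character(0), level_name = character(0)),
            stats::setNames(rep(list(numeric(0)), length(METRIC_NAMES)), METRIC_NAMES),
            list(osteo_flag = logical(0)))
  as.data.frame(cols)
}

#' Canonical two-rectangle test level
#'
#' Two width-20, height-12 rectangular vertebrae stacked with a parallel-sided
#' disc of height 6 (30% endplate width): the analytic fixture for which every
#' offset and angle is zero.
#'
#' @param sup_label label of the superior vertebra (the inferior one is the
#'   next label down).
#' @return a `spine_level`.
#' @export
rectangle_level <- function(sup_label = "L3") {
  i <- match(sup_label, VERTEBRA_LABELS[-length(VERTEBRA_LABELS)])
  if (is.na(i)) stop("sup_label must be L1..L5")
  inf_label <- VERTEBRA_LABELS[i + 1L]
  sup <- vertebra_landmarks(sup_label, c(10, 18), c(-10, 18), c(10, 6), c(-10, 6))
  inf <- vertebra_landmarks(inf_label, c(10, 0), c(-10, 0), c(10, -12), c(-10, -12))
  spine_level(sup, inf)
}
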