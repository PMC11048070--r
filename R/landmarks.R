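#' spondyref: reference data and standardized scores for lumbar disc metrics
#'
#' Tools to compute sagittal plane offset (SPO) and disc metrics from
#' four-corner vertebral body landmarks on lateral lumbar radiographs, build
#' trimmed level-specific reference statistics, standardize measurements
#' (Z scores, robust normalized scores, SpondyIndex), and quantify the
#' measurement error introduced by out-of-plane radiographic projection.
#'
#' All lengths are relative: SPO and disc heights are reported in percent of
#' the anterior-posterior width of the superior endplate of the inferior
#' vertebra, angles in degrees, disc area in endplate-width squared.  No
#' millimeter outputs exist anywhere because the source radiographs carry no
#' scaling device.
#'
#' @name spondyref-package
#' @keywords internal
"_PACKAGE"

#' Vertebra labels and intervertebral level names
#'
#' Cranio-caudal order of the vertebrae carrying landmarks, and the five
#' lumbar intervertebral levels formed by adjacent pairs.
#'
#' @export
VERTEBRA_LABELS <- c("L1", "L2", "L3", "L4", "L5", "S1")

#' @rdname VERTEBRA_LABELS
#' @export
LEVEL_NAMES <- c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")

#' The nine SPO/disc metrics plus composite metrics
#'
#' Column names of a metrics table: method-1 metrics (adh, pdh, da, aspo,
#' pspo), method-2 metrics (vdh, ddh, mpa, cspo), and composites (avg_dh,
#' disc_area, epwr, hw_ratio).
#'
#' @export
METRIC_NAMES <- c("adh", "pdh", "avg_dh", "da", "aspo", "pspo",
                  "vdh", "ddh", "mpa", "cspo",
                  "disc_area", "epwr", "hw_ratio")

#' Construct the four-corner landmark set of one vertebral body
#'
#' The atomic geometric input of the pipeline: the four corners of a vertebral
#' body outline in the sagittal plane.  Coordinate convention: +x is anterior,
#' +y is cephalad; units are arbitrary because every downstream metric is a
#' ratio or an angle.
#'
#' @param label vertebra name, one of `VERTEBRA_LABELS`.
#' @param as_pt,ps_pt,ai_pt,pi_pt numeric length-2 (x, y) positions of the
#'   antero-superior, postero-superior, antero-inferior and postero-inferior
#'   corners.
#' @param check_frame if `TRUE`, additionally require the canonical
#'   axis-aligned corner ordering (anterior corners at larger x, superior
#'   corners at larger y).  Geometry functions themselves are rotation
#'   invariant, so landmark sets produced by rigid transformations may be
#'   constructed with `check_frame = FALSE`.
#' @return an object of class `vertebra_landmarks`.
#' @examples
#' v <- vertebra_landmarks("L4", c(10, 18), c(-10, 18), c(10, 6), c(-10, 6))
#' @export
vertebra_landmarks <- function(label, as_pt, ps_pt, ai_pt, pi_pt,
                               check_frame = TRUE) {
  label <- match.arg(label, VERTEBRA_LABELS)
  pts <- list(as_pt = as_pt, ps_pt = ps_pt, ai_pt = ai_pt, pi_pt = pi_pt)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop("corner '", nm, "' of ", label, " must be a finite (x, y) pair")
    pts[[nm]] <- p
  }
  v <- structure(c(list(label = label), pts), class = "vertebra_landmarks")
  if (check_frame) {
    bad <- landmark_frame_violations(v)
    if (length(bad))
      stop("invalid landmark ordering for ", label, ": ",
           paste(bad, collapse = "; "))
  }
  v
}

# Canonical-frame corner-order checks; returns character vector of violations.
landmark_frame_violations <- function(v) {
  bad <- character(0)
  if (!(v$as_pt[1] > v$ps_pt[1]))
    bad <- c(bad, "antero-superior corner must be anterior to postero-superior (as.x > ps.x)")
  if (!(v$ai_pt[1] > v$pi_pt[1]))
    bad <- c(bad, "antero-inferior corner must be anterior to postero-inferior (ai.x > pi.x)")
  if (!(v$as_pt[2] > v$ai_pt[2]))
    bad <- c(bad, "antero-superior corner must be above antero-inferior (as.y > ai.y)")
  if (!(v$ps_pt[2] > v$pi_pt[2]))
    bad <- c(bad, "postero-superior corner must be above postero-inferior (ps.y > pi.y)")
  bad
}

#' @export
print.vertebra_landmarks <- function(x, ...) {
  cat("<vertebra_landmarks>", x$label, "\n")
  for (nm in c("as_pt", "ps_pt", "ai_pt", "pi_pt"))
    cat(sprintf("  %s: (%.4g, %.4g)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Construct one intervertebral level from two adjacent vertebrae
#'
#' @param sup,inf `vertebra_landmarks` of the superior and inferior vertebra;
#'   their labels must be adjacent in cranio-caudal order (e.g. L3 over L4).
#' @param osteo_flag logical; definite osteophytes/sclerosis present at this
#'   level.  The flag is an input (typically from an upstream image grading
#'   step), never computed here.
#' @return an object of class `spine_level` with fields `level_name`, `sup`,
#'   `inf`, `osteo_flag`.
#' @examples
#' lv <- rectangle_level()
#' level_metrics(lv)
#' @export
spine_level <- function(sup, inf, osteo_flag = FALSE) {
  stopifnot(inherits(sup, "vertebra_landmarks"),
            inherits(inf, "vertebra_landmarks"))
  i_sup <- match(sup$label, VERTEBRA_LABELS)
  i_inf <- match(inf$label, VERTEBRA_LABELS)
  if (i_inf != i_sup + 1L)
    stop("vertebrae ", sup$label, "/", inf$label,
         " are not adjacent in cranio-caudal order")
  structure(list(level_name = paste0(sup$label, inf$label),
                 sup = sup, inf = inf,
                 osteo_flag = isTRUE(osteo_flag)),
            class = "spine_level")
}

#' @export
print.spine_level <- function(x, ...) {
  cat("<spine_level>", x$level_name,
      if (x$osteo_flag) "(osteophytes/sclerosis flagged)" else "", "\n")
  invisible(x)
}

#' Construct a subject record
#'
#' @param subject_id identifier (coerced to character).
#' @param age years, `>= 0`.
#' @param sex free-form (e.g. "F"/"M"); not interpreted by the pipeline.
#' @param bmi body-mass index, kg/m^2.
#' @param back_pain logical; back pain on most days for at least two weeks.
#' @param position exam position tag, one of `"side-lying"`, `"standing"`,
#'   `"flexion"`, `"extension"`.
#' @param levels list of `spine_level` records with distinct level names.
#' @return an object of class `spondy_subject`.
#' @export
spondy_subject <- function(subject_id, age = NA_real_, sex = NA_character_,
                           bmi = NA_real_, back_pain = NA,
                           position = "side-lying", levels = list()) {
  position <- match.arg(position, c("side-lying", "standing", "flexion", "extension"))
  if (!is.na(age) && age < 0) stop("age must be >= 0")
  nms <- vapply(levels, function(l) l$level_name, character(1))
  if (anyDuplicated(nms)) stop("duplicate level names within one subject")
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 sex = as.character(sex), bmi = as.numeric(bmi),
                 back_pain = back_pain, position = position, levels = levels),
            class = "spondy_subject")
}

#' @export
print.spondy_subject <- function(x, ...) {
  cat("<spondy_subject>", x$subject_id, "-", length(x$levels), "level(s),",
      "age", x$age, "\n")
  invisible(x)
}
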