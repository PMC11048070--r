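# File formats.  Wide landmark schema: one row per vertebra with columns
# subject_id, vertebra, x_as, y_as, x_ps, y_ps, x_ai, y_ai, x_pi, y_pi.
# Per-level osteophyte flags live in a separate levels table
# (subject_id, level_name, osteo_flag) keyed independently of the landmark
# rows, and demographics in a subjects table
# (subject_id, age, sex, bmi, back_pain, position).

LANDMARK_COLS <- c("subject_id", "vertebra",
                   "x_as", "y_as", "x_ps", "y_ps", "x_ai", "y_ai", "x_pi", "y_pi")

#' Read a landmark population from disk
#'
#' Assembles subjects from a wide landmark table plus optional per-level flag
#' and demographics tables.  Rows violating the corner-ordering invariants are
#' rejected with a per-row diagnostic; levels are assembled only when both
#' vertebrae of an adjacent pair are present (a lone vertebra yields a
#' warning count, not a fabricated level).  The reader never silently drops
#' data: accepted rows plus diagnostics always account for every input row.
#'
#' @param path landmark table (CSV or JSON).
#' @param levels_path,subjects_path optional companion tables.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @param y_down flip the y axis on input (image-space convention with y
#'   growing downward).
#' @return list of `spondy_subject`; attribute `"diagnostics"` is a
#'   data.frame (row, subject_id, vertebra, problem), attribute `"counts"`
#'   has input/accepted/rejected row counts and the number of unpaired
#'   vertebrae.
#' @export
read_landmarks <- function(path, levels_path = NULL, subjects_path = NULL,
                           format = c("auto", "csv", "json"), y_down = FALSE) {
  format <- match.arg(format)
  tab <- read_table_file(path, format)
  if (!all(LANDMARK_COLS %in% names(tab)))
    stop("malformed landmark header: missing column(s) ",
         paste(setdiff(LANDMARK_COLS, names(tab)), collapse = ", "))
  if (y_down) for (cc in c("y_as", "y_ps", "y_ai", "y_pi")) tab[[cc]] <- -tab[[cc]]

  flags <- if (!is.null(levels_path)) read_table_file(levels_path, format) else NULL
  demog <- if (!is.null(subjects_path)) read_table_file(subjects_path, format) else NULL

  diags <- list(); verts <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    v <- tryCatch(
      vertebra_landmarks(row$vertebra,
                         c(row$x_as, row$y_as), c(row$x_ps, row$y_ps),
                         c(row$x_ai, row$y_ai), c(row$x_pi, row$y_pi)),
      error = function(e) conditionMessage(e))
    if (is.character(v)) {
      diags[[length(diags) + 1L]] <- data.frame(
        row = i, subject_id = row$subject_id, vertebra = row$vertebra,
        problem = v)
    } else {
      verts[[length(verts) + 1L]] <- list(sid = as.character(row$subject_id), v = v)
    }
  }
  diags <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(0), subject_id = character(0),
               vertebra = character(0), problem = character(0))

  sids <- unique(vapply(verts, `[[`, character(1), "sid"))
  n_unpaired <- 0L
  subjects <- lapply(sids, function(sid) {
    vs <- lapply(Filter(function(x) x$sid == sid, verts), `[[`, "v")
    labs <- vapply(vs, function(v) v$label, character(1))
    if (anyDuplicated(labs))
      stop("duplicate vertebra ", labs[duplicated(labs)][1], " for subject ", sid)
    lvls <- list(); used <- logical(length(vs))
    for (j in seq_len(length(VERTEBRA_LABELS) - 1L)) {
      i_sup <- match(VERTEBRA_LABELS[j], labs)
      i_inf <- match(VERTEBRA_LABELS[j + 1L], labs)
      if (is.na(i_sup) || is.na(i_inf)) next
      ln <- paste0(VERTEBRA_LABELS[j], VERTEBRA_LABELS[j + 1L])
      fl <- FALSE
      if (!is.null(flags)) {
        hit <- flags$subject_id == sid & flags$level_name == ln
        if (any(hit)) fl <- as.logical(flags$osteo_flag[hit][1])
      }
      lvls[[length(lvls) + 1L]] <- spine_level(vs[[i_sup]], vs[[i_inf]], fl)
      used[c(i_sup, i_inf)] <- TRUE
    }
    n_unpaired <<- n_unpaired + sum(!used)
    args <- list(subject_id = sid, levels = lvls)
    if (!is.null(demog)) {
      d <- demog[demog$subject_id == sid, ]
      if (nrow(d) == 1L)
        args <- c(args, list(age = d$age, sex = d$sex, bmi = d$bmi,
                             back_pain = as.logical(d$back_pain),
                             position = d$position))
    }
    do.call(spondy_subject, args)
  })
  if (n_unpaired > 0L)
    warning(n_unpaired, " vertebra(e) without an adjacent partner; ",
            "no level assembled for them")
  attr(subjects, "diagnostics") <- diags
  attr(subjects, "counts") <- c(input = nrow(tab),
                                accepted = length(verts),
                                rejected = nrow(diags),
                                unpaired = n_unpaired)
  subjects
}

read_table_file <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json")
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a tabular artifact
#'
#' Round-trip stable serialization of the pipeline's tables (landmarks,
#' metrics, reference, scores): `read_table(write_table(x))` reproduces `x`
#' field-wise, numerics to full double precision.
#'
#' @param records data.frame.
#' @param path output path.
#' @param format `"csv"`, `"json"`, or `"auto"` by extension.
#' @export
write_table <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "columns",
                         auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    old <- options(digits = 15); on.exit(options(old))
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, format = c("auto", "csv", "json")) {
  read_table_file(path, match.arg(format))
}

#' Export a landmark population to the on-disk schema
#'
#' Writes `landmarks.csv`, `levels.csv` and `subjects.csv` for a subject
#' collection (the inverse of [read_landmarks()]).
#'
#' @param subjects list of `spondy_subject`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_landmarks <- function(subjects, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lm_rows <- list(); lv_rows <- list(); su_rows <- list()
  for (s in subjects) {
    seen <- character(0)
    for (lv in s$levels) {
      for (v in list(lv$sup, lv$inf)) {
        if (v$label %in% seen) next
        seen <- c(seen, v$label)
        lm_rows[[length(lm_rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, vertebra = v$label,
          x_as = v$as_pt[1], y_as = v$as_pt[2], x_ps = v$ps_pt[1],
          y_ps = v$ps_pt[2], x_ai = v$ai_pt[1], y_ai = v$ai_pt[2],
          x_pi = v$pi_pt[1], y_pi = v$pi_pt[2])
      }
      lv_rows[[length(lv_rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, level_name = lv$level_name,
        osteo_flag = lv$osteo_flag)
    }
    su_rows[[length(su_rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, age = s$age, sex = s$sex, bmi = s$bmi,
      back_pain = s$back_pain, position = s$position)
  }
  paths <- file.path(dir, c("landmarks.csv", "levels.csv", "subjects.csv"))
  write_table(do.call(rbind, lm_rows), paths[1])
  write_table(do.call(rbind, lv_rows), paths[2])
  write_table(do.call(rbind, su_rows), paths[3])
  invisible(paths)
}
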