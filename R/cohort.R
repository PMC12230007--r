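# CSV dialect: UTF-8, comma separator, header row, "." decimal point,
# empty string = missing. Codes: timepoint {0 = baseline, 1 = follow-up},
# sex {F, M}, booleans {0, 1}. See inst/extdata/column_dictionary.csv.

cohort_base_types <- list(
  participant_id = "character", timepoint = "integer",
  age = "numeric", sex = "character", education = "character",
  hgs = "numeric", bmi = "numeric", weight_loss_3mo = "numeric",
  appetite_loss = "logical", wears_glasses = "logical",
  vision_difficulty = "logical", uses_hearing_aid = "logical",
  hearing_difficulty = "logical", tug = "numeric",
  chair_stand = "integer", sit_reach = "numeric", balance = "numeric",
  gds15 = "integer", moca = "integer"
)

ic_score_cols <- c("sensory", "psychological", "cognitive", "vitality",
                   "locomotion", "composite", "category")

convert_col <- function(x, type, col) {
  if (type == "character") return(as.character(x))
  orig <- as.character(x)
  out <- switch(type,
    numeric = suppressWarnings(as.numeric(orig)),
    integer = suppressWarnings(as.integer(orig)),
    logical = {
      v <- suppressWarnings(as.integer(orig))
      v[!is.na(v) & !(v %in% 0:1)] <- NA_integer_
      as.logical(v)
    },
    stop("unknown column type: ", type, call. = FALSE)
  )
  bad <- which(is.na(out) & !is.na(orig) & nzchar(orig))
  if (length(bad)) {
    stop(sprintf("unparseable value \"%s\" in column %s, row %d",
                 orig[bad[1]], col, bad[1]), call. = FALSE)
  }
  out
}

#' Read a longitudinal cohort CSV
#'
#' Reads and validates a long-format cohort file: one row per participant per
#' timepoint, with the raw assessment columns (see
#' `system.file("extdata", "column_dictionary.csv", package = "icap")`) and
#' any number of declared secondary outcome columns. The dialect is UTF-8,
#' comma-separated, `"."` decimal point, empty cell = missing; `timepoint` is
#' coded 0 (baseline) / 1 (follow-up), sex `F`/`M`, booleans 0/1.
#'
#' Integrity rules enforced: `(participant_id, timepoint)` pairs unique;
#' every participant has a baseline row (follow-up rows are optional --
#' dropout); ordinal outcome values must lie within their declared levels.
#'
#' @param path CSV path.
#' @param outcomes named list declaring secondary outcome columns, each entry
#'   a list with `type` in `"continuous"`, `"continuous-skewed"`, `"ordinal"`,
#'   `"binary"`, and for ordinal a character `levels` vector in order.
#'   Declared columns must exist in the file.
#' @return A `data.frame` of class `"cohort_table"` with typed columns;
#'   ordinal outcomes become ordered factors; the outcome declaration is
#'   attached as attribute `"outcomes"`.
#' @export
read_cohort <- function(path, outcomes = list()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         fileEncoding = "UTF-8", check.names = FALSE)
  need <- names(cohort_base_types)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (col in intersect(names(raw), names(cohort_base_types))) {
    out[[col]] <- convert_col(raw[[col]], cohort_base_types[[col]], col)
  }
  if (any(!out$timepoint %in% c(0L, 1L))) {
    stop("timepoint must be coded 0 (baseline) or 1 (follow-up)", call. = FALSE)
  }
  for (col in intersect(names(raw), ic_score_cols)) {
    if (col == "category") next
    out[[col]] <- convert_col(raw[[col]], "numeric", col)
  }
  for (nm in names(outcomes)) {
    spec <- outcomes[[nm]]
    if (!nm %in% names(out)) {
      stop("declared outcome column not in file: ", nm, call. = FALSE)
    }
    if (spec$type %in% c("continuous", "continuous-skewed")) {
      out[[nm]] <- convert_col(raw[[nm]], "numeric", nm)
    } else if (spec$type == "binary") {
      out[[nm]] <- convert_col(raw[[nm]], "integer", nm)
      if (any(!is.na(out[[nm]]) & !(out[[nm]] %in% 0:1))) {
        stop("binary outcome ", nm, " must be coded 0/1", call. = FALSE)
      }
    } else if (spec$type == "ordinal") {
      vals <- as.character(raw[[nm]])
      bad <- setdiff(vals[!is.na(vals)], spec$levels)
      if (length(bad)) {
        stop("ordinal outcome ", nm, " has value(s) outside declared levels: ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
      }
      out[[nm]] <- factor(vals, levels = spec$levels, ordered = TRUE)
    } else {
      stop("unknown outcome type for ", nm, ": ", spec$type, call. = FALSE)
    }
  }
  key <- paste(out$participant_id, out$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (participant_id, timepoint) pair: (%s, %d)",
                 d$participant_id, d$timepoint), call. = FALSE)
  }
  base_ids <- out$participant_id[out$timepoint == 0L]
  orphans <- setdiff(out$participant_id[out$timepoint == 1L], base_ids)
  if (length(orphans)) {
    stop("follow-up row(s) without a baseline row: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  attr(out, "outcomes") <- outcomes
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table as CSV
#'
#' Inverse of [read_cohort()]: booleans become 0/1, factors their labels,
#' missing values empty cells. Reading the file back (with the same outcome
#' declaration) reproduces all values exactly; score columns lie on the exact
#' 0.5 grid, and raw measures are stored at instrument precision, so the
#' round trip is lossless.
#'
#' @param x a cohort (or scored cohort) data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a scored cohort, checking score columns are present
#'
#' @param x a cohort data frame produced by [ic_score()] (must contain the
#'   five domain-score columns plus `composite` and `category`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(x, path) {
  missing_cols <- setdiff(ic_score_cols, names(x))
  if (length(missing_cols)) {
    stop("scored table is missing score column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  write_cohort(x, path)
}

#' Enrolment summary of a cohort table
#'
#' @param x a cohort table.
#' @return List with `n_enrolled` (participants with a baseline row),
#'   `n_complete` (participants with both timepoints) and `n_dropout`.
#' @export
cohort_counts <- function(x) {
  base_ids <- unique(x$participant_id[x$timepoint == 0L])
  fu_ids <- unique(x$participant_id[x$timepoint == 1L])
  list(n_enrolled = length(base_ids),
       n_complete = length(intersect(base_ids, fu_ids)),
       n_dropout = length(setdiff(base_ids, fu_ids)))
}
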