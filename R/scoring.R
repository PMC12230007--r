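#' @keywords internal
"_PACKAGE"

# All sub-scores are exact multiples of 0.5. Powers of two are exactly
# representable in binary doubles, so sums over the 0.5 grid are exact and
# equality tests against grid values are safe. Internally every domain score
# is accumulated as 0.5 * (number of passing sub-rules).

check_no_na <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (anyNA(args[[nm]])) {
      stop("missing value in required field: ", nm, call. = FALSE)
    }
  }
  invisible(NULL)
}

check_sex <- function(sex) {
  bad <- setdiff(unique(as.character(sex)), c("F", "M"))
  if (length(bad)) {
    stop("unknown sex category: ", paste(bad, collapse = ", "),
         " (expected \"F\" or \"M\")", call. = FALSE)
  }
  invisible(NULL)
}

#' Vitality domain score
#'
#' Four pass/fail sub-rules, each worth 0.5 points: handgrip strength at or
#' above the sex-specific cutoff (27 kgf men, 16 kgf women); BMI inside the
#' closed band 22--27 kg/m\eqn{^2}; unintentional weight loss over the last
#' 3 months below 3 kg; no self-reported appetite loss. The domain score is
#' the sum, in \{0, 0.5, 1, 1.5, 2\}.
#'
#' @param hgs handgrip strength in kgf (non-negative).
#' @param sex `"F"` or `"M"`.
#' @param bmi body mass index in kg/m\eqn{^2} (positive).
#' @param weight_loss_3mo unintentional weight loss in kg over 3 months
#'   (non-negative; 0 means none).
#' @param appetite_loss logical; `TRUE` if appetite loss was reported.
#' @param thresholds an [ic_thresholds()] object.
#' @param detail if `TRUE`, return a data frame with one column per sub-rule
#'   (0/0.5 each) plus `score`.
#' @return Numeric vector of domain scores (or a data frame when
#'   `detail = TRUE`). All arguments are vectorized and recycled to a common
#'   length by the usual rules.
#' @export
score_vitality <- function(hgs, sex, bmi, weight_loss_3mo, appetite_loss,
                           thresholds = ic_thresholds(), detail = FALSE) {
  check_no_na(hgs = hgs, sex = sex, bmi = bmi,
              weight_loss_3mo = weight_loss_3mo, appetite_loss = appetite_loss)
  check_sex(sex)
  stopifnot(all(hgs >= 0), all(bmi > 0), all(weight_loss_3mo >= 0),
            is.logical(appetite_loss) || all(appetite_loss %in% c(0, 1)))
  f <- thresholds$fixed
  hgs_cut <- ifelse(sex == "M", f$hgs_male_min, f$hgs_female_min)
  sub <- cbind(
    hgs = 0.5 * (hgs >= hgs_cut),
    bmi = 0.5 * (bmi >= f$bmi_low & bmi <= f$bmi_high),
    weight_loss = 0.5 * (weight_loss_3mo < f$weight_loss_kg),
    appetite = 0.5 * (!as.logical(appetite_loss))
  )
  score <- rowSums(sub)
  if (detail) return(data.frame(sub, score = score))
  score
}

#' Sensory domain score
#'
#' Vision and hearing each contribute 0 or 1 point. A sense scores 1 only
#' when the participant reports neither difficulty nor use of a corrective
#' device (prescription glasses / hearing aid); any impairment indicator
#' scores 0. The domain score is the sum, in \{0, 1, 2\}.
#'
#' @param wears_glasses,vision_difficulty,uses_hearing_aid,hearing_difficulty
#'   logical flags (self-report).
#' @param detail if `TRUE`, return a data frame with `vision`, `hearing` and
#'   `score` columns.
#' @return Numeric vector of domain scores (or data frame when `detail = TRUE`).
#' @export
score_sensory <- function(wears_glasses, vision_difficulty,
                          uses_hearing_aid, hearing_difficulty,
                          detail = FALSE) {
  check_no_na(wears_glasses = wears_glasses,
              vision_difficulty = vision_difficulty,
              uses_hearing_aid = uses_hearing_aid,
              hearing_difficulty = hearing_difficulty)
  vision <- 1 * (!as.logical(vision_difficulty) & !as.logical(wears_glasses))
  hearing <- 1 * (!as.logical(hearing_difficulty) & !as.logical(uses_hearing_aid))
  score <- vision + hearing
  if (detail) return(data.frame(vision = vision, hearing = hearing, score = score))
  score
}

#' Locomotion domain score
#'
#' Four pass/fail sub-rules, each worth 0.5 points: Timed Up and Go strictly
#' under 10 s; sit-to-stand repetitions at or above the age- and sex-specific
#' norm; sit-and-reach inside the recommended range (closed interval); and a
#' one-leg stand held strictly longer than 20 s. The domain score is the sum,
#' in \{0, 0.5, 1, 1.5, 2\}.
#'
#' @param tug Timed Up and Go time in seconds (positive).
#' @param chair_stand sit-to-stand repetitions (non-negative integer).
#' @param sit_reach sit-and-reach distance in centimetres (may be negative).
#' @param balance one-leg stand time in seconds (non-negative).
#' @param age age in whole years (>= 60); with `sex`, keys the norm lookups.
#' @param sex `"F"` or `"M"`.
#' @param thresholds an [ic_thresholds()] object whose norm table covers
#'   every requested (sex, age); a missing band is an error.
#' @param detail if `TRUE`, return the per-sub-rule breakdown.
#' @return Numeric vector of domain scores (or data frame when `detail = TRUE`).
#' @export
score_locomotion <- function(tug, chair_stand, sit_reach, balance, age, sex,
                             thresholds = ic_thresholds(), detail = FALSE) {
  check_no_na(tug = tug, chair_stand = chair_stand, sit_reach = sit_reach,
              balance = balance, age = age, sex = sex)
  check_sex(sex)
  stopifnot(all(tug > 0), all(chair_stand >= 0), all(balance >= 0),
            all(age >= 60))
  n <- max(length(tug), length(chair_stand), length(sit_reach),
           length(balance), length(age), length(sex))
  sex <- rep_len(as.character(sex), n); age <- rep_len(age, n)
  cs_min <- vapply(seq_len(n), function(i)
    norm_chair_stand_min(thresholds, sex[i], age[i]), numeric(1))
  sr <- vapply(seq_len(n), function(i)
    norm_sit_reach_range(thresholds, sex[i], age[i]), numeric(2))
  f <- thresholds$fixed
  sub <- cbind(
    tug = 0.5 * (rep_len(tug, n) < f$tug_max),
    chair_stand = 0.5 * (rep_len(chair_stand, n) >= cs_min),
    sit_reach = 0.5 * (rep_len(sit_reach, n) >= sr[1, ] &
                         rep_len(sit_reach, n) <= sr[2, ]),
    balance = 0.5 * (rep_len(balance, n) > f$balance_min)
  )
  score <- rowSums(sub)
  if (detail) return(data.frame(sub, score = score))
  score
}

#' Psychological domain score
#'
#' Banded scoring of the 15-item Geriatric Depression Scale total:
#' 0--5 points scores 2, 6--10 scores 1, 11--15 scores 0.
#'
#' @param gds15 GDS-15 total, integer in 0..15.
#' @param thresholds an [ic_thresholds()] object (uses `gds_band_edges`).
#' @return Numeric vector of domain scores in \{0, 1, 2\}.
#' @export
score_psychological <- function(gds15, thresholds = ic_thresholds()) {
  check_no_na(gds15 = gds15)
  if (any(gds15 < 0 | gds15 > 15)) {
    stop("gds15 out of range 0..15", call. = FALSE)
  }
  g <- thresholds$fixed$gds_band_edges
  ifelse(gds15 <= g[1], 2, ifelse(gds15 <= g[2], 1, 0))
}

#' Cognition domain score
#'
#' All-or-nothing scoring of the Montreal Cognitive Assessment against the
#' education-adjusted cutoff: at or above the cutoff scores 2, below it 0.
#'
#' @param moca MoCA total, integer in 0..30.
#' @param education education band label, resolved against the configured
#'   MoCA cutoff table.
#' @param thresholds an [ic_thresholds()] object (uses its `moca` table).
#' @return Numeric vector of domain scores in \{0, 2\}.
#' @export
score_cognition <- function(moca, education, thresholds = ic_thresholds()) {
  check_no_na(moca = moca, education = education)
  if (any(moca < 0 | moca > 30)) stop("moca out of range 0..30", call. = FALSE)
  n <- max(length(moca), length(education))
  education <- rep_len(as.character(education), n)
  cut <- vapply(education, function(e) moca_cutoff(thresholds, e),
                numeric(1), USE.NAMES = FALSE)
  ifelse(rep_len(moca, n) >= cut, 2, 0)
}

domain_value_sets <- list(
  sensory = c(0, 1, 2),
  psychological = c(0, 1, 2),
  cognitive = c(0, 2),
  vitality = c(0, 0.5, 1, 1.5, 2),
  locomotion = c(0, 0.5, 1, 1.5, 2)
)

#' Composite intrinsic-capacity score
#'
#' Unweighted sum of the five domain scores (each 0--2), giving a composite
#' on the half-point grid 0--10, plus its low/moderate/high classification.
#'
#' @param sensory,psychological,cognitive,vitality,locomotion domain scores,
#'   each within its admissible value set.
#' @param thresholds an [ic_thresholds()] object (classification bands).
#' @return A data frame with columns `score` (points) and `category`
#'   (factor low/moderate/high).
#' @export
ic_composite <- function(sensory, psychological, cognitive, vitality,
                         locomotion, thresholds = ic_thresholds()) {
  doms <- list(sensory = sensory, psychological = psychological,
               cognitive = cognitive, vitality = vitality,
               locomotion = locomotion)
  for (nm in names(doms)) {
    if (anyNA(doms[[nm]])) {
      stop("missing value in required field: ", nm, call. = FALSE)
    }
    bad <- !(doms[[nm]] %in% domain_value_sets[[nm]])
    if (any(bad)) {
      stop(nm, " domain score outside its value set {",
           paste(domain_value_sets[[nm]], collapse = ", "), "}", call. = FALSE)
    }
  }
  score <- sensory + psychological + cognitive + vitality + locomotion
  data.frame(score = score, category = classify_ic(score, thresholds))
}

#' Classify a composite intrinsic-capacity score
#'
#' Bands follow the published integer definition -- 0--4 low, 5--8 moderate,
#' 9--10 high -- extended to the half-point grid so the partition is total:
#' low is below 5, moderate is at least 5 and below 9, high is 9 or more
#' (so 4.5 is low and 8.5 moderate). Band edges are configurable via
#' `composite_low_max` / `composite_moderate_max`.
#'
#' @param score composite score(s) in \[0, 10\].
#' @param thresholds an [ic_thresholds()] object.
#' @return Factor with ordered levels `low`, `moderate`, `high`.
#' @export
classify_ic <- function(score, thresholds = ic_thresholds()) {
  check_no_na(score = score)
  if (any(score < 0 | score > 10)) {
    stop("composite score out of range 0..10", call. = FALSE)
  }
  f <- thresholds$fixed
  lab <- ifelse(score < f$composite_low_max + 1, "low",
                ifelse(score < f$composite_moderate_max + 1, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"))
}

ic_raw_fields <- c("age", "sex", "education", "hgs", "bmi", "weight_loss_3mo",
                   "appetite_loss", "wears_glasses", "vision_difficulty",
                   "uses_hearing_aid", "hearing_difficulty", "tug",
                   "chair_stand", "sit_reach", "balance", "gds15", "moca")

#' Score a single assessment record
#'
#' Applies the five domain scorers and the composite to one participant
#' assessment. Every raw field must be present and non-missing: partial
#' scoring is refused (a hard error naming the offending field(s)), mirroring
#' the requirement that participants complete assessments in all five domains.
#'
#' @param record a named list or one-row data frame with the raw assessment
#'   fields (`age`, `sex`, `education`, `hgs`, `bmi`, `weight_loss_3mo`,
#'   `appetite_loss`, `wears_glasses`, `vision_difficulty`,
#'   `uses_hearing_aid`, `hearing_difficulty`, `tug`, `chair_stand`,
#'   `sit_reach`, `balance`, `gds15`, `moca`).
#' @param thresholds an [ic_thresholds()] object with norm and MoCA tables
#'   covering the record.
#' @return A list with elements `domains` (named numeric: sensory,
#'   psychological, cognitive, vitality, locomotion), `score` and `category`.
#' @examples
#' th <- example_thresholds()
#' rec <- list(age = 65, sex = "F", education = "high", hgs = 25, bmi = 24,
#'             weight_loss_3mo = 0, appetite_loss = FALSE,
#'             wears_glasses = FALSE, vision_difficulty = FALSE,
#'             uses_hearing_aid = FALSE, hearing_difficulty = FALSE,
#'             tug = 8.5, chair_stand = 14, sit_reach = 2, balance = 30,
#'             gds15 = 2, moca = 28)
#' score_record(rec, th)
#' @export
score_record <- function(record, thresholds = ic_thresholds()) {
  record <- as.list(record)
  present <- vapply(ic_raw_fields, function(f)
    !is.null(record[[f]]) && !anyNA(record[[f]]), logical(1))
  if (!all(present)) {
    stop("record is missing required field(s): ",
         paste(ic_raw_fields[!present], collapse = ", "), call. = FALSE)
  }
  doms <- c(
    sensory = score_sensory(record$wears_glasses, record$vision_difficulty,
                            record$uses_hearing_aid, record$hearing_difficulty),
    psychological = score_psychological(record$gds15, thresholds),
    cognitive = score_cognition(record$moca, record$education, thresholds),
    vitality = score_vitality(record$hgs, record$sex, record$bmi,
                              record$weight_loss_3mo, record$appetite_loss,
                              thresholds),
    locomotion = score_locomotion(record$tug, record$chair_stand,
                                  record$sit_reach, record$balance,
                                  record$age, record$sex, thresholds)
  )
  comp <- ic_composite(doms[["sensory"]], doms[["psychological"]],
                       doms[["cognitive"]], doms[["vitality"]],
                       doms[["locomotion"]], thresholds)
  list(domains = doms, score = comp$score, category = comp$category)
}

#' Score every record of a cohort table
#'
#' Adds the five domain-score columns plus `composite` and `category` to a
#' long-format cohort table (one row per participant per timepoint). All
#' rows must be complete in the raw assessment fields.
#'
#' @param cohort a cohort data frame (see [read_cohort()]) containing the raw
#'   assessment columns.
#' @param thresholds an [ic_thresholds()] object.
#' @return The input data frame with columns `sensory`, `psychological`,
#'   `cognitive`, `vitality`, `locomotion`, `composite`, `category` appended.
#' @export
ic_score <- function(cohort, thresholds = ic_thresholds()) {
  missing_cols <- setdiff(ic_raw_fields, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (f in ic_raw_fields) {
    if (anyNA(cohort[[f]])) {
      bad <- which(is.na(cohort[[f]]))[1]
      stop("missing value in required field ", f, " (row ", bad, ")",
           call. = FALSE)
    }
  }
  out <- cohort
  out$sensory <- score_sensory(cohort$wears_glasses, cohort$vision_difficulty,
                               cohort$uses_hearing_aid, cohort$hearing_difficulty)
  out$psychological <- score_psychological(cohort$gds15, thresholds)
  out$cognitive <- score_cognition(cohort$moca, cohort$education, thresholds)
  out$vitality <- score_vitality(cohort$hgs, cohort$sex, cohort$bmi,
                                 cohort$weight_loss_3mo, cohort$appetite_loss,
                                 thresholds)
  out$locomotion <- score_locomotion(cohort$tug, cohort$chair_stand,
                                     cohort$sit_reach, cohort$balance,
                                     cohort$age, cohort$sex, thresholds)
  comp <- ic_composite(out$sensory, out$psychological, out$cognitive,
                       out$vitality, out$locomotion, thresholds)
  out$composite <- comp$score
  out$category <- comp$category
  out
}
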