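# Shared fixtures and independent oracles.

# Small hand-written threshold fixture: one norm band per sex at ages 60-69,
# one extra female band to exercise boundary matching, two education bands.
fixture_thresholds <- function() {
  ic_thresholds(
    norms = data.frame(
      sex = c("F", "F", "M"),
      age_min = c(60, 65, 60),
      age_max = c(64, 69, 69),
      chair_stand_min = c(12, 11, 14),
      sit_reach_min = c(-0.5, -0.5, -2.5),
      sit_reach_max = c(5.0, 4.5, 4.0),
      stringsAsFactors = FALSE
    ),
    moca = data.frame(education = c("low", "high"), cutoff = c(24, 26),
                      stringsAsFactors = FALSE)
  )
}

# A complete assessment record with every sub-item at its most favourable
# level (given the fixture thresholds); fields can be overridden.
favourable_record <- function(...) {
  rec <- list(
    participant_id = "P01", timepoint = 0L,
    age = 62, sex = "F", education = "high",
    hgs = 30, bmi = 24.5, weight_loss_3mo = 0, appetite_loss = FALSE,
    wears_glasses = FALSE, vision_difficulty = FALSE,
    uses_hearing_aid = FALSE, hearing_difficulty = FALSE,
    tug = 9.0, chair_stand = 14L, sit_reach = 2.0, balance = 25,
    gds15 = 0L, moca = 28L
  )
  utils::modifyList(rec, list(...))
}

# Independent oracle: a literal transcription of the published rule table,
# written as explicit if-chains and direct table subsets (no reuse of the
# package scorers). Returns the five domain scores, composite and class.
oracle_score <- function(rec, th) {
  f <- th$fixed
  hgs_sub <- if (rec$sex == "M") {
    if (rec$hgs >= f$hgs_male_min) 0.5 else 0
  } else {
    if (rec$hgs >= f$hgs_female_min) 0.5 else 0
  }
  bmi_sub <- if (rec$bmi >= f$bmi_low && rec$bmi <= f$bmi_high) 0.5 else 0
  wl_sub <- if (rec$weight_loss_3mo >= f$weight_loss_kg) 0 else 0.5
  app_sub <- if (rec$appetite_loss) 0 else 0.5
  vitality <- hgs_sub + bmi_sub + wl_sub + app_sub

  vision <- if (!rec$vision_difficulty && !rec$wears_glasses) 1 else 0
  hearing <- if (!rec$hearing_difficulty && !rec$uses_hearing_aid) 1 else 0
  sensory <- vision + hearing

  tug_sub <- if (rec$tug < f$tug_max) 0.5 else 0
  row <- th$norms[th$norms$sex == rec$sex &
                    th$norms$age_min <= rec$age &
                    rec$age <= th$norms$age_max, ]
  stopifnot(nrow(row) == 1)
  cs_sub <- if (rec$chair_stand >= row$chair_stand_min) 0.5 else 0
  sr_sub <- if (rec$sit_reach >= row$sit_reach_min &&
                  rec$sit_reach <= row$sit_reach_max) 0.5 else 0
  bal_sub <- if (rec$balance > f$balance_min) 0.5 else 0
  locomotion <- tug_sub + cs_sub + sr_sub + bal_sub

  psychological <- if (rec$gds15 >= 0 && rec$gds15 <= 5) 2 else
    if (rec$gds15 <= 10) 1 else 0

  cut <- th$moca$cutoff[th$moca$education == rec$education]
  cognitive <- if (rec$moca >= cut) 2 else 0

  score <- sensory + psychological + cognitive + vitality + locomotion
  category <- if (score < 5) "low" else if (score < 9) "moderate" else "high"
  list(sensory = sensory, psychological = psychological,
       cognitive = cognitive, vitality = vitality, locomotion = locomotion,
       score = score, category = category)
}

# Deterministic two-timepoint dataset used to freeze external GEE reference
# values (continuous outcome y, binary outcome yb, 4 dropouts).
oracle_dataset <- function() {
  set.seed(2024)
  n <- 30
  id <- sprintf("P%02d", seq_len(n))
  b <- rnorm(n, 50, 8)
  pre <- round(b + rnorm(n, 0, 3), 2)
  post <- round(b + 2.5 + rnorm(n, 0, 3), 2)
  pb <- plogis(-0.4 + 0.05 * (b - 50))
  yb_pre <- as.integer(runif(n) < pb)
  yb_post <- as.integer(runif(n) < plogis(qlogis(pb) + 0.8))
  keep_fu <- rep(TRUE, n); keep_fu[sample.int(n, 4)] <- FALSE
  d <- rbind(
    data.frame(participant_id = id, timepoint = 0L, y = pre, yb = yb_pre),
    data.frame(participant_id = id, timepoint = 1L, y = post,
               yb = yb_post)[keep_fu, ]
  )
  d[order(d$participant_id, d$timepoint), ]
}

# Paired-mean-difference oracle for the balanced two-timepoint linear GEE.
paired_mean_diff <- function(data, variable) {
  pre <- data[data$timepoint == 0L, ]
  post <- data[data$timepoint == 1L, ]
  v <- post[[variable]][match(pre$participant_id, post$participant_id)] -
    pre[[variable]]
  mean(v, na.rm = TRUE)
}

# Enumeration grid crossing every scoring rule's boundary (about 1.4e4
# cells); sensory flag combinations are cycled across rows so all 16 appear
# many times.
scoring_grid <- function(th) {
  g <- expand.grid(
    sex = c("F", "M"),
    hgs_off = c(-1, 0, 1),
    bmi = c(21, 22, 27, 28),
    weight_loss_3mo = c(2.9, 3),
    appetite_loss = c(FALSE, TRUE),
    tug = c(8, 10, 12),
    balance = c(20, 21),
    gds15 = c(0L, 5L, 6L, 10L, 11L, 15L),
    moca = c(25L, 26L),
    stringsAsFactors = FALSE
  )
  n <- nrow(g)
  flags <- expand.grid(wears_glasses = c(FALSE, TRUE),
                       vision_difficulty = c(FALSE, TRUE),
                       uses_hearing_aid = c(FALSE, TRUE),
                       hearing_difficulty = c(FALSE, TRUE))
  fi <- rep_len(seq_len(16), n)
  g <- cbind(g, flags[fi, ], row.names = NULL)
  g$age <- 62
  g$education <- "high"
  g$hgs <- ifelse(g$sex == "M", th$fixed$hgs_male_min,
                  th$fixed$hgs_female_min) + g$hgs_off
  cs_min <- ifelse(g$sex == "M", 14L, 12L)  # fixture bands at age 62
  g$chair_stand <- cs_min + rep_len(c(-1L, 0L), n)
  g$sit_reach <- rep_len(c(-3, 0, 6), n)
  g$participant_id <- sprintf("G%05d", seq_len(n))
  g$timepoint <- 0L
  g
}
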