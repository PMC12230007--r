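th <- fixture_thresholds()

test_that("vitality sums four half-point sub-rules with inclusive boundaries", {
  expect_equal(score_vitality(30, "M", 24.5, 0, FALSE, th), 2.0)
  expect_equal(score_vitality(14, "F", 20, 4, TRUE, th), 0.0)
  # every boundary lands on its passing side: hgs == cutoff, bmi == band
  # edge, weight loss just under the limit
  expect_equal(score_vitality(16.0, "F", 27.0, 2.9, FALSE, th), 2.0)
  expect_equal(score_vitality(27.0, "M", 22.0, 0, FALSE, th), 2.0)
  # a man at 25 kgf fails only the handgrip sub-rule
  d <- score_vitality(25, "M", 24.5, 0, FALSE, th, detail = TRUE)
  expect_equal(d$hgs, 0)
  expect_equal(d$score, 1.5)
  expect_error(score_vitality(20, "X", 24, 0, FALSE, th), "unknown sex")
  expect_error(score_vitality(NA, "F", 24, 0, FALSE, th), "missing value")
})

test_that("sensory scores 1 per sense only when free of difficulty and device", {
  expect_equal(score_sensory(FALSE, FALSE, FALSE, FALSE), 2)
  expect_equal(score_sensory(TRUE, TRUE, TRUE, TRUE), 0)
  expect_equal(score_sensory(TRUE, FALSE, FALSE, FALSE), 1)
  # brute force over all 16 flag states against the any-impairment rule
  g <- expand.grid(gl = c(FALSE, TRUE), vd = c(FALSE, TRUE),
                   ha = c(FALSE, TRUE), hd = c(FALSE, TRUE))
  got <- score_sensory(g$gl, g$vd, g$ha, g$hd)
  want <- (!g$vd & !g$gl) + (!g$hd & !g$ha)
  expect_equal(got, as.numeric(want))
})

test_that("locomotion sums four half-point sub-rules with strict TUG/balance ties", {
  expect_equal(score_locomotion(9.0, 14, 2, 25, 62, "F", th), 2.0)
  expect_equal(score_locomotion(12, 10, 6, 15, 62, "F", th), 0.0)
  expect_equal(score_locomotion(9.5, 10, 2, 30, 62, "F", th), 1.5)
  # tie handling: TUG at exactly 10 s fails; balance at exactly 20 s fails,
  # 21 s passes, and anything strictly over 20 s passes
  expect_equal(score_locomotion(10.0, 14, 2, 21, 62, "F", th), 1.5)
  expect_equal(score_locomotion(9.9, 14, 2, 20.0, 62, "F", th), 1.5)
  expect_equal(score_locomotion(9.9, 14, 2, 20.5, 62, "F", th), 2.0)
  # each pass/fail combination scores 0.5 per passing sub-rule
  combos <- expand.grid(tug = c(8, 12), cs = c(14, 10), sr = c(2, 8),
                        bal = c(25, 10))
  got <- score_locomotion(combos$tug, combos$cs, combos$sr, combos$bal,
                          62, "F", th)
  want <- 0.5 * ((combos$tug < 10) + (combos$cs >= 12) +
                   (combos$sr >= -0.5 & combos$sr <= 5) + (combos$bal > 20))
  expect_equal(got, want)
  expect_error(score_locomotion(9, 12, 2, 25, 75, "F", th), "age=75")
})

test_that("psychological applies the GDS-15 bands 0-5/6-10/11-15", {
  expect_equal(score_psychological(3, th), 2)
  expect_equal(score_psychological(8, th), 1)
  expect_equal(score_psychological(13, th), 0)
  expect_equal(score_psychological(c(0, 5, 6, 10, 11, 15), th),
               c(2, 2, 1, 1, 0, 0))
  expect_error(score_psychological(16, th), "0..15", fixed = TRUE)
})

test_that("cognition is a single step at the education-adjusted cutoff", {
  expect_equal(score_cognition(28, "high", th), 2)
  expect_equal(score_cognition(20, "high", th), 0)
  expect_equal(score_cognition(26, "high", th), 2)  # at-cutoff passes
  scores <- score_cognition(0:30, "high", th)
  expect_true(all(scores %in% c(0, 2)))
  expect_equal(sum(diff(scores) != 0), 1)            # exactly one jump
  expect_equal(which(diff(scores) != 0), 26)         # located at the cutoff
  expect_error(score_cognition(25, "unknown-band", th), "unknown-band")
})

test_that("composite sums the five domains and classifies consistently", {
  full <- ic_composite(2, 2, 2, 2, 2, th)
  expect_equal(full$score, 10)
  expect_equal(as.character(full$category), "high")
  zero <- ic_composite(0, 0, 0, 0, 0, th)
  expect_equal(zero$score, 0)
  expect_equal(as.character(zero$category), "low")
  mid <- ic_composite(1, 2, 2, 1.5, 1.5, th)
  expect_equal(mid$score, 8)
  expect_equal(as.character(mid$category), "moderate")
  expect_error(ic_composite(1.5, 2, 2, 2, 2, th), "sensory")
  expect_error(ic_composite(1, 2, 1, 2, 2, th), "cognitive")
})

test_that("classifier partitions the half-point grid monotonically", {
  expect_equal(as.character(classify_ic(4, th)), "low")
  expect_equal(as.character(classify_ic(9, th)), "high")
  expect_equal(as.character(classify_ic(4.5, th)), "low")
  expect_equal(as.character(classify_ic(8.5, th)), "moderate")
  grid <- seq(0, 10, by = 0.5)
  cls <- classify_ic(grid, th)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_equal(as.character(unique(cls)), c("low", "moderate", "high"))
  expect_error(classify_ic(10.5, th), "0..10", fixed = TRUE)
})

test_that("score_record composes the domains and demands completeness", {
  res <- score_record(favourable_record(), th)
  expect_equal(res$score, 10)
  expect_equal(as.character(res$category), "high")
  expect_identical(score_record(favourable_record(), th), res)  # idempotent
  rec <- favourable_record(); rec$gds15 <- NULL
  expect_error(score_record(rec, th), "gds15")
  rec2 <- favourable_record(moca = NA)
  expect_error(score_record(rec2, th), "moca")
})

test_that("scorers agree with the literal decision-table oracle on random records", {
  set.seed(41)
  for (i in 1:200) {
    rec <- favourable_record(
      sex = sample(c("F", "M"), 1),
      age = sample(60:69, 1),
      education = sample(c("low", "high"), 1),
      hgs = round(runif(1, 10, 35), 1),
      bmi = round(runif(1, 18, 31), 1),
      weight_loss_3mo = round(runif(1, 0, 5), 1),
      appetite_loss = runif(1) < 0.5,
      wears_glasses = runif(1) < 0.5,
      vision_difficulty = runif(1) < 0.5,
      uses_hearing_aid = runif(1) < 0.5,
      hearing_difficulty = runif(1) < 0.5,
      tug = round(runif(1, 7, 13), 1),
      chair_stand = sample(8:16, 1),
      sit_reach = round(runif(1, -6, 8), 1),
      balance = round(runif(1, 10, 30), 1),
      gds15 = sample(0:15, 1),
      moca = sample(20:30, 1)
    )
    want <- oracle_score(rec, th)
    got <- score_record(rec, th)
    expect_equal(unname(got$domains["sensory"]), want$sensory)
    expect_equal(unname(got$domains["psychological"]), want$psychological)
    expect_equal(unname(got$domains["cognitive"]), want$cognitive)
    expect_equal(unname(got$domains["vitality"]), want$vitality)
    expect_equal(unname(got$domains["locomotion"]), want$locomotion)
    expect_equal(got$score, want$score)
    expect_equal(as.character(got$category), want$category)
  }
})

test_that("improving any single raw measure never lowers a score", {
  set.seed(42)
  better <- list(
    function(r) { r$hgs <- r$hgs + 2; r },
    function(r) { r$tug <- max(r$tug - 1, 0.1); r },
    function(r) { r$chair_stand <- r$chair_stand + 1L; r },
    function(r) { r$balance <- r$balance + 2; r },
    function(r) { r$sit_reach <- 2; r },  # into every fixture band's range
    function(r) { r$gds15 <- max(r$gds15 - 1L, 0L); r },
    function(r) { r$moca <- min(r$moca + 1L, 30L); r },
    function(r) { r$weight_loss_3mo <- max(r$weight_loss_3mo - 1, 0); r },
    function(r) { r$appetite_loss <- FALSE; r },
    function(r) { r$wears_glasses <- FALSE; r$vision_difficulty <- FALSE; r },
    function(r) { r$uses_hearing_aid <- FALSE; r$hearing_difficulty <- FALSE; r }
  )
  for (i in 1:50) {
    rec <- favourable_record(
      sex = sample(c("F", "M"), 1), age = sample(60:69, 1),
      hgs = runif(1, 10, 35), bmi = runif(1, 18, 31),
      weight_loss_3mo = runif(1, 0, 5), appetite_loss = runif(1) < 0.5,
      wears_glasses = runif(1) < 0.5, vision_difficulty = runif(1) < 0.5,
      uses_hearing_aid = runif(1) < 0.5, hearing_difficulty = runif(1) < 0.5,
      tug = runif(1, 7, 13), chair_stand = sample(8:16, 1),
      sit_reach = runif(1, -6, 8), balance = runif(1, 10, 30),
      gds15 = sample(0:15, 1), moca = sample(20:30, 1)
    )
    base <- score_record(rec, th)$score
    for (fn in better) {
      expect_gte(score_record(fn(rec), th)$score, base)
    }
  }
})

test_that("domain scores stay on their declared grids for a whole cohort", {
  coh <- generate_cohort(cohort_config(seed = 5, n = 60, dropout_n = 4))
  sc <- ic_score(coh, example_thresholds())
  expect_true(all(sc$sensory %in% c(0, 1, 2)))
  expect_true(all(sc$psychological %in% c(0, 1, 2)))
  expect_true(all(sc$cognitive %in% c(0, 2)))
  expect_true(all(sc$vitality %in% seq(0, 2, 0.5)))
  expect_true(all(sc$locomotion %in% seq(0, 2, 0.5)))
  expect_true(all(sc$composite %in% seq(0, 10, 0.5)))
  expect_equal(sc$composite, sc$sensory + sc$psychological + sc$cognitive +
                 sc$vitality + sc$locomotion)
})
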