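test_that("default configuration matches the study cohort's descriptives", {
  cfg <- cohort_config()
  expect_equal(cfg$n, 43L)
  expect_equal(cfg$dropout_n, 3L)
  expect_equal(cfg$prop_female, 0.86)
  expect_equal(cfg$age_mean, 67.7)
  expect_equal(cfg$age_sd, 4.3)
  expect_equal(cfg$variables$body_fat$mean, 37.5)
  expect_equal(cfg$variables$body_fat$sd, 9.5)
  expect_equal(cfg$variables$muscle_mass$mean, 26.6)
  expect_equal(cfg$variables$abdominal_circ$mean, 93.1)
  expect_equal(cfg$variables$sf6d$mean, 0.84)
  expect_equal(cfg$variables$heart_rate$mean, 73.2)
  effs <- vapply(cfg$variables, function(s) s$effect, numeric(1))
  expect_true(all(effs == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n = 0), "n >= 1")
  expect_error(cohort_config(n = 3, dropout_n = 3), "dropout")
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(prop_female = 1.2), "prop_female")
  expect_error(cohort_config(effects = list(nope = 1)), "unknown variable")
})

test_that("identical config and seed give identical cohorts", {
  a <- generate_cohort(cohort_config(seed = 123))
  b <- generate_cohort(cohort_config(seed = 123))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a, c2))
})

test_that("generated records satisfy the assessment invariants", {
  coh <- generate_cohort(cohort_config(n = 300, dropout_n = 10, seed = 6))
  expect_true(all(coh$age >= 60))
  expect_true(all(coh$gds15 >= 0 & coh$gds15 <= 15))
  expect_true(all(coh$moca >= 0 & coh$moca <= 30))
  expect_true(all(coh$chair_stand >= 0))
  expect_true(all(coh$weight_loss_3mo >= 0))
  expect_true(all(coh$tug > 0))
  expect_true(all(coh$balance >= 0))
  expect_true(all(coh$sex %in% c("F", "M")))
  expect_true(is.logical(coh$appetite_loss))
  # scorable end to end with the shipped example thresholds
  expect_silent(ic_score(coh, example_thresholds()))
})

test_that("sample moments recover configured values at n = 2000 within 3 SE", {
  coh <- generate_cohort(cohort_config(n = 2000, dropout_n = 0, seed = 101))
  pre <- coh[coh$timepoint == 0L, ]
  n <- nrow(pre)
  # body fat: mean within 3*sd/sqrt(n), sd within 3*sd/sqrt(2n)
  expect_lt(abs(mean(pre$body_fat) - 37.5), 3 * 9.5 / sqrt(n))
  expect_lt(abs(sd(pre$body_fat) - 9.5), 3 * 9.5 / sqrt(2 * n))
  expect_lt(abs(mean(pre$age) - 67.7), 3 * 4.3 / sqrt(n) + 0.1)  # +truncation
  expect_lt(abs(mean(pre$sex == "F") - 0.86),
            3 * sqrt(0.86 * 0.14 / n))
  # null cohort: standardized effect sizes stay near zero
  es <- effect_size(coh, "body_fat", R = 200, seed = 1)
  expect_lt(abs(es$es), 0.05)
})

test_that("a configured effect is recovered by the analysis stage", {
  # linear GEE covers the true additive effect in >= 90% of 50 replicates
  ok <- vapply(1:50, function(s) {
    cfg <- cohort_config(seed = 30000 + s, effects = list(body_fat = -2))
    f <- prepost_gee("body_fat", generate_cohort(cfg), family = "linear")
    abs(f$estimate - (-2)) <= 2 * f$se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a TUG improvement near the cutoff lifts the locomotion domain", {
  th <- example_thresholds()
  cfg <- cohort_config(n = 400, dropout_n = 0, seed = 99,
                       effects = list(tug = -1.5),
                       variables = list(tug = list(mean = 10.8, sd = 0.8)))
  sc <- ic_score(generate_cohort(cfg), th)
  expect_gt(median(sc$locomotion[sc$timepoint == 1L]),
            median(sc$locomotion[sc$timepoint == 0L]))
})

test_that("cohort config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n: 20", "dropout_n: 2", "seed: 77", "rho: 0.5",
    "effects: {tug: -1.0}",
    "variables:", "  tug: {mean: 10.2, sd: 1.5}"), f)
  cfg <- read_cohort_config(f)
  expect_equal(cfg$n, 20L)
  expect_equal(cfg$rho, 0.5)
  expect_equal(cfg$variables$tug$effect, -1)
  expect_equal(cfg$variables$tug$mean, 10.2)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  writeLines("nonsense: 1", f)
  expect_error(read_cohort_config(f), "unknown cohort config key")
})
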