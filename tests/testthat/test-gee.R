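# Reference values frozen from an independent estimating-equation
# implementation (statsmodels GEE, exchangeable working correlation, robust
# covariance) run on the exact dataset oracle_dataset() regenerates.
sm_ref <- list(
  linear = list(est = 3.1764658210, se = 0.7945811731, alpha = 0.939352),
  binary = list(est = 0.3101549283, se = 0.4761670572, alpha = 0.243976)
)

test_that("gaussian GEE matches the independent reference on unbalanced data", {
  d <- oracle_dataset()
  f <- prepost_gee("y", d, family = "linear")
  expect_equal(f$estimate, sm_ref$linear$est, tolerance = 1e-8)
  expect_equal(f$se, sm_ref$linear$se, tolerance = 1e-6)
  expect_equal(f$alpha, sm_ref$linear$alpha, tolerance = 1e-4)
  expect_true(f$converged)
  expect_equal(f$n_participants, 30)
  expect_equal(f$n_obs, 56)
})

test_that("binomial GEE matches the independent reference on unbalanced data", {
  d <- oracle_dataset()
  f <- prepost_gee("yb", d, family = "binary-logistic")
  expect_equal(f$estimate, sm_ref$binary$est, tolerance = 1e-8)
  expect_equal(f$se, sm_ref$binary$se, tolerance = 1e-6)
  expect_equal(f$alpha, sm_ref$binary$alpha, tolerance = 1e-4)
})

test_that("balanced linear time effect equals the paired mean difference", {
  for (s in c(1, 2, 3)) {
    coh <- generate_cohort(cohort_config(dropout_n = 0, seed = s))
    f <- prepost_gee("body_fat", coh, family = "linear")
    expect_equal(f$estimate, paired_mean_diff(coh, "body_fat"),
                 tolerance = 1e-10)
  }
})

test_that("identical pre and post values give a zero time effect", {
  pre <- data.frame(participant_id = sprintf("P%02d", 1:10), timepoint = 0L,
                    y = rnorm(10))
  post <- pre; post$timepoint <- 1L
  f <- prepost_gee("y", rbind(pre, post), family = "linear")
  expect_lt(abs(f$estimate), 1e-12)
})

test_that("log-linear family equals linear on log-transformed values", {
  d <- oracle_dataset()
  d$ypos <- exp(d$y / 25)
  f1 <- prepost_gee("ypos", d, family = "log-linear")
  d$ylog <- log(d$ypos)
  f2 <- prepost_gee("ylog", d, family = "linear")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  d$yneg <- d$y - 100
  expect_error(prepost_gee("yneg", d, family = "log-linear"),
               "strictly positive")
})

test_that("degenerate outcomes are refused with informative errors", {
  d <- oracle_dataset()
  d$const <- 5
  expect_error(prepost_gee("const", d, family = "linear"), "degenerate")
  d$onecell <- ifelse(d$timepoint == 0, 0L, rbinom(nrow(d), 1, 0.5))
  expect_error(prepost_gee("onecell", d, family = "binary-logistic"),
               "empty cell")
  d$notbin <- d$y
  expect_error(prepost_gee("notbin", d, family = "binary-logistic"), "0/1")
  two <- d[d$participant_id == "P01", ]
  expect_error(prepost_gee("y", two, family = "linear"), "at least 2")
  expect_error(prepost_gee("nope", d, family = "linear"), "unknown variable")
})

test_that("ordinal family fits and degenerates to binary logistic at 2 levels", {
  set.seed(7)
  n <- 40
  id <- sprintf("P%02d", 1:n)
  lat <- rnorm(n)
  mk <- function(shift) cut(lat + shift + rnorm(n, 0, 0.5),
                            breaks = c(-Inf, -0.5, 0.5, Inf),
                            labels = c("lo", "mid", "hi"), ordered_result = TRUE)
  d <- rbind(data.frame(participant_id = id, timepoint = 0L, g = mk(0)),
             data.frame(participant_id = id, timepoint = 1L, g = mk(0.8)))
  f <- prepost_gee("g", d, family = "ordinal-logistic")
  expect_true(is.finite(f$estimate) && f$estimate > 0)
  expect_true(f$p.value >= 0 && f$p.value <= 1)
  expect_equal(f$corstr, "independence")

  # two observed levels: cumulative-logit == binary logistic on the indicator
  d$g2 <- factor(ifelse(d$g == "hi", "hi", "lo"), levels = c("lo", "hi"),
                 ordered = TRUE)
  f2 <- prepost_gee("g2", d, family = "ordinal-logistic")
  d$g01 <- as.integer(d$g2 == "hi")
  fb <- prepost_gee("g01", d, family = "binary-logistic")
  expect_equal(f2$estimate, fb$estimate, tolerance = 1e-10)
  expect_equal(f2$se, fb$se, tolerance = 1e-10)
})

test_that("fit object methods expose coefficients and intervals coherently", {
  f <- prepost_gee("y", oracle_dataset(), family = "linear")
  expect_named(coef(f), c("(Intercept)", "time"))
  expect_equal(unname(sqrt(diag(vcov(f)))["time"]), f$se)
  ci <- confint(f)
  expect_lt(ci[1], f$estimate)
  expect_gt(ci[2], f$estimate)
  expect_output(print(summary(f)), "time")
})
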