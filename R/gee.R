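# Generalized estimating equations for the two-timepoint pre/post design.
#
# The solver below implements the Liang-Zeger estimating equations with an
# exchangeable working correlation and a robust (sandwich) covariance,
# for identity-link gaussian and logit-link binomial marginal models.
# Cluster = participant; clusters of size 1 (dropout) contribute their
# baseline row, so estimation is intention-to-treat over all available rows.

gee_engine <- function(y, X, id, family = c("gaussian", "binomial"),
                       corstr = c("exchangeable", "independence"),
                       maxit = 100L, tol = 1e-12) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  clusters <- split(seq_len(n), id)

  linkinv <- if (family == "binomial") stats::plogis else identity
  varfun <- if (family == "binomial") function(mu) mu * (1 - mu) else
    function(mu) rep(1, length(mu))

  beta <- stats::glm.fit(X, y,
                         family = if (family == "binomial")
                           stats::binomial() else stats::gaussian())$coefficients
  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    v <- varfun(mu)
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (n - p)

    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in clusters) {
        m <- length(ix)
        if (m > 1) {
          s <- sum(e[ix])
          num <- num + (s^2 - sum(e[ix]^2)) / 2
          npairs <- npairs + m * (m - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / (phi * (npairs - p)) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }

    B <- matrix(0, p, p)
    U <- numeric(p)
    for (ix in clusters) {
      m <- length(ix)
      Di <- X[ix, , drop = FALSE] * (if (family == "binomial") v[ix] else 1)
      sv <- sqrt(v[ix])
      R <- diag(1, m)
      if (m > 1 && corstr == "exchangeable") R[R == 0] <- alpha
      Vi <- phi * (sv %o% sv) * R
      Wi <- solve(Vi)
      B <- B + crossprod(Di, Wi %*% Di)
      U <- U + drop(crossprod(Di, Wi %*% (y[ix] - mu[ix])))
    }
    delta <- solve(B, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(X %*% beta)
  mu <- linkinv(eta)
  v <- varfun(mu)
  e <- (y - mu) / sqrt(v)
  phi <- sum(e^2) / (n - p)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in clusters) {
    m <- length(ix)
    Di <- X[ix, , drop = FALSE] * (if (family == "binomial") v[ix] else 1)
    sv <- sqrt(v[ix])
    R <- diag(1, m)
    if (m > 1 && corstr == "exchangeable") R[R == 0] <- alpha
    Vi <- phi * (sv %o% sv) * R
    Wi <- solve(Vi)
    g <- drop(crossprod(Di, Wi %*% (y[ix] - mu[ix])))
    B <- B + crossprod(Di, Wi %*% Di)
    M <- M + g %o% g
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, vcov = vcov_robust, naive_vcov = Binv,
       alpha = if (corstr == "exchangeable") alpha else NA_real_,
       phi = phi, converged = converged, n_obs = n,
       n_clusters = length(clusters), family = family, corstr = corstr)
}

#' Pre/post marginal model for one outcome
#'
#' Fits a marginal (population-averaged) regression of an outcome on the
#' timepoint indicator using generalized estimating equations, with the
#' participant as the cluster. The model family is chosen per variable type:
#'
#' * `"linear"` -- identity-link gaussian for approximately normal outcomes;
#' * `"log-linear"` -- gaussian on the log-transformed outcome, for strictly
#'   positive right-skewed outcomes (estimate is on the log scale);
#' * `"binary-logistic"` -- logit-link binomial for 0/1 outcomes;
#' * `"ordinal-logistic"` -- proportional-odds cumulative-logit model
#'   ([MASS::polr()]) with a cluster-robust covariance
#'   ([sandwich::vcovCL()]); a working-independence estimating-equation fit.
#'
#' Gaussian and binomial fits use an exchangeable working correlation by
#' default and always report the robust (sandwich) variance, so inference is
#' valid under within-participant dependence whatever the working structure.
#' All available rows contribute (intention-to-treat): a participant lacking
#' the follow-up still informs the baseline mean.
#'
#' @param variable name of the outcome column.
#' @param data a cohort table (long format, `timepoint` coded 0/1) as
#'   returned by [read_cohort()], [generate_cohort()] or [ic_score()].
#' @param family model family (see above).
#' @param corstr working correlation for the gaussian/binomial families:
#'   `"exchangeable"` (default) or `"independence"`.
#' @return An object of class `"prepost_gee"` with `print()`, `summary()`,
#'   `coef()`, `vcov()` and `confint()` methods. The time-effect estimate is
#'   in `$estimate` with robust standard error `$se` and two-sided Wald
#'   p-value `$p.value`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' coh <- generate_cohort(cfg)
#' fit <- prepost_gee("body_fat", coh, family = "linear")
#' fit
#' @export
prepost_gee <- function(variable, data,
                        family = c("linear", "log-linear",
                                   "binary-logistic", "ordinal-logistic"),
                        corstr = c("exchangeable", "independence")) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  if (!variable %in% names(data)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  keep <- !is.na(data[[variable]])
  d <- data[keep, , drop = FALSE]
  if (length(unique(d$participant_id[d$timepoint == 0L])) < 2) {
    stop("need at least 2 participants with baseline data for ", variable,
         call. = FALSE)
  }
  yraw <- d[[variable]]
  time <- as.numeric(d$timepoint)
  id <- d$participant_id
  cl <- match.call()

  if (family %in% c("linear", "log-linear")) {
    y <- as.numeric(yraw)
    if (family == "log-linear") {
      if (any(y <= 0)) {
        stop("log-linear family requires strictly positive values (",
             variable, ")", call. = FALSE)
      }
      y <- log(y)
    }
    if (stats::sd(y) == 0) {
      stop("degenerate fit: outcome ", variable, " is constant", call. = FALSE)
    }
    X <- cbind(`(Intercept)` = 1, time = time)
    eng <- gee_engine(y, X, id, family = "gaussian", corstr = corstr)
  } else if (family == "binary-logistic") {
    y <- as.numeric(yraw)
    if (!all(y %in% c(0, 1))) {
      stop("binary-logistic family requires a 0/1 outcome (", variable, ")",
           call. = FALSE)
    }
    for (tp in c(0, 1)) {
      ytp <- y[time == tp]
      if (length(ytp) && (all(ytp == 0) || all(ytp == 1))) {
        stop("degenerate fit: outcome ", variable,
             " has an empty cell at timepoint ", tp, call. = FALSE)
      }
    }
    X <- cbind(`(Intercept)` = 1, time = time)
    eng <- gee_engine(y, X, id, family = "binomial", corstr = corstr)
  } else { # ordinal-logistic
    y <- if (is.ordered(yraw)) droplevels(yraw) else
      factor(yraw, levels = sort(unique(yraw)), ordered = TRUE)
    if (nlevels(y) < 2) {
      stop("degenerate fit: outcome ", variable, " is constant", call. = FALSE)
    }
    if (nlevels(y) == 2) {
      # the two-level cumulative-logit model is binary logistic: fit it as
      # a binomial GEE on the indicator of the upper level
      y01 <- as.numeric(y == levels(y)[2])
      for (tp in c(0, 1)) {
        ytp <- y01[time == tp]
        if (length(ytp) && (all(ytp == 0) || all(ytp == 1))) {
          stop("degenerate fit: outcome ", variable,
               " has an empty cell at timepoint ", tp, call. = FALSE)
        }
      }
      X <- cbind(`(Intercept)` = 1, time = time)
      eng <- gee_engine(y01, X, id, family = "binomial", corstr = corstr)
      est <- unname(eng$coefficients["time"])
      se <- sqrt(eng$vcov["time", "time"])
      return(structure(list(
        variable = variable, family = family, corstr = corstr,
        coefficients = eng$coefficients, vcov = eng$vcov,
        estimate = est, se = se, z = est / se,
        p.value = 2 * stats::pnorm(-abs(est / se)),
        alpha = eng$alpha, phi = eng$phi, converged = eng$converged,
        n_obs = eng$n_obs, n_participants = eng$n_clusters,
        call = cl), class = "prepost_gee"))
    }
    df <- data.frame(y = y, time = time)
    fit <- MASS::polr(y ~ time, data = df, method = "logistic", Hess = TRUE)
    vc <- sandwich::vcovCL(fit, cluster = id)
    est <- unname(stats::coef(fit)["time"])
    se <- sqrt(vc["time", "time"])
    eng <- list(coefficients = c(stats::coef(fit), fit$zeta),
                vcov = vc, alpha = NA_real_, phi = NA_real_,
                converged = fit$convergence == 0, n_obs = nrow(df),
                n_clusters = length(unique(id)),
                family = "cumulative-logit", corstr = "independence")
    out <- structure(list(
      variable = variable, family = family, corstr = "independence",
      coefficients = eng$coefficients, vcov = eng$vcov,
      estimate = est, se = se, z = est / se,
      p.value = 2 * stats::pnorm(-abs(est / se)),
      alpha = NA_real_, phi = NA_real_, converged = eng$converged,
      n_obs = eng$n_obs, n_participants = eng$n_clusters,
      polr_fit = fit, call = cl), class = "prepost_gee")
    return(out)
  }

  est <- unname(eng$coefficients["time"])
  se <- sqrt(eng$vcov["time", "time"])
  structure(list(
    variable = variable, family = family, corstr = corstr,
    coefficients = eng$coefficients, vcov = eng$vcov,
    estimate = est, se = se, z = est / se,
    p.value = 2 * stats::pnorm(-abs(est / se)),
    alpha = eng$alpha, phi = eng$phi, converged = eng$converged,
    n_obs = eng$n_obs, n_participants = eng$n_clusters,
    call = cl), class = "prepost_gee")
}

#' @export
print.prepost_gee <- function(x, digits = 4, ...) {
  cat(sprintf("Pre/post GEE (%s, %s working correlation)\n",
              x$family, x$corstr))
  cat(sprintf("  outcome: %s;  %d observations, %d participants\n",
              x$variable, x$n_obs, x$n_participants))
  cat(sprintf("  time effect: %s  (robust SE %s, p = %s)\n",
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              format.pval(x$p.value, digits = digits)))
  if (!is.na(x$alpha)) {
    cat(sprintf("  working correlation alpha = %s\n",
                format(x$alpha, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.prepost_gee <- function(object, ...) object$coefficients

#' @export
vcov.prepost_gee <- function(object, ...) object$vcov

#' @export
confint.prepost_gee <- function(object, parm = "time", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- sqrt(diag(object$vcov))[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
summary.prepost_gee <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  cf <- object$coefficients[names(se)]
  tab <- cbind(Estimate = cf, `Robust SE` = se, z = cf / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(cf / se)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.prepost_gee")
}

#' @export
print.summary.prepost_gee <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE)
  invisible(x)
}
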