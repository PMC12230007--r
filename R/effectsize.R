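# Standardized effect size for the pre/post design, with a participant-level
# nonparametric bootstrap CI.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

es_from_vectors <- function(pre, post, method) {
  pair <- !is.na(pre) & !is.na(post)
  diffs <- post[pair] - pre[pair]
  sd0 <- switch(method,
    "baseline-sd" = stats::sd(pre[!is.na(pre)]),
    "pooled-sd" = sqrt((stats::var(pre[!is.na(pre)]) +
                          stats::var(post[!is.na(post)])) / 2),
    "change-sd" = stats::sd(diffs)
  )
  if (sum(pair) < 2 || !is.finite(sd0) || sd0 == 0) return(NA_real_)
  mean(diffs) / sd0
}

#' Standardized effect size of the pre/post change
#'
#' Computes a standardized (dimensionless) magnitude of change:
#' mean within-participant change over complete pairs divided by a
#' standardizing standard deviation. The default standardizer is the
#' baseline SD over all participants with a baseline observation;
#' alternatives are the pooled pre/post SD and the SD of the change scores.
#' The 95% confidence interval is a participant-level nonparametric
#' percentile bootstrap (participants resampled with replacement; the whole
#' pre/post pair travels together).
#'
#' Ordinal variables (ordered factors) are coerced to their integer level
#' codes before computation.
#'
#' @param data a cohort table in long format (`timepoint` coded 0/1).
#' @param variable name of a continuous or ordinal column.
#' @param method standardizer: `"baseline-sd"` (default), `"pooled-sd"`, or
#'   `"change-sd"`.
#' @param R number of bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap (optional; RNG state is
#'   restored afterwards).
#' @param conf confidence level (default 0.95).
#' @return An object of class `"ic_effect_size"`: a list with `es`, `ci`
#'   (length-2), `band` (Cohen band of `|es|`), `n_pairs`, `sd0`, `method`.
#' @export
effect_size <- function(data, variable, method = c("baseline-sd", "pooled-sd",
                                                   "change-sd"),
                        R = 2000, seed = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (!variable %in% names(data)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  v <- data[[variable]]
  if (is.factor(v)) v <- as.integer(v)
  v <- as.numeric(v)
  ids <- unique(data$participant_id[data$timepoint == 0L])
  pre <- v[match(paste0(ids, "\r0"),
                 paste0(data$participant_id, "\r", data$timepoint))]
  post <- v[match(paste0(ids, "\r1"),
                  paste0(data$participant_id, "\r", data$timepoint))]
  n_pairs <- sum(!is.na(pre) & !is.na(post))
  if (n_pairs < 2) {
    stop("insufficient data: fewer than 2 complete pre/post pairs for ",
         variable, call. = FALSE)
  }
  es <- es_from_vectors(pre, post, method)
  if (is.na(es)) {
    stop("degenerate standardizer: zero variance for ", variable,
         call. = FALSE)
  }
  n <- length(ids)
  boots <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * R, replace = TRUE), nrow = R)
    vapply(seq_len(R), function(r)
      es_from_vectors(pre[idx[r, ]], post[idx[r, ]], method), numeric(1))
  })
  boots <- boots[is.finite(boots)]
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  structure(list(variable = variable, es = es, ci = ci,
                 band = classify_effect_size(es), n_pairs = n_pairs,
                 n_boot = length(boots), method = method, R = R,
                 seed = seed, conf = conf),
            class = "ic_effect_size")
}

#' @export
print.ic_effect_size <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized effect size (%s): %s [%s, %s]  (%s effect)\n",
              x$method, format(x$es, digits = digits),
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits), as.character(x$band)))
  cat(sprintf("  %d complete pairs; %d bootstrap resamples\n",
              x$n_pairs, x$n_boot))
  invisible(x)
}

#' Cohen band of a standardized effect size
#'
#' The magnitude is judged on the absolute value: below 0.5 is a small
#' effect, 0.5 to 0.8 (inclusive) moderate, above 0.8 large.
#'
#' @param es numeric vector of standardized effect sizes (finite).
#' @return Factor with levels `small`, `moderate`, `large`.
#' @export
classify_effect_size <- function(es) {
  if (any(!is.finite(es))) {
    stop("effect size must be finite", call. = FALSE)
  }
  a <- abs(es)
  lab <- ifelse(a < 0.5, "small", ifelse(a <= 0.8, "moderate", "large"))
  factor(lab, levels = c("small", "moderate", "large"))
}
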