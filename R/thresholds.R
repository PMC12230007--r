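#' Assessment cutoffs for intrinsic-capacity scoring
#'
#' Bundles the three kinds of cutoff the domain scorers need:
#'
#' * **fixed** cutoffs with published defaults: handgrip strength (27 kgf men /
#'   16 kgf women), the BMI band (22--27 kg/m\eqn{^2}), the Timed Up and Go
#'   limit (10 s), the one-leg-stand pass time (strictly greater than 20 s),
#'   the 3-month weight-loss limit (3 kg), the GDS-15 band edges (5, 10) and
#'   the composite classification bands (low \eqn{\le} 4, moderate \eqn{\le} 8);
#' * an age- and sex-specific **norm table** for the sit-to-stand repetition
#'   threshold and the sit-and-reach recommended range (these norms are not
#'   fixed by the scoring system itself -- they come from senior fitness test
#'   reference tables and must be supplied by configuration);
#' * education-banded **MoCA cutoffs** for the cognition domain (likewise
#'   configuration: published cutoffs vary by population and edition).
#'
#' @param fixed named list overriding any of the fixed cutoffs
#'   (`hgs_male_min`, `hgs_female_min`, `bmi_low`, `bmi_high`, `tug_max`,
#'   `balance_min`, `weight_loss_kg`, `gds_band_edges`, `composite_low_max`,
#'   `composite_moderate_max`). Omitted entries keep their defaults.
#' @param norms `data.frame` with columns `sex` ("F"/"M"), `age_min`,
#'   `age_max` (closed integer age bands), `chair_stand_min` (repetitions),
#'   `sit_reach_min`, `sit_reach_max` (centimetres). May be `NULL` (empty).
#' @param moca `data.frame` with columns `education` (free-form band label,
#'   matched exactly) and `cutoff` (points, 0--30). May be `NULL` (empty).
#'
#' @return An object of class `"ic_thresholds"`: a list with elements
#'   `fixed`, `norms`, `moca`.
#' @examples
#' th <- ic_thresholds()
#' th$fixed$hgs_male_min
#' @export
ic_thresholds <- function(fixed = list(), norms = NULL, moca = NULL) {
  defaults <- list(
    hgs_male_min = 27, hgs_female_min = 16,
    bmi_low = 22, bmi_high = 27,
    tug_max = 10, balance_min = 20,
    weight_loss_kg = 3,
    gds_band_edges = c(5L, 10L),
    composite_low_max = 4, composite_moderate_max = 8
  )
  if (!is.list(fixed)) stop("`fixed` must be a named list", call. = FALSE)
  unknown <- setdiff(names(fixed), names(defaults))
  if (length(unknown)) {
    stop("unknown fixed cutoff key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(fixed)] <- fixed

  if (is.null(norms)) {
    norms <- data.frame(
      sex = character(), age_min = numeric(), age_max = numeric(),
      chair_stand_min = numeric(), sit_reach_min = numeric(),
      sit_reach_max = numeric(), stringsAsFactors = FALSE
    )
  }
  if (is.null(moca)) {
    moca <- data.frame(education = character(), cutoff = numeric(),
                       stringsAsFactors = FALSE)
  }
  obj <- structure(list(fixed = defaults,
                        norms = as.data.frame(norms),
                        moca = as.data.frame(moca)),
                   class = "ic_thresholds")
  validate_thresholds(obj)
  obj
}

validate_thresholds <- function(x) {
  f <- x$fixed
  chk <- function(ok, rule) {
    if (!isTRUE(ok)) stop("threshold validation failed: ", rule, call. = FALSE)
  }
  chk(is.numeric(f$hgs_male_min) && f$hgs_male_min > 0, "hgs_male_min > 0")
  chk(is.numeric(f$hgs_female_min) && f$hgs_female_min > 0, "hgs_female_min > 0")
  chk(f$bmi_low < f$bmi_high, "bmi_low < bmi_high")
  chk(f$tug_max > 0, "tug_max > 0")
  chk(f$balance_min >= 0, "balance_min >= 0")
  chk(f$weight_loss_kg > 0, "weight_loss_kg > 0")
  g <- f$gds_band_edges
  chk(length(g) == 2 && g[1] < g[2] && g[1] >= 0 && g[2] <= 15,
      "gds_band_edges strictly increasing within 0..15")
  chk(f$composite_low_max < f$composite_moderate_max &&
        f$composite_moderate_max < 10,
      "composite_low_max < composite_moderate_max < 10")

  n <- x$norms
  need <- c("sex", "age_min", "age_max", "chair_stand_min",
            "sit_reach_min", "sit_reach_max")
  chk(all(need %in% names(n)), paste("norm table has columns:",
                                     paste(need, collapse = ", ")))
  if (nrow(n)) {
    chk(all(n$sex %in% c("F", "M")), "norm sex codes in {F, M}")
    chk(all(n$age_min <= n$age_max), "age_min <= age_max")
    chk(all(n$age_min >= 60), "norm bands start at age 60 or later")
    chk(all(n$chair_stand_min >= 0), "chair_stand_min >= 0")
    chk(all(n$sit_reach_min <= n$sit_reach_max), "sit_reach_min <= sit_reach_max")
    # closed integer bands must not overlap within a sex
    for (s in unique(n$sex)) {
      b <- n[n$sex == s, , drop = FALSE]
      b <- b[order(b$age_min), , drop = FALSE]
      if (nrow(b) > 1) {
        chk(all(b$age_min[-1] > b$age_max[-nrow(b)]),
            paste0("age bands for sex ", s, " are non-overlapping"))
      }
    }
  }

  m <- x$moca
  chk(all(c("education", "cutoff") %in% names(m)),
      "moca table has columns: education, cutoff")
  if (nrow(m)) {
    chk(!anyDuplicated(m$education), "moca education bands are unique")
    chk(all(m$cutoff >= 0 & m$cutoff <= 30), "moca cutoffs within 0..30")
  }
  invisible(x)
}

#' @export
print.ic_thresholds <- function(x, ...) {
  cat("Intrinsic-capacity threshold configuration\n")
  f <- x$fixed
  cat(sprintf("  handgrip:   >= %g kgf (men), >= %g kgf (women)\n",
              f$hgs_male_min, f$hgs_female_min))
  cat(sprintf("  BMI band:   [%g, %g] kg/m^2\n", f$bmi_low, f$bmi_high))
  cat(sprintf("  TUG pass:   < %g s;  one-leg stand pass: > %g s\n",
              f$tug_max, f$balance_min))
  cat(sprintf("  weight loss limit: %g kg / 3 months\n", f$weight_loss_kg))
  cat(sprintf("  GDS-15 bands: 0..%d / %d..%d / %d..15\n",
              f$gds_band_edges[1], f$gds_band_edges[1] + 1L,
              f$gds_band_edges[2], f$gds_band_edges[2] + 1L))
  cat(sprintf("  composite bands: low <= %g < moderate <= %g < high\n",
              f$composite_low_max, f$composite_moderate_max))
  cat(sprintf("  norm table: %d row(s); MoCA cutoffs: %d band(s)\n",
              nrow(x$norms), nrow(x$moca)))
  invisible(x)
}

#' Read a threshold configuration file
#'
#' The file is a single YAML or JSON document with up to three keys:
#' `fixed` (a mapping of fixed-cutoff overrides), `norms` (a list of rows
#' with `sex`, `age_min`, `age_max`, `chair_stand_min`, `sit_reach_min`,
#' `sit_reach_max`) and `moca` (a list of rows with `education`, `cutoff`).
#' All keys are optional; omitted fixed cutoffs take the package defaults.
#' An empty file yields the default configuration with empty norm and MoCA
#' tables.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ic_thresholds` object.
#' @seealso [ic_thresholds()], [write_thresholds()]
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("threshold config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("threshold config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), c("fixed", "norms", "moca"))
  if (length(unknown)) {
    stop("unknown threshold config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fixed <- raw$fixed
  if (is.null(fixed)) fixed <- list()
  if (!is.null(fixed$gds_band_edges)) {
    fixed$gds_band_edges <- as.integer(unlist(fixed$gds_band_edges))
  }
  rows_to_df <- function(rows, cols, where) {
    if (is.null(rows) || length(rows) == 0) return(NULL)
    lst <- lapply(rows, function(r) {
      miss <- setdiff(cols, names(r))
      if (length(miss)) {
        stop("threshold config: row in `", where, "` missing key(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    })
    do.call(rbind, lst)
  }
  norms <- rows_to_df(raw$norms,
                      c("sex", "age_min", "age_max", "chair_stand_min",
                        "sit_reach_min", "sit_reach_max"), "norms")
  moca <- rows_to_df(raw$moca, c("education", "cutoff"), "moca")
  ic_thresholds(fixed = fixed, norms = norms, moca = moca)
}

#' Write a threshold configuration to YAML
#'
#' Serialises an `ic_thresholds` object so that [read_thresholds()] recovers
#' an identical configuration (round-trip identity).
#'
#' @param x an `ic_thresholds` object.
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(x, path) {
  stopifnot(inherits(x, "ic_thresholds"))
  df_to_rows <- function(df) {
    if (!nrow(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  doc <- list(fixed = x$fixed)
  nr <- df_to_rows(x$norms); if (!is.null(nr)) doc$norms <- nr
  mr <- df_to_rows(x$moca); if (!is.null(mr)) doc$moca <- mr
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Example threshold configuration (synthetic stand-in norms)
#'
#' Returns the configuration shipped at
#' `system.file("extdata", "thresholds_synthetic_example.yaml", package = "icap")`.
#' Its fixed cutoffs are the published defaults; its sit-to-stand /
#' sit-and-reach norm table and MoCA education cutoffs are **illustrative
#' synthetic stand-ins** in the style of senior fitness test reference tables
#' (plausible magnitudes, full age coverage 60--99 for both sexes), not values
#' from any published norm edition. Replace them with your population's norms
#' for real analyses.
#'
#' @return An `ic_thresholds` object.
#' @export
example_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds_synthetic_example.yaml",
                              package = "icap", mustWork = TRUE))
}

norm_match_row <- function(norms, sex, age) {
  hit <- which(norms$sex == sex & norms$age_min <= age & age <= norms$age_max)
  if (length(hit) != 1) {
    stop(sprintf("no norm band for sex=%s, age=%s", sex, format(age)),
         call. = FALSE)
  }
  hit
}

#' Look up the sit-to-stand repetition threshold
#'
#' Age bands are closed intervals `[age_min, age_max]`; a query at a shared
#' boundary age resolves to the band whose `age_max` equals the query.
#'
#' @param thresholds an `ic_thresholds` object (its `norms` table is used).
#' @param sex `"F"` or `"M"`.
#' @param age age in whole years, at least 60.
#' @return Minimum passing repetition count (scalar).
#' @export
norm_chair_stand_min <- function(thresholds, sex, age) {
  stopifnot(inherits(thresholds, "ic_thresholds"))
  if (age < 60) stop("norm lookup requires age >= 60", call. = FALSE)
  thresholds$norms$chair_stand_min[norm_match_row(thresholds$norms, sex, age)]
}

#' Look up the recommended sit-and-reach range
#'
#' @inheritParams norm_chair_stand_min
#' @return Numeric length-2 vector `c(min, max)` in centimetres.
#' @export
norm_sit_reach_range <- function(thresholds, sex, age) {
  stopifnot(inherits(thresholds, "ic_thresholds"))
  if (age < 60) stop("norm lookup requires age >= 60", call. = FALSE)
  i <- norm_match_row(thresholds$norms, sex, age)
  c(thresholds$norms$sit_reach_min[i], thresholds$norms$sit_reach_max[i])
}

#' Look up the education-adjusted MoCA cutoff
#'
#' Education bands are free-form labels matched exactly against the
#' configured table.
#'
#' @param thresholds an `ic_thresholds` object (its `moca` table is used).
#' @param education education band label.
#' @return Cutoff in MoCA points (scalar).
#' @export
moca_cutoff <- function(thresholds, education) {
  stopifnot(inherits(thresholds, "ic_thresholds"))
  hit <- which(thresholds$moca$education == education)
  if (length(hit) != 1) {
    stop("no MoCA cutoff configured for education band: ", education,
         call. = FALSE)
  }
  thresholds$moca$cutoff[hit]
}
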