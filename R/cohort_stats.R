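# Cohort-level statistics: eligibility filtering, random eye selection,
# spherical equivalent, two-group tests from raw or summary data, and the
# covariate-adjusted group comparison of the OCTA metrics.

#' Spherical equivalent of a refraction
#'
#' `sphere + cylinder / 2`, all in diopters.
#'
#' @param sphere_D Spherical power, diopters.
#' @param cylinder_D Cylindrical power, diopters.
#' @return Spherical equivalent, diopters.
#' @export
spherical_equivalent <- function(sphere_D, cylinder_D) {
  sphere_D + cylinder_D / 2
}

#' Apply scan-quality exclusions
#'
#' Removes eyes with signal strength below 6 or any grader quality flag
#' (motion artefact, floater affecting signal, misalignment, incorrect
#' segmentation), recording one reason per exclusion. Signal strength is
#' checked first; among flags the first set flag (in the order above) is the
#' recorded reason.
#'
#' @param records Data.frame of eye-level records with columns `eye_id` and
#'   `signal_strength`.
#' @param quality_flags Data.frame with `eye_id` and logical columns
#'   `motion`, `floater`, `misalignment`, `segmentation` (missing columns
#'   are treated as all-FALSE).
#' @return List with `kept` (rows of `records`) and `excluded` (rows plus a
#'   `reason` column).
#' @export
apply_exclusions <- function(records, quality_flags = NULL) {
  stopifnot(is.data.frame(records), "signal_strength" %in% names(records))
  flag_names <- c("motion", "floater", "misalignment", "segmentation")
  flags <- matrix(FALSE, nrow(records), length(flag_names),
                  dimnames = list(NULL, flag_names))
  if (!is.null(quality_flags)) {
    idx <- match(records$eye_id, quality_flags$eye_id)
    for (fn in intersect(flag_names, names(quality_flags))) {
      v <- quality_flags[[fn]][idx]
      flags[, fn] <- !is.na(v) & v
    }
  }
  reason <- rep(NA_character_, nrow(records))
  reason[apply(flags, 1, any)] <-
    flag_names[apply(flags, 1, function(r) which(r)[1])[apply(flags, 1, any)]]
  reason[records$signal_strength < 6] <- "signal_strength"
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], excluded = excluded)
}

#' Select one eye per participant at random
#'
#' With one eligible eye that eye is taken; with two, one is chosen
#' uniformly by a seeded generator (reproducible: the same seed always
#' yields the same choice). Participants with no eligible eye are dropped
#' and reported.
#'
#' @param participant_eyes Data.frame with columns `participant_id` and
#'   `eye_id`, one row per eligible eye.
#' @param seed Integer seed.
#' @return List with `selected` (data.frame `participant_id`, `eye_id`) and
#'   `dropped` (participant ids with zero eligible eyes, from the factor
#'   levels of `participant_id` if present).
#' @export
select_random_eye <- function(participant_eyes, seed = 1L) {
  stopifnot(all(c("participant_id", "eye_id") %in% names(participant_eyes)))
  ids <- unique(participant_eyes$participant_id)
  hash_id <- function(pid) {
    h <- 0
    for (ch in utf8ToInt(as.character(pid))) h <- (h * 131 + ch) %% 2147483563
    h
  }
  sel <- vapply(ids, function(pid) {
    eyes <- participant_eyes$eye_id[participant_eyes$participant_id == pid]
    if (length(eyes) == 1) return(as.character(eyes))
    # per-participant substream: independent of participant order and free
    # of id collisions (polynomial hash of the id string)
    set.seed((seed * 7919 + hash_id(pid)) %% 2147483647)
    as.character(sample(eyes, 1))
  }, character(1))
  dropped <- if (is.factor(participant_eyes$participant_id)) {
    setdiff(levels(participant_eyes$participant_id), as.character(ids))
  } else character(0)
  list(selected = data.frame(participant_id = ids, eye_id = sel,
                             stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Group summary (mean, SD, n)
#'
#' @param x Numeric vector, or a mean when `sd` and `n` are given.
#' @param sd,n Standard deviation and count when constructing from
#'   summaries.
#' @return A `group_summary` list.
#' @export
group_summary <- function(x, sd = NULL, n = NULL) {
  if (is.null(sd)) {
    x <- x[!is.na(x)]
    out <- list(mean = mean(x), sd = stats::sd(x), n = length(x))
  } else {
    out <- list(mean = x, sd = sd, n = n)
  }
  if (out$n < 2 || out$sd < 0) stop("need n >= 2 and sd >= 0", call. = FALSE)
  structure(out, class = "group_summary")
}

test_result <- function(statistic, df, p_value, method, estimate) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, estimate = estimate),
            class = "octa_test_result")
}

#' @export
print.octa_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, df %s, estimate %.4g, p %.4g\n",
              x$method, x$statistic, format(x$df), x$estimate, x$p_value))
  invisible(x)
}

#' Independent two-sample t-test from group summaries
#'
#' Pooled-variance (Student) t by default, computable directly from printed
#' group means, SDs and counts; `welch = TRUE` uses the Welch-Satterthwaite
#' form instead. Raw vectors are accepted and reduced to summaries first.
#'
#' @param g1,g2 [group_summary()] objects or raw numeric vectors.
#' @param welch Use the unequal-variance form (default `FALSE`).
#' @return A test result with the t statistic, df, two-sided p and the
#'   mean difference `g1 - g2`.
#' @export
t_test_from_summary <- function(g1, g2, welch = FALSE) {
  if (!inherits(g1, "group_summary")) g1 <- group_summary(g1)
  if (!inherits(g2, "group_summary")) g2 <- group_summary(g2)
  est <- g1$mean - g2$mean
  if (welch) {
    se2a <- g1$sd^2 / g1$n; se2b <- g2$sd^2 / g2$n
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (g1$n - 1) + se2b^2 / (g2$n - 1))
  } else {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  }
  if (se == 0) {
    if (est == 0) return(test_result(0, df, 1, "pooled_t", 0))
    warning("zero pooled variance with unequal means; p = 0")
    return(test_result(sign(est) * Inf, df, 0,
                       if (welch) "welch_t" else "pooled_t", est))
  }
  tstat <- est / se
  test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
              if (welch) "welch_t" else "pooled_t", est)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1. Counts are
#' `[a b; c d]` with rows = outcome, columns = group.
#'
#' @param a,b,c,d Non-negative counts.
#' @return A test result with the chi-square statistic, df = 1, two-sided p
#'   and the difference in column-1 proportions as the estimate.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate input: a zero margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result(unname(res$statistic), 1L, res$p.value, "chi_square",
              a / (a + b) - c / (c + d))
}

#' Covariate-adjusted group difference by ordinary least squares
#'
#' Regresses the outcome on a binary group indicator plus covariates and
#' returns the group coefficient with its two-sided p-value and residual df.
#'
#' @param table Data.frame with outcome, group and covariate columns.
#' @param outcome_column Name of the numeric outcome.
#' @param group_column Name of the binary group column (two levels; the
#'   coefficient is for the second level relative to the first).
#' @param covariate_columns Character vector of covariate column names
#'   (numeric or 0/1).
#' @return A test result with method `ols_coefficient`.
#' @export
adjusted_group_difference <- function(table, outcome_column, group_column,
                                      covariate_columns = character(0)) {
  cols <- c(outcome_column, group_column, covariate_columns)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- table[[group_column]]
  if (!is.numeric(g)) g <- as.integer(factor(g)) - 1L
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("group column must be binary", call. = FALSE)
  df <- table[, c(outcome_column, covariate_columns), drop = FALSE]
  df$.group <- as.numeric(g == lev[2])
  if (nrow(df) <= length(covariate_columns) + 2) {
    stop("too few rows for the number of predictors", call. = FALSE)
  }
  fml <- stats::reformulate(c(".group", covariate_columns),
                            response = outcome_column)
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients[".group", ]
  test_result(unname(cf["t value"]), fit$df.residual,
              unname(cf["Pr(>|t|)"]), "ols_coefficient",
              unname(cf["Estimate"]))
}

#' Covariates of the adjusted comparison
#'
#' Age, diabetes, hypertension, signal strength, spherical equivalent
#' (droppable via config), intraocular pressure and axial length.
#'
#' @param config Configuration from [octa_config()].
#' @return Character vector of column names.
#' @export
adjustment_covariates <- function(config = octa_config()) {
  covs <- c("age", "diabetes", "hypertension", "signal_strength",
            "spherical_equivalent", "iop_mmHg", "axial_length_mm")
  if (!isTRUE(config$adjust_spherical_equivalent)) {
    covs <- setdiff(covs, "spherical_equivalent")
  }
  covs
}

#' Build the two cohort comparison tables
#'
#' Table A: participant characteristics by group — mean (SD) with an
#' unadjusted pooled t-test for continuous rows, n (%) with a 2x2
#' chi-square for categorical rows. Table B: the 13 OCTA metrics — mean
#' (SD) per group with the covariate-adjusted OLS p-value. No
#' multiple-testing correction is applied (each metric is tested at
#' alpha = 0.05).
#'
#' @param records Data.frame of per-participant records: `ethnicity` (two
#'   levels), `age`, `sex` (`"F"`/`"M"`), `diabetes`, `hypertension`
#'   (0/1 or logical), `axial_length_mm`, `spherical_equivalent` (or
#'   `sphere_D` + `cylinder_D`), `iop_mmHg`, `signal_strength`, plus the
#'   columns of [metrics_columns()].
#' @param config Configuration from [octa_config()].
#' @return List with data.frames `characteristics` and `octa_metrics`, each
#'   with columns `variable`, `mean_g1`, `sd_g1`, `mean_g2`, `sd_g2`,
#'   `estimate`, `p_value`, `method`.
#' @export
build_comparison_tables <- function(records, config = octa_config()) {
  stopifnot(is.data.frame(records))
  if (!"spherical_equivalent" %in% names(records)) {
    if (all(c("sphere_D", "cylinder_D") %in% names(records))) {
      records$spherical_equivalent <-
        spherical_equivalent(records$sphere_D, records$cylinder_D)
    } else {
      stop("validation error: no spherical_equivalent (or sphere/cylinder)",
           call. = FALSE)
    }
  }
  for (col in c("diabetes", "hypertension")) {
    if (col %in% names(records)) records[[col]] <- as.numeric(records[[col]])
  }
  grp <- factor(records$ethnicity)
  if (nlevels(grp) != 2) {
    stop("validation error: exactly two groups required", call. = FALSE)
  }
  g1 <- records[grp == levels(grp)[1], , drop = FALSE]
  g2 <- records[grp == levels(grp)[2], , drop = FALSE]

  cont_row <- function(var) {
    s1 <- group_summary(g1[[var]]); s2 <- group_summary(g2[[var]])
    r <- t_test_from_summary(s1, s2, welch = isTRUE(config$welch))
    data.frame(variable = var, mean_g1 = s1$mean, sd_g1 = s1$sd,
               mean_g2 = s2$mean, sd_g2 = s2$sd, estimate = r$estimate,
               p_value = r$p_value, method = r$method,
               stringsAsFactors = FALSE)
  }
  cat_row <- function(var, positive) {
    a <- sum(g1[[var]] == positive); b <- sum(g1[[var]] != positive)
    cc <- sum(g2[[var]] == positive); d <- sum(g2[[var]] != positive)
    # a variable absent (or universal) in both groups has a zero margin and
    # no testable contrast; report the proportions with an NA p
    r <- tryCatch(chi_square_2x2(a, b, cc, d),
                  error = function(e) list(estimate = NA_real_,
                                           p_value = NA_real_,
                                           method = "chi_square"))
    data.frame(variable = var, mean_g1 = a / (a + b), sd_g1 = NA_real_,
               mean_g2 = cc / (cc + d), sd_g2 = NA_real_,
               estimate = r$estimate, p_value = r$p_value, method = r$method,
               stringsAsFactors = FALSE)
  }

  char_rows <- list(cont_row("age"))
  if ("sex" %in% names(records)) char_rows <- c(char_rows, list(cat_row("sex", "F")))
  for (v in c("diabetes", "hypertension")) {
    if (v %in% names(records)) char_rows <- c(char_rows, list(cat_row(v, 1)))
  }
  for (v in c("axial_length_mm", "spherical_equivalent", "iop_mmHg",
              "signal_strength")) {
    if (v %in% names(records)) char_rows <- c(char_rows, list(cont_row(v)))
  }
  characteristics <- do.call(rbind, char_rows)

  metrics <- metrics_columns()
  missing <- setdiff(metrics, names(records))
  if (length(missing)) {
    stop("validation error: missing metric columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  covs <- adjustment_covariates(config)
  constant <- covs[vapply(covs, function(v) {
    v %in% names(records) && length(unique(records[[v]])) < 2
  }, logical(1))]
  if (length(constant)) {
    message("dropping zero-variance adjusters: ",
            paste(constant, collapse = ", "))
    covs <- setdiff(covs, constant)
  }
  octa_rows <- lapply(metrics, function(var) {
    s1 <- group_summary(g1[[var]]); s2 <- group_summary(g2[[var]])
    r <- adjusted_group_difference(records, var, "ethnicity", covs)
    data.frame(variable = var, mean_g1 = s1$mean, sd_g1 = s1$sd,
               mean_g2 = s2$mean, sd_g2 = s2$sd, estimate = r$estimate,
               p_value = r$p_value, method = r$method,
               stringsAsFactors = FALSE)
  })
  list(characteristics = characteristics,
       octa_metrics = do.call(rbind, octa_rows))
}
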