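#' Literature reference concentrations for sweat arginine
#'
#' Published mean arginine concentrations in eccrine sweat by biological
#' sex, with their standard errors: 94.8 +/- 12.9 µM for females and
#' 54.0 +/- 12.6 µM for males. These anchor both the classification
#' threshold and the cohort-versus-literature comparisons.
#'
#' @param mu_female,sem_female,mu_male,sem_male Override the defaults (µM).
#' @return A `literature_reference` list.
#' @export
literature_reference <- function(mu_female = 94.8, sem_female = 12.9,
                                 mu_male = 54.0, sem_male = 12.6) {
  stopifnot(mu_female >= 0, mu_male >= 0, sem_female >= 0, sem_male >= 0)
  structure(list(mu_female = mu_female, sem_female = sem_female,
                 mu_male = mu_male, sem_male = sem_male),
            class = "literature_reference")
}

#' Donor mean over admitted fingers
#'
#' Thumb and little-finger deposits give erratic concentrations (finger
#' size changes the contact area), so donor-level aggregation admits only
#' the index, middle and ring fingers by default.
#'
#' @param prints A data frame with columns `finger` and `concentration`
#'   (µM), one row per print.
#' @param admitted_fingers Character vector of fingers to average over.
#' @return The arithmetic mean concentration (µM) over admitted prints.
#' @export
aggregate_donor <- function(prints,
                            admitted_fingers = c("index", "middle", "ring")) {
  stopifnot(is.data.frame(prints),
            all(c("finger", "concentration") %in% names(prints)))
  keep <- prints$finger %in% admitted_fingers
  if (!any(keep)) {
    stop("no prints on admitted fingers (", paste(admitted_fingers, collapse = ", "),
         ")", call. = FALSE)
  }
  mean(prints$concentration[keep])
}

#' Presumptive biological sex from a donor-mean concentration
#'
#' Midpoint threshold between the literature sex means (74.4 µM at the
#' defaults): donor means above it are called female, below it male, and a
#' mean exactly on the threshold is inconclusive.
#'
#' @param donor_mean Donor mean concentration(s), µM.
#' @param ref A [literature_reference()].
#' @return Character vector: `"female"`, `"male"` or `"inconclusive"`.
#' @export
classify_sex <- function(donor_mean, ref = literature_reference()) {
  stopifnot(inherits(ref, "literature_reference"), all(donor_mean >= 0))
  threshold <- (ref$mu_female + ref$mu_male) / 2
  ifelse(donor_mean > threshold, "female",
         ifelse(donor_mean < threshold, "male", "inconclusive"))
}

#' Cohort summary statistics
#'
#' Mean, standard error of the mean (sample SD over sqrt(n)) and a Student-t
#' 95 % confidence interval for a set of concentration values.
#'
#' @param values Numeric vector of concentrations (µM), n >= 2.
#' @return A `cohort_summary` list: `n`, `mean`, `sem`, `ci95_low`,
#'   `ci95_high`.
#' @export
cohort_summary <- function(values) {
  n <- length(values)
  if (n < 2L) stop("cohort summary needs at least two values", call. = FALSE)
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(n)
  half <- stats::qt(0.975, df = n - 1L) * sem
  structure(list(n = n, mean = m, sem = sem,
                 ci95_low = m - half, ci95_high = m + half),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean %.1f +/- %.1f uM (SEM), 95%% CI [%.1f, %.1f]\n",
              x$n, x$mean, x$sem, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Compare two summarised means by pooled standard errors
#'
#' Two-sided normal (z) test of two means known only through their
#' summaries: `z = |mean1 - mean2| / sqrt(sem1^2 + sem2^2)`. Used to set an
#' observed cohort mean against a literature value for which only mean and
#' SEM are published. Symmetric in its two arguments.
#'
#' @param mean1,sem1,mean2,sem2 The two means and their standard errors
#'   (µM); the SEMs must not both be zero unless the means are equal.
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result`: `statistic` (z), `p_value`, `significant`,
#'   `method`, and `degenerate` (TRUE when both SEMs are zero).
#' @export
compare_summary_to_reference <- function(mean1, sem1, mean2, sem2,
                                         alpha = 0.05) {
  stopifnot(sem1 >= 0, sem2 >= 0)
  pooled <- sqrt(sem1^2 + sem2^2)
  degenerate <- pooled == 0
  if (degenerate) {
    z <- if (mean1 == mean2) 0 else Inf
    p <- if (mean1 == mean2) 1 else 0
  } else {
    z <- abs(mean1 - mean2) / pooled
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(statistic = z, p_value = p, significant = p < alpha,
                 method = "pooled-SEM normal test", degenerate = degenerate),
            class = "comparison_result")
}

#' Compare two groups of per-print concentrations
#'
#' Welch two-sample t test (unequal variances, Welch–Satterthwaite degrees
#' of freedom) on raw per-print values, as used to contrast male against
#' female samples.
#'
#' @param group1,group2 Numeric vectors of concentrations (µM), each with
#'   at least two values.
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result`: `statistic` (t), `p_value`, `significant`,
#'   `df`, `method`.
#' @export
compare_print_samples <- function(group1, group2, alpha = 0.05) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    # degenerate: constant groups; identical means -> no evidence of difference
    same <- mean(group1) == mean(group2)
    return(structure(list(statistic = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0,
                          significant = !same, df = NA_real_,
                          method = "Welch two-sample t test (degenerate)"),
                     class = "comparison_result"))
  }
  ht <- stats::t.test(group1, group2, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 significant = ht$p.value < alpha,
                 df = unname(ht$parameter),
                 method = "Welch two-sample t test"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Score a blind study against ground truth
#'
#' Counts presumptive/actual matches over donors and reports accuracy as a
#' whole-number percentage. Inconclusive presumptive calls are scored as
#' mismatches.
#'
#' @param records A data frame with character columns `presumptive_sex` and
#'   `actual_sex`, one row per donor.
#' @return A list: `matches`, `total`, `accuracy` (percent, rounded to the
#'   nearest whole number).
#' @export
score_blind_study <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("presumptive_sex", "actual_sex") %in% names(records)))
  if (anyNA(records$actual_sex)) {
    stop("every record needs an actual sex to score against", call. = FALSE)
  }
  match_ok <- records$presumptive_sex == records$actual_sex &
    records$presumptive_sex %in% c("female", "male")
  matches <- sum(match_ok)
  total <- nrow(records)
  list(matches = matches, total = total,
       accuracy = round(100 * matches / total))
}

#' The blind study's published presumptive/actual table
#'
#' The 15-donor table of presumptive and actual biological sexes from the
#' assay's blind validation study (one mismatch), shipped as a plain-text
#' fixture for replay through [score_blind_study()].
#'
#' @return A tibble: `sample_number`, `presumptive_sex`, `actual_sex`.
#' @export
blind_study_table <- function() {
  path <- system.file("extdata", "blind_study_table1.csv", package = "argmark",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
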