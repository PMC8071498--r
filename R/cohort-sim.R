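#' Configuration for simulated donor cohorts
#'
#' Statistical model for per-print arginine concentrations in male and
#' female donors. The sex means default to the sweat literature values
#' (94.8 µM female, 54.0 µM male). Per-print total SDs default to the
#' blind-study dispersion implied by the reported SEMs and sample sizes
#' (female 5.1 * sqrt(33) ~ 29.3 µM, male 5.3 * sqrt(12) ~ 18.4 µM). Total
#' variance is split into a donor-level random effect (fraction
#' `between_fraction`) and independent print-to-print noise.
#'
#' `lifting_efficiency` multiplies the concentration actually rendered
#' (recovery loss when prints are lifted from a surface);
#' `powder_artifact_fraction` overwrites that fraction of window pixels
#' with near-black speckle, emulating residual fingerprint powder. The
#' defaults (1 and 0) are the direct-deposit, unpowdered protocol.
#'
#' @param mu_female,mu_male Cohort mean concentrations, µM.
#' @param sd_print_female,sd_print_male Per-print total SDs, µM.
#' @param between_fraction Fraction of total variance assigned to donor
#'   effects, in [0, 1].
#' @param prints_per_donor Admitted prints per donor (default 3:
#'   index, middle, ring).
#' @param lifting_efficiency Multiplicative recovery factor in (0, 1].
#' @param powder_artifact_fraction Fraction of window pixels speckled,
#'   in [0, 0.5).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(mu_female = 94.8, mu_male = 54.0,
                          sd_print_female = 5.1 * sqrt(33),
                          sd_print_male = 5.3 * sqrt(12),
                          between_fraction = 0.7,
                          prints_per_donor = 3L,
                          lifting_efficiency = 1,
                          powder_artifact_fraction = 0) {
  stopifnot(mu_female >= 0, mu_male >= 0,
            sd_print_female >= 0, sd_print_male >= 0,
            between_fraction >= 0, between_fraction <= 1,
            prints_per_donor >= 1,
            lifting_efficiency > 0, lifting_efficiency <= 1,
            powder_artifact_fraction >= 0, powder_artifact_fraction < 0.5)
  structure(
    list(mu_female = mu_female, mu_male = mu_male,
         sd_print_female = sd_print_female, sd_print_male = sd_print_male,
         between_fraction = between_fraction,
         prints_per_donor = as.integer(prints_per_donor),
         lifting_efficiency = lifting_efficiency,
         powder_artifact_fraction = powder_artifact_fraction),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("cohort config: female %.1f +/- %.1f uM, male %.1f +/- %.1f uM, ",
           "between fraction %.2f, %d prints/donor\n"),
    x$mu_female, x$sd_print_female, x$mu_male, x$sd_print_male,
    x$between_fraction, x$prints_per_donor))
  if (x$lifting_efficiency < 1 || x$powder_artifact_fraction > 0) {
    cat(sprintf("  lifting efficiency %.2f, powder fraction %.2f\n",
                x$lifting_efficiency, x$powder_artifact_fraction))
  }
  invisible(x)
}

#' Sample per-print concentrations for a set of donors
#'
#' Each print value is `max(0, mu + donor_effect + print_noise)` with
#' `donor_effect ~ N(0, sd^2 * between_fraction)` shared within a donor and
#' `print_noise ~ N(0, sd^2 * (1 - between_fraction))` independent per
#' print. Negative draws are truncated at zero (concentrations are
#' physical quantities).
#'
#' @param config A [cohort_config()].
#' @param sex `"female"` or `"male"`.
#' @param n_donors Number of donors (>= 1).
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @return A named list, one numeric vector of per-print µM values per
#'   donor.
#' @export
sample_print_concentrations <- function(config, sex, n_donors, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), n_donors >= 1)
  sex <- match.arg(sex, c("female", "male"))
  mu <- if (sex == "female") config$mu_female else config$mu_male
  sd_tot <- if (sex == "female") config$sd_print_female else config$sd_print_male
  sd_between <- sd_tot * sqrt(config$between_fraction)
  sd_within <- sd_tot * sqrt(1 - config$between_fraction)
  k <- config$prints_per_donor

  draw <- function() {
    donor_effect <- stats::rnorm(n_donors, 0, sd_between)
    out <- lapply(seq_len(n_donors), function(i) {
      pmax(0, mu + donor_effect[i] + stats::rnorm(k, 0, sd_within))
    })
    names(out) <- sprintf("%s%03d", substr(sex, 1L, 1L), seq_len(n_donors))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic donor cohort with rendered images
#'
#' Draws per-print concentrations for `n_female` female and `n_male` male
#' donors, applies the lifting-efficiency recovery factor, renders one
#' detection-window image per print, and optionally speckles a fraction of
#' window pixels with near-black powder artifacts. Prints are labelled
#' index, middle, ring (then little and thumb when more than three per
#' donor are requested).
#'
#' @param config A [cohort_config()].
#' @param n_female,n_male Donor counts; the total must be >= 1.
#' @param model A [forward_model()].
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with one row per print: `donor_id`, `actual_sex`,
#'   `finger`, `concentration_true` (µM, before lifting loss), `image`
#'   (list of image arrays).
#' @export
generate_cohort <- function(config = cohort_config(), n_female, n_male,
                            model = forward_model(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "forward_model"),
            n_female >= 0, n_male >= 0, n_female + n_male >= 1)
  fingers <- c("index", "middle", "ring", "little", "thumb")
  labels <- rep_len(fingers, config$prints_per_donor)

  build_sex <- function(sex, n) {
    if (n == 0L) return(NULL)
    conc <- sample_print_concentrations(config, sex, n)
    rows <- lapply(names(conc), function(id) {
      true_c <- conc[[id]]
      imgs <- lapply(true_c * config$lifting_efficiency, function(cc) {
        img <- render_detection_window(cc, model)
        speckle_window(img, model, config$powder_artifact_fraction)
      })
      tibble::tibble(donor_id = id, actual_sex = sex, finger = labels,
                     concentration_true = true_c, image = imgs)
    })
    do.call(rbind, rows)
  }
  build <- function() rbind(build_sex("female", n_female),
                            build_sex("male", n_male))
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# overwrite a fraction of window pixels with dark equal-channel speckle
speckle_window <- function(image, model, fraction) {
  if (fraction <= 0) return(image)
  rows <- (model$window[2L] + 1):(model$window[2L] + model$window[4L])
  cols <- (model$window[1L] + 1):(model$window[1L] + model$window[3L])
  npx <- length(rows) * length(cols)
  n_spk <- round(fraction * npx)
  if (n_spk == 0L) return(image)
  idx <- sample.int(npx, n_spk)
  level <- sample.int(31L, n_spk, replace = TRUE) - 1L  # brightness <= 30
  win <- image[rows, cols, , drop = FALSE]
  for (ch in 1:3) {
    plane <- win[, , ch]
    plane[idx] <- level
    win[, , ch] <- plane
  }
  image[rows, cols, ] <- win
  image
}
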