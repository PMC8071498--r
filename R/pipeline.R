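#' Simulate a cohort to disk: images plus manifest
#'
#' Renders a synthetic donor cohort and writes one image file per print
#' together with a manifest CSV (`donor_id`, `sex`, `finger`,
#' `concentration_true`, `image_path`). The seed and generator settings are
#' echoed into a sidecar JSON so every output is reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [cohort_config()].
#' @param n_female,n_male Donor counts.
#' @param model A [forward_model()].
#' @param seed Integer seed for the whole simulation.
#' @param format `"tiff"` or `"png"`.
#' @return The manifest tibble, invisibly; files land under `out_dir`.
#' @export
simulate_cohort_images <- function(out_dir, config = cohort_config(),
                                   n_female, n_male,
                                   model = forward_model(), seed = 1L,
                                   format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (n_female + n_male == 0L) {
    warning("no donors requested: writing an empty manifest", call. = FALSE)
    manifest <- tibble::tibble(donor_id = character(), sex = character(),
                               finger = character(),
                               concentration_true = numeric(),
                               image_path = character())
  } else {
    cohort <- generate_cohort(config, n_female, n_male, model, seed = seed)
    paths <- file.path(out_dir, sprintf("%s_%s.%s", cohort$donor_id,
                                        cohort$finger, ext))
    Map(write_image, cohort$image, paths)
    manifest <- tibble::tibble(donor_id = cohort$donor_id,
                               sex = cohort$actual_sex,
                               finger = cohort$finger,
                               concentration_true = cohort$concentration_true,
                               image_path = paths)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_female = n_female, n_male = n_male,
         config = unclass(config), model = unclass(model)),
    file.path(out_dir, "simulation_settings.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Quantify prints: segment, tint, measure, invert
#'
#' Runs the measurement chain over a set of prints — either an in-memory
#' cohort tibble with an `image` list-column, or a manifest tibble with an
#' `image_path` column — and converts each mean saturation to a
#' concentration through the calibration. Per-image failures (unreadable
#' file, window not found without an ROI fallback) are logged into the
#' `status` column and do not abort the run.
#'
#' @param prints A tibble with `image` (list of arrays) or `image_path`
#'   (character) plus any id columns, which are carried through.
#' @param calibration A [calibration_model][fit_calibration()].
#' @param roi Optional `c(x, y, w, h)` rectangle used when thresholding
#'   fails (see [roi_mask()]).
#' @param ... Segmentation settings passed to [segment_detection_window()].
#' @return The input tibble (minus the `image` column) with `pixel_count`,
#'   `mean_red`, `mean_saturation`, `concentration` (µM), `in_range` and
#'   `status` (`"ok"`, `"window_not_found"`, `"read_error"`) appended.
#' @export
quantify_prints <- function(prints, calibration, roi = NULL, ...) {
  stopifnot(inherits(calibration, "calibration_model"),
            is.data.frame(prints))
  has_images <- "image" %in% names(prints)
  if (!has_images && !"image_path" %in% names(prints)) {
    stop("prints must carry an `image` or `image_path` column", call. = FALSE)
  }
  n <- nrow(prints)
  out <- tibble::as_tibble(prints[setdiff(names(prints), "image")])
  out$pixel_count <- NA_integer_
  out$mean_red <- NA_real_
  out$mean_saturation <- NA_real_
  out$concentration <- NA_real_
  out$in_range <- NA
  out$status <- rep("ok", length.out = n)

  for (i in seq_len(n)) {
    img <- tryCatch(
      if (has_images) prints$image[[i]] else read_image(prints$image_path[i]),
      error = function(e) e
    )
    if (inherits(img, "error")) {
      out$status[i] <- "read_error"
      next
    }
    mask <- tryCatch(segment_detection_window(img, ...), error = function(e) e)
    if (inherits(mask, "argmark_window_not_found") && !is.null(roi)) {
      mask <- roi_mask(img, roi)
    }
    if (inherits(mask, "error")) {
      out$status[i] <- "window_not_found"
      next
    }
    metrics <- measure_window(img, mask, tint = TRUE)
    est <- invert_calibration(calibration, metrics$mean_saturation)
    out$pixel_count[i] <- metrics$pixel_count
    out$mean_red[i] <- metrics$mean_red
    out$mean_saturation[i] <- metrics$mean_saturation
    out$concentration[i] <- est$value
    out$in_range[i] <- est$in_range
  }
  out
}

#' Donor-level classification report and cohort statistics
#'
#' Aggregates quantified prints to donor means over the admitted fingers,
#' assigns presumptive sexes by the midpoint threshold, and — where at
#' least two admitted prints per group exist — summarises each presumptive
#' cohort, compares it against the literature reference, and contrasts the
#' two groups' per-print values with a Welch t test. When ground-truth
#' sexes are present the blind-study accuracy is scored; donors with no
#' admitted prints are listed as skipped.
#'
#' @param quantified Output of [quantify_prints()]: needs `donor_id`,
#'   `finger`, `concentration`, optionally `sex` or `actual_sex`.
#' @param admitted_fingers Fingers admitted to the donor mean.
#' @param ref A [literature_reference()].
#' @param alpha Significance level for comparisons.
#' @return A list: `donors` (tibble: donor_id, n_prints, donor_mean,
#'   presumptive_sex, actual_sex, match), `skipped` (donor ids),
#'   `summaries` (per presumptive sex, over admitted per-print values),
#'   `comparisons` (vs literature and female-vs-male), `blind_score`
#'   (when ground truth is available).
#' @export
classify_donors <- function(quantified,
                            admitted_fingers = c("index", "middle", "ring"),
                            ref = literature_reference(), alpha = 0.05) {
  stopifnot(is.data.frame(quantified),
            all(c("donor_id", "finger", "concentration") %in% names(quantified)))
  actual_col <- intersect(c("actual_sex", "sex"), names(quantified))[1]
  ok <- !is.na(quantified$concentration)
  admitted <- ok & quantified$finger %in% admitted_fingers

  ids <- unique(quantified$donor_id)
  rows <- lapply(ids, function(id) {
    sub <- quantified[quantified$donor_id == id & admitted, , drop = FALSE]
    actual <- if (!is.na(actual_col)) {
      stats::na.omit(unique(quantified[[actual_col]][quantified$donor_id == id]))[1]
    } else NA_character_
    if (nrow(sub) == 0L) {
      return(tibble::tibble(donor_id = id, n_prints = 0L,
                            donor_mean = NA_real_,
                            presumptive_sex = NA_character_,
                            actual_sex = as.character(actual)))
    }
    dm <- mean(sub$concentration)
    tibble::tibble(donor_id = id, n_prints = nrow(sub), donor_mean = dm,
                   presumptive_sex = classify_sex(dm, ref),
                   actual_sex = as.character(actual))
  })
  donors <- do.call(rbind, rows)
  donors$match <- !is.na(donors$presumptive_sex) &
    !is.na(donors$actual_sex) &
    donors$presumptive_sex == donors$actual_sex
  skipped <- donors$donor_id[donors$n_prints == 0L]
  scored <- donors[donors$n_prints > 0L, , drop = FALSE]

  # per-print values pooled by presumptive group (each deposit enumerated)
  prints_by_group <- lapply(c(female = "female", male = "male"), function(sx) {
    dn <- scored$donor_id[scored$presumptive_sex == sx]
    quantified$concentration[admitted & quantified$donor_id %in% dn]
  })
  summaries <- lapply(prints_by_group, function(v) {
    if (length(v) >= 2L) cohort_summary(v) else NULL
  })
  comparisons <- list()
  lit <- list(female = c(ref$mu_female, ref$sem_female),
              male = c(ref$mu_male, ref$sem_male))
  for (sx in c("female", "male")) {
    if (!is.null(summaries[[sx]])) {
      comparisons[[paste0(sx, "_vs_literature")]] <-
        compare_summary_to_reference(summaries[[sx]]$mean, summaries[[sx]]$sem,
                                     lit[[sx]][1], lit[[sx]][2], alpha = alpha)
    }
  }
  if (all(lengths(prints_by_group) >= 2L)) {
    comparisons$female_vs_male <-
      compare_print_samples(prints_by_group$female, prints_by_group$male,
                            alpha = alpha)
  }
  blind_score <- if (!all(is.na(scored$actual_sex)) && nrow(scored) > 0L) {
    score_blind_study(scored[!is.na(scored$actual_sex), , drop = FALSE])
  } else NULL

  list(donors = donors, skipped = skipped, summaries = summaries,
       comparisons = comparisons, blind_score = blind_score)
}

#' Read a pipeline run configuration from YAML
#'
#' Layout mirrors the pipeline stages: a `synthetic` block (cohort and
#' forward-model settings), `segmentation`, `calibration` (standard
#' concentrations), `analysis` (admitted fingers, literature reference,
#' alpha) and `seed`. Every field is optional; omitted fields fall back to
#' the package defaults documented on the respective constructors.
#'
#' @param path YAML file path.
#' @return A list with elements `config` ([cohort_config()]), `model`
#'   ([forward_model()]), `segmentation` (list), `standards` (numeric),
#'   `analysis` (list), `seed` (integer).
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  syn <- raw$synthetic %||% list()
  cfg_args <- syn[intersect(names(syn), names(formals(cohort_config)))]
  mod_args <- syn[intersect(names(syn), names(formals(forward_model)))]
  seg <- raw$segmentation %||% list()
  ana <- raw$analysis %||% list()
  ref_args <- ana$literature_reference %||% list()
  list(
    config = do.call(cohort_config, cfg_args),
    model = do.call(forward_model, mod_args),
    segmentation = seg[intersect(names(seg), c("hue_range", "min_saturation",
                                               "min_area_fraction", "roi"))],
    standards = raw$calibration$standards %||% seq(20, 120, by = 20),
    analysis = list(
      admitted_fingers = ana$admitted_fingers %||% c("index", "middle", "ring"),
      ref = do.call(literature_reference, ref_args),
      alpha = ana$alpha %||% 0.05
    ),
    seed = as.integer(raw$seed %||% 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
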