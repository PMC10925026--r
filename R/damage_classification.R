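#' Spatial localization statistic for dye-positive fibers
#'
#' Mechanically caused cell death concentrates around the indentation site
#' (a centralised damage pattern), while background death is scattered
#' throughout the cross-section. This test operationalizes that distinction:
#' the statistic is the mean pairwise distance among the positive-fiber
#' centroids, and its null distribution is obtained by drawing equal-size
#' fiber subsets uniformly from all centroids. A small Monte-Carlo p-value
#' means the positives are more tightly packed than random subsets, i.e.
#' spatially clustered.
#'
#' @param positive_centroids Data frame with `row`, `col` of dye-positive
#'   fiber centroids.
#' @param all_centroids Data frame with `row`, `col` of all fiber centroids
#'   in the section.
#' @param n_null Number of null draws (default 999).
#' @param seed Optional integer seed for the null draws.
#'
#' @return One-row tibble: `statistic` (mean pairwise distance, px),
#'   `p_value` (Monte-Carlo rank, lower tail), `n_positive`. With fewer than
#'   3 positives no pattern is detectable: statistic and p-value are `NA`
#'   (treated as not localized downstream).
#' @export
localization_statistic <- function(positive_centroids, all_centroids,
                                   n_null = 999, seed = NULL) {
  stopifnot(is.data.frame(positive_centroids), is.data.frame(all_centroids),
            n_null >= 1)
  m <- nrow(positive_centroids)
  if (m < 3) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_positive = m))
  }
  if (m > nrow(all_centroids)) {
    stop("more positive centroids than fibers in the section", call. = FALSE)
  }
  P <- as.matrix(positive_centroids[c("row", "col")])
  A <- as.matrix(all_centroids[c("row", "col")])
  obs <- mean(stats::dist(P))
  draw_null <- function() {
    vapply(seq_len(n_null), function(i) {
      mean(stats::dist(A[sample.int(nrow(A), m), , drop = FALSE]))
    }, numeric(1))
  }
  null_stats <- if (!is.null(seed)) withr::with_seed(seed, draw_null())
    else draw_null()
  p <- (1 + sum(null_stats <= obs)) / (n_null + 1)
  tibble::tibble(statistic = obs, p_value = p, n_positive = m)
}

#' Sample-level localization call
#'
#' A sample is categorised as showing a centralised damage pattern when one
#' or more of its sections does: the smallest section p-value is compared
#' against `alpha_loc`. Sections where the test was undefined (`NA`, fewer
#' than 3 positives) carry no evidence and are ignored; a sample with only
#' undefined sections is not localized.
#'
#' @param p_values Numeric vector of per-section localization p-values.
#' @param alpha_loc Significance level (default 0.05).
#' @return Logical scalar.
#' @export
is_sample_localized <- function(p_values, alpha_loc = 0.05) {
  stopifnot(length(p_values) >= 1)
  p <- p_values[!is.na(p_values)]
  length(p) > 0 && min(p) < alpha_loc
}

#' Derive the dead-cell count baseline
#'
#' The lowest mean dead-fiber count among samples showing a centralised
#' (localized) damage pattern. Samples at or above this baseline are
#' classified as "cell death", samples below it as "no damage".
#'
#' @param samples Data frame with logical `localized` and numeric
#'   `mean_count` columns.
#' @return The baseline count (numeric scalar).
#' @export
derive_baseline <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("localized", "mean_count") %in% names(samples)))
  loc <- samples$mean_count[samples$localized]
  if (length(loc) == 0) {
    stop("baseline undefined: no sample shows a localized damage pattern",
         call. = FALSE)
  }
  min(loc)
}

#' Classify samples against the count baseline
#'
#' Mean counts at or above the baseline are `"cell_death"`, below it
#' `"no_damage"` (the baseline-defining sample is itself damaged, so the
#' boundary is inclusive).
#'
#' @param mean_count Numeric vector of per-sample mean dead-fiber counts.
#' @param baseline Baseline from [derive_baseline()].
#' @return Character vector of labels.
#' @export
classify_sample <- function(mean_count, baseline) {
  stopifnot(is.numeric(mean_count), is.numeric(baseline), length(baseline) == 1)
  ifelse(mean_count >= baseline, "cell_death", "no_damage")
}

#' Classify a whole study dataset
#'
#' Runs the localization test on every section of every sample, makes the
#' sample-level localization calls, derives the count baseline from the
#' localized samples, and labels every sample. The per-section significance
#' level is Sidak-adjusted, `1 - (1 - alpha_loc)^(1/n_sections)`, so that
#' `alpha_loc` is the sample-level false-localization rate regardless of how
#' many sections a sample has.
#'
#' @param study A study tibble as produced by [simulate_study()] (columns
#'   `sample_id`, `mean_count`, `sections` with per-section
#'   `positive_centroids` / `all_centroids`).
#' @param alpha_loc Sample-level localization significance level.
#' @param n_null Null draws per section.
#' @param seed Optional integer seed for all permutation draws.
#' @return The study tibble with `section_p` (list), `localized`, `label`
#'   columns added and the derived `baseline` as an attribute.
#' @export
classify_study <- function(study, alpha_loc = 0.05, n_null = 999,
                           seed = NULL) {
  stopifnot(is.data.frame(study),
            all(c("sample_id", "mean_count", "sections") %in% names(study)))
  max_sections <- max(vapply(study$sections, nrow, integer(1)))
  if (1 / (n_null + 1) >= 1 - (1 - alpha_loc)^(1 / max_sections)) {
    stop("`n_null` too small: the permutation p-value cannot resolve the ",
         "per-section significance level; increase n_null", call. = FALSE)
  }
  run <- function() {
    section_p <- purrr::map(study$sections, function(sec) {
      purrr::map2_dbl(sec$positive_centroids, sec$all_centroids,
                      function(pos, all) {
                        localization_statistic(pos, all,
                                               n_null = n_null)$p_value
                      })
    })
    n_sec <- vapply(section_p, length, integer(1))
    alpha_section <- 1 - (1 - alpha_loc)^(1 / pmax(n_sec, 1))
    localized <- purrr::map2_lgl(section_p, alpha_section,
                                 is_sample_localized)
    out <- dplyr::mutate(study, section_p = section_p, localized = localized)
    baseline <- derive_baseline(out)
    out <- dplyr::mutate(out,
                         label = classify_sample(.data$mean_count, baseline))
    attr(out, "baseline") <- baseline
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Assemble stress-time fit points from a classified study
#'
#' Splits the classified, non-excluded samples into the point sets used to
#' fit the cell-death and no-damage threshold curves. The stress coordinate
#' is the internal compressive stress. Exclusions are explicit user inputs
#' (e.g. a known staining failure), never automatic.
#'
#' @param study Classified study (with `label` column; see
#'   [classify_study()]).
#' @param exclude Character vector of `sample_id`s to drop.
#' @return Tibble `sample_id`, `t_min`, `sigma_kpa`, `label`; the dropped
#'   ids are recorded in the `"excluded"` attribute. Feed each label's rows
#'   to [fit_threshold()].
#' @export
assemble_fit_points <- function(study, exclude = character()) {
  stopifnot(is.data.frame(study))
  if (!"label" %in% names(study) || anyNA(study$label)) {
    stop("study contains unclassified samples; run classify_study() first",
         call. = FALSE)
  }
  missing_ids <- setdiff(exclude, study$sample_id)
  if (length(missing_ids) > 0) {
    warning("excluded ids not in study: ", paste(missing_ids, collapse = ", "),
            call. = FALSE)
  }
  out <- study[!study$sample_id %in% exclude,
               c("sample_id", "duration_min", "sigma_int_kpa", "label")]
  out <- tibble::as_tibble(out)
  names(out)[names(out) == "duration_min"] <- "t_min"
  names(out)[names(out) == "sigma_int_kpa"] <- "sigma_kpa"
  attr(out, "excluded") <- intersect(exclude, study$sample_id)
  out
}
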