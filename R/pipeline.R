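#' Quantify one section image end to end
#'
#' Convenience wrapper chaining the per-section image stages: preprocess both
#' channels, segment fibers on the autofluorescence channel, optionally
#' restrict to the indented area, and score dye positivity against a
#' control-derived threshold.
#'
#' @param auto,dye Raw channel matrices (same shape).
#' @param threshold Dye intensity threshold from
#'   [control_intensity_threshold()].
#' @param background_radius,min_area See [preprocess_channel()] and
#'   [segment_fibers()].
#' @param indent_center,indent_radius See [restrict_to_indented_area()];
#'   the default (`Inf`) scores the whole section.
#' @return One-row tibble from [score_dye_positive()].
#' @export
quantify_section <- function(auto, dye, threshold, background_radius = 50,
                             min_area = 40, indent_center = NULL,
                             indent_radius = Inf) {
  auto_pp <- preprocess_channel(auto, background_radius = background_radius)
  dye_pp <- preprocess_channel(dye, background_radius = background_radius)
  fibmap <- segment_fibers(auto_pp, min_area = min_area)
  if (!is.null(indent_center) && is.finite(indent_radius)) {
    fibmap <- restrict_to_indented_area(fibmap, indent_center, indent_radius)
  }
  score_dye_positive(fibmap, dye_pp, threshold)
}

#' Control-derived threshold for a stack of control sections
#'
#' Preprocesses each control section's channels and pools the dye intensity
#' over the tissue foreground of all of them.
#'
#' @param controls List of sections, each a list with `auto` and `dye`
#'   matrices (e.g. the `image` element of [simulate_scene()] outputs).
#' @param background_radius See [preprocess_channel()].
#' @return Intensity threshold in `[0, 1]`.
#' @export
threshold_from_controls <- function(controls, background_radius = 50) {
  stopifnot(length(controls) >= 1)
  dye_pp <- purrr::map(controls, function(s)
    preprocess_channel(s$dye, background_radius = background_radius))
  masks <- purrr::map(controls, function(s)
    tissue_mask(preprocess_channel(s$auto,
                                   background_radius = background_radius)))
  control_intensity_threshold(dye_pp, masks)
}

#' Run the full stress-time study analysis
#'
#' Sequences the analysis stages on a study dataset: localization testing and
#' baseline classification, explicit exclusions, assembly of stress-time
#' points, and constrained Boltzmann threshold fitting for both categories.
#' When no `study` is supplied, a synthetic one is simulated from `design`
#' under `seed`, so the bundled end-to-end example is fully reproducible.
#'
#' @param study Optional study tibble (see [simulate_study()]); simulated
#'   from `design` when `NULL`.
#' @param design Study design used when simulating.
#' @param seed Integer seed controlling simulation, permutation draws and
#'   fit multi-starts.
#' @param exclude Character vector of sample ids excluded from fitting (with
#'   a reason recorded in the manifest).
#' @param exclusion_reason Free-text reason stored alongside `exclude`.
#' @param alpha_loc,n_null Localization test settings, see
#'   [classify_study()].
#' @param starts Multi-start count for [fit_threshold()].
#' @param reference Reference [threshold_model] for the comparison table
#'   (`NULL` to skip).
#'
#' @return A list of class `dti_run`: `study` (classified tibble),
#'   `baseline`, `fit_points`, `models` (per category), `comparison`,
#'   and a `manifest` (seed, parameters, design hash) sufficient to
#'   reproduce the run.
#' @export
run_study_pipeline <- function(study = NULL, design = default_study_design(),
                               seed = NULL, exclude = character(),
                               exclusion_reason = NULL,
                               alpha_loc = 0.05, n_null = 999, starts = 16,
                               reference = in_vivo_reference_threshold()) {
  if (is.null(study)) study <- simulate_study(design, seed = seed)
  classified <- classify_study(study, alpha_loc = alpha_loc, n_null = n_null,
                               seed = if (!is.null(seed)) seed + 1L)
  pts <- assemble_fit_points(classified, exclude = exclude)
  models <- list()
  for (cat in c("cell_death", "no_damage")) {
    sub <- pts[pts$label == cat, ]
    if (nrow(sub) >= 4) {
      models[[cat]] <- fit_threshold(sub, category = cat, starts = starts,
                                     seed = if (!is.null(seed)) seed + 2L)
    }
  }
  comparison <- NULL
  if (!is.null(reference) && !is.null(models$cell_death)) {
    comparison <- compare_thresholds(models$cell_death, reference)
  }
  structure(
    list(study = classified,
         baseline = attr(classified, "baseline"),
         fit_points = pts,
         models = models,
         comparison = comparison,
         reference = reference,
         manifest = list(
           seed = seed,
           alpha_loc = alpha_loc, n_null = n_null, starts = starts,
           exclude = exclude, exclusion_reason = exclusion_reason,
           n_samples = nrow(classified),
           design_hash = rlang::hash(design),
           package_version = as.character(utils::packageVersion("dtithresh")))),
    class = "dti_run")
}

#' @export
print.dti_run <- function(x, ...) {
  cat("Stress-time study analysis\n")
  cat(sprintf("  %d samples, baseline %.1f dead fibers\n",
              nrow(x$study), x$baseline))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(table(x$study$label)),
                            table(x$study$label)), collapse = ", ")))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %s fit: K=%.2f alpha=%.3f t0=%.1f C=%.2f (SSE %.3f)\n",
                nm, m$K, m$alpha, m$t0, m$C, m$sse))
  }
  invisible(x)
}

#' Render a Markdown analysis report
#'
#' Produces the comparison report of a pipeline run: sample classification
#' table, count baseline, fitted Boltzmann parameters per category, and —
#' when a reference model is available — the parameter deltas against it
#' (a positive delta means the reference exceeds the fitted curve, i.e. the
#' study's threshold sits lower).
#'
#' @param run A `dti_run` from [run_study_pipeline()].
#' @param path Optional file path; the report text is written there too.
#' @return The report as a single Markdown string, invisibly when `path` is
#'   given.
#' @export
render_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "dti_run"))
  if (length(run$models) == 0) {
    stop("no fitted models in this run; nothing to report", call. = FALSE)
  }
  fmt_row <- function(...) paste(unlist(list(...)), collapse = " | ")
  lines <- c(
    "# Stress-time cell death threshold report",
    "",
    sprintf("Samples: %d; excluded from fitting: %s", nrow(run$study),
            if (length(run$manifest$exclude) == 0) "none"
            else paste(run$manifest$exclude, collapse = ", ")),
    sprintf("Dead-cell count baseline (lowest localized sample mean): %.1f",
            run$baseline),
    "",
    "## Sample classification",
    "",
    fmt_row("sample", "t (min)", "sigma_int (kPa)", "mean count",
            "localized", "label"),
    fmt_row("---", "---", "---", "---", "---", "---"),
    sprintf("%s | %g | %g | %.1f | %s | %s",
            run$study$sample_id, run$study$duration_min,
            run$study$sigma_int_kpa, run$study$mean_count,
            ifelse(run$study$localized, "yes", "no"), run$study$label),
    "",
    "## Fitted Boltzmann threshold parameters",
    ""
  )
  has_ref <- !is.null(run$reference)
  header <- c("category", "K (kPa)", "alpha (1/min)", "t0 (min)", "C (kPa)",
              "SSE (kPa^2)")
  if (has_ref) header <- c(header, "dK vs ref", "dC vs ref")
  lines <- c(lines, fmt_row(header),
             fmt_row(rep("---", length(header))))
  for (nm in names(run$models)) {
    m <- run$models[[nm]]
    row <- c(nm, sprintf("%.2f", m$K), sprintf("%.3f", m$alpha),
             sprintf("%.1f", m$t0), sprintf("%.2f", m$C),
             sprintf("%.3f", m$sse))
    if (has_ref) {
      cmp <- compare_thresholds(m, run$reference)
      row <- c(row, sprintf("%.2f", cmp$delta[cmp$term == "K"]),
               sprintf("%.2f", cmp$delta[cmp$term == "C"]))
    }
    lines <- c(lines, fmt_row(row))
  }
  if (has_ref) {
    r <- run$reference
    row <- c("reference", sprintf("%.2f", r$K), sprintf("%.3f", r$alpha),
             sprintf("%.1f", r$t0), sprintf("%.2f", r$C), "-")
    lines <- c(lines, fmt_row(c(row, "0.00", "0.00")))
  }
  lines <- c(lines, "",
             sprintf("Run manifest: seed=%s, alpha_loc=%g, n_null=%d, starts=%d, design=%s",
                     run$manifest$seed %||% "NULL", run$manifest$alpha_loc,
                     run$manifest$n_null, run$manifest$starts,
                     run$manifest$design_hash))
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Plot a classified study with its fitted threshold curves
#'
#' Stress-time scatter (triangles for cell death, circles for no damage)
#' with the fitted threshold curves overlaid.
#'
#' @param object A `dti_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dti_run <- function(object, ...) {
  st <- object$study
  t_rng <- range(st$duration_min)
  tt <- seq(t_rng[1], t_rng[2], length.out = 200)
  curves <- purrr::imap_dfr(object$models, function(m, nm) {
    tibble::tibble(label = nm, t_min = tt, sigma_kpa = predict(m, tt))
  })
  ggplot2::ggplot(st, ggplot2::aes(.data$duration_min, .data$sigma_int_kpa,
                                   shape = .data$label)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$t_min, .data$sigma_kpa,
                                    colour = .data$label),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::scale_shape_manual(values = c(cell_death = 17, no_damage = 1)) +
    ggplot2::labs(x = "loading duration (min)",
                  y = "internal compressive stress (kPa)",
                  shape = "classified", colour = "fitted threshold") +
    ggplot2::theme_minimal()
}

#' Read study input tables
#'
#' Thin CSV readers for the package's two tabular input contracts: the
#' loading table (`sample_id`, `mass_g` or `force_n`, `radius_mm`,
#' `duration_min`) and stress-time fit points (`t_min`, `sigma_kpa`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_loading_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path))
  need <- c("sample_id", "radius_mm", "duration_min")
  if (!all(need %in% names(tbl))) {
    stop("loading table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' @rdname read_loading_table
#' @export
read_fit_points <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("t_min", "sigma_kpa") %in% names(tbl))) {
    stop("fit points need columns t_min, sigma_kpa", call. = FALSE)
  }
  tbl
}

#' Export a fitted threshold model as JSON
#'
#' @param model A [threshold_model].
#' @param path Optional file to write to.
#' @return JSON string (invisibly when written to `path`).
#' @export
threshold_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "threshold_model"))
  obj <- list(K = model$K, alpha = model$alpha, t0 = model$t0, C = model$C,
              sse = model$sse, category = model$category,
              n_points = model$n_points,
              constraints = lapply(model$constraints[c("lower", "upper")],
                                   as.list))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
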