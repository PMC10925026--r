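#' Default rendering parameters for synthetic sections
#'
#' Intensity model for the two channels of a rendered cross-section.
#' Viable fibers carry a per-fiber lognormal autofluorescence level; dead
#' fibers are slightly dimmer in the autofluorescence channel and gain strong
#' dye signal. The interstitial space between fibers accumulates dye above
#' the viable-fiber interior level (soak staining pools dye extracellularly),
#' which is what gives the control-derived mean-intensity threshold its
#' margin over viable fibers. Noise is additive Gaussian plus a
#' signal-dependent (shot-noise-like) component.
#'
#' @return Named list of rendering parameters (intensities on a `[0, 1]`
#'   scale).
#' @export
default_render_params <- function() {
  list(
    auto_mean = 0.55,        # median autofluorescence of viable fibers
    auto_sdlog = 0.15,       # lognormal spread between fibers
    auto_dead_factor = 0.85, # dead fibers keep most autofluorescence
    interstitial_auto = 0.05,
    dye_base = 0.06,         # dye level inside viable fibers
    dye_sdlog = 0.10,
    dye_interstitial = 0.28, # extracellular dye accumulation
    dye_gain = 0.50,         # added dye signal in dead fibers
    noise_add = 0.02,
    noise_mult = 0.05
  )
}

# jittered hexagonal grid of fiber centers filling `shape`, exactly n points
hex_fiber_centers <- function(n_fibers, shape) {
  stopifnot(n_fibers >= 1)
  target <- ceiling(n_fibers * 1.15)
  s <- sqrt(prod(shape) / target / (sqrt(3) / 2))
  for (i in 1:8) {
    ry <- s * sqrt(3) / 2
    rows <- seq(1 + ry / 2, shape[1], by = ry)
    pts <- do.call(rbind, lapply(seq_along(rows), function(k) {
      off <- if (k %% 2 == 0) s / 2 else 0
      cols <- seq(1 + s / 2 + off, shape[2], by = s)
      cbind(rows[k], cols)
    }))
    jit <- matrix(stats::runif(length(pts), -0.22 * s, 0.22 * s),
                  nrow(pts), 2)
    pts <- pts + jit
    ok <- pts[, 1] >= 2 & pts[, 1] <= shape[1] - 1 &
      pts[, 2] >= 2 & pts[, 2] <= shape[2] - 1
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) >= n_fibers) {
      sel <- sort(sample.int(nrow(pts), n_fibers))
      return(list(centers = pts[sel, , drop = FALSE], spacing = s))
    }
    s <- s * 0.95
  }
  stop("could not place ", n_fibers, " fiber centers", call. = FALSE)
}

# nearest-center label assignment within a capped radius (truncated Voronoi)
assign_fiber_labels <- function(centers, shape, spacing) {
  L <- matrix(0L, shape[1], shape[2])
  D <- matrix(Inf, shape[1], shape[2])
  cap2 <- (0.8 * spacing)^2
  w <- ceiling(0.8 * spacing)
  for (k in seq_len(nrow(centers))) {
    r0 <- max(1, floor(centers[k, 1] - w)); r1 <- min(shape[1], ceiling(centers[k, 1] + w))
    c0 <- max(1, floor(centers[k, 2] - w)); c1 <- min(shape[2], ceiling(centers[k, 2] + w))
    dr <- (r0:r1) - centers[k, 1]
    dc <- (c0:c1) - centers[k, 2]
    d2 <- outer(dr^2, dc^2, "+")
    upd <- d2 < D[r0:r1, c0:c1] & d2 <= cap2
    Lb <- L[r0:r1, c0:c1]; Db <- D[r0:r1, c0:c1]
    Lb[upd] <- k; Db[upd] <- d2[upd]
    L[r0:r1, c0:c1] <- Lb; D[r0:r1, c0:c1] <- Db
  }
  L
}

# zero out pixels adjacent to a different label -> interstitial boundary
carve_boundaries <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  b <- matrix(FALSE, nr, nc)
  diff_with <- function(A, B) A != B
  b[-nr, ] <- b[-nr, ] | diff_with(L[-nr, ], L[-1, ])
  b[-1, ] <- b[-1, ] | diff_with(L[-1, ], L[-nr, ])
  b[, -nc] <- b[, -nc] | diff_with(L[, -nc], L[, -1])
  b[, -1] <- b[, -1] | diff_with(L[, -1], L[, -nc])
  out <- L
  out[b] <- 0L
  out
}

draw_dead_fibers <- function(n_fibers, dead_fraction, pattern, centers,
                             indent_center, kernel_width) {
  n_dead <- round(dead_fraction * n_fibers)
  if (n_dead == 0) return(integer(0))
  if (pattern == "scattered") {
    sort(sample.int(n_fibers, n_dead))
  } else {
    d2 <- (centers[, 1] - indent_center[1])^2 +
      (centers[, 2] - indent_center[2])^2
    w <- exp(-d2 / (2 * kernel_width^2))
    sort(sample.int(n_fibers, n_dead, prob = w + 1e-12))
  }
}

#' Simulate one ground-truthed two-channel muscle cross-section
#'
#' Builds a densely packed polygonal fiber tessellation (jittered hexagonal
#' grid, truncated-Voronoi cells separated by interstitial boundaries),
#' plants a known set of dead fibers either scattered uniformly or
#' concentrated around an indentation centre (sampling probability
#' proportional to a Gaussian kernel), and renders autofluorescence and dye
#' channels with the [default_render_params()] intensity model.
#'
#' @param n_fibers Number of fibers (>= 1).
#' @param shape Image shape `c(rows, cols)` in px.
#' @param pattern `"scattered"`, `"localized"`, or `"none"` (no dead fibers).
#' @param dead_fraction Fraction of fibers planted dead, in `[0, 1]`. The
#'   planted count is exactly `round(dead_fraction * n_fibers)`.
#' @param indent_center `c(row, col)` of the indentation, px. Required for
#'   the localized pattern; defaults to the image centre.
#' @param kernel_width Gaussian kernel sd in px for the localized pattern;
#'   default 10% of the section radius (`0.1 * min(shape) / 2`).
#' @param seed Optional integer; the same seed reproduces the scene
#'   bit-for-bit.
#' @param render_params Intensity model, see [default_render_params()].
#'
#' @return A list of class `synthetic_scene`:
#'   `centers` (tibble `fiber`, `row`, `col`), `labels` (ground-truth interior
#'   label matrix), `dead_fibers` (integer ids), `pattern`, `indent_center`,
#'   `kernel_width`, `image` (list with `auto` and `dye` matrices in
#'   `[0, 1]`), and the generation parameters.
#' @export
simulate_scene <- function(n_fibers = 800, shape = c(400, 400),
                           pattern = c("scattered", "localized", "none"),
                           dead_fraction = 0, indent_center = NULL,
                           kernel_width = NULL, seed = NULL,
                           render_params = default_render_params()) {
  pattern <- match.arg(pattern)
  stopifnot(n_fibers >= 1, dead_fraction >= 0, dead_fraction <= 1)
  if (pattern == "none" && dead_fraction > 0) {
    stop("pattern \"none\" requires dead_fraction = 0", call. = FALSE)
  }
  if (pattern == "localized" && is.null(indent_center)) {
    stop("localized pattern needs `indent_center`", call. = FALSE)
  }
  indent_center <- indent_center %||% (shape / 2)
  kernel_width <- kernel_width %||% (0.1 * min(shape) / 2)

  build <- function() {
    hc <- hex_fiber_centers(n_fibers, shape)
    L_full <- assign_fiber_labels(hc$centers, shape, hc$spacing)
    L <- carve_boundaries(L_full)
    dead <- draw_dead_fibers(n_fibers, dead_fraction, pattern, hc$centers,
                             indent_center, kernel_width)
    rp <- render_params
    is_dead <- seq_len(n_fibers) %in% dead
    auto_lvl <- rp$auto_mean * exp(stats::rnorm(n_fibers, 0, rp$auto_sdlog))
    auto_lvl[is_dead] <- auto_lvl[is_dead] * rp$auto_dead_factor
    dye_lvl <- rp$dye_base * exp(stats::rnorm(n_fibers, 0, rp$dye_sdlog))
    dye_lvl[is_dead] <- dye_lvl[is_dead] + rp$dye_gain

    auto <- matrix(rp$interstitial_auto, shape[1], shape[2])
    dye <- matrix(rp$dye_interstitial, shape[1], shape[2])
    idx <- which(L > 0L)
    lab <- L[idx]
    auto[idx] <- auto_lvl[lab]
    dye[idx] <- dye_lvl[lab]
    n <- length(auto)
    auto <- auto + stats::rnorm(n, 0, rp$noise_add) +
      stats::rnorm(n, 0, rp$noise_mult) * sqrt(pmax(auto, 0))
    dye <- dye + stats::rnorm(n, 0, rp$noise_add) +
      stats::rnorm(n, 0, rp$noise_mult) * sqrt(pmax(dye, 0))
    auto <- matrix(pmin(pmax(auto, 0), 1), shape[1], shape[2])
    dye <- matrix(pmin(pmax(dye, 0), 1), shape[1], shape[2])

    structure(
      list(centers = tibble::tibble(fiber = seq_len(n_fibers),
                                    row = hc$centers[, 1],
                                    col = hc$centers[, 2]),
           labels = L, dead_fibers = dead, pattern = pattern,
           indent_center = indent_center, kernel_width = kernel_width,
           image = list(auto = auto, dye = dye),
           n_fibers = n_fibers, shape = shape,
           dead_fraction = dead_fraction, render_params = rp, seed = seed),
      class = "synthetic_scene")
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic section: %d fibers (%d dead, %s) on %d x %d px\n",
              x$n_fibers, length(x$dead_fibers), x$pattern,
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Simulate negative-control sections
#'
#' Control sections contain no planted dead fibers (`dead_fraction = 0`);
#' their pooled dye intensity defines the masking threshold for the sample's
#' indented sections.
#'
#' @param n_sections Number of control sections (default 6 per sample).
#' @param n_fibers,shape,render_params Passed to [simulate_scene()].
#' @param seed Optional integer seed for the whole stack.
#' @return List of `synthetic_scene` objects.
#' @export
simulate_control_sections <- function(n_sections = 6, n_fibers = 800,
                                      shape = c(400, 400), seed = NULL,
                                      render_params = default_render_params()) {
  stopifnot(n_sections >= 1)
  build <- function() {
    lapply(seq_len(n_sections), function(i) {
      simulate_scene(n_fibers = n_fibers, shape = shape, pattern = "none",
                     dead_fraction = 0, render_params = render_params)
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

#' Simulate stress-time points from a threshold curve
#'
#' Recovery harness for threshold fitting: evaluates a truth curve on a time
#' grid and adds i.i.d. Gaussian stress noise.
#'
#' @param truth A [threshold_model].
#' @param t_grid Loading durations in min.
#' @param noise_sd Gaussian noise sd in kPa (>= 0).
#' @param replicates Replicates per grid point.
#' @param seed Optional integer seed.
#' @return Tibble with `t_min`, `sigma_kpa`.
#' @export
simulate_fit_points <- function(truth, t_grid = seq(30, 120, by = 15),
                                noise_sd = 0.3, replicates = 5, seed = NULL) {
  stopifnot(inherits(truth, "threshold_model"), noise_sd >= 0, replicates >= 1)
  build <- function() {
    t <- rep(t_grid, each = replicates)
    tibble::tibble(
      t_min = t,
      sigma_kpa = predict(truth, t) + stats::rnorm(length(t), 0, noise_sd)
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

#' Default stress-time study design
#'
#' Twelve samples: four loading durations (30, 60, 90, 120 min) crossed with
#' three internal-stress levels per duration. The low level is the lowest
#' internal stress used in the reference protocol (3.4 kPa), the high level
#' the highest (69 kPa), and the middle level lies halfway between the
#' cell-death and no-damage threshold curves at that duration (the transition
#' zone). One sample per stress-duration combination, six sections each.
#'
#' @param truth_death,truth_no_damage Truth curves used to place the middle
#'   level.
#' @return Tibble `sample_id`, `duration_min`, `level`, `sigma_int_kpa`.
#' @export
default_study_design <- function(truth_death = cell_death_threshold(),
                                 truth_no_damage = no_damage_threshold()) {
  durations <- c(30, 60, 90, 120)
  rows <- purrr::map_dfr(durations, function(t) {
    mid <- (predict(truth_death, t) + predict(truth_no_damage, t)) / 2
    tibble::tibble(duration_min = t,
                   level = c("low", "mid", "high"),
                   sigma_int_kpa = c(3.4, round(mid, 1), 69))
  })
  dplyr::mutate(rows,
                sample_id = sprintf("S%02d", dplyr::row_number()),
                .before = 1)
}

#' Simulate a full stress-time indentation study
#'
#' Generates a ground-truth-labelled study: each stress-duration condition is
#' labelled by the truth curves (`cell_death` above the cell-death curve,
#' `no_damage` below the no-damage curve, stochastic in the transition zone
#' with probability interpolated between the curves), then per-section
#' dead-fiber counts are drawn from an overdispersed (negative binomial)
#' count model and per-section centroid point patterns are generated with the
#' matching spatial pattern (localized around the indent for damaged samples,
#' scattered for undamaged ones).
#'
#' Section data are point patterns (fiber centroids plus the dead subset),
#' which is what the localization test consumes; set `render_images = TRUE`
#' to also render full two-channel images per section.
#'
#' @param design Study design tibble, see [default_study_design()].
#' @param seed Optional integer seed; fixes labels, counts and patterns.
#' @param truth_death,truth_no_damage Truth threshold curves.
#' @param count_model Named list: `mean_damaged`, `size_damaged`,
#'   `mean_undamaged`, `size_undamaged` (negative-binomial mean/size per
#'   section). Defaults keep damaged sample means within the observed
#'   110-254 range and undamaged means below it.
#' @param sections_per_sample Sections per sample (default 6).
#' @param n_fibers Fibers per section point pattern.
#' @param shape Section shape in px.
#' @param render_images Also render two-channel images per section (slow).
#'
#' @return A tibble of class `study_dataset` with one row per sample:
#'   `sample_id`, `duration_min`, `sigma_int_kpa`, `truth_label`,
#'   `mean_count`, and a `sections` list column (per-section tibbles with
#'   `n_positive`, `all_centroids`, `positive_centroids`, and optionally
#'   `image`).
#' @export
simulate_study <- function(design = default_study_design(), seed = NULL,
                           truth_death = cell_death_threshold(),
                           truth_no_damage = no_damage_threshold(),
                           count_model = list(mean_damaged = 180,
                                              size_damaged = 40,
                                              mean_undamaged = 70,
                                              size_undamaged = 50),
                           sections_per_sample = 6,
                           n_fibers = 800, shape = c(400, 400),
                           render_images = FALSE) {
  stopifnot(is.data.frame(design), nrow(design) >= 1,
            all(c("sample_id", "duration_min", "sigma_int_kpa") %in%
                  names(design)))
  build <- function() {
    indent_center <- shape / 2
    kernel_width <- 0.1 * min(shape) / 2
    out <- purrr::pmap_dfr(
      design[c("sample_id", "duration_min", "sigma_int_kpa")],
      function(sample_id, duration_min, sigma_int_kpa) {
        hi <- predict(truth_death, duration_min)
        lo <- predict(truth_no_damage, duration_min)
        p_death <- if (sigma_int_kpa >= hi) 1
          else if (sigma_int_kpa <= lo) 0
          else (sigma_int_kpa - lo) / (hi - lo)
        label <- if (stats::runif(1) < p_death) "cell_death" else "no_damage"
        damaged <- label == "cell_death"
        mu <- if (damaged) count_model$mean_damaged else count_model$mean_undamaged
        size <- if (damaged) count_model$size_damaged else count_model$size_undamaged
        counts <- stats::rnbinom(sections_per_sample, mu = mu, size = size)
        counts <- pmin(pmax(counts, 3L), n_fibers)
        sections <- purrr::map_dfr(seq_len(sections_per_sample), function(s) {
          hc <- hex_fiber_centers(n_fibers, shape)
          cen <- tibble::tibble(fiber = seq_len(n_fibers),
                                row = hc$centers[, 1], col = hc$centers[, 2])
          dead <- draw_dead_fibers(
            n_fibers, counts[s] / n_fibers,
            pattern = if (damaged) "localized" else "scattered",
            centers = hc$centers, indent_center = indent_center,
            kernel_width = kernel_width)
          tibble::tibble(section = s, n_positive = length(dead),
                         all_centroids = list(cen[c("row", "col")]),
                         positive_centroids = list(cen[dead, c("row", "col")]))
        })
        if (render_images) {
          sections$image <- purrr::map(seq_len(sections_per_sample), function(s) {
            simulate_scene(n_fibers = n_fibers, shape = shape,
                           pattern = if (damaged) "localized" else "scattered",
                           dead_fraction = sections$n_positive[s] / n_fibers,
                           indent_center = indent_center,
                           kernel_width = kernel_width)$image
          })
        }
        tibble::tibble(sample_id = sample_id, duration_min = duration_min,
                       sigma_int_kpa = sigma_int_kpa, truth_label = label,
                       mean_count = mean(sections$n_positive),
                       sections = list(sections))
      })
    class(out) <- c("study_dataset", class(out))
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}
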