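#' Four-parameter Boltzmann stress-time threshold model
#'
#' The stress-time tolerance of muscle tissue to sustained compression is
#' described by a decreasing single-step Boltzmann sigmoid
#' \deqn{\sigma(t) = K / (1 + e^{\alpha (t - t_0)}) + C}
#' where `K` (kPa) is the range of the function, `alpha` (1/min) the slope
#' coefficient, `t0` (min) the time at midrange and `C` (kPa) the minimum
#' compressive stress asymptote. Stress-time combinations above the curve kill
#' muscle fibers; combinations below it are tolerated.
#'
#' @param K Range of the function, kPa (> 0).
#' @param alpha Slope coefficient, 1/min (> 0).
#' @param t0 Time at midrange, min (> 0).
#' @param C Minimum compressive stress asymptote, kPa (>= 0).
#' @param category One of `"cell_death"`, `"no_damage"`, `"reference"`;
#'   which side of the damage boundary the curve describes.
#' @param sse Optional sum of squared residuals (kPa^2) when the model came
#'   from a fit.
#'
#' @return An object of class `threshold_model`.
#' @examples
#' m <- threshold_model(K = 16.2, alpha = 0.5, t0 = 90, C = 5.5)
#' predict(m, t = 90) # K/2 + C = 13.6
#' @export
threshold_model <- function(K, alpha, t0, C,
                            category = c("reference", "cell_death", "no_damage"),
                            sse = NA_real_) {
  category <- match.arg(category)
  stopifnot(is.numeric(K), is.numeric(alpha), is.numeric(t0), is.numeric(C))
  if (K <= 0) stop("`K` must be positive", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (t0 <= 0) stop("`t0` must be positive", call. = FALSE)
  if (C < 0) stop("`C` must be non-negative", call. = FALSE)
  structure(
    list(K = K, alpha = alpha, t0 = t0, C = C,
         category = category, sse = sse,
         data = NULL, constraints = NULL, n_points = NA_integer_,
         converged = NA),
    class = "threshold_model"
  )
}

boltzmann_sigma <- function(t, K, alpha, t0, C) {
  # plogis keeps e^z from overflowing for large alpha * (t - t0)
  K * stats::plogis(-alpha * (t - t0)) + C
}

#' Evaluate a threshold curve
#'
#' @param object A [threshold_model].
#' @param t Loading durations in minutes.
#' @param ... Unused.
#' @return Compressive stress in kPa at each `t`.
#' @export
predict.threshold_model <- function(object, t, ...) {
  boltzmann_sigma(t, object$K, object$alpha, object$t0, object$C)
}

#' Canonical ex vivo and in vivo threshold curves
#'
#' `cell_death_threshold()` and `no_damage_threshold()` are the fitted ex vivo
#' curves bounding the "cell death" and "no damage" regions of the stress-time
#' plane (between them lies a region of uncertainty where a fiber's fate is
#' not clearly destined). `in_vivo_reference_threshold()` is the earlier
#' in vivo cell-death threshold used for comparison, reconstructed from the
#' reported parameter reductions (K lower by 6.8 kPa and C by 3.1 kPa in the
#' ex vivo study) and the published slope 0.15/min.
#'
#' @return A [threshold_model].
#' @export
cell_death_threshold <- function() {
  threshold_model(K = 16.2, alpha = 0.5, t0 = 90, C = 5.5,
                  category = "cell_death")
}

#' @rdname cell_death_threshold
#' @export
no_damage_threshold <- function() {
  threshold_model(K = 13.1, alpha = 0.5, t0 = 90, C = 4.2,
                  category = "no_damage")
}

#' @rdname cell_death_threshold
#' @export
in_vivo_reference_threshold <- function() {
  threshold_model(K = 23.0, alpha = 0.15, t0 = 90, C = 8.6,
                  category = "reference")
}

#' Box constraints for threshold fitting
#'
#' The minimum-stress asymptote `C` is restricted conservatively: a
#' cell-death curve must stay below all cell-death datapoints (`C < 6` kPa)
#' and a no-damage curve above all no-damage datapoints (`C > 3.7` kPa).
#' The remaining bounds are wide sanity boxes; `t0` defaults to the observed
#' time range and is filled in at fit time.
#'
#' @param category `"cell_death"`, `"no_damage"` or `"reference"`.
#' @return A list with named `lower` and `upper` vectors over
#'   `K`, `alpha`, `t0`, `C`.
#' @export
default_fit_constraints <- function(category = c("cell_death", "no_damage",
                                                 "reference")) {
  category <- match.arg(category)
  lower <- c(K = 1e-6, alpha = 1e-6, t0 = NA_real_, C = 0)
  upper <- c(K = 50, alpha = 5, t0 = NA_real_, C = 20)
  if (category == "cell_death") upper[["C"]] <- 6 - 1e-8
  if (category == "no_damage") lower[["C"]] <- 3.7 + 1e-8
  list(lower = lower, upper = upper)
}

#' Fit a Boltzmann stress-time threshold by constrained least squares
#'
#' Minimises the sum of squared vertical (stress) residuals over box-bounded
#' parameters with a seeded multi-start strategy: Latin-hypercube starting
#' points across the feasible box plus a data-driven start, each refined by
#' `L-BFGS-B` with an analytic gradient, keeping the best optimum.
#'
#' @param data A data frame with columns `t_min` and `sigma_kpa`.
#' @param category Which constraint set to apply; see
#'   [default_fit_constraints()].
#' @param constraints Optional list with `lower`/`upper` named vectors over
#'   `K`, `alpha`, `t0`, `C`, overriding the defaults. `NA` entries for `t0`
#'   are replaced by the observed time range.
#' @param fixed Optional named numeric vector of parameters held fixed
#'   (e.g. `c(alpha = 0.15, t0 = 90)` to adopt slope and midrange time from a
#'   reference study and fit only `K` and `C`).
#' @param starts Number of multi-start points (default 16).
#' @param seed Optional seed making the Latin-hypercube draw reproducible.
#'
#' @return A [threshold_model] with `sse`, `n_points`, `data`, `constraints`
#'   and `converged` filled in.
#' @examples
#' pts <- simulate_fit_points(cell_death_threshold(),
#'                            t_grid = seq(30, 120, by = 5),
#'                            noise_sd = 0, replicates = 1)
#' fit <- fit_threshold(pts, category = "cell_death", seed = 1)
#' round(unlist(fit[c("K", "alpha", "t0", "C")]), 3)
#' @export
fit_threshold <- function(data,
                          category = c("cell_death", "no_damage", "reference"),
                          constraints = NULL, fixed = NULL,
                          starts = 16, seed = NULL) {
  category <- match.arg(category)
  stopifnot(is.data.frame(data),
            all(c("t_min", "sigma_kpa") %in% names(data)))
  t <- data$t_min
  y <- data$sigma_kpa
  if (anyNA(t) || anyNA(y)) stop("fit points contain missing values", call. = FALSE)

  par_names <- c("K", "alpha", "t0", "C")
  fixed <- fixed %||% stats::setNames(numeric(0), character(0))
  if (!all(names(fixed) %in% par_names)) {
    stop("`fixed` may only name K, alpha, t0, C", call. = FALSE)
  }
  free <- setdiff(par_names, names(fixed))
  if (length(t) < length(free)) {
    stop("underdetermined fit: ", length(t), " points for ", length(free),
         " free parameters", call. = FALSE)
  }
  if (length(unique(t)) < 2) {
    stop("degenerate design: all loading durations identical", call. = FALSE)
  }

  cst <- constraints %||% default_fit_constraints(category)
  lower <- cst$lower[par_names]
  upper <- cst$upper[par_names]
  if (is.na(lower[["t0"]])) lower[["t0"]] <- min(t)
  if (is.na(upper[["t0"]])) upper[["t0"]] <- max(t)
  if (any(lower[free] >= upper[free])) {
    stop("each free parameter needs lower < upper bounds", call. = FALSE)
  }

  full_par <- function(p_free) {
    p <- stats::setNames(numeric(4), par_names)
    p[free] <- p_free
    p[names(fixed)] <- fixed
    p
  }
  obj <- function(p_free) {
    p <- full_par(p_free)
    sum((y - boltzmann_sigma(t, p["K"], p["alpha"], p["t0"], p["C"]))^2)
  }
  grad <- function(p_free) {
    p <- full_par(p_free)
    s <- stats::plogis(-p["alpha"] * (t - p["t0"]))
    r <- y - (p["K"] * s + p["C"])
    d <- cbind(K = s,
               alpha = -p["K"] * (t - p["t0"]) * s * (1 - s),
               t0 = p["K"] * p["alpha"] * s * (1 - s),
               C = rep(1, length(t)))
    (-2 * colSums(r * d))[free]
  }

  # data-driven start: range and floor of the observed stresses
  guess <- c(K = max(1e-3, diff(range(y))), alpha = 0.5,
             t0 = stats::median(t), C = max(0, min(y)))
  guess <- pmin(pmax(guess, lower), upper)
  draw <- if (!is.null(seed)) {
    withr::with_seed(seed, lhs::randomLHS(starts, length(free)))
  } else {
    lhs::randomLHS(starts, length(free))
  }
  start_mat <- rbind(
    guess[free],
    sweep(sweep(draw, 2, (upper - lower)[free], "*"), 2, lower[free], "+")
  )

  best <- NULL
  for (i in seq_len(nrow(start_mat))) {
    res <- tryCatch(
      stats::optim(start_mat[i, ], obj, grad, method = "L-BFGS-B",
                   lower = lower[free], upper = upper[free],
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("all optimiser starts failed", call. = FALSE)
  converged <- best$convergence == 0
  # polish the winner; at machine precision the line search may abort (code
  # 52) without harm, so keep the polished point only when it is no worse
  polish <- tryCatch(
    stats::optim(best$par, obj, grad, method = "L-BFGS-B",
                 lower = lower[free], upper = upper[free],
                 control = list(maxit = 1000, factr = 10)),
    error = function(e) best
  )
  if (polish$value <= best$value) best <- polish

  p <- full_par(best$par)
  out <- threshold_model(K = p[["K"]], alpha = p[["alpha"]],
                         t0 = p[["t0"]], C = p[["C"]],
                         category = category, sse = best$value)
  out$data <- tibble::as_tibble(data[c("t_min", "sigma_kpa")])
  out$constraints <- list(lower = lower, upper = upper, fixed = fixed)
  out$n_points <- length(t)
  out$converged <- converged
  out
}

#' Sum of squared residuals of a threshold model
#'
#' @param model A [threshold_model].
#' @param data Data frame with `t_min`, `sigma_kpa`; defaults to the points
#'   the model was fitted to.
#' @return Sum of squared stress residuals, kPa^2.
#' @export
sse_threshold <- function(model, data = model$data) {
  stopifnot(inherits(model, "threshold_model"))
  if (is.null(data) || nrow(data) == 0) {
    stop("no points to evaluate residuals on", call. = FALSE)
  }
  sum((data$sigma_kpa - predict(model, data$t_min))^2)
}

#' Compare two threshold models parameter by parameter
#'
#' @param a,b [threshold_model] objects.
#' @return A tibble with one row per parameter and columns `term`, `a`, `b`,
#'   `delta` (`b - a`): a positive `delta` means the parameter is larger in
#'   `b`.
#' @examples
#' # the ex vivo cell-death curve sits 6.8 kPa (K) and 3.1 kPa (C) below
#' # the in vivo reference:
#' compare_thresholds(cell_death_threshold(), in_vivo_reference_threshold())
#' @export
compare_thresholds <- function(a, b) {
  stopifnot(inherits(a, "threshold_model"), inherits(b, "threshold_model"))
  terms <- c("K", "alpha", "t0", "C")
  va <- unlist(a[terms])
  vb <- unlist(b[terms])
  tibble::tibble(term = terms, a = unname(va), b = unname(vb),
                 delta = unname(vb - va))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold model
#'
#' @param x A [threshold_model].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`, `fixed`.
#' @export
tidy.threshold_model <- function(x, ...) {
  fixed_names <- names(x$constraints$fixed %||% character(0))
  tibble::tibble(
    term = c("K", "alpha", "t0", "C"),
    estimate = c(x$K, x$alpha, x$t0, x$C),
    unit = c("kPa", "1/min", "min", "kPa"),
    fixed = c("K", "alpha", "t0", "C") %in% fixed_names
  )
}

#' Glance at a threshold model
#'
#' @param x A [threshold_model].
#' @param ... Unused.
#' @return A one-row tibble with `category`, `sse`, `n_points`, `converged`,
#'   and the half-range stress `sigma_mid = K/2 + C` at `t0`.
#' @export
glance.threshold_model <- function(x, ...) {
  tibble::tibble(category = x$category, sse = x$sse, n_points = x$n_points,
                 converged = x$converged, sigma_mid = x$K / 2 + x$C)
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("Boltzmann stress-time threshold [%s]\n", x$category))
  cat(sprintf("  sigma(t) = %.3f / (1 + exp(%.3f (t - %.2f))) + %.3f  [kPa, t in min]\n",
              x$K, x$alpha, x$t0, x$C))
  if (!is.na(x$sse)) {
    cat(sprintf("  SSE %.4f kPa^2 on %s points\n", x$sse,
                ifelse(is.na(x$n_points), "?", x$n_points)))
  }
  invisible(x)
}

#' Plot a threshold curve with its fit points
#'
#' @param object A [threshold_model].
#' @param t_range Time range (min) for the curve; defaults to the fitted data
#'   range or 30-120 min.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_model <- function(object, t_range = NULL, ...) {
  t_range <- t_range %||%
    if (!is.null(object$data)) range(object$data$t_min) else c(30, 120)
  tt <- seq(t_range[1], t_range[2], length.out = 200)
  curve_df <- tibble::tibble(t_min = tt, sigma_kpa = predict(object, tt))
  p <- ggplot2::ggplot(curve_df, ggplot2::aes(.data$t_min, .data$sigma_kpa)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "loading duration (min)",
                  y = "compressive stress (kPa)",
                  title = sprintf("stress-time threshold (%s)", object$category)) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data, shape = 17, size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
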