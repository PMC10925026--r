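#' Preprocess a fluorescence channel
#'
#' Standard preparation of a raw section channel before thresholding or
#' segmentation: optional 8-bit quantisation, background estimation by
#' grayscale morphological opening with a disc (a rolling-ball equivalent)
#' and subtraction, then percentile-clipped rescaling to `[0, 1]`.
#'
#' @param img Numeric matrix of non-negative intensities (one channel of one
#'   section). Pixel indices are 1-based `(row, col)` with the origin at the
#'   top-left, as everywhere in this package.
#' @param background_radius Disc radius in pixels for background estimation
#'   (> 0). Structures much larger than this are treated as background.
#' @param clip Lower/upper percentiles (in `[0, 100]`) used for robust
#'   rescaling after subtraction. Default `c(0.1, 99.9)`.
#' @param quantize_8bit If `TRUE`, quantise to 256 grey levels first
#'   (mirrors 8-bit conversion in common imaging workflows).
#'
#' @return Numeric matrix of the same shape with values in `[0, 1]`. A
#'   constant image maps to all zeros.
#' @export
preprocess_channel <- function(img, background_radius = 50,
                               clip = c(0.1, 99.9), quantize_8bit = FALSE) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (length(img) == 0) stop("empty image", call. = FALSE)
  if (any(!is.finite(img)) || any(img < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(background_radius) || background_radius <= 0) {
    stop("`background_radius` must be positive", call. = FALSE)
  }
  mx <- max(img)
  x <- if (mx > 0) img / mx else img
  if (quantize_8bit) x <- round(x * 255) / 255
  brush_w <- 2L * floor(background_radius) + 1L
  bg <- as.matrix(EBImage::opening(EBImage::Image(x),
                                   EBImage::makeBrush(brush_w, "disc")))
  x <- pmax(x - bg, 0)
  qs <- stats::quantile(x, clip / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  pmin(pmax((x - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Tissue foreground mask from the autofluorescence channel
#'
#' Automatic (Otsu) intensity threshold on the preprocessed autofluorescence
#' channel, followed by morphological closing so that thin interstitial gaps
#' between adjacent fibers are included in the tissue area.
#'
#' @param auto Preprocessed autofluorescence channel (matrix in `[0, 1]`).
#' @param close_radius Disc radius in pixels for the closing step; 0 disables
#'   it.
#' @return Logical matrix, `TRUE` on tissue.
#' @export
tissue_mask <- function(auto, close_radius = 3) {
  stopifnot(is.matrix(auto))
  if (max(auto) <= 0) return(matrix(FALSE, nrow(auto), ncol(auto)))
  thr <- EBImage::otsu(EBImage::Image(auto))
  m <- auto > thr
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2L * floor(close_radius) + 1L, "disc")
    m <- as.matrix(EBImage::closing(EBImage::Image(m * 1), brush)) > 0.5
  }
  m
}

#' Control-derived dye intensity threshold
#'
#' Computes the combined average dye intensity of a sample's control sections:
#' the pooled mean over all tissue-foreground pixels of every control section.
#' This value is used as the masking threshold for unlabelled fibers when
#' scoring the same sample's indented sections.
#'
#' @param dye_channels List of preprocessed dye-channel matrices (control
#'   sections of one sample).
#' @param masks List of logical foreground masks, same shapes; defaults to
#'   [tissue_mask()] of each dye channel's paired autofluorescence channel
#'   must be supplied by the caller — there is no default because the mask
#'   comes from the other channel.
#'
#' @return A single intensity threshold in `[0, 1]`.
#' @export
control_intensity_threshold <- function(dye_channels, masks) {
  if (is.matrix(dye_channels)) dye_channels <- list(dye_channels)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(dye_channels) >= 1,
            length(dye_channels) == length(masks))
  vals <- unlist(purrr::map2(dye_channels, masks, function(d, m) {
    stopifnot(all(dim(d) == dim(m)))
    d[m]
  }))
  if (length(vals) == 0) {
    stop("empty foreground: no tissue pixels in the control sections",
         call. = FALSE)
  }
  mean(vals)
}

new_fiber_map <- function(labels, centroids) {
  structure(list(labels = labels, centroids = centroids),
            class = "fiber_map")
}

#' @export
print.fiber_map <- function(x, ...) {
  cat(sprintf("fiber map: %d fibers on a %d x %d section\n",
              nrow(x$centroids), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0) {
    return(tibble::tibble(fiber = integer(), row = numeric(), col = numeric(),
                          area = integer()))
  }
  lab <- labels[idx]
  pos <- arrayInd(idx, dim(labels))
  area <- tabulate(lab)
  keep <- which(area > 0)
  tibble::tibble(
    fiber = keep,
    row = as.numeric(rowsum(as.numeric(pos[, 1]), lab)[, 1]) / area[keep],
    col = as.numeric(rowsum(as.numeric(pos[, 2]), lab)[, 1]) / area[keep],
    area = area[keep]
  )
}

densify_labels <- function(labels, keep) {
  # keep: integer vector of surviving label ids; relabel to 1..length(keep)
  lut <- integer(max(labels, 1L))
  lut[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos]]
  out
}

#' Segment individual muscle fibers
#'
#' Instance segmentation of myofibers in a preprocessed autofluorescence
#' channel: Otsu foreground thresholding, then splitting of touching fibers
#' by watershed on the distance transform (fiber interiors become distance
#' peaks, boundaries become watershed lines), then removal of specks below
#' `min_area` and dense relabelling.
#'
#' @param auto Preprocessed autofluorescence channel (matrix in `[0, 1]`).
#' @param min_area Minimum fiber area in px^2; smaller labels are dropped.
#' @param tolerance Watershed tolerance (minimum object height in the
#'   distance map separating two fibers).
#' @param ext Watershed neighbourhood radius in pixels.
#'
#' @return A `fiber_map`: integer label matrix (0 = background, k = fiber k)
#'   plus a tibble of per-fiber centroids (`fiber`, `row`, `col`, `area`).
#'   A blank image yields a map with zero fibers, not an error.
#' @export
segment_fibers <- function(auto, min_area = 40, tolerance = 1, ext = 1) {
  stopifnot(is.matrix(auto))
  blank <- matrix(0L, nrow(auto), ncol(auto))
  if (max(auto) <= 0) return(new_fiber_map(blank, label_centroids(blank)))
  mask <- auto > EBImage::otsu(EBImage::Image(auto))
  if (!any(mask)) return(new_fiber_map(blank, label_centroids(blank)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(auto), ncol(auto))
  if (max(labels) == 0L) return(new_fiber_map(blank, label_centroids(blank)))
  area <- tabulate(labels[labels > 0L])
  keep <- which(area >= min_area)
  if (length(keep) == 0) return(new_fiber_map(blank, label_centroids(blank)))
  labels <- densify_labels(labels, keep)
  new_fiber_map(labels, label_centroids(labels))
}

#' Restrict a fiber map to the indented area
#'
#' Counting is performed in the region beneath and around the indenter. This
#' keeps only fibers whose centroid falls inside a disc of `radius` pixels
#' around `center`; with an infinite radius (the default when the indent
#' position is unknown) the map is returned unchanged.
#'
#' @param fibmap A `fiber_map` from [segment_fibers()].
#' @param center Numeric `c(row, col)` of the indentation centre, px.
#' @param radius Disc radius in px (> 0); `Inf` keeps everything.
#' @return A `fiber_map` containing the retained fibers, relabelled densely.
#' @export
restrict_to_indented_area <- function(fibmap, center, radius = Inf) {
  stopifnot(inherits(fibmap, "fiber_map"))
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be positive (use Inf for the whole section)",
         call. = FALSE)
  }
  if (is.infinite(radius)) return(fibmap)
  stopifnot(length(center) == 2)
  cen <- fibmap$centroids
  inside <- sqrt((cen$row - center[1])^2 + (cen$col - center[2])^2) <= radius
  keep <- cen$fiber[inside]
  if (length(keep) == 0) {
    blank <- matrix(0L, nrow(fibmap$labels), ncol(fibmap$labels))
    return(new_fiber_map(blank, label_centroids(blank)))
  }
  labels <- densify_labels(fibmap$labels, keep)
  new_fiber_map(labels, label_centroids(labels))
}

#' Count dye-positive fibers in a section
#'
#' A fiber is dye-positive (dead: its sarcolemma admitted the
#' membrane-impermeable dye) when its mean dye intensity strictly exceeds the
#' control-derived threshold.
#'
#' @param fibmap A `fiber_map` of the fibers to score.
#' @param dye Preprocessed dye channel, same shape as the label image.
#' @param threshold Intensity threshold from [control_intensity_threshold()].
#'
#' @return A one-row tibble: `n_positive`, `n_fibers`, `threshold_used`, and
#'   `positive_centroids` (list column holding a tibble of `row`, `col` for
#'   each positive fiber).
#' @export
score_dye_positive <- function(fibmap, dye, threshold) {
  stopifnot(inherits(fibmap, "fiber_map"), is.matrix(dye))
  if (!all(dim(fibmap$labels) == dim(dye))) {
    stop("label image and dye channel have different shapes", call. = FALSE)
  }
  cen <- fibmap$centroids
  if (nrow(cen) == 0) {
    return(tibble::tibble(n_positive = 0L, n_fibers = 0L,
                          threshold_used = threshold,
                          positive_centroids = list(
                            tibble::tibble(row = numeric(), col = numeric()))))
  }
  idx <- which(fibmap$labels > 0L)
  lab <- fibmap$labels[idx]
  mean_dye <- as.numeric(rowsum(dye[idx], lab)[, 1]) / cen$area
  pos <- mean_dye > threshold
  tibble::tibble(
    n_positive = sum(pos),
    n_fibers = nrow(cen),
    threshold_used = threshold,
    positive_centroids = list(cen[pos, c("row", "col")])
  )
}

#' Average dye-positive counts across a sample's sections
#'
#' Dead-fiber counts are made per cross-section and averaged across the
#' sample (six sections per sample in the reference protocol).
#'
#' @param sections Data frame with one row per section and a column
#'   `n_positive` (e.g. rows from [score_dye_positive()]).
#' @param expected_n Expected number of sections; a different number triggers
#'   a warning, not an error.
#' @return Mean dye-positive count (numeric scalar).
#' @export
quantify_sample <- function(sections, expected_n = 6) {
  stopifnot(is.data.frame(sections), "n_positive" %in% names(sections))
  if (nrow(sections) == 0) stop("no sections to average", call. = FALSE)
  if (nrow(sections) != expected_n) {
    warning(sprintf("sample has %d sections (expected %d)",
                    nrow(sections), expected_n), call. = FALSE)
  }
  mean(sections$n_positive)
}

#' Read and write two-channel section TIFFs
#'
#' Sections are stored as 2-page grayscale TIFFs (page 1 autofluorescence,
#' page 2 dye by default). Values are read as numeric matrices.
#'
#' @param path TIFF file path.
#' @param channel_order Character vector naming the pages, default
#'   `c("auto", "dye")`.
#' @return `read_section_tiff()`: named list of matrices. `write_section_tiff()`:
#'   the path, invisibly.
#' @export
read_section_tiff <- function(path, channel_order = c("auto", "dye")) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) < length(channel_order)) {
    stop("TIFF ", path, " has ", length(pages), " pages; need ",
         length(channel_order), call. = FALSE)
  }
  out <- lapply(pages[seq_along(channel_order)], function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  stats::setNames(out, channel_order)
}

#' @rdname read_section_tiff
#' @param channels Named list of matrices to write (values in `[0, 1]`).
#' @export
write_section_tiff <- function(channels, path,
                               channel_order = c("auto", "dye")) {
  stopifnot(all(channel_order %in% names(channels)))
  imgs <- lapply(channels[channel_order], function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}
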