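# independent closed-form OLS oracle (normal equations, no lm)
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b1 <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(b0 = yb - b1 * xb, b1 = b1)
}

# tiny hand-built fiber map: square blobs of side 5 centred at given points
toy_fiber_map <- function(centers, shape = c(60, 60)) {
  labels <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    r <- centers[k, 1]; c <- centers[k, 2]
    labels[(r - 2):(r + 2), (c - 2):(c + 2)] <- k
  }
  segment_from_labels(labels)
}

# rebuild a fiber_map object from a label matrix through the public surface:
# render the labels as a clean image and segment it is overkill here, so we
# reach the same structure via score-compatible fields computed by hand
segment_from_labels <- function(labels) {
  idx <- which(labels > 0L)
  lab <- labels[idx]
  pos <- arrayInd(idx, dim(labels))
  area <- tabulate(lab)
  keep <- which(area > 0)
  centroids <- tibble::tibble(
    fiber = keep,
    row = as.numeric(rowsum(as.numeric(pos[, 1]), lab)[, 1]) / area[keep],
    col = as.numeric(rowsum(as.numeric(pos[, 2]), lab)[, 1]) / area[keep],
    area = area[keep]
  )
  structure(list(labels = labels, centroids = centroids), class = "fiber_map")
}
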