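# Independent reference implementations used to freeze expected values.
# These deliberately share no code with the package internals they check.

# 3x3 (or k x k) convolution with replicate padding, plain loops
conv_oracle <- function(x, kernel) {
  k <- nrow(kernel)
  pad <- (k - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[clamp_idx(seq_len(nr + 2L * pad) - pad, nr),
          clamp_idx(seq_len(nc + 2L * pad) - pad, nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- sum(xp[i:(i + k - 1L), j:(j + k - 1L)] * kernel)
  }
  out
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

gaussian_kernel_oracle <- function(k, sigma) {
  if (sigma <= 0) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  i <- seq(-(k - 1) / 2, (k - 1) / 2)
  g <- exp(-i^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

# full edge-magnitude pipeline, loop-based: Lab lightness, Gaussian blur,
# Sobel x/y, combined magnitude on the fixed 0-255 scale
edge_magnitude_oracle <- function(pixels, blur_kernel = 5L, blur_sigma = 0,
                                  ...) {
  m <- matrix(as.double(pixels), ncol = 3L) / 255
  L <- matrix(grDevices::convertColor(m, from = "sRGB", to = "Lab")[, 1],
              dim(pixels)[1], dim(pixels)[2]) / 100
  Lb <- conv_oracle(L, gaussian_kernel_oracle(blur_kernel, blur_sigma))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv_oracle(Lb, sx)
  gy <- conv_oracle(Lb, t(sx))
  pmin(sqrt(gx^2 + gy^2) * 255 / 4, 255)
}

# 8-connected components by breadth-first flood fill; returns the bounding
# rectangles (0-based half-open), one row per component
floodfill_rects_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  rects <- list()
  for (sr in seq_len(nr)) for (sc in seq_len(nc)) {
    if (!mask[sr, sc] || seen[sr, sc]) next
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE
    rmin <- sr; rmax <- sr; cmin <- sc; cmax <- sc
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      rmin <- min(rmin, p[1]); rmax <- max(rmax, p[1])
      cmin <- min(cmin, p[2]); cmax <- max(cmax, p[2])
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    rects[[length(rects) + 1L]] <-
      data.frame(x0 = cmin - 1L, y0 = rmin - 1L, x1 = cmax, y1 = rmax)
  }
  if (!length(rects)) data.frame(x0 = integer(), y0 = integer(),
                                 x1 = integer(), y1 = integer())
  else do.call(rbind, rects)
}

# exhaustive maximum one-to-one matching: the largest number of pred/truth
# pairs with IoU >= threshold, by recursion over all assignments
max_matching_oracle <- function(pred, truth, iou_threshold) {
  rect_iou <- function(a, b) {
    ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
    iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
    inter <- ix * iy
    inter / ((a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter)
  }
  np <- nrow(pred); nt <- nrow(truth)
  ok <- matrix(FALSE, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt))
    ok[i, j] <- rect_iou(pred[i, ], truth[j, ]) >= iou_threshold
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > np) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used, count)                      # pred i unmatched
    for (j in seq_len(nt)) if (ok[i, j] && !used[j]) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
  }
  if (np > 0L) recurse(1L, logical(nt), 0L)
  best
}

# calendar validity from first principles: explicit day counts + leap rule
valid_date_oracle <- function(y, m, d) {
  if (m < 1 || m > 12 || d < 1) return(FALSE)
  leap <- (y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0
  days <- c(31, if (leap) 29 else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <= days[m]
}
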