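# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# windowed mean by explicit double loop, symmetric-reflection border
slow_window_mean <- function(img, size = 9L) {
  r <- (size - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  reflect <- function(i, len) {
    # symmetric half-sample reflection: ... 2 1 | 1 2 ... len | len len-1 ...
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > len, 2L * len + 1L - i, i)
  }
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ri <- reflect((i - r):(i + r), n)
      ci <- reflect((j - r):(j + r), m)
      out[i, j] <- mean(img[ri, ci])
    }
  }
  out
}

# exhaustive search over all candidate thresholds (unique observed values),
# minimizing the weighted within-class variance
slow_otsu <- function(img) {
  v <- sort(unique(as.vector(img)))
  best <- NULL
  best_wcv <- Inf
  for (t in v[-length(v)]) {
    lo <- img[img <= t]
    hi <- img[img > t]
    # population within-class variance, weighted by class size
    vlo <- if (length(lo) > 1) mean((lo - mean(lo))^2) else 0
    vhi <- if (length(hi) > 1) mean((hi - mean(hi))^2) else 0
    wcv <- (length(lo) * vlo + length(hi) * vhi) / length(img)
    if (wcv < best_wcv) {
      best_wcv <- wcv
      best <- t
    }
  }
  best
}

# shift-based binary dilation/erosion with an arbitrary 0/1 kernel
# (independent of EBImage)
slow_dilate <- function(mask, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  offs <- which(kern > 0, arr.ind = TRUE) - (r + 1L)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    sr <- max(1L, 1L - dr):min(n, n - dr)
    sc <- max(1L, 1L - dc):min(m, m - dc)
    out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
  }
  out
}

slow_erode <- function(mask, kern) {
  !slow_dilate(!mask, kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern)))])
}

slow_close_open <- function(mask, kern) {
  closed <- slow_erode(slow_dilate(mask, kern), kern)
  slow_dilate(slow_erode(closed, kern), kern)
}

# Spearman rho: mid-ranks computed by hand, then the Pearson formula by hand
slow_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random connected blob: union of a dilated random walk (independent of the
# package's shape generators)
random_connected_mask <- function(n_steps = 40L, side = 48L, dilate_r = 2L) {
  pos <- matrix(c(side %/% 2L, side %/% 2L), 1L)
  for (s in seq_len(n_steps)) {
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    nxt <- pmin(pmax(pos[nrow(pos), ] + step, dilate_r + 2L),
                side - dilate_r - 1L)
    pos <- rbind(pos, nxt)
  }
  m <- matrix(FALSE, side, side)
  m[pos] <- TRUE
  kern <- outer(seq(-dilate_r, dilate_r)^2, seq(-dilate_r, dilate_r)^2,
                `+`) <= dilate_r^2
  slow_dilate(m, kern)
}

# rasterize a disk/ellipse directly (for morphometry reference shapes)
raster_disk_ref <- function(r, side = 2L * ceiling(r) + 5L) {
  ctr <- (side + 1) / 2
  d <- seq_len(side)
  outer(d, d, function(i, j) (i - ctr)^2 + (j - ctr)^2) <= r^2
}

raster_ellipse_ref <- function(a, b, theta = 0) {
  side <- 2L * ceiling(max(a, b)) + 5L
  ctr <- (side + 1) / 2
  d <- seq_len(side)
  xx <- outer(d, d, function(i, j) j - ctr)
  yy <- outer(d, d, function(i, j) i - ctr)
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
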