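# Independent reference implementations used as oracles. These are written
# naively (exhaustive search, direct convolution, breadth-first flood fill)
# and share no code with the package internals.

random_image <- function(h, w) matrix(sample(0:255, h * w, replace = TRUE), h, w)

random_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# exhaustive Otsu: evaluate between-class variance at every candidate
# threshold from explicit class means over the floored pixel population
oracle_otsu <- function(image, floor = 0L) {
  v <- as.integer(image)
  kept <- v[v >= floor]
  if (length(kept) == 0 || length(unique(kept)) < 2) {
    return(list(threshold = 255L, mask = matrix(0L, nrow(image), ncol(image))))
  }
  best_t <- NA_integer_; best_s <- -1
  for (t in 0:255) {
    c0 <- kept[kept <= t]; c1 <- kept[kept > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(kept); w1 <- 1 - w0
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  mask <- matrix(as.integer(image > best_t & image >= floor),
                 nrow(image), ncol(image))
  list(threshold = as.integer(max(best_t, floor)), mask = mask)
}

# direct per-pixel Gaussian-weighted local mean with reflect-101 borders;
# exact ties resolve to background via the same 1e-9 guard as the operator
oracle_adaptive <- function(image, block_size, c_offset) {
  sigma <- 0.3 * ((block_size - 1) * 0.5 - 1) + 0.8
  x <- seq_len(block_size) - 1 - (block_size - 1) / 2
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  K <- outer(g, g)
  r <- (block_size - 1) / 2
  n <- nrow(image); m <- ncol(image)
  refl <- function(i, nn) {
    per <- 2 * (nn - 1)
    k <- (i - 1) %% per
    ifelse(k >= nn, per - k, k) + 1
  }
  mask <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    ri <- refl((i - r):(i + r), n)
    for (j in seq_len(m)) {
      cj <- refl((j - r):(j + r), m)
      T <- sum(K * image[ri, cj]) - c_offset
      mask[i, j] <- as.integer(image[i, j] - T > 1e-9)
    }
  }
  mask
}

# breadth-first flood fill labeling
oracle_label <- function(mask, connectivity = 8L) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nb <- if (connectivity == 8L) {
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  }
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% n + 1L; pc <- (p - 1L) %/% n + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- pr + nb[k, 1]; c2 <- pc + nb[k, 2]
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m &&
            mask[r2, c2] != 0 && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- c(queue, (c2 - 1L) * n + r2)
        }
      }
    }
  }
  lab
}

# TRUE iff two label maps describe the same partition (up to renaming)
labels_equivalent <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# count distinct colors of an RGB png file
distinct_png_colors <- function(path) {
  arr <- png::readPNG(path)
  length(unique(paste(arr[, , 1], arr[, , 2], arr[, , 3])))
}
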