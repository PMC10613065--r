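# Independent brute-force oracles used across the suite.

# sliding-window median with replicate padding
oracle_median <- function(m, k) {
  r <- (k - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- pmin(pmax((i - r):(i + r), 1), nrow(m))
    jj <- pmin(pmax((j - r):(j + r), 1), ncol(m))
    out[i, j] <- stats::median(m[ii, jj])
  }
  out
}

# set-operation morphology on a logical mask (outside raster = background)
oracle_dilate <- function(mask, brush) {
  r <- (nrow(brush) - 1) / 2
  out <- mask & FALSE
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    acc <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      if (brush[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
          mask[ii, jj]) { acc <- TRUE; break }
    }
    out[i, j] <- acc
  }
  out
}

oracle_erode <- function(mask, brush) {
  r <- (nrow(brush) - 1) / 2
  out <- mask & FALSE
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    acc <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (brush[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      inside <- ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask)
      if (inside && !mask[ii, jj]) { acc <- FALSE; break }
    }
    out[i, j] <- acc
  }
  out
}

# exhaustive nearest-background-pixel Euclidean distance
oracle_distmap <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  if (!nrow(fg) || !nrow(bg)) return(out)
  step <- 2000
  for (s in seq(1, nrow(fg), by = step)) {
    blk <- fg[s:min(s + step - 1, nrow(fg)), , drop = FALSE]
    d2 <- outer(blk[, 1], bg[, 1], "-")^2 + outer(blk[, 2], bg[, 2], "-")^2
    out[blk] <- sqrt(apply(d2, 1, min))
  }
  out
}

# exhaustive contiguous-split optimum for 1-D 2-means (direct sums)
oracle_split_cost <- function(x) {
  xs <- sort(x); n <- length(xs)
  best <- Inf; bestk <- NA
  for (k in 1:(n - 1)) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    cost <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (cost < best) { best <- cost; bestk <- k }
  }
  list(cost = best, k = bestk, cut = sort(x)[bestk])
}

# full 2-partition enumeration (any assignment, not just contiguous)
oracle_partition_cost <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- x[g]; b <- x[!g]
    cost <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (cost < best) best <- cost
  }
  best
}

# term-by-term transcriptions of the accuracy statistics
oracle_r2 <- function(m, e) {
  num <- 0; den <- 0; mb <- sum(m) / length(m)
  for (j in seq_along(m)) {
    num <- num + (m[j] - e[j])^2
    den <- den + (m[j] - mb)^2
  }
  1 - num / den
}
oracle_rmse <- function(m, e) {
  s <- 0
  for (j in seq_along(m)) s <- s + (m[j] - e[j])^2
  sqrt(s / length(m))
}
oracle_mape <- function(m, e) {
  s <- 0
  for (j in seq_along(m)) s <- s + abs(e[j] - m[j]) / m[j]
  s / length(m)
}

# cluster-based dark-pixel count the way the pipeline defines it, but
# computed straight from a gray vector (for cross-checks)
match_regions_to_manifest <- function(phenotypes, manifest) {
  vapply(seq_len(nrow(phenotypes)), function(i) {
    which.min((manifest$cx - phenotypes$centroid_x[i])^2 +
                (manifest$cy - phenotypes$centroid_y[i])^2)
  }, integer(1))
}
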