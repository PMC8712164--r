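# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive loops / direct formulas, not
# the package's vectorised implementations.

rand_img <- function(nr, nc, seed, max_val = 255) {
  set.seed(seed)
  matrix(sample(0:max_val, nr * nc, replace = TRUE), nr, nc)
}

# median filter oracle: per-pixel apply() over replicate-padded image
median3_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- stats::median(p[r:(r + 2), c:(c + 2)])
  out
}

# GLCM feature oracles: naive double loops over the matrix
contrast_oracle <- function(A) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + ((i - 1) - (j - 1))^2 * A[i, j]
  s
}
homogeneity_oracle <- function(A) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + A[i, j] / (1 + abs((i - 1) - (j - 1)))
  s
}
correlation_oracle <- function(A) {
  lv <- seq_len(nrow(A)) - 1
  pi_ <- rowSums(A); pj <- colSums(A)
  mi <- sum(lv * pi_); mj <- sum(lv * pj)
  si <- sqrt(sum((lv - mi)^2 * pi_)); sj <- sqrt(sum((lv - mj)^2 * pj))
  s <- 0
  for (i in seq_along(lv)) for (j in seq_along(lv))
    s <- s + (lv[i] - mi) * (lv[j] - mj) * A[i, j]
  s / (si * sj)
}

# random normalized GLCM
rand_glcm <- function(ng, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(ng * ng), ng, ng)
  A <- A + t(A)
  A / sum(A)
}

# Gini oracle: normalized mean absolute pairwise difference
gini_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
}

# Shannon entropy oracle over integer-valued vector
entropy_oracle <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

# connected-component bounding box oracle: brute-force BFS, 8-connectivity
largest_component_bbox_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  best <- NULL; best_n <- -1
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    members <- matrix(0L, 0, 2)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- rbind(members, p)
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    n <- nrow(members)
    bb <- c(min(members[, 1]), max(members[, 1]),
            min(members[, 2]), max(members[, 2]))
    if (n > best_n ||
        (n == best_n && (bb[1] < best[1] ||
                         (bb[1] == best[1] && bb[3] < best[3])))) {
      best_n <- n; best <- bb
    }
  }
  list(bbox = best, size = best_n)  # bbox is 1-based inclusive
}
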