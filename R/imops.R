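# Low-level matrix image operations shared across modules. All operate on
# plain numeric matrices (rows = y, cols = x), 0-based geometry handled by
# callers.

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  m[ri, ci, drop = FALSE]
}

# The 3x3 neighborhood of every pixel as a list of 9 same-shaped matrices
# (replicate border). Order: (dr, dc) over {-1,0,1} x {-1,0,1}, row-major.
shift_stack_3x3 <- function(m) {
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    out[[k]] <- p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc),
                  drop = FALSE]
  }
  out
}

# Elementwise median across a list of matrices via an odd-even transposition
# sorting network (fully vectorised; no per-pixel apply()).
stack_median <- function(lanes) {
  n <- length(lanes)
  for (pass in seq_len(n)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    i <- start
    while (i + 1L <= n) {
      lo <- pmin(lanes[[i]], lanes[[i + 1L]])
      hi <- pmax(lanes[[i]], lanes[[i + 1L]])
      lanes[[i]] <- lo; lanes[[i + 1L]] <- hi
      i <- i + 2L
    }
  }
  if (n %% 2L == 1L) lanes[[(n + 1L) %/% 2L]]
  else (lanes[[n %/% 2L]] + lanes[[n %/% 2L + 1L]]) / 2
}

# Separable Gaussian blur with replicate borders; kernel radius 3*sigma.
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # vertical pass
  v <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k))
    v <- v + k[i] * p[(i):(nr + i - 1L), , drop = FALSE]
  # horizontal pass
  h <- matrix(0, nr, nc)
  for (i in seq_along(k))
    h <- h + k[i] * v[, (i):(nc + i - 1L), drop = FALSE]
  h
}

# 3x3 correlation with replicate borders. `kern` is a 3x3 matrix laid out as
# kern[dr+2, dc+2]; output[y,x] = sum kern * m[y+dr, x+dc].
conv3 <- function(m, kern) {
  st <- shift_stack_3x3(m)
  out <- matrix(0, nrow(m), ncol(m))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    w <- kern[dr + 2L, dc + 2L]
    if (w != 0) out <- out + w * st[[k]]
  }
  out
}

# Bilinear resize to out_nr x out_nc. Output pixel centers map to input
# coordinates via src = (dst + 0.5) * scale - 0.5 (edge clamped).
resize_bilinear <- function(m, out_nr, out_nc) {
  nr <- nrow(m); nc <- ncol(m)
  map <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    s <- pmin(pmax(s, 1), n_in)
    lo <- pmin(floor(s), n_in - 1L)
    if (n_in == 1L) lo <- rep(1, n_out)
    list(lo = as.integer(lo),
         hi = as.integer(pmin(lo + 1L, n_in)),
         w  = s - lo)
  }
  ry <- map(out_nr, nr); rx <- map(out_nc, nc)
  m_top <- m[ry$lo, , drop = FALSE]; m_bot <- m[ry$hi, , drop = FALSE]
  mv <- m_top * (1 - ry$w) + m_bot * ry$w
  mv[, rx$lo, drop = FALSE] * rep(1 - rx$w, each = out_nr) +
    mv[, rx$hi, drop = FALSE] * rep(rx$w, each = out_nr)
}

# Rotate a matrix by `deg` degrees (counter-clockwise about the image
# center), nearest-neighbor sampling. Output canvas expands to contain the
# rotated rectangle; pixels with no source (the padding frame) are NA so
# histogram-based consumers can exclude them.
rotate_nn <- function(m, deg) {
  th <- deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cth <- cos(th); sth <- sin(th)
  out_nr <- ceiling(abs(nr * cth) + abs(nc * sth))
  out_nc <- ceiling(abs(nc * cth) + abs(nr * sth))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  oy <- (out_nr + 1) / 2; ox <- (out_nc + 1) / 2
  # inverse map: for each output pixel, rotate back into source coords
  yy <- matrix(seq_len(out_nr) - oy, out_nr, out_nc)
  xx <- matrix(seq_len(out_nc) - ox, out_nr, out_nc, byrow = TRUE)
  sy <- round(cth * yy + sth * xx + cy)
  sx <- round(-sth * yy + cth * xx + cx)
  ok <- sy >= 1 & sy <= nr & sx >= 1 & sx <= nc
  out <- matrix(NA_real_, out_nr, out_nc)
  out[ok] <- m[cbind(sy[ok], sx[ok])]
  out
}

# 8-connected component labelling of a logical mask by row-run union-find.
# Returns an integer matrix (0 = background, components numbered from 1 in
# raster order of their first run).
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  row_runs <- vector("list", nr)
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) { row_runs[[r]] <- integer(0); next }
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    ids <- length(run_row) + seq_len(sum(keep))
    run_row <- c(run_row, rep(r, sum(keep)))
    run_s <- c(run_s, starts[keep]); run_e <- c(run_e, ends[keep])
    row_runs[[r]] <- ids
  }
  n <- length(run_row)
  if (n == 0L) return(matrix(0L, nr, nc))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in 2:nr) {
    if (r > nr) break
    a <- row_runs[[r - 1L]]; b <- row_runs[[r]]
    if (!length(a) || !length(b)) next
    for (i in b) for (j in a) {
      # 8-connectivity: runs touch if column ranges overlap when one is
      # widened by a single pixel on each side
      if (run_s[i] <= run_e[j] + 1L && run_e[i] >= run_s[j] - 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab_of_root <- integer(n)
  lab_of_root[unique(roots)] <- seq_along(unique(roots))
  labs <- lab_of_root[roots]
  out <- matrix(0L, nr, nc)
  for (i in seq_len(n))
    out[run_row[i], run_s[i]:run_e[i]] <- labs[i]
  out
}

clip255 <- function(m) pmin(pmax(m, 0), 255)
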