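# Independent reference implementations used to cross-check the package.
# These are written as literal, loop-based transcriptions of the rules and
# share no code with the implementation under test.

# --- Y-threshold rule chain, bin by bin ------------------------------------

oracle_smooth <- function(h, window = 25) {
  half <- (window - 1) %/% 2
  n <- length(h)
  s <- numeric(n)
  for (i in 0:(n - 1)) {
    acc <- 0
    for (j in (i - half):(i + half)) {
      idx <- j
      if (idx < 0) idx <- -idx - 1          # symmetric reflection
      if (idx > n - 1) idx <- 2 * n - 1 - idx
      acc <- acc + h[idx + 1]
    }
    s[i + 1] <- acc / window
  }
  s
}

oracle_peaks <- function(s) {
  n <- length(s)
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (j == n) -Inf else s[j + 1]
    if (left < s[i] && right < s[i]) peaks <- c(peaks, i - 1L)
    i <- j + 1
  }
  peaks
}

oracle_y_threshold <- function(vals, window = 25, min_sep = 30,
                               valley_frac = 0.10) {
  h <- numeric(256)
  for (v in as.integer(vals)) h[v + 1] <- h[v + 1] + 1
  s <- oracle_smooth(h, window)
  if (sum(s[1:10]) > sum(s[101:256]))
    return(list(status = "dark", threshold = 10L))
  peaks <- oracle_peaks(s)
  if (length(peaks) >= 2) {
    kept <- peaks[1]
    for (p in peaks[-1]) {
      last <- kept[length(kept)]
      if (p - last < min_sep) {
        if (s[p + 1] > s[last + 1]) kept[length(kept)] <- p
      } else kept <- c(kept, p)
    }
    peaks <- kept
  }
  if (length(peaks) < 2) return(list(status = "discarded", threshold = NA_integer_))
  p1 <- peaks[1]; p2 <- peaks[2]
  if (p2 - p1 < 2) return(list(status = "valid", threshold = as.integer(p1)))
  # scan from just below the second peak toward the first for the first
  # qualifying valley bin
  for (b in (p2 - 1):(p1 + 1)) {
    if (s[b + 1] < valley_frac * s[p2 + 1])
      return(list(status = "valid", threshold = as.integer(b)))
  }
  best <- p1 + 1
  for (b in (p1 + 1):(p2 - 1)) if (s[b + 1] < s[best + 1]) best <- b
  list(status = "valid", threshold = as.integer(best))
}

# Random 8-bit value sets whose histograms exercise the dark, unimodal and
# multi-peak branches.
random_hist_values <- function(seed) {
  set.seed(seed)
  kind <- sample(1:4, 1)
  n <- sample(2000:20000, 1)
  if (kind == 1) {          # dark-heavy
    v <- c(sample(0:9, round(n * 0.6), TRUE),
           sample(100:255, n - round(n * 0.6), TRUE))
  } else if (kind == 2) {   # single broad mode
    v <- round(stats::rnorm(n, stats::runif(1, 60, 200), stats::runif(1, 10, 40)))
  } else if (kind == 3) {   # two modes
    m <- sort(sample(10:245, 2))
    v <- c(round(stats::rnorm(n * 0.3, m[1], stats::runif(1, 3, 20))),
           round(stats::rnorm(n * 0.7, m[2], stats::runif(1, 3, 20))))
  } else {                  # several narrow modes
    k <- sample(3:5, 1)
    m <- sample(0:255, k)
    v <- unlist(lapply(m, function(mu)
      round(stats::rnorm(n / k, mu, stats::runif(1, 2, 10)))))
  }
  pmin(pmax(round(v), 0), 255)
}

# --- convex hull / solidity ------------------------------------------------

# Gift-wrapping (Jarvis march) convex hull of points (x, y).
oracle_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-7)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull did not close")
  }
  pts[hull, , drop = FALSE]
}

# Solidity by lattice-point counting inside the gift-wrapped hull.
oracle_solidity <- function(rs, cs) {
  area <- length(rs)
  pts <- unique(cbind(cs, rs))
  if (nrow(pts) <= 2 || nrow(unique(oracle_hull(cs, rs))) <= 2) {
    # collinear: hull is a segment
    o <- order(pts[, 1], pts[, 2])
    v <- pts[o[nrow(pts)], ] - pts[o[1], ]
    g <- if (all(v == 0)) 0 else {
      a <- abs(v[1]); b <- abs(v[2])
      while (b > 0) { t <- a %% b; a <- b; b <- t }
      a
    }
    return(area / max(g + 1, area))
  }
  hull <- oracle_hull(cs, rs)
  cand_x <- min(cs):max(cs)
  cand_y <- min(rs):max(rs)
  grid <- expand.grid(x = cand_x, y = cand_y)
  inside <- pracma::inpolygon(grid$x, grid$y, hull[, 1], hull[, 2],
                              boundary = TRUE)
  area / max(sum(inside), area)
}

# All fixed polyominoes with up to n cells, as lists of (row, col) matrices
# normalized to min row/col = 0.
enumerate_polyominoes <- function(max_cells) {
  norm_key <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    o <- order(cells[, 1], cells[, 2])
    paste(cells[o, 1], cells[o, 2], sep = ",", collapse = ";")
  }
  normalize <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  }
  out <- list()
  current <- list(matrix(c(0L, 0L), 1, 2))
  seen <- new.env(hash = TRUE)
  assign(norm_key(current[[1]]), TRUE, envir = seen)
  out[[1]] <- current
  for (n in seq_len(max_cells - 1)) {
    nxt <- list()
    for (poly in current) {
      for (i in seq_len(nrow(poly))) {
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          cell <- poly[i, ] + d
          if (any(poly[, 1] == cell[1] & poly[, 2] == cell[2])) next
          cand <- normalize(rbind(poly, cell))
          key <- norm_key(cand)
          if (!exists(key, envir = seen)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1]] <- cand
          }
        }
      }
    }
    out[[n + 1]] <- nxt
    current <- nxt
  }
  unlist(out, recursive = FALSE)
}

poly_to_mask <- function(cells, pad = 1) {
  m <- matrix(FALSE, max(cells[, 1]) + 1 + 2 * pad, max(cells[, 2]) + 1 + 2 * pad)
  m[cbind(cells[, 1] + 1 + pad, cells[, 2] + 1 + pad)] <- TRUE
  m
}

# --- mask fusion set algebra ------------------------------------------------

# Flood-fill component restore: keep a Y pixel iff it is 8-connected within
# Y to a pixel also set in M.
oracle_restore <- function(y, m) {
  H <- nrow(y); W <- ncol(y)
  keep <- matrix(FALSE, H, W)
  seeds <- which(y & m)
  queue <- seeds
  keep[seeds] <- TRUE
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        q <- (cc - 1) * H + rr
        if (y[q] && !keep[q]) { keep[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  keep
}

random_mask <- function(seed, H = 8, W = 8, p = 0.4) {
  set.seed(seed)
  matrix(stats::runif(H * W) < p, H, W)
}

# Build a mask_set object directly from six matrices (for fusion tests).
make_mask_set <- function(C, M, YT, YT2, YT4, custom) {
  structure(list(mask_C = C, mask_M = M, mask_Y_T = YT, mask_Y_T2 = YT2,
                 mask_Y_T4 = YT4, mask_custom = custom,
                 global_Y_threshold = NA_integer_, y_valid = TRUE,
                 all_inactive = FALSE, quadrants = list()),
            class = "mask_set")
}

# --- misc -------------------------------------------------------------------

# Uniform-color image array.
uniform_image <- function(H, W, rgb) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  px
}
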