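# Independent reference implementations ("oracles") used to cross-check the
# package's optimized numerics. Each oracle is written from the mathematical
# definition with no shared code with the implementation under test.

# Brute-force zero-mean NCC of a template at every fully contained placement.
ncc_oracle <- function(image, template) {
  h <- nrow(template); w <- ncol(template)
  out <- matrix(0, nrow(image) - h + 1L, ncol(image) - w + 1L)
  tv <- as.numeric(template)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      win <- as.numeric(image[i:(i + h - 1L), j:(j + w - 1L)])
      if (sd(win) < 1e-12 || sd(tv) < 1e-12) next
      out[i, j] <- cor(win, tv)
    }
  }
  out
}

# Exhaustive minimum-cost boundary path with |row step| <= 1 per column.
# Cost definition mirrors the documented graph: edge weight between
# horizontally adjacent nodes a, b is 2 - (g_a + g_b) + w_min, plus virtual
# entry/exit padding edges (pad nodes have g = 1).
dp_oracle <- function(g, w_min = 1e-5) {
  H <- nrow(g); W <- ncol(g)
  best_cost <- Inf; best_path <- NULL
  paths <- list(as.list(seq_len(H)))
  recurse <- function(path, cost) {
    c0 <- length(path)
    r0 <- path[c0]
    if (c0 == W) {
      total <- cost + 1 + w_min - g[r0, W]
      if (total < best_cost) {
        best_cost <<- total
        best_path <<- path
      }
      return(invisible())
    }
    for (dr in -1:1) {
      r1 <- r0 + dr
      if (r1 < 1 || r1 > H) next
      recurse(c(path, r1), cost + 2 + w_min - g[r0, c0] - g[r1, c0 + 1])
    }
  }
  for (r in seq_len(H)) recurse(r, 1 + w_min - g[r, 1])
  list(path = best_path, cost = best_cost)
}

# Closed-form circle-circle intersection ("lens") area.
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                      (d + r1 + r2))
  a1 + a2 - tri
}

# Naive moving-window sample standard deviation with reflected borders.
std_filter_oracle <- function(frame, window) {
  h <- window %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  reflect <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ri <- reflect((i - h):(i + h), H)
      rj <- reflect((j - h):(j + h), W)
      out[i, j] <- sd(frame[ri, rj])
    }
  }
  out
}
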