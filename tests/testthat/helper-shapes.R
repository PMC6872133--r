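# Geometric fixtures built in code, plus small independent oracles.

# closed polygon sampled at uniform parameter values
unit_circle <- function(P = 500L, start = 0) {
  u <- 2 * pi * (0:(P - 1L)) / P + start
  structure(list(points = cbind(x = cos(u), y = sin(u)),
                 base_index = 1L, view = "front", P = P),
            class = c("resampled_contour", "contour"))
}

ellipse_uniform <- function(a = 2, b = 1, P = 500L, rot = 0, start = 0) {
  u <- 2 * pi * (0:(P - 1L)) / P + start
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2L, 2L)
  structure(list(points = cbind(a * cos(u), b * sin(u)) %*% R,
                 base_index = 1L, view = "front", P = P),
            class = c("resampled_contour", "contour"))
}

# smooth random blob, resampled to equal arc spacing
random_blob <- function(seed, P = 500L, n_theta = 600L, elong = 0.1) {
  set.seed(seed)
  th <- 2 * pi * (0:(n_theta - 1L)) / n_theta
  r <- 1 + elong * cos(2 * th + stats::runif(1, 0, 2 * pi)) +
    0.06 * cos(3 * th + stats::runif(1, 0, 2 * pi)) +
    0.03 * sin(4 * th + stats::runif(1, 0, 2 * pi))
  resample(contour(cbind(r * cos(th), r * sin(th)), 1L), P)
}

# elongated seed with an indentation at the top, base landmark in the dent,
# with mildly asymmetric per-seed noise (the Fig-5-style averaging fixture)
dented_seed <- function(seed, P = 400L, depth = 0.25) {
  set.seed(900 + seed)
  th <- 2 * pi * (0:599) / 600 + pi / 2
  a <- 1.5 * exp(stats::rnorm(1, 0, 0.02)); b <- exp(stats::rnorm(1, 0, 0.02))
  r <- (abs(cos(th) / a)^2.5 + abs(sin(th) / b)^2.5)^(-1 / 2.5)
  ang <- atan2(sin(th - pi / 2), cos(th - pi / 2))
  r <- r * (1 - depth * exp(-0.5 * (ang / 0.3)^2))
  for (k in 2:6)
    r <- r * (1 + stats::rnorm(1, 0, 0.02 / k) * cos(k * th) +
                stats::rnorm(1, 0, 0.02 / k) * sin(k * th))
  resample(contour(cbind(r * cos(th), r * sin(th)), 1L), P)
}

rot_mat <- function(theta) matrix(c(cos(theta), -sin(theta),
                                    sin(theta), cos(theta)), 2L, 2L)

# radial indentation depth of an averaged point set
dent_depth_metric <- function(pts) {
  r <- sqrt(rowSums(pts^2))
  1 - min(r) / stats::median(r)
}

# independent flood-fill (BFS, 8-connected) component counter
flood_fill_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comp <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    comp <- comp + 1L
    queue <- matrix(c(r0, c0), 1L)
    seen[r0, c0] <- TRUE
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1L] + dr; cc <- cur[2L] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  comp
}

# trapezoid-quadrature oracle for elliptic Fourier coefficients of the
# piecewise-linear path through `pts`, harmonics `ns`
efd_quadrature_oracle <- function(pts, ns, n_samples = 1e5) {
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  tt <- c(0, cumsum(seg)); TT <- tt[length(tt)]
  s <- seq(0, TT, length.out = n_samples + 1L)
  x <- stats::approx(tt, closed[, 1L], xout = s)$y
  y <- stats::approx(tt, closed[, 2L], xout = s)$y
  trap <- function(f) {
    (sum(f) - (f[1L] + f[length(f)]) / 2) * (TT / n_samples)
  }
  out <- matrix(0, length(ns), 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (i in seq_along(ns)) {
    n <- ns[i]
    co <- cos(2 * pi * n * s / TT); si <- sin(2 * pi * n * s / TT)
    out[i, ] <- (2 / TT) * c(trap(x * co), trap(x * si),
                             trap(y * co), trap(y * si))
  }
  out
}
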