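# Contour containers and the acquisition chain: Freeman chain codes,
# Moore boundary tracing, arc-length resampling, size/ratio measurements.
#
# Coordinate convention throughout: x to the right, y up, 0-based pixel
# indexing with pixel centers at integer coordinates.  Image matrices are
# stored [row, col] with row 1 at the top; `px_xy()` converts.

#' Construct a contour
#'
#' A contour is an ordered, closed sequence of 2D points with a marked base
#' landmark (the point where the seed was attached to the parent plant) and a
#' view label. The closing edge from the last point back to the first is
#' implicit: the first point is not repeated.
#'
#' @param points numeric matrix with two columns (x, y), at least 8 rows.
#' @param base_index index of the base landmark within `points`.
#' @param view `"front"` or `"side"`.
#' @return An object of class `contour`.
#' @export
contour <- function(points, base_index = 1L, view = c("front", "side")) {
  view <- match.arg(view)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 8L) stop("a contour needs at least 8 points")
  if (base_index < 1L || base_index > n) stop("`base_index` out of range")
  dup <- rowSums((points - points[c(2:n, 1L), , drop = FALSE])^2) == 0
  if (any(dup)) stop("contour has duplicated consecutive points")
  structure(list(points = points, base_index = as.integer(base_index),
                 view = view),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, %s view, base landmark at index %d\n",
              nrow(x$points), x$view, x$base_index))
  invisible(x)
}

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise contours in the x-right / y-up convention.
#'
#' @param points two-column coordinate matrix of a closed polygon
#'   (closing vertex not repeated).
#' @return Signed area.
#' @export
signed_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Freeman 8-direction steps, code 0 = east, counter-clockwise.
.freeman_steps <- matrix(c(1, 0, 1, 1, 0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1),
                         ncol = 2L, byrow = TRUE)

#' Encode a pixel path as Freeman chain codes
#'
#' Each consecutive pair of points must differ by a king move (both
#' coordinate differences in -1/0/1, not both zero). The closing step from
#' the last point back to the first is included, so the code vector has as
#' many entries as the path has points.
#'
#' @param points integer-valued coordinate matrix (x, y).
#' @return Integer vector of chain codes in 0..7.
#' @export
freeman_encode <- function(points) {
  n <- nrow(points)
  nxt <- points[c(2:n, 1L), , drop = FALSE]
  d <- nxt - points
  if (any(abs(d) > 1) || any(d[, 1L] == 0 & d[, 2L] == 0))
    stop("consecutive points must differ by one king move")
  code <- integer(n)
  for (k in 0:7) {
    hit <- d[, 1L] == .freeman_steps[k + 1L, 1L] &
           d[, 2L] == .freeman_steps[k + 1L, 2L]
    code[hit] <- k
  }
  code
}

#' Decode Freeman chain codes to a pixel path
#'
#' @param codes integer vector of chain codes in 0..7.
#' @param start numeric length-2 starting coordinate.
#' @return Coordinate matrix with `length(codes)` rows (the final closing
#'   step is not emitted as a duplicate of the start).
#' @export
freeman_decode <- function(codes, start = c(0, 0)) {
  if (any(codes < 0 | codes > 7)) stop("chain codes must be in 0..7")
  dx <- .freeman_steps[codes + 1L, 1L]
  dy <- .freeman_steps[codes + 1L, 2L]
  cbind(x = start[1L] + c(0, cumsum(dx[-length(dx)])),
        y = start[2L] + c(0, cumsum(dy[-length(dy)])))
}

# mask[row, col] (row 1 = top) -> pixel-center coordinates, x right, y up.
px_xy <- function(row, col, nrow_mask) cbind(x = col - 1, y = nrow_mask - row)
xy_px <- function(x, y, nrow_mask) cbind(row = nrow_mask - round(y), col = round(x) + 1)

#' Trace the boundary of a binary mask
#'
#' Moore neighbour tracing of the single foreground component, recorded
#' internally as eight-direction Freeman chain codes and decoded back to
#' pixel coordinates. The trace is forced counter-clockwise (signed area
#' \eqn{> 0}) and rotated so the vertex nearest `base_landmark` comes first.
#'
#' @param img a [binary_image] (or logical matrix) containing one cleaned
#'   foreground component.
#' @param base_landmark length-2 (x, y) coordinate of the base landmark; must
#'   lie within 3 px of the traced boundary.
#' @param view view label passed to [contour()].
#' @return A [contour] whose `chain` attribute carries the emitted Freeman
#'   codes (matching the returned point order).
#' @export
trace_contour <- function(img, base_landmark, view = c("front", "side")) {
  view <- match.arg(view)
  mask <- if (inherits(img, "binary_image")) img$mask else img
  if (!is.matrix(mask)) stop("`img` must be a binary_image or logical matrix")
  mask <- mask != 0
  if (!any(mask)) stop("no seed found")
  nr <- nrow(mask); nc <- ncol(mask)
  # pad so neighbour lookups never fall off the grid
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # start: first foreground pixel in row-major scan order; its west and
  # north neighbours are then guaranteed background
  idx <- which(pad, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  start <- unname(idx[ord[1L], ])
  # Moore neighbourhood in clockwise order on the matrix (row downwards),
  # starting west: W, NW, N, NE, E, SE, S, SW as (drow, dcol)
  off <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                ncol = 2L, byrow = TRUE)
  off_index <- function(d) which(off[, 1L] == d[1L] & off[, 2L] == d[2L])
  path <- matrix(0L, nrow = 8L * sum(mask) + 8L, ncol = 2L)
  np <- 0L
  cur <- start
  bidx <- 1L          # entered the start from its west neighbour
  second <- NULL
  repeat {
    np <- np + 1L
    if (np > nrow(path)) stop("boundary trace exceeded bound; is the mask a single component?")
    path[np, ] <- cur
    found <- FALSE
    for (s in 1:8) {                 # clockwise from just after the backtrack
      k <- ((bidx - 1L + s) %% 8L) + 1L
      cand <- cur + off[k, ]
      if (pad[cand[1L], cand[2L]]) {
        kprev <- ((k - 2L) %% 8L) + 1L
        newb <- cur + off[kprev, ]   # background pixel examined just before
        found <- TRUE
        break
      }
    }
    if (!found) break                # isolated single pixel
    # stop when the trace is about to repeat its first move (start -> second)
    if (np > 1L && all(cur == start) && all(cand == second)) break
    if (np == 1L) second <- cand
    bidx <- off_index(newb - cand)
    cur <- cand
  }
  path <- path[seq_len(np), , drop = FALSE]
  pts <- px_xy(path[, 1L] - 1L, path[, 2L] - 1L, nr)
  # drop a degenerate duplicate closing vertex, if any
  if (nrow(pts) >= 2L && all(pts[nrow(pts), ] == pts[1L, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) >= 3L && signed_area(pts) < 0)
    pts <- pts[c(1L, nrow(pts):2), , drop = FALSE]
  d2 <- (pts[, 1L] - base_landmark[1L])^2 + (pts[, 2L] - base_landmark[2L])^2
  if (min(d2) > 9) stop("landmark off contour")
  i0 <- which.min(d2)
  pts <- pts[c(i0:nrow(pts), seq_len(i0 - 1L)), , drop = FALSE]
  out <- if (nrow(pts) >= 8L) contour(pts, 1L, view) else
    structure(list(points = pts, base_index = 1L, view = view), class = "contour")
  attr(out, "chain") <- freeman_encode(pts)
  out
}

#' Resample a contour to equally spaced points
#'
#' Linear interpolation along the polygonal perimeter at arc lengths
#' \eqn{k L / P} (\eqn{k = 0, \dots, P-1}) measured from the base landmark, so
#' the base landmark is always the first returned point.
#'
#' @param c a [contour].
#' @param P number of equally spaced points (default 500).
#' @return A `resampled_contour` (also a `contour`) with exactly `P` points
#'   and the base landmark at index 1.
#' @export
resample <- function(c, P = 500L) {
  P <- as.integer(P)
  if (P < 8L) stop("too few points")
  pts <- c$points
  n <- nrow(pts)
  ord <- c(c$base_index:n, seq_len(c$base_index - 1L))
  pts <- pts[ord, , drop = FALSE]
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  L <- sum(seg)
  if (L <= 0) stop("contour has zero perimeter")
  t <- c(0, cumsum(seg))
  target <- (0:(P - 1L)) * (L / P)
  i <- findInterval(target, t, rightmost.closed = TRUE)
  i[i >= length(t)] <- length(t) - 1L
  w <- (target - t[i]) / seg[i]
  out <- closed[i, , drop = FALSE] * (1 - w) + closed[i + 1L, , drop = FALSE] * w
  structure(list(points = out, base_index = 1L, view = c$view, P = P),
            class = c("resampled_contour", "contour"))
}

#' Seed size and shape-index measurements
#'
#' Length is the longest Euclidean distance from the base landmark to any
#' contour point in the front view. Width (front view) and thickness (side
#' view) are coordinate ranges on the axis perpendicular to each view's
#' base-landmark-to-farthest-point direction (ties among farthest points
#' broken by smallest index). Areas are foreground pixel counts supplied by
#' the caller.
#'
#' @param front,side resampled contours of the two views (base landmark at
#'   index 1).
#' @param front_area_px,side_area_px foreground pixel counts of the two views.
#' @return A list of class `seed_measurements` with fields `area_front`,
#'   `area_side`, `length`, `width`, `thickness`, `length_width_ratio`,
#'   `length_thickness_ratio`.
#' @export
measure <- function(front, side, front_area_px = NA_real_, side_area_px = NA_real_) {
  perp_range <- function(rc) {
    p <- rc$points
    base <- p[1L, ]
    d2 <- (p[, 1L] - base[1L])^2 + (p[, 2L] - base[2L])^2
    far <- which.max(d2)                       # which.max takes the first tie
    len <- sqrt(d2[far])
    if (len <= 0) stop("degenerate contour")
    u <- (p[far, ] - base) / len               # length axis
    v <- c(-u[2L], u[1L])                      # perpendicular axis
    proj <- (p[, 1L] - base[1L]) * v[1L] + (p[, 2L] - base[2L]) * v[2L]
    r <- diff(range(proj))
    if (r <= 0) stop("degenerate contour")
    list(length = len, range = r)
  }
  f <- perp_range(front)
  s <- perp_range(side)
  structure(list(area_front = front_area_px, area_side = side_area_px,
                 length = f$length, width = f$range, thickness = s$range,
                 length_width_ratio = f$length / f$range,
                 length_thickness_ratio = f$length / s$range),
            class = "seed_measurements")
}
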