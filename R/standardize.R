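# Direction/scale standardization of resampled contours.
#
# Four procedures are provided, each with scaling on or off:
#   SL   - align by the base landmark and the centroid;
#   GPA  - iterative generalized Procrustes superposition (rotation only,
#          reflections forbidden), points matched by index;
#   FESA - align by the first-harmonic ellipse, trace start relocated to the
#          semi-major axis endpoint;
#   FESL - FESA's rotation/scale, but the base landmark stays the start.
# With scaling on the reference distance c is 1 (landmark distance for SL,
# semi-major length for FESA/FESL, unit centroid size for GPA).

# rotation matrix acting on row-vector points: p %*% rot2(theta) rotates
# counter-clockwise by theta
rot2 <- function(theta) matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)

new_standardized <- function(points, procedure, scale, c_ref, view,
                             base_index = 1L, start_moved = FALSE) {
  structure(list(points = points, base_index = as.integer(base_index),
                 view = view,
                 config = list(procedure = procedure, scale = scale, c = c_ref),
                 start_moved = start_moved),
            class = c("standardized_contour", "contour"))
}

#' Simple-landmark (SL) standardization
#'
#' Translates the centroid to the origin and rotates the contour so the base
#' landmark lies on the positive x-axis. With `scale = TRUE` coordinates are
#' divided by the landmark-centroid distance, putting the base landmark at
#' (1, 0); otherwise it lands at (d, 0) where d is the original distance.
#'
#' @param c a `resampled_contour` (base landmark first).
#' @param scale logical; standardize scale as well as direction.
#' @return A `standardized_contour`.
#' @export
standardize_sl <- function(c, scale = TRUE) {
  p <- sweep(c$points, 2L, colMeans(c$points))
  base <- p[1L, ]
  d <- sqrt(sum(base^2))
  if (d < 1e-12) stop("degenerate landmark")
  theta <- atan2(base[2L], base[1L])
  p <- p %*% rot2(-theta)              # rotate base onto angle 0
  c_ref <- if (scale) { p <- p / d; 1 } else d
  new_standardized(p, "SL", scale, c_ref, c$view)
}

#' First-harmonic ellipse parameters of a contour
#'
#' Fits the first elliptic-Fourier harmonic under the arc-length
#' parameterization and reports the parameter offset of the semi-major axis
#' (`theta1`), the spatial rotation of the ellipse (`psi1`), and the
#' semi-major/semi-minor lengths (`E >= e`). For a (near-)circular contour
#' the orientation is undefined and `psi1`/`theta1` are reported as 0.
#'
#' @param c a `resampled_contour`.
#' @return List with `theta1`, `psi1`, `E`, `e`.
#' @export
first_harmonic_params <- function(c) {
  ef <- efd_from_contour(c, 1L)
  a1 <- ef$coef[1L, 1L]; b1 <- ef$coef[1L, 2L]
  c1 <- ef$coef[1L, 3L]; d1 <- ef$coef[1L, 4L]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-24) stop("degenerate (point-mass) contour")
  theta1 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  axes_at <- function(th) {
    aa <- a1 * cos(th) + b1 * sin(th)
    cc <- c1 * cos(th) + d1 * sin(th)
    c(sqrt(aa^2 + cc^2), atan2(cc, aa))
  }
  major <- axes_at(theta1)
  minor <- axes_at(theta1 + pi / 2)
  if (minor[1L] > major[1L]) {         # ensure theta1 points at the major axis
    theta1 <- theta1 + pi / 2
    tmp <- major; major <- minor; minor <- tmp
  }
  E <- major[1L]; e <- minor[1L]; psi1 <- major[2L]
  if (E <= 0 || e <= 0) stop("degenerate (point-mass) contour")
  if (abs(E / e - 1) < 1e-9) { psi1 <- 0; theta1 <- 0 }   # circular: convention
  list(theta1 = as.numeric(theta1), psi1 = as.numeric(psi1),
       E = as.numeric(E), e = as.numeric(e))
}

# Shared FESA/FESL transform: center on the harmonic-ellipse center (the
# position terms A0, C0), rotate the semi-major axis onto the x-axis, resolve
# the 180-degree ambiguity by sending the base landmark's image into the
# right half-plane (tie exactly on the y-axis: smaller |rotation|), and
# optionally scale by the semi-major length.
fes_transform <- function(c, scale) {
  par <- first_harmonic_params(c)
  if (par$E / par$e < 1.01)
    warning("unstable orientation: contour is nearly circular")
  ef <- efd_from_contour(c, 1L)
  ctr <- ef$dc
  p0 <- sweep(c$points, 2L, ctr)
  wrap <- function(a) atan2(sin(a), cos(a))
  phis <- wrap(c(-par$psi1, -par$psi1 + pi))
  base1 <- p0[1L, ] %*% rot2(phis[1L])
  phi <- if (abs(base1[1L]) < 1e-12) {
    phis[which.min(abs(phis))]
  } else if (base1[1L] > 0) phis[1L] else phis[2L]
  p <- p0 %*% rot2(phi)
  c_ref <- if (scale) { p <- p / par$E; 1 } else par$E
  list(points = p, c_ref = c_ref, phi = phi, par = par)
}

#' First-ellipse standardization with semi-major start (FESA)
#'
#' Rotates and (optionally) scales the contour so the terminal points of the
#' first-harmonic semi-major axis sit at (-c, 0) and (c, 0), then cyclically
#' shifts the start point to the resampled vertex nearest the (+c, 0)
#' endpoint. The base landmark's new index is retained in `base_index`.
#'
#' @inheritParams standardize_sl
#' @return A `standardized_contour` with `start_moved = TRUE`.
#' @export
standardize_fesa <- function(c, scale = TRUE) {
  tr <- fes_transform(c, scale)
  p <- tr$points
  n <- nrow(p)
  i0 <- which.min((p[, 1L] - tr$c_ref)^2 + p[, 2L]^2)
  ordr <- c(i0:n, seq_len(i0 - 1L))
  base_new <- ((1L - i0) %% n) + 1L    # where the old start (base) ends up
  out <- new_standardized(p[ordr, , drop = FALSE], "FESA", scale, tr$c_ref,
                          c$view, base_index = base_new, start_moved = TRUE)
  attr(out, "rotation") <- tr$phi
  out
}

#' First-ellipse standardization with base-landmark start (FESL)
#'
#' Identical rotation, centering and scaling to [standardize_fesa()], but
#' the trace start stays at the base landmark.
#'
#' @inheritParams standardize_sl
#' @return A `standardized_contour`.
#' @export
standardize_fesl <- function(c, scale = TRUE) {
  tr <- fes_transform(c, scale)
  out <- new_standardized(tr$points, "FESL", scale, tr$c_ref, c$view)
  attr(out, "rotation") <- tr$phi
  out
}

#' Generalized Procrustes superposition of a contour set
#'
#' Points are matched by index (all contours start at the base landmark).
#' Each contour is centered; with `scale = TRUE` it is scaled to unit
#' centroid size; contours are then iteratively rotated onto the current
#' consensus by the optimal rotation (reflections forbidden) and the
#' consensus (pointwise mean) is recomputed until it moves by less than
#' `tol`. The sum of squared distances to the consensus is non-increasing
#' across iterations.
#'
#' @param cs list of `resampled_contour`s sharing the same `P`.
#' @param scale logical; normalize centroid size to 1.
#' @param tol convergence tolerance on the consensus displacement.
#' @param max_iter maximum number of iterations (warning if exceeded).
#' @return A `superposition_set`: coordinate matrices `X`, `Y`
#'   (contours x points), the `consensus`, the per-iteration `objective`
#'   trace, and the standardization config.
#' @export
standardize_gpa <- function(cs, scale = TRUE, tol = 1e-10, max_iter = 200L) {
  if (length(cs) < 2L) stop("GPA needs at least 2 contours")
  P <- nrow(cs[[1L]]$points)
  if (!all(vapply(cs, function(ci) nrow(ci$points), 0L) == P))
    stop("all contours must share the same number of points")
  n <- length(cs)
  X <- t(vapply(cs, function(ci) ci$points[, 1L], numeric(P)))
  Y <- t(vapply(cs, function(ci) ci$points[, 2L], numeric(P)))
  X <- X - rowMeans(X); Y <- Y - rowMeans(Y)
  if (scale) {
    cs_size <- sqrt(rowSums(X^2 + Y^2))
    X <- X / cs_size; Y <- Y / cs_size
  }
  Cx <- X[1L, ]; Cy <- Y[1L, ]         # initial consensus: first contour
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sc <- X %*% Cx + Y %*% Cy          # per-contour rotation to consensus
    ss <- X %*% Cy - Y %*% Cx
    th <- atan2(ss, sc)
    ct <- as.numeric(cos(th)); st <- as.numeric(sin(th))
    Xn <- ct * X - st * Y
    Yn <- st * X + ct * Y
    X <- Xn; Y <- Yn
    Cx_new <- colMeans(X); Cy_new <- colMeans(Y)
    objective <- c(objective,
                   sum(sweep(X, 2L, Cx_new)^2) + sum(sweep(Y, 2L, Cy_new)^2))
    delta <- sqrt(sum((Cx_new - Cx)^2 + (Cy_new - Cy)^2))
    Cx <- Cx_new; Cy <- Cy_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GPA did not converge in ", max_iter,
                          " iterations; returning best iterate")
  views <- vapply(cs, function(ci) ci$view, "")
  structure(list(X = X, Y = Y, P = P,
                 consensus = cbind(x = Cx, y = Cy),
                 objective = objective, converged = converged,
                 config = list(procedure = "GPA", scale = scale, c = 1),
                 views = views, ids = names(cs), start_moved = FALSE),
            class = "superposition_set")
}

#' @export
print.superposition_set <- function(x, ...) {
  cat(sprintf("<superposition_set> %d contours x %d points, %s%s\n",
              nrow(x$X), x$P, x$config$procedure,
              if (x$config$scale) " (scaled)" else ""))
  invisible(x)
}

#' Standardize a set of contours with any procedure
#'
#' Applies the chosen direction/scale standardization to every contour and
#' packs the results into a `superposition_set` (the container used by
#' [descriptor_matrix()]).
#'
#' @param cs named list of `resampled_contour`s with a common `P`.
#' @param procedure one of `"SL"`, `"GPA"`, `"FESA"`, `"FESL"`.
#' @param scale logical scale-standardization flag.
#' @param ... further arguments to [standardize_gpa()].
#' @return A `superposition_set`.
#' @export
standardize_set <- function(cs, procedure = c("GPA", "SL", "FESA", "FESL"),
                            scale = TRUE, ...) {
  procedure <- match.arg(procedure)
  if (procedure == "GPA") return(standardize_gpa(cs, scale = scale, ...))
  f <- switch(procedure, SL = standardize_sl,
              FESA = standardize_fesa, FESL = standardize_fesl)
  std <- lapply(cs, f, scale = scale)
  P <- nrow(std[[1L]]$points)
  X <- t(vapply(std, function(s) s$points[, 1L], numeric(P)))
  Y <- t(vapply(std, function(s) s$points[, 2L], numeric(P)))
  structure(list(X = X, Y = Y, P = P, consensus = NULL, objective = NULL,
                 converged = TRUE,
                 config = std[[1L]]$config,
                 views = vapply(std, function(s) s$view, ""),
                 ids = names(cs),
                 start_moved = std[[1L]]$start_moved),
            class = "superposition_set")
}

#' Extract one standardized contour from a superposition set
#'
#' @param set a `superposition_set`.
#' @param i contour index or name.
#' @return A `standardized_contour`.
#' @export
set_contour <- function(set, i) {
  if (is.character(i)) i <- match(i, set$ids)
  new_standardized(cbind(x = set$X[i, ], y = set$Y[i, ]),
                   set$config$procedure, set$config$scale, set$config$c,
                   set$views[i], start_moved = isTRUE(set$start_moved))
}
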