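# Genomic prediction machinery: MAF filtering, the additive (VanRaden)
# relationship matrix, REML variance components (efficient spectral form
# for one kernel, fixed-point score iteration for several), and
# GBLUP / multi-kernel Gaussian RKHS fit-and-predict.

#' Construct a genotype matrix
#'
#' @param geno lines x markers matrix with codes 0/1/2 (copies of the
#'   counted allele); rownames are line ids, colnames marker ids.
#' @param map data frame with one row per marker: columns `marker`, `chr`,
#'   `pos`. Sorted by (chr, pos) on ingest.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0, 1, 2))) stop("genotype codes must be 0, 1 or 2")
  if (is.null(map))
    map <- data.frame(marker = colnames(geno) %||% paste0("m", seq_len(ncol(geno))),
                      chr = 1L, pos = seq_len(ncol(geno)))
  if (nrow(map) != ncol(geno)) stop("map must describe every marker")
  ord <- order(map$chr, map$pos)
  structure(list(geno = geno[, ord, drop = FALSE], map = map[ord, , drop = FALSE]),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers, %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

#' Minor allele frequencies
#'
#' @param g a `genotype_matrix`.
#' @return Numeric vector of per-marker MAF.
#' @export
maf <- function(g) {
  p <- colMeans(g$geno) / 2
  pmin(p, 1 - p)
}

#' Filter markers by minor allele frequency
#'
#' Retains markers with MAF strictly greater than `threshold` (default
#' 0.03, the conventional cutoff for diversity panels).
#'
#' @param g a `genotype_matrix`.
#' @param threshold MAF cutoff.
#' @return A filtered `genotype_matrix`.
#' @export
maf_filter <- function(g, threshold = 0.03) {
  keep <- maf(g) > threshold
  if (!any(keep)) stop("all markers removed by the MAF filter")
  genotype_matrix(g$geno[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
}

#' Additive genomic relationship matrix
#'
#' VanRaden's first method: marker codes are centered by twice the allele
#' frequency and \eqn{A = W W' / (2 \sum_j p_j (1 - p_j))}.
#'
#' @param g a `genotype_matrix` (MAF-filtered).
#' @return Symmetric lines x lines `kinship` matrix (attribute
#'   `kind = "A"`).
#' @export
additive_relationship <- function(g) {
  p <- colMeans(g$geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: relationship undefined")
  W <- sweep(g$geno, 2L, 2 * p)
  A <- tcrossprod(W) / denom
  A <- (A + t(A)) / 2
  attr(A, "kind") <- "A"
  A
}

#' Gaussian kernels for RKHS regression
#'
#' Kernels \eqn{K_h = \exp(-h D)} with D the squared Euclidean distance
#' matrix between line genotype vectors and bandwidths \eqn{h = X / M},
#' where X ranges over `x_set` and M is the median squared distance between
#' lines (the kernel-averaging rule of multi-kernel RKHS).
#'
#' @param g a `genotype_matrix`.
#' @param x_set bandwidth multipliers (default 1/5, 1, 5).
#' @return List with `kernels` (list of matrices), `h`, `M`, `D`.
#' @export
gaussian_kernels <- function(g, x_set = c(1 / 5, 1, 5)) {
  D <- as.matrix(stats::dist(g$geno))^2
  M <- stats::median(D[upper.tri(D)])
  if (!is.finite(M) || M <= 0) stop("degenerate genotype distances: M <= 0")
  h <- x_set / M
  kernels <- lapply(h, function(hi) exp(-hi * D))
  list(kernels = kernels, h = h, M = M, D = D)
}

# Single-kernel REML via the spectral decomposition of K (EMMA-style).
# Model: y = X b + u + e, u ~ (0, su2 K), e ~ (0, se2 I).  The REML
# criterion is profiled over lambda = su2/se2 and minimized by 1D search,
# which is deterministic and has no convergence failures.
reml_kernel <- function(y, K, X = matrix(1, length(y), 1L), eig = NULL,
                        interval = c(-14, 14)) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  crit <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    b <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    se2 <- rss / (n - p)
    (n - p) * log(se2) + sum(log(lam * d + 1)) + determinant(XtWX)$modulus[1L]
  }
  opt <- stats::optimize(crit, interval = interval, tol = 1e-8)
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  b <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  se2 <- sum(w * r^2) / (n - p)
  su2 <- lam * se2
  # BLUP of u on the training lines: su2 K V^{-1} (y - Xb)
  Vinv_r <- U %*% (w * r) / se2
  u <- su2 * (K %*% Vinv_r)
  list(lambda = lam, sigma_u2 = su2, sigma_e2 = se2, beta = as.numeric(b),
       u = as.numeric(u), Vinv_resid = as.numeric(Vinv_r), eig = eig,
       reml = -opt$objective / 2)
}

# Multi-kernel REML by fixed-point iteration on the REML score equations
# (y'P K_k P y = tr(P K_k) at the optimum); multiplicative updates with a
# floor keep every component positive.
reml_multikernel <- function(y, kernels, X = matrix(1, length(y), 1L),
                             max_iter = 200L, tol = 1e-6) {
  n <- length(y)
  nk <- length(kernels)
  vy <- stats::var(y)
  s2 <- rep(vy / (nk + 1), nk + 1L)      # kernel components then residual
  floor_s2 <- 1e-8 * vy
  for (it in seq_len(max_iter)) {
    V <- diag(s2[nk + 1L], n)
    for (k in seq_len(nk)) V <- V + s2[k] * kernels[[k]]
    Vinv <- chol2inv(chol(V))
    VX <- Vinv %*% X
    P <- Vinv - VX %*% solve(crossprod(X, VX), t(VX))
    Py <- P %*% y
    s2_new <- s2
    for (k in seq_len(nk)) {
      num <- as.numeric(crossprod(Py, kernels[[k]] %*% Py))
      den <- sum(P * kernels[[k]])
      if (den > 0 && num > 0) s2_new[k] <- max(s2[k] * sqrt(num / den), floor_s2)
    }
    num <- sum(Py^2); den <- sum(diag(P))
    if (den > 0 && num > 0) s2_new[nk + 1L] <- max(s2[nk + 1L] * sqrt(num / den), floor_s2)
    delta <- max(abs(s2_new - s2) / (abs(s2) + floor_s2))
    s2 <- s2_new
    if (delta < tol) break
  }
  V <- diag(s2[nk + 1L], n)
  for (k in seq_len(nk)) V <- V + s2[k] * kernels[[k]]
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  b <- solve(crossprod(X, VX), crossprod(VX, y))
  r <- y - X %*% b
  list(sigma2 = s2[seq_len(nk)], sigma_e2 = s2[nk + 1L], beta = as.numeric(b),
       Vinv_resid = as.numeric(Vinv %*% r), iterations = it,
       converged = delta < tol)
}

#' GBLUP: fit on training lines, predict test lines
#'
#' Mixed model \eqn{y = \mu + u + e}, \eqn{u \sim (0, \sigma_u^2 K)},
#' \eqn{e \sim (0, \sigma_e^2 I)}. Variance components are estimated by
#' REML on the training subset (profiled spectral form, deterministic);
#' test-line breeding values come from the kinship cross-block:
#' \eqn{\hat u_{test} = \sigma_u^2 K_{te,tr} V_{tr}^{-1} (y_{tr} - \mu)}.
#'
#' @param y numeric phenotype vector over all lines (only `train_idx`
#'   entries are used for fitting).
#' @param K lines x lines kinship matrix.
#' @param train_idx,test_idx integer (or logical) indices into `y`.
#' @return List with `pred` (predictions for `test_idx`), `fit` (training
#'   REML fit) and `h2_hat`.
#' @export
gblup_fit_predict <- function(y, K, train_idx, test_idx) {
  train_idx <- to_idx(train_idx, length(y)); test_idx <- to_idx(test_idx, length(y))
  fit <- reml_kernel(y[train_idx], K[train_idx, train_idx, drop = FALSE])
  u_test <- fit$sigma_u2 * (K[test_idx, train_idx, drop = FALSE] %*% fit$Vinv_resid)
  list(pred = as.numeric(fit$beta[1L] + u_test), fit = fit,
       h2_hat = fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2))
}

#' Multi-kernel Gaussian RKHS: fit on training lines, predict test lines
#'
#' One variance component per Gaussian kernel (bandwidths h = X/M over
#' `x_set`) plus a residual, estimated by REML score iteration on the
#' training subset; prediction uses the variance-weighted kernel sum.
#'
#' @inheritParams gblup_fit_predict
#' @param g a `genotype_matrix` (kernels are built from all lines so the
#'   test cross-blocks exist).
#' @param x_set bandwidth multipliers, default `c(1/5, 1, 5)`.
#' @return List with `pred`, `fit`, `kernel_weights`.
#' @export
rkhs_fit_predict <- function(y, g, train_idx, test_idx, x_set = c(1 / 5, 1, 5)) {
  train_idx <- to_idx(train_idx, length(y)); test_idx <- to_idx(test_idx, length(y))
  gk <- gaussian_kernels(g, x_set)
  ktr <- lapply(gk$kernels, function(K) K[train_idx, train_idx, drop = FALSE])
  fit <- reml_multikernel(y[train_idx], ktr)
  u_test <- numeric(length(test_idx))
  for (k in seq_along(gk$kernels)) {
    u_test <- u_test + fit$sigma2[k] *
      as.numeric(gk$kernels[[k]][test_idx, train_idx, drop = FALSE] %*% fit$Vinv_resid)
  }
  list(pred = as.numeric(fit$beta[1L] + u_test), fit = fit,
       kernel_weights = fit$sigma2 / sum(fit$sigma2))
}

to_idx <- function(i, n) {
  if (is.logical(i)) which(i) else as.integer(i)
}
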